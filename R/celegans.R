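#' Construct an embryo snapshot
#'
#' A snapshot of an embryo at one developmental stage: named cells, each
#' carrying a discrete state label (derived from booleanized gene
#' expression; labels follow the convention of naming a state by the
#' lower-case name of the first cell entering it) and an undirected
#' cell-contact graph.  Unlike the one-dimensional tissue, contacts form a
#' general graph, so neighbour information is an unordered multiset of
#' neighbouring states.
#'
#' @param cells character vector of unique cell names (lineage
#'   nomenclature, e.g. `ABa`, `ABp`, `EMS`, `P2`).
#' @param states character vector of state labels, one per cell.
#' @param contacts two-column matrix or data frame of cell-name pairs;
#'   stored symmetrically.
#' @param stage optional stage label (e.g. `"4-cell"`).
#' @return An object of class `embryo_snapshot`.
#' @export
embryo_snapshot <- function(cells, states, contacts, stage = NULL) {
  cells <- as.character(cells)
  if (anyDuplicated(cells)) stop("cell names must be unique")
  if (length(states) != length(cells))
    stop("one state label per cell is required")
  contacts <- as.matrix(contacts)
  if (ncol(contacts) != 2) stop("contacts must have two columns")
  unknown <- setdiff(c(contacts), cells)
  if (length(unknown))
    stop("contact names not in the cell list: ",
         paste(unique(unknown), collapse = ", "))
  structure(list(cells = cells, states = as.character(states),
                 contacts = contacts, stage = stage),
            class = "embryo_snapshot")
}

#' @export
print.embryo_snapshot <- function(x, ...) {
  cat(sprintf("Embryo snapshot%s: %d cells, %d states, %d contacts\n",
              if (is.null(x$stage)) "" else paste0(" (", x$stage, ")"),
              length(x$cells), length(unique(x$states)), nrow(x$contacts)))
  cat(" ", paste(sprintf("%s=%s", x$cells, x$states), collapse = " "), "\n")
  invisible(x)
}

neighbour_names <- function(snapshot, cell) {
  ct <- snapshot$contacts
  c(ct[ct[, 1] == cell, 2], ct[ct[, 2] == cell, 1])
}

#' Built-in early C. elegans embryo snapshots
#'
#' `celegans_four_cell()` returns the 4-cell stage before and after the
#' Notch-Delta signalling event: cells ABa, ABp (both in the inherited
#' "ab" state, expressing the Notch receptor), EMS ("ems") and P2 ("p2",
#' expressing the Delta ligand).  P2 contacts ABp and EMS but not ABa;
#' ABa, ABp and EMS touch each other.  After the event ABa — the AB
#' daughter lacking P2 contact — has transitioned to "aba" while
#' P2-contacted ABp is held in "ab".
#'
#' `celegans_twelve_cell()` returns a 12-cell-stage snapshot built around
#' the two fate-specification examples at that stage: the four ABal/ABar
#' granddaughters inherit "aba" and the four ABpl/ABpr granddaughters
#' inherit "ab"; ABalp contacts MS, and ABarp and ABpra both contact C,
#' but only ABarp (inheriting "aba") responds to that contact.
#'
#' Both snapshots are constructed in code from the in-text account of the
#' embryo; they are working fixtures, not the full supplementary
#' expression/contact tables.
#'
#' @param after_notch for the 4-cell snapshot, return the state after the
#'   Notch-Delta event (default `FALSE`).
#' @return An [embryo_snapshot()].
#' @export
celegans_four_cell <- function(after_notch = FALSE) {
  contacts <- rbind(c("ABa", "ABp"), c("ABa", "EMS"), c("ABp", "EMS"),
                    c("ABp", "P2"), c("EMS", "P2"))
  states <- if (after_notch) c("aba", "ab", "ems", "p2")
            else c("ab", "ab", "ems", "p2")
  embryo_snapshot(c("ABa", "ABp", "EMS", "P2"), states, contacts,
                  stage = if (after_notch) "4-cell post-Notch" else "4-cell")
}

#' @rdname celegans_four_cell
#' @param after_contact return the 12-cell snapshot after the
#'   contact-driven transitions (ABalp to "abalp", ABarp to "abarp").
#' @export
celegans_twelve_cell <- function(after_contact = FALSE) {
  cells <- c("ABala", "ABalp", "ABara", "ABarp",
             "ABpla", "ABplp", "ABpra", "ABprp",
             "MS", "E", "C", "P3")
  states <- c("aba", "aba", "aba", "aba",
              "ab", "ab", "ab", "ab",
              "ms", "e", "c", "p3")
  if (after_contact) {
    states[cells == "ABalp"] <- "abalp"
    states[cells == "ABarp"] <- "abarp"
  }
  contacts <- rbind(
    c("ABala", "ABalp"), c("ABala", "ABara"),
    c("ABalp", "ABarp"), c("ABalp", "MS"),
    c("ABara", "ABarp"),
    c("ABarp", "C"), c("ABarp", "ABpra"),
    c("ABpla", "ABplp"), c("ABpla", "ABala"),
    c("ABplp", "ABpra"), c("ABplp", "MS"),
    c("ABpra", "C"), c("ABpra", "ABprp"),
    c("ABprp", "C"),
    c("MS", "E"), c("E", "P3"), c("C", "P3"))
  embryo_snapshot(cells, states, contacts,
                  stage = if (after_contact) "12-cell post-contact"
                          else "12-cell")
}

#' Load embryo snapshots from expression and contact tables
#'
#' Reads two delimited tables (TSV or CSV, header row required) in the
#' layout of the supplementary booleanized-expression and cell-contact
#' tables and assembles one [embryo_snapshot()] per stage.  The
#' expression table needs columns for the cell name and stage plus either
#' a `state` column of labels or one column per (booleanized) gene, in
#' which case states are derived as the distinct binary vectors; the
#' contact table needs columns for the stage and the two cell names.
#' Column names are configurable via `schema`, so tables with other
#' headers map on without editing.
#'
#' @param expression_path path to the expression table.
#' @param contact_path path to the contact table.
#' @param schema named list of column names: `cell`, `stage`, `state`
#'   (optional), `cell_a`, `cell_b`; gene columns are all remaining
#'   expression columns when `state` is absent.
#' @param sep field separator (default tab; use `","` for CSV).
#' @return A list of [embryo_snapshot()], ordered by increasing cell
#'   count.  Contacts naming cells absent from a stage's expression rows
#'   raise an error listing them.
#' @export
load_embryo_tables <- function(expression_path, contact_path,
                               schema = list(cell = "cell", stage = "stage",
                                             state = "state",
                                             cell_a = "cell_a",
                                             cell_b = "cell_b"),
                               sep = "\t") {
  expr <- utils::read.table(expression_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, comment.char = "#")
  ct <- utils::read.table(contact_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!nrow(expr)) stop("expression table is empty")
  for (col in c("cell", "stage"))
    if (!schema[[col]] %in% names(expr))
      stop("expression table lacks column '", schema[[col]], "'")
  for (col in c("stage", "cell_a", "cell_b"))
    if (!schema[[col]] %in% names(ct))
      stop("contact table lacks column '", schema[[col]], "'")

  stages <- unique(expr[[schema$stage]])
  snaps <- lapply(stages, function(sg) {
    ex <- expr[expr[[schema$stage]] == sg, , drop = FALSE]
    cells <- ex[[schema$cell]]
    if (!is.null(schema$state) && schema$state %in% names(ex)) {
      states <- ex[[schema$state]]
    } else {
      gcols <- setdiff(names(ex), unlist(schema))
      if (!length(gcols)) stop("no state or gene columns found")
      states <- apply(ex[gcols], 1, paste, collapse = "")
    }
    cc <- ct[ct[[schema$stage]] == sg, c(schema$cell_a, schema$cell_b),
             drop = FALSE]
    missing <- setdiff(unique(unlist(cc)), cells)
    if (length(missing))
      stop("stage ", sg, ": contacts name unknown cells: ",
           paste(missing, collapse = ", "))
    embryo_snapshot(cells, states, as.matrix(cc), stage = as.character(sg))
  })
  snaps[order(vapply(snaps, function(s) length(s$cells), integer(1)))]
}

#' Positional and potential information of embryo snapshots
#'
#' Positional information of a snapshot is the entropy of its state-label
#' frequencies (every cell occupies a unique position, so the conditional
#' term vanishes, exactly as for a single deterministic tissue).
#' Potential information generalizes the concatenated-matrix construction
#' to the contact graph: each cell's class is its own state together with
#' the unordered multiset of its neighbours' states, and the potential
#' information is the entropy of the class frequencies.
#'
#' @param snapshots an [embryo_snapshot()] or list of them.
#' @return Data frame: `stage`, `n_cells`, `pi_bits`, `potential_bits`.
#' @export
#' @examples
#' embryo_information_trace(celegans_four_cell())  # 1.5 bit PI, 2.0 bit potential
embryo_information_trace <- function(snapshots) {
  if (inherits(snapshots, "embryo_snapshot")) snapshots <- list(snapshots)
  rows <- lapply(snapshots, function(sn) {
    classes <- vapply(seq_along(sn$cells), function(i) {
      nb <- sort(sn$states[match(neighbour_names(sn, sn$cells[i]),
                                 sn$cells)])
      paste(sn$states[i], "|", paste(nb, collapse = ","))
    }, "")
    data.frame(stage = if (is.null(sn$stage)) NA_character_ else sn$stage,
               n_cells = length(sn$cells),
               pi_bits = shannon_entropy(table(sn$states)),
               potential_bits = shannon_entropy(table(classes)))
  })
  do.call(rbind, rows)
}

#' Check a lineage-plus-contact fate rule against a snapshot pair
#'
#' A fate rule says: a cell that inherited `from_state` and does
#' (`require_contact = TRUE`) or does not (`FALSE`) touch a cell in
#' `contact_state` transitions to `to_state`.  Applying the rule to a
#' "before" snapshot predicts each cell's next state; comparing against
#' an "after" snapshot shows that fate information uses both the
#' neighbours' states and the cell's own inherited state — cells in the
#' same contact situation but with different pedigrees respond
#' differently.
#'
#' @param before,after two [embryo_snapshot()]s with the same cells.
#' @param rule list with `from_state`, `contact_state`, `to_state`, and
#'   optionally `require_contact` (default `TRUE`).
#' @return Data frame: `cell`, `state`, `has_contact`, `predicted`,
#'   `observed`, `match`.
#' @export
#' @examples
#' rule <- list(from_state = "ab", contact_state = "p2",
#'              to_state = "aba", require_contact = FALSE)
#' contact_rule_check(celegans_four_cell(), celegans_four_cell(TRUE), rule)
contact_rule_check <- function(before, after, rule) {
  stopifnot(inherits(before, "embryo_snapshot"),
            inherits(after, "embryo_snapshot"),
            setequal(before$cells, after$cells))
  req <- if (is.null(rule$require_contact)) TRUE else rule$require_contact
  rows <- lapply(seq_along(before$cells), function(i) {
    cell <- before$cells[i]
    nb_states <- before$states[match(neighbour_names(before, cell),
                                     before$cells)]
    has <- rule$contact_state %in% nb_states
    fires <- before$states[i] == rule$from_state && (has == req)
    predicted <- if (fires) rule$to_state else before$states[i]
    observed <- after$states[match(cell, after$cells)]
    data.frame(cell = cell, state = before$states[i], has_contact = has,
               predicted = predicted, observed = observed,
               match = predicted == observed)
  })
  do.call(rbind, rows)
}
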