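#' Construct a tissue state
#'
#' A tissue is an ordered one-dimensional array of cells, each carrying a
#' binary gene-state vector.  Internally the states form the m x n matrix S
#' (rows = cells left to right, columns = genes).  Lineage ids trace the
#' pedigree (the founding cell is 1; the daughters of cell k are 2k and
#' 2k + 1), and `clock` counts updates elapsed in the current cell cycle
#' (used by the asynchronous-division module only).
#'
#' @param states binary matrix (m x n) or vector (one cell / one gene per
#'   entry for n = 1, or a single cell's gene vector via `ncell = 1`).
#' @param generation positive integer generation counter.
#' @param lineage integer lineage labels, one per cell.
#' @param clock non-negative integer update counters, one per cell.
#' @return An object of class `tissue_state` with fields `S`, `generation`,
#'   `lineage`, `clock`.
#' @export
#' @examples
#' tissue_state(matrix(c(1, 0, 0, 1), ncol = 1))
tissue_state <- function(states, generation = 1L, lineage = NULL, clock = NULL) {
  S <- as.matrix(states)
  if (!all(S %in% c(0, 1))) stop("gene states must be 0 or 1")
  storage.mode(S) <- "double"
  m <- nrow(S)
  if (m < 1) stop("a tissue needs at least one cell")
  if (is.null(lineage)) lineage <- seq_len(m)
  if (is.null(clock)) clock <- integer(m)
  if (length(lineage) != m || length(clock) != m)
    stop("lineage and clock must have one entry per cell")
  structure(list(S = S, generation = as.integer(generation),
                 lineage = as.integer(lineage), clock = as.integer(clock)),
            class = "tissue_state")
}

n_cells <- function(tissue) nrow(tissue$S)

#' @export
print.tissue_state <- function(x, ...) {
  m <- n_cells(x)
  n <- ncol(x$S)
  cat(sprintf("Tissue: %d cell%s, %d gene%s, generation %d\n",
              m, if (m > 1) "s" else "", n, if (n > 1) "s" else "",
              x$generation))
  cat(" ", paste(state_labels(x$S), collapse = " "), "\n")
  invisible(x)
}

# Composite-state code of each cell: base-2 reading of its gene vector
# (A + 2B + 4C ...). Shared by information, screening and attractor code.
state_codes <- function(S) {
  as.integer(S %*% 2^(seq_len(ncol(S)) - 1))
}

# Human-readable composite-state labels. For two genes the colour scheme is
# YELLOW (0,0), GREEN (1,0), RED (0,1), BLUE (1,1).
state_labels <- function(S) {
  n <- ncol(S)
  codes <- state_codes(S)
  if (n == 1) return(c("0", "1")[codes + 1])
  if (n == 2) return(c("Y", "G", "R", "B")[codes + 1])
  apply(S, 1, paste, collapse = "")
}

#' Cell-contact matrix of a one-dimensional tissue
#'
#' On a line of m cells the contact matrix C is the symmetric binary
#' tridiagonal matrix with `C[i, j] = 1` iff `|i - j| = 1`: every cell
#' touches its immediate neighbours only, and boundary cells have a single
#' contact.
#'
#' @param m number of cells.
#' @return m x m binary matrix.
#' @export
contact_matrix <- function(m) {
  C <- matrix(0, m, m)
  if (m >= 2) {
    idx <- seq_len(m - 1)
    C[cbind(idx, idx + 1)] <- 1
    C[cbind(idx + 1, idx)] <- 1
  }
  C
}

# Neighbour gene-state sums C.S for the line topology without forming C.
line_neighbor_sum <- function(S) {
  m <- nrow(S)
  if (m == 1) return(S * 0)
  rbind(0, S[-m, , drop = FALSE]) + rbind(S[-1, , drop = FALSE], 0)
}

check_contacts <- function(contacts, m) {
  if (is.null(contacts)) return(invisible(NULL))
  if (!is.matrix(contacts) || !all(dim(contacts) == c(m, m)))
    stop("contact matrix size does not match the tissue (", m, " cells)")
  invisible(NULL)
}

#' Concatenated state/contact matrix [S, C.S]
#'
#' The per-cell input available for a state decision: each row is a cell's
#' own gene states followed by the per-gene sums of its contacting
#' neighbours' states.  The entropy of the distinct rows of this matrix is
#' the tissue's potential information.
#'
#' @param tissue a [tissue_state()].
#' @param contacts optional m x m contact matrix; defaults to the line
#'   topology of [contact_matrix()].
#' @return m x 2n numeric matrix.
#' @export
#' @examples
#' t4 <- tissue_state(matrix(1, 4, 1))
#' concatenated_matrix(t4)  # rows [1|1], [1|2], [1|2], [1|1]
concatenated_matrix <- function(tissue, contacts = NULL) {
  S <- tissue$S
  check_contacts(contacts, nrow(S))
  nbr <- if (is.null(contacts)) line_neighbor_sum(S) else contacts %*% S
  cbind(S, nbr)
}

# Core synchronous Boolean step on a raw state matrix.
# H[i, p] = sum_q wi[p, q] S[i, q] + sum_q wt[p, q] (C.S)[i, q]  (+1 biased)
# new state: 1 if H > 0, 0 if H < 0, unchanged on ties.
# frozen: logical row mask of cells that never update (fixed boundary cell).
bool_step <- function(S, w_intra, w_inter, bias = 0, contacts = NULL,
                      frozen = NULL) {
  nbr <- if (is.null(contacts)) line_neighbor_sum(S) else contacts %*% S
  H <- tcrossprod(S, w_intra) + tcrossprod(nbr, w_inter) + bias
  out <- S
  out[H > 0] <- 1
  out[H < 0] <- 0
  if (!is.null(frozen) && any(frozen)) out[frozen, ] <- S[frozen, ]
  out
}

rule_bias <- function(network) {
  if (network$rule_variant == "biased_plus_one") 1 else 0
}

#' Synchronous tissue update
#'
#' Recomputes every gene of every cell from the previous tissue snapshot
#' (a Markov step): the weighted sum of intracellular and neighbour inputs
#' is thresholded at zero, with ties keeping the current state.  Under the
#' `biased_plus_one` rule variant the threshold is applied to the sum plus
#' one.  Cell count, lineage and generation are unchanged.
#'
#' @param network a [genetic_network()].
#' @param tissue a [tissue_state()] with matching gene count.
#' @param contacts optional contact matrix (default: line topology).
#' @param frozen optional logical vector marking cells whose state never
#'   changes (they still signal to neighbours).
#' @return The updated `tissue_state`.
#' @export
#' @examples
#' o1 <- canonical_networks("O1")
#' update_tissue(o1, tissue_state(matrix(1, 4, 1)))  # -> 1 0 0 1
update_tissue <- function(network, tissue, contacts = NULL, frozen = NULL) {
  S <- tissue$S
  if (ncol(S) != network$n_genes)
    stop("tissue has ", ncol(S), " genes but the network has ",
         network$n_genes)
  check_contacts(contacts, nrow(S))
  tissue$S <- bool_step(S, network$w_intra, network$w_inter,
                        rule_bias(network), contacts, frozen)
  tissue
}

#' Single-gene update
#'
#' The update of one gene in one cell, exposed mainly for didactic use and
#' oracle testing; [update_tissue()] performs the same computation for all
#' genes and cells at once.
#'
#' @inheritParams update_tissue
#' @param cell_index cell position (1-based, left to right).
#' @param gene_index gene index (1-based; gene A is 1).
#' @return The updated binary value of that gene.
#' @export
update_gene <- function(network, tissue, contacts = NULL,
                        cell_index, gene_index) {
  m <- n_cells(tissue)
  if (cell_index < 1 || cell_index > m) stop("cell_index out of range")
  if (gene_index < 1 || gene_index > network$n_genes)
    stop("gene_index out of range")
  check_contacts(contacts, m)
  up <- update_tissue(network, tissue, contacts)
  up$S[cell_index, gene_index]
}

#' Read and write tissue snapshots
#'
#' Tab-separated, one row per cell: `position`, `lineage_id`, then one
#' column per gene (`g1 ... gn`).  A `#`-prefixed header records the
#' generation.
#'
#' @param tissue a [tissue_state()].
#' @param path file path.
#' @return `write_tissue()` returns `path` invisibly; `read_tissue()` the
#'   `tissue_state`.
#' @export
write_tissue <- function(tissue, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# divdec tissue generation=%d", tissue$generation), con)
  df <- data.frame(position = seq_len(n_cells(tissue)),
                   lineage_id = tissue$lineage)
  g <- as.data.frame(tissue$S)
  names(g) <- paste0("g", seq_len(ncol(tissue$S)))
  utils::write.table(cbind(df, g), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tissue
#' @export
read_tissue <- function(path) {
  lines <- readLines(path)
  gen <- 1L
  hdr <- grep("^# divdec tissue", lines, value = TRUE)
  if (length(hdr))
    gen <- as.integer(sub(".*generation=(\\d+).*", "\\1", hdr[1]))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t")
  gcols <- grep("^g\\d+$", names(df))
  tissue_state(as.matrix(df[gcols]), generation = gen,
               lineage = df$lineage_id)
}
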