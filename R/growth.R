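#' Simultaneous cell division
#'
#' Every cell divides at once; each mother's two daughters are adjacent, in
#' the mother's original neighbourhood order, and both inherit the mother's
#' gene vector, so the state matrix is the mother matrix with every row
#' duplicated in place.  One daughter occupies the mother's position while
#' the sibling takes a random side (boundary mothers place it outward);
#' because daughters are state-identical this randomness affects lineage
#' labels only, never the state sequence.  Daughters of the cell with
#' lineage id k get ids 2k and 2k + 1; the generation counter increments.
#'
#' @param tissue a [tissue_state()].
#' @param keep logical vector marking cells that do not divide (a fixed
#'   boundary cell); default all divide.
#' @return The post-division `tissue_state`.
#' @export
#' @examples
#' divide(tissue_state(matrix(c(1, 0, 0, 1), ncol = 1)))
divide <- function(tissue, keep = NULL) {
  m <- n_cells(tissue)
  if (is.null(keep)) keep <- rep(FALSE, m)
  rows <- integer(0)
  lineage <- integer(0)
  for (i in seq_len(m)) {
    if (keep[i]) {
      rows <- c(rows, i)
      lineage <- c(lineage, tissue$lineage[i])
      next
    }
    k <- tissue$lineage[i]
    ids <- c(2L * k, 2L * k + 1L)
    side <- if (i == 1) "left"
            else if (i == m) "right"
            else sample(c("left", "right"), 1)
    if (side == "left") ids <- rev(ids)
    rows <- c(rows, i, i)
    lineage <- c(lineage, ids)
  }
  tissue_state(tissue$S[rows, , drop = FALSE],
               generation = tissue$generation + 1L,
               lineage = lineage,
               clock = integer(length(rows)))
}

#' Simulate division-decision growth
#'
#' Grows a one-dimensional tissue from a single cell: within each
#' generation the whole tissue is updated synchronously
#' `updates_per_generation` times (default 20, enough for the screened
#' networks to reach a within-generation fixed point), then all cells
#' divide simultaneously and the daughters inherit their mothers' states.
#' Every step is recorded, including the post-division snapshot that opens
#' each generation.
#'
#' An optional immutable boundary cell (`fixed_left`) is prepended at the
#' left end: it signals to its neighbour but never updates nor divides,
#' imposing an external asymmetry on the system.
#'
#' @param network a [genetic_network()].
#' @param init binary initial gene vector of the founding cell.
#' @param generations number of generations to simulate (the tissue ends
#'   with `2^(generations - 1)` dividing-lineage cells).
#' @param updates_per_generation synchronous updates per generation.
#' @param fixed_left optional binary gene vector of the immutable left
#'   boundary cell, or `NULL` for none.
#' @param seed optional integer seed for the (lineage-label-only) sibling
#'   placement randomness.
#' @return An object of class `div_trajectory`: a list with `steps` (list
#'   of [tissue_state()]), `stable` (per-step within-generation fixed-point
#'   flags), `generation_starts` (step indices of post-division snapshots),
#'   `oscillating` (per-generation flag: the generation never settled), and
#'   the run configuration.
#' @export
#' @examples
#' traj <- simulate_growth(canonical_networks("O1"), init = 1, generations = 3)
#' information_trace(display_steps(traj, 3))
simulate_growth <- function(network, init, generations,
                            updates_per_generation = 20,
                            fixed_left = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(init) != network$n_genes)
    stop("init must have one entry per gene")
  if (updates_per_generation < 1) stop("updates_per_generation must be >= 1")
  wi <- network$w_intra
  wt <- network$w_inter
  bias <- rule_bias(network)

  has_fixed <- !is.null(fixed_left)
  if (has_fixed && length(fixed_left) != network$n_genes)
    stop("fixed_left must have one entry per gene")
  S0 <- if (has_fixed) rbind(fixed_left, init) else rbind(init)
  dimnames(S0) <- NULL
  tissue <- tissue_state(S0, generation = 1L,
                         lineage = if (has_fixed) c(0L, 1L) else 1L)

  steps <- list(tissue)
  stable <- logical(0)
  gen_starts <- 1L
  oscillating <- logical(0)

  for (g in seq_len(generations)) {
    frozen <- if (has_fixed) c(TRUE, rep(FALSE, n_cells(tissue) - 1)) else NULL
    settled <- FALSE
    for (u in seq_len(updates_per_generation)) {
      nxt <- bool_step(tissue$S, wi, wt, bias, frozen = frozen)
      stable <- c(stable, identical(nxt, tissue$S))
      tissue$S <- nxt
      steps[[length(steps) + 1L]] <- tissue
      if (stable[length(stable)]) { settled <- TRUE }
    }
    # classify the generation's final state
    final_stable <- identical(bool_step(tissue$S, wi, wt, bias,
                                        frozen = frozen), tissue$S)
    stable <- c(stable, final_stable)
    oscillating <- c(oscillating, !settled && !final_stable)
    if (g < generations) {
      tissue <- divide(tissue, keep = if (has_fixed)
        c(TRUE, rep(FALSE, n_cells(tissue) - 1)) else NULL)
      steps[[length(steps) + 1L]] <- tissue
      gen_starts <- c(gen_starts, length(steps))
    }
  }
  # align stability flags with steps: flag i says steps[[i]] is a
  # within-generation fixed point.  Post-division snapshots get the flag
  # computed on entry to the next loop; recompute cleanly instead.
  stable <- vapply(seq_along(steps), function(i) {
    tis <- steps[[i]]
    frozen <- if (has_fixed) c(TRUE, rep(FALSE, n_cells(tis) - 1)) else NULL
    identical(bool_step(tis$S, wi, wt, bias, frozen = frozen), tis$S)
  }, logical(1))

  structure(list(steps = steps, stable = stable,
                 generation_starts = gen_starts,
                 oscillating = oscillating,
                 network = network,
                 config = list(init = init, generations = generations,
                               updates_per_generation = updates_per_generation,
                               fixed_left = fixed_left, seed = seed)),
            class = "div_trajectory")
}

#' @export
print.div_trajectory <- function(x, ...) {
  gens <- length(x$generation_starts)
  last <- x$steps[[length(x$steps)]]
  cat(sprintf("Division-decision trajectory: %d generations, %d recorded steps\n",
              gens, length(x$steps)))
  nm <- x$network$name
  if (!is.null(nm)) cat("  network:", nm, "\n")
  cat(sprintf("  final tissue (%d cells): %s\n", n_cells(last),
              paste(state_labels(last$S), collapse = " ")))
  cat(sprintf("  final positional information: %.2f bits\n",
              positional_information(last)))
  invisible(x)
}

# Final tissue of each generation (the state that divides).
generation_finals <- function(trajectory) {
  ends <- c(trajectory$generation_starts[-1] - 1L,
            length(trajectory$steps))
  lapply(ends, function(i) trajectory$steps[[i]])
}

#' Re-index a trajectory to a fixed number of displayed steps per generation
#'
#' The screened networks settle within a few updates of each generation, so
#' development patterns are conventionally displayed with a small fixed
#' number of steps per generation: each generation contributes its
#' post-division snapshot followed by `steps_per_generation - 1` updates.
#' With 3 steps per generation the single-gene O1 pattern's information
#' leap lands at displayed step 8; with 4 steps per generation the two-gene
#' T1 pattern leaps at steps 10 and 14.
#'
#' @param trajectory a [simulate_growth()] trajectory.
#' @param steps_per_generation displayed steps per generation (at most
#'   `updates_per_generation`).
#' @return A `div_trajectory` containing only the displayed steps.  If a
#'   generation has not settled within the displayed window a warning is
#'   issued and the truncation recorded in the `truncated` field.
#' @export
display_steps <- function(trajectory, steps_per_generation) {
  stopifnot(inherits(trajectory, "div_trajectory"))
  k <- steps_per_generation
  if (k < 1 || k > trajectory$config$updates_per_generation)
    stop("steps_per_generation must be in 1..updates_per_generation")
  starts <- trajectory$generation_starts
  ends <- c(starts[-1] - 1L, length(trajectory$steps))
  keep <- integer(0)
  truncated <- logical(length(starts))
  for (g in seq_along(starts)) {
    win <- starts[g]:min(starts[g] + k - 1L, ends[g])
    keep <- c(keep, win)
    # truncated if the window's last state differs from the generation's
    # final state
    truncated[g] <- !identical(trajectory$steps[[win[length(win)]]]$S,
                               trajectory$steps[[ends[g]]]$S)
  }
  if (any(truncated))
    warning("generation(s) ", paste(which(truncated), collapse = ", "),
            " not settled within the displayed window; pattern truncated")
  out <- trajectory
  out$steps <- trajectory$steps[keep]
  out$stable <- trajectory$stable[keep]
  out$generation_starts <- seq(1L, by = k, length.out = length(starts))
  out$truncated <- truncated
  out
}

#' Export a trajectory as a long-format table
#'
#' One row per (step, cell): `step`, `generation`, `position`,
#' `lineage_id`, then one column per gene.  A `#`-prefixed provenance
#' header records the network and configuration.
#'
#' @param trajectory a [simulate_growth()] trajectory.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  rows <- lapply(seq_along(trajectory$steps), function(i) {
    tis <- trajectory$steps[[i]]
    g <- as.data.frame(tis$S)
    names(g) <- paste0("g", seq_len(ncol(tis$S)))
    cbind(data.frame(step = i, generation = tis$generation,
                     position = seq_len(n_cells(tis)),
                     lineage_id = tis$lineage), g)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  nm <- trajectory$network$name
  writeLines(sprintf("# divdec trajectory network=%s generations=%d updates=%d",
                     if (is.null(nm)) network_id(trajectory$network) else nm,
                     trajectory$config$generations,
                     trajectory$config$updates_per_generation), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
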