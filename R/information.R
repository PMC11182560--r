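# Shannon entropy (bits) of a count or probability vector; 0 log 0 = 0.
shannon_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Positional information of a tissue
#'
#' Positional information is the mutual information between cell position
#' and composite cell state, `PI = H(state) - H(state | position)` in bits,
#' with positions weighted uniformly (1/m).  `H(state)` is the entropy of
#' the position-marginalized state distribution; `H(state | position)` is
#' the mean per-position conditional entropy estimated across replicate
#' tissues.  For a single deterministic tissue the conditional term is zero
#' and PI reduces to the Shannon entropy of the tissue's state frequencies.
#'
#' Estimates are plug-in (maximum likelihood); no small-sample bias
#' correction is applied.
#'
#' @param samples a single [tissue_state()] or a list of replicate tissues
#'   with identical cell and gene counts.
#' @return Positional information in bits.
#' @export
#' @examples
#' positional_information(tissue_state(matrix(c(1, 0, 0, 1), ncol = 1)))  # 1 bit
positional_information <- function(samples) {
  if (inherits(samples, "tissue_state")) samples <- list(samples)
  if (!length(samples)) stop("at least one tissue sample is required")
  dims <- vapply(samples, function(t) dim(t$S), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all samples must have the same numbers of cells and genes")
  m <- dims[1, 1]
  codes <- vapply(samples, function(t) state_codes(t$S), integer(m))
  codes <- matrix(codes, nrow = m)          # m x replicates
  h_marginal <- shannon_entropy(table(codes))
  h_cond <- mean(apply(codes, 1, function(x) shannon_entropy(table(x))))
  h_marginal - h_cond
}

#' Potential information of a tissue
#'
#' The entropy (bits) of the frequency distribution of distinct rows of the
#' concatenated matrix `[S, C.S]` — the information available to cells for
#' their next state decision, before the genetic network converts it (with
#' possible degeneracy) into actual state differences.
#'
#' @inheritParams concatenated_matrix
#' @return Potential information in bits.
#' @export
#' @examples
#' potential_information(tissue_state(matrix(1, 4, 1)))  # 1 bit
potential_information <- function(tissue, contacts = NULL) {
  rows <- apply(concatenated_matrix(tissue, contacts), 1, paste,
                collapse = ",")
  shannon_entropy(table(rows))
}

#' Per-step information trace of a trajectory
#'
#' Positional and potential information of every recorded step, together
#' with the generation, cell count and within-generation stability flag.
#' No monotonicity is assumed: information can rise at a division (the
#' contact matrix changes) and be converted into positional information by
#' subsequent updates.
#'
#' @param trajectory a [simulate_growth()] trajectory.
#' @return A data frame with columns `step`, `generation`, `m`, `pi_bits`,
#'   `potential_bits`, `stable`.
#' @export
information_trace <- function(trajectory) {
  stopifnot(inherits(trajectory, "div_trajectory"))
  rows <- lapply(seq_along(trajectory$steps), function(i) {
    tis <- trajectory$steps[[i]]
    data.frame(step = i,
               generation = tis$generation,
               m = n_cells(tis),
               pi_bits = positional_information(tis),
               potential_bits = potential_information(tis),
               stable = trajectory$stable[i])
  })
  do.call(rbind, rows)
}
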