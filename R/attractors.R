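# State-space enumeration at a fixed cell count.  A multicellular state of
# m cells and n genes is encoded as an integer in 0:(2^(nm) - 1): cell i's
# composite code (base-2 over genes) occupies base-2^n digit i - 1, with
# cell 1 (the left end) least significant.

all_state_matrix <- function(m, n) {
  N <- (2^n)^m
  idx <- 0:(N - 1)
  S <- matrix(0, N, m * n)
  for (i in seq_len(m)) {
    code <- (idx %/% (2^n)^(i - 1)) %% 2^n
    for (p in seq_len(n)) {
      S[, (p - 1) * m + i] <- (code %/% 2^(p - 1)) %% 2
    }
  }
  S  # column block p holds gene p across cells 1..m
}

encode_states <- function(S, n) {
  # S: m x n single-state matrix -> integer code
  m <- nrow(S)
  codes <- state_codes(S)
  sum(codes * (2^n)^(seq_len(m) - 1))
}

decode_state <- function(code, m, n) {
  S <- matrix(0, m, n)
  for (i in seq_len(m)) {
    c_i <- (code %/% (2^n)^(i - 1)) %% 2^n
    S[i, ] <- (c_i %/% 2^(seq_len(n) - 1)) %% 2
  }
  S
}

# Synchronous transition map over the whole state space, vectorized across
# states: returns for each state code the code of its successor.
transition_map <- function(network, m) {
  n <- network$n_genes
  N <- (2^n)^m
  if (N > 2^24) stop("state space of ", N, " states exceeds the ",
                     "enumeration guard (2^24); sample instead")
  wi <- network$w_intra
  wt <- network$w_inter
  bias <- rule_bias(network)
  G <- all_state_matrix(m, n)          # N x (m*n), gene-major blocks
  gene_block <- function(M, p) M[, (p - 1) * m + seq_len(m), drop = FALSE]
  nbr <- matrix(0, N, m * n)
  for (p in seq_len(n)) {
    B <- gene_block(G, p)
    nb <- cbind(0, B[, -m, drop = FALSE]) + cbind(B[, -1, drop = FALSE], 0)
    nbr[, (p - 1) * m + seq_len(m)] <- nb
  }
  new_code <- numeric(N)
  for (p in seq_len(n)) {
    H <- matrix(bias, N, m)
    for (q in seq_len(n)) {
      H <- H + wi[p, q] * gene_block(G, q) + wt[p, q] * gene_block(nbr, q)
    }
    B <- gene_block(G, p)
    newB <- B
    newB[H > 0] <- 1
    newB[H < 0] <- 0
    new_code <- new_code + newB %*% (2^(p - 1) * (2^n)^(seq_len(m) - 1))
  }
  as.numeric(new_code)
}

#' Fixed points of the synchronous dynamics at fixed cell count
#'
#' Enumerates every multicellular state of `m` cells (no division) and
#' returns those invariant under one synchronous update — the stable
#' multicellular states of the network at that size.
#'
#' @param network a [genetic_network()].
#' @param m cell count; the full `(2^n)^m` state space must not exceed
#'   `2^24` states.
#' @return Integer-code vector of fixed points (see [basin_sizes()] for
#'   the decoded report).
#' @export
#' @examples
#' length(find_fixed_points(canonical_networks("T1"), 2))  # 10
find_fixed_points <- function(network, m) {
  tm <- transition_map(network, m)
  which(tm == seq_along(tm) - 1) - 1
}

#' Basin-of-attraction report at fixed cell count
#'
#' Iterates the synchronous update from every initial state of an `m`-cell
#' tissue until a fixed point or limit cycle and tallies, for each fixed
#' point, its basin size (the number of initial states whose trajectory
#' converges to it; a fixed point reaches itself, so basins are at least
#' one).  States falling into limit cycles of period > 1 are excluded from
#' all basins and reported as cycle mass; basins plus cycle mass always
#' partition the `(2^n)^m` states exactly.
#'
#' @inheritParams find_fixed_points
#' @return An object of class `basin_report`: a list with `m`, `n_genes`,
#'   `fixed_points` (data frame `state`, `pattern`, `basin_size`,
#'   `pi_bits`), `cycle_mass`, `n_states`, and the network.
#' @export
#' @examples
#' basin_sizes(canonical_networks("T1"), 4)
basin_sizes <- function(network, m) {
  n <- network$n_genes
  tm <- transition_map(network, m)
  N <- length(tm)
  # functional-graph convergence by iterated map doubling: after k
  # doublings every state has advanced 2^k steps, past any transient
  dest <- tm + 1  # 1-based
  steps <- ceiling(log2(N)) + 1
  for (i in seq_len(steps)) dest <- dest[dest]
  fp <- which(tm == seq_len(N) - 1)        # 1-based positions of fixed points
  at_fp <- dest %in% fp
  basin <- tabulate(dest[at_fp], nbins = N)[fp]
  pats <- vapply(fp - 1, function(code) {
    S <- decode_state(code, m, n)
    paste(state_labels(S), collapse = "")
  }, "")
  pis <- vapply(fp - 1, function(code) {
    S <- decode_state(code, m, n)
    shannon_entropy(tabulate(state_codes(S) + 1L))
  }, numeric(1))
  df <- data.frame(state = fp - 1, pattern = pats, basin_size = basin,
                   pi_bits = pis)
  df <- df[order(-df$basin_size, df$state), ]
  rownames(df) <- NULL
  structure(list(m = m, n_genes = n, fixed_points = df,
                 cycle_mass = sum(!at_fp), n_states = N,
                 network = network),
            class = "basin_report")
}

#' @export
print.basin_report <- function(x, ...) {
  cat(sprintf("Basin report: %d cells, %d states, %d fixed points, cycle mass %d\n",
              x$m, x$n_states, nrow(x$fixed_points), x$cycle_mass))
  cat(sprintf("  largest basin %d, mean basin %.2f\n",
              max(x$fixed_points$basin_size),
              mean(x$fixed_points$basin_size)))
  print(utils::head(x$fixed_points, 5))
  if (nrow(x$fixed_points) > 5) cat("  ...\n")
  invisible(x)
}

#' Basin sizes of the states visited by a growing system
#'
#' For each generation of a division-decision trajectory, reports the
#' generation's settled state and the basin size and positional
#' information that state has within the full fixed-size enumeration at
#' that cell count — the "funnel" diagnostic: division escorts the system
#' into high-information fixed points whose basins are small relative to
#' the whole state space.
#'
#' @param network the [genetic_network()] that generated the trajectory.
#' @param trajectory a [simulate_growth()] trajectory of the same network.
#' @param max_cells largest cell count to enumerate (default 8).
#' @return A data frame: `generation`, `m`, `pattern`, `stable`,
#'   `basin_size`, `pi_bits` (basin columns `NA` where the generation did
#'   not settle or exceeds `max_cells`).
#' @export
trajectory_basin <- function(network, trajectory, max_cells = 8) {
  stopifnot(inherits(trajectory, "div_trajectory"))
  finals <- generation_finals(trajectory)
  rows <- lapply(seq_along(finals), function(g) {
    tis <- finals[[g]]
    m <- n_cells(tis)
    stable <- identical(update_tissue(network, tis)$S, tis$S)
    out <- data.frame(generation = g, m = m,
                      pattern = paste(state_labels(tis$S), collapse = ""),
                      stable = stable,
                      basin_size = NA_real_, pi_bits = NA_real_)
    if (stable && m <= max_cells) {
      rep <- basin_sizes(network, m)
      code <- encode_states(tis$S, network$n_genes)
      hit <- rep$fixed_points[rep$fixed_points$state == code, ]
      out$basin_size <- hit$basin_size
      out$pi_bits <- hit$pi_bits
    }
    out
  })
  do.call(rbind, rows)
}

#' Basin-size / information scatter table
#'
#' The per-fixed-point `(basin size, positional information)` table of a
#' [basin_sizes()] report, with the Spearman rank correlation between the
#' two attached as attribute `"rank_correlation"`.  For the screened
#' networks the trade-off lives in the upper tail: the maximal-information
#' fixed points never hold the largest basins, so a growing system must be
#' funnelled into them by division rather than by random initialization.
#'
#' @param report a [basin_sizes()] report.
#' @return Data frame `basin_size`, `pi_bits` (one row per fixed point).
#' @export
basin_info_scatter <- function(report) {
  stopifnot(inherits(report, "basin_report"))
  df <- report$fixed_points[, c("basin_size", "pi_bits")]
  rho <- if (nrow(df) > 2 && stats::sd(df$pi_bits) > 0)
    stats::cor(df$basin_size, df$pi_bits, method = "spearman")
  else NA_real_
  attr(df, "rank_correlation") <- rho
  df
}
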