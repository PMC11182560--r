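# Lean growth simulator used by the exhaustive screens.  Tracks, per run,
# the maximum positional information over all recorded steps, the maximum
# attained at a within-generation fixed point, and the step of first
# attainment (raw step index: post-division snapshots and every update
# count).  Within a generation the update loop exits early once the state
# is a fixed point (further updates are identical) or a period-2
# oscillation (the remaining states alternate; the final state is fixed by
# parity), which leaves the recorded dynamics unchanged.
screen_sim <- function(wi, wt, bias, init, generations = 5,
                       updates_per_generation = 20,
                       fixed_left = NULL, want_final = FALSE) {
  has_fixed <- !is.null(fixed_left)
  S <- if (has_fixed) rbind(fixed_left, init) else rbind(init)
  dimnames(S) <- NULL
  frozen_row <- if (has_fixed) 1L else 0L

  max_pi <- 0
  max_pi_stable <- 0
  step_at <- 1L
  step <- 1L
  osc <- FALSE
  final_stable <- FALSE

  pi_of <- function(S) shannon_entropy(tabulate(state_codes(S) + 1L))

  note <- function(pi, stable) {
    if (pi > max_pi + 1e-9) {
      max_pi <<- pi
      step_at <<- step
    }
    if (stable && pi > max_pi_stable + 1e-9) max_pi_stable <<- pi
  }

  frozen <- NULL
  for (g in seq_len(generations)) {
    if (has_fixed) frozen <- c(TRUE, rep(FALSE, nrow(S) - 1))
    prev <- NULL
    settled <- FALSE
    u <- 0L
    while (u < updates_per_generation) {
      nxt <- bool_step(S, wi, wt, bias, frozen = frozen)
      u <- u + 1L
      step <- step + 1L
      if (identical(nxt, S)) {
        # fixed point: this state (already noted) is stable; re-note it
        note(pi_of(S), TRUE)
        settled <- TRUE
        step <- step + (updates_per_generation - u)  # remaining identical steps
        break
      }
      if (!is.null(prev) && identical(nxt, prev)) {
        # period-2 oscillation: both states already noted, neither stable;
        # the generation's final state depends on parity of remaining steps
        remaining <- updates_per_generation - u
        if (remaining %% 2 == 1) nxt <- S
        step <- step + remaining
        osc <- TRUE
        S <- nxt
        note(pi_of(S), FALSE)
        break
      }
      prev <- S
      S <- nxt
      note(pi_of(S), FALSE)
    }
    final_stable <- settled ||
      identical(bool_step(S, wi, wt, bias, frozen = frozen), S)
    if (final_stable) note(pi_of(S), TRUE)
    if (g < generations) {
      keep <- if (has_fixed) c(1L, rep(2:nrow(S), each = 2)) else
        rep(seq_len(nrow(S)), each = 2)
      S <- S[keep, , drop = FALSE]
      step <- step + 1L
      note(pi_of(S), FALSE)
    }
  }
  out <- list(max_pi = max_pi, max_pi_stable = max_pi_stable,
              step = step_at, oscillating = osc,
              final_stable = final_stable)
  if (want_final) out$final <- S
  out
}

#' Enumerate all genetic networks of a given gene count
#'
#' There are `3^(2 n^2)` signed-ternary networks on n genes: 9 for one
#' gene, 6561 for two.  Networks are identified by the canonical integer
#' id of [network_id()]; ids round-trip through [decode_network()].
#'
#' @param n_genes number of genes (1 or 2 for exhaustive work; larger
#'   counts are allowed with a warning, as the space grows as `3^(2 n^2)`).
#' @return Integer vector of all network ids, `0:(3^(2 n_genes^2) - 1)`.
#' @export
enumerate_networks <- function(n_genes) {
  if (n_genes > 2)
    warning("3^(2 n^2) networks for n = ", n_genes,
            " is a very large enumeration; consider sampling")
  0:(3^(2 * n_genes^2) - 1)
}

#' Exhaustive max-information screen
#'
#' Simulates the division-decision growth of every n-gene network from
#' each supplied initial state and records the maximal positional
#' information each run attains, together with whether that maximum was
#' realized at a within-generation fixed point ("stable": the headline
#' counts of the screens refer to stable states) and the raw step of
#' first attainment.
#'
#' @param n_genes 1 or 2.
#' @param initial_states list of binary initial gene vectors (or a single
#'   vector).
#' @param generations generations per run (default 5).
#' @param updates_per_generation updates per generation (default 20).
#' @param rule_variant update rule applied to every network.
#' @param ids optional subset of network ids to screen (default: all).
#' @return A data frame of class `screen_result`: one row per network x
#'   initial state with columns `id`, `init`, `max_pi`, `max_pi_stable`,
#'   `step`, `oscillating`.
#' @export
#' @examples
#' sc <- screen(1, list(1, 0), generations = 5)
#' subset(sc, max_pi_stable >= 1)  # only O1, from init 1
screen <- function(n_genes, initial_states, generations = 5,
                   updates_per_generation = 20,
                   rule_variant = c("threshold_zero", "biased_plus_one"),
                   ids = NULL) {
  rule_variant <- match.arg(rule_variant)
  bias <- if (rule_variant == "biased_plus_one") 1 else 0
  if (!is.list(initial_states)) initial_states <- list(initial_states)
  if (any(vapply(initial_states, length, 1L) != n_genes))
    stop("each initial state must have one entry per gene")
  if (is.null(ids)) ids <- enumerate_networks(n_genes)

  init_lab <- vapply(initial_states, paste, "", collapse = "")
  nr <- length(ids) * length(initial_states)
  res <- data.frame(id = integer(nr), init = character(nr),
                    max_pi = numeric(nr), max_pi_stable = numeric(nr),
                    step = integer(nr), oscillating = logical(nr))
  r <- 0L
  for (id in ids) {
    net <- decode_network(id, n_genes, rule_variant)
    for (s in seq_along(initial_states)) {
      sim <- screen_sim(net$w_intra, net$w_inter, bias,
                        initial_states[[s]], generations,
                        updates_per_generation)
      r <- r + 1L
      res$id[r] <- id
      res$init[r] <- init_lab[s]
      res$max_pi[r] <- sim$max_pi
      res$max_pi_stable[r] <- sim$max_pi_stable
      res$step[r] <- sim$step
      res$oscillating[r] <- sim$oscillating
    }
  }
  attr(res, "n_genes") <- n_genes
  attr(res, "rule_variant") <- rule_variant
  class(res) <- c("screen_result", class(res))
  res
}

#' Regulatory motif flags of a two-gene network
#'
#' Pure predicates over the weight matrices:
#' * intracellular: `self_activation` (some diagonal `w_intra` entry +1),
#'   `self_inhibition` (-1), `cross_activation` / `cross_inhibition`
#'   (off-diagonal +1 / -1), `positive_feedback` / `negative_feedback`
#'   (the product of the two off-diagonal intracellular edges is +1 / -1);
#' * intercellular: `direct_lateral_activation` / `direct_lateral_inhibition`
#'   (diagonal `w_inter` entry +1 / -1), and `indirect_lateral_activation` /
#'   `indirect_lateral_inhibition` (a two-edge path on gene p via gene q:
#'   one membrane crossing `w_inter[q, p]` followed by the intracellular
#'   edge `w_intra[p, q]`, with net sign +1 / -1).
#'
#' @param network a [genetic_network()] (or a network id with `n_genes`).
#' @param n_genes gene count when `network` is an id.
#' @return Named logical vector of motif flags.
#' @export
motif_flags <- function(network, n_genes = 2) {
  if (!inherits(network, "genetic_network"))
    network <- decode_network(network, n_genes)
  wi <- network$w_intra
  wt <- network$w_inter
  n <- network$n_genes
  d <- seq_len(n)
  off <- which(row(wi) != col(wi))
  # indirect lateral paths: for each ordered pair p != q,
  # sign = w_inter[q, p] * w_intra[p, q]
  ind <- 0
  if (n > 1) {
    pq <- which(row(wi) != col(wi), arr.ind = TRUE)  # rows (p, q)
    ind <- wt[cbind(pq[, 2], pq[, 1])] * wi[pq]
  }
  c(self_activation = any(diag(wi) == 1),
    self_inhibition = any(diag(wi) == -1),
    cross_activation = length(off) > 0 && any(wi[off] == 1),
    cross_inhibition = length(off) > 0 && any(wi[off] == -1),
    positive_feedback = n > 1 && wi[1, 2] * wi[2, 1] == 1,
    negative_feedback = n > 1 && wi[1, 2] * wi[2, 1] == -1,
    direct_lateral_activation = any(diag(wt) == 1),
    direct_lateral_inhibition = any(diag(wt) == -1),
    indirect_lateral_activation = any(ind == 1),
    indirect_lateral_inhibition = any(ind == -1))
}

#' Motif-ratio table by maximal positional information
#'
#' Groups the networks of a screen by the maximal (stable) positional
#' information they attain and, within each group, reports the motif
#' ratio: the fraction of the group's networks carrying each regulatory
#' motif.  Also reports the group composition by lateral-inhibition class
#' (direct, indirect-only, none).  When records cover several initial
#' states, each network is placed by its maximum over them.
#'
#' @param records a [screen()] result (two-gene).
#' @param stable use the stable maximum (`max_pi_stable`, default) or the
#'   raw maximum (`max_pi`).
#' @return A data frame, one row per PI group: `max_pi`, `n_networks`, one
#'   column per motif ratio, and `direct_li` / `indirect_li_only` /
#'   `no_li` composition fractions.  The attribute `"correlations"` holds
#'   the Pearson correlation of each motif ratio with the group PI.
#' @export
motif_ratios <- function(records, stable = TRUE) {
  n_genes <- attr(records, "n_genes")
  pi_col <- if (stable) records$max_pi_stable else records$max_pi
  per_net <- tapply(pi_col, records$id, max)
  ids <- as.integer(names(per_net))
  pi_grp <- round(as.numeric(per_net), 6)

  flags <- t(vapply(ids, motif_flags, logical(10), n_genes = n_genes))
  groups <- sort(unique(pi_grp))
  rows <- lapply(groups, function(g) {
    in_g <- pi_grp == g
    f <- flags[in_g, , drop = FALSE]
    ratios <- colMeans(f)
    direct <- f[, "direct_lateral_inhibition"]
    indirect <- f[, "indirect_lateral_inhibition"]
    data.frame(max_pi = g, n_networks = sum(in_g), t(ratios),
               direct_li = mean(direct),
               indirect_li_only = mean(!direct & indirect),
               no_li = mean(!direct & !indirect))
  })
  out <- do.call(rbind, rows)
  motif_cols <- colnames(flags)
  cors <- vapply(motif_cols, function(mc) {
    s <- stats::sd(out[[mc]])
    if (is.na(s) || s == 0) return(NA_real_)
    stats::cor(out$max_pi, out[[mc]])
  }, numeric(1))
  attr(out, "correlations") <- cors
  out
}

#' Fixed-boundary-cell screen
#'
#' Screens every two-gene network in the variant model with an immutable
#' cell fixed at the left end: the fixed cell signals to its neighbour but
#' never updates nor divides.  After three division rounds the system has
#' nine cells; the screen records each network's stable 9-cell pattern,
#' its stripe count and the maximal (stable) positional information.
#'
#' @param n_genes gene count (2 for the exhaustive screen).
#' @param initial_state binary initial state of the single dividing cell.
#' @param fixed_state binary state of the immutable left cell.
#' @param generations generations (default 4: three division rounds).
#' @param updates_per_generation updates per generation.
#' @param rule_variant update rule.
#' @param ids optional subset of network ids.
#' @param count_fixed_cell include the fixed cell as a position in the
#'   positional-information and stripe computations (default `TRUE`).
#' @return Data frame with one row per network: `id`, `stable` (reached a
#'   9-cell fixed point), `pattern` (composite-state labels of the stable
#'   pattern, `NA` if unstable), `stripes` (maximal-run count),
#'   `distinct_blocks` (the number of stripes when every distinct state of
#'   the dividing cells forms exactly one contiguous block — the fixed
#'   boundary cell is not part of the pattern it organizes — and `NA` when
#'   the pattern is not of that block form), `max_pi`, `max_pi_stable`.
#' @export
screen_fixed_cell <- function(n_genes, initial_state, fixed_state,
                              generations = 4, updates_per_generation = 20,
                              rule_variant = c("threshold_zero",
                                               "biased_plus_one"),
                              ids = NULL, count_fixed_cell = TRUE) {
  rule_variant <- match.arg(rule_variant)
  bias <- if (rule_variant == "biased_plus_one") 1 else 0
  if (is.null(ids)) ids <- enumerate_networks(n_genes)
  rows <- lapply(ids, function(id) {
    net <- decode_network(id, n_genes, rule_variant)
    sim <- screen_sim(net$w_intra, net$w_inter, bias, initial_state,
                      generations, updates_per_generation,
                      fixed_left = fixed_state, want_final = TRUE)
    Sfin <- if (count_fixed_cell) sim$final else
      sim$final[-1, , drop = FALSE]
    core <- state_codes(sim$final[-1, , drop = FALSE])
    runs <- stripe_count_codes(core)
    blocky <- runs == length(unique(core))
    stable <- sim$final_stable
    data.frame(id = id, stable = stable,
               pattern = if (stable)
                 paste(state_labels(Sfin), collapse = "") else NA_character_,
               stripes = if (stable) stripe_count_codes(state_codes(Sfin))
                         else NA_integer_,
               distinct_blocks = if (stable && blocky) runs else NA_integer_,
               max_pi = sim$max_pi, max_pi_stable = sim$max_pi_stable)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_genes") <- n_genes
  out
}

stripe_count_codes <- function(codes) {
  if (!length(codes)) stop("empty tissue")
  1L + sum(codes[-1] != codes[-length(codes)])
}

#' Stripe count of a pattern
#'
#' The number of maximal runs of consecutive cells sharing one composite
#' state ("stripes" or "blocks") along the one-dimensional tissue.
#'
#' @param tissue a [tissue_state()].
#' @return Positive integer.
#' @export
#' @examples
#' stripe_count(tissue_state(rbind(c(1, 0), c(0, 1), c(0, 1), c(1, 0))))  # 3
stripe_count <- function(tissue) {
  stripe_count_codes(state_codes(tissue$S))
}
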