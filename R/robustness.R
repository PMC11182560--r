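#' Noise / asynchrony configuration
#'
#' Parameters of the stochastic perturbation experiments: `error_prob` is
#' the probability, per cell and per update, that the updated gene vector
#' is corrupted; `cycle_length` (L) is the number of updates per
#' generation; `sigma` the standard deviation of per-cell cycle lengths
#' under asynchronous division; `replicates` the Monte-Carlo sample size.
#'
#' @param error_prob corruption probability in `[0, 1]`.
#' @param cycle_length updates per generation (L >= 1).
#' @param sigma standard deviation of cell-cycle lengths (>= 0).
#' @param replicates Monte-Carlo replicates for [accuracy()].
#' @param seed integer seed.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(error_prob = 0, cycle_length = 7, sigma = 0,
                         replicates = 10000, seed = NULL) {
  stopifnot(error_prob >= 0, error_prob <= 1, cycle_length >= 1, sigma >= 0)
  structure(list(error_prob = error_prob, cycle_length = cycle_length,
                 sigma = sigma, replicates = replicates, seed = seed),
            class = "noise_config")
}

# Corrupt rows of S flagged in `hit`: each corrupted cell's gene vector is
# resampled uniformly from the 2^n - 1 vectors different from the correct
# outcome (per-cell corruption, matching mistake-at-cell-granularity).
corrupt_cells <- function(S, hit) {
  n <- ncol(S)
  for (i in which(hit)) {
    repeat {
      cand <- stats::rbinom(n, 1, 0.5)
      if (any(cand != S[i, ])) break
    }
    S[i, ] <- cand
  }
  S
}

#' Growth under noisy state updates
#'
#' As the noise-free division-decision simulation, but after each
#' synchronous update every cell's gene vector is corrupted with
#' probability `error_prob` (resampled uniformly among the wrong vectors).
#' Each generation runs `cycle_length` updates before simultaneous
#' division; the run ends after `generations` generations (default 4,
#' eight cells).
#'
#' @param network a [genetic_network()].
#' @param init binary initial gene vector.
#' @param noise a [noise_config()].
#' @param generations generations to run (default 4).
#' @return The final [tissue_state()].
#' @export
noisy_simulate <- function(network, init, noise, generations = 4) {
  wi <- network$w_intra; wt <- network$w_inter; bias <- rule_bias(network)
  S <- rbind(init); dimnames(S) <- NULL
  p <- noise$error_prob
  for (g in seq_len(generations)) {
    for (u in seq_len(noise$cycle_length)) {
      S <- bool_step(S, wi, wt, bias)
      if (p > 0) {
        hit <- stats::runif(nrow(S)) < p
        if (any(hit)) S <- corrupt_cells(S, hit)
      }
    }
    if (g < generations) S <- S[rep(seq_len(nrow(S)), each = 2), , drop = FALSE]
  }
  tissue_state(S, generation = generations)
}

#' Growth under asynchronous cell division
#'
#' State updates remain globally synchronous (all cells step together,
#' noise-free), but each newborn cell draws its own cycle length from a
#' rounded normal distribution with mean `cycle_length` and standard
#' deviation `sigma` (floored at one update), and divides individually
#' when its clock elapses.  Lineages stop dividing at `generations`, and
#' the run ends at the nominal developmental horizon
#' `generations * cycle_length` — the step at which the synchronous
#' reference run ends — so lagging lineages have less slack to complete
#' their divisions and rectify aberrant states the shorter the cycle.
#' With `sigma = 0` the result is identical to the synchronous
#' simulation.
#'
#' @inheritParams noisy_simulate
#' @return The final [tissue_state()].
#' @export
async_simulate <- function(network, init, noise, generations = 4) {
  wi <- network$w_intra; wt <- network$w_inter; bias <- rule_bias(network)
  L <- noise$cycle_length
  draw_len <- function(k) pmax(1L, as.integer(round(stats::rnorm(k, L, noise$sigma))))
  S <- rbind(init); dimnames(S) <- NULL
  gens <- rep(1L, 1)
  clock <- integer(1)
  length_left <- draw_len(1)
  horizon <- generations * L
  for (step in seq_len(horizon)) {
    S <- bool_step(S, wi, wt, bias)
    clock <- clock + 1L
    due <- clock >= length_left & gens < generations
    if (any(due)) {
      rows <- rep(seq_len(nrow(S)), times = 1L + due)
      S <- S[rows, , drop = FALSE]
      gens <- rep(gens + due, times = 1L + due)
      newborn <- rep(due, times = 1L + due)
      clock <- rep(clock, times = 1L + due)
      clock[newborn] <- 0L
      length_left <- rep(length_left, times = 1L + due)
      length_left[newborn] <- draw_len(sum(newborn))
    }
  }
  tissue_state(S, generation = generations)
}

# Noise-free standard pattern: the stable maximal-information state the
# network reaches at the final generation.  Errors if the network never
# attains the full n-gene information there.
standard_state <- function(network, init, generations = 4,
                           updates_per_generation = 20) {
  traj <- simulate_growth(network, init, generations,
                          updates_per_generation)
  fin <- generation_finals(traj)[[generations]]
  if (!identical(update_tissue(network, fin)$S, fin$S))
    stop("network does not settle at generation ", generations)
  if (positional_information(fin) < network$n_genes - 1e-9)
    stop("standard state undefined: network does not reach ",
         network$n_genes, ".0 bit at generation ", generations)
  fin$S
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(successes, trials, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / trials
  den <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / den
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Patterning accuracy under noise or asynchrony
#'
#' The fraction of stochastic simulations whose final tissue equals,
#' exactly, the standard state: the noise-free synchronous stable
#' maximal-information pattern of the network at the final generation
#' (eight cells for the default four generations).  A Wilson 95% score
#' interval is attached.
#'
#' @param network a [genetic_network()].
#' @param condition `"noise"` (stochastic update errors,
#'   [noisy_simulate()]) or `"async"` (asynchronous division,
#'   [async_simulate()]).
#' @param noise a [noise_config()]; `replicates` and `seed` are taken from
#'   it.
#' @param init binary initial gene vector (default `(1, 0)` for two
#'   genes, `1` for one).
#' @param generations generations per run (default 4).
#' @return A list of class `accuracy_result`: `accuracy`, `ci` (Wilson
#'   bounds), `replicates`, `condition`, `noise`.
#' @export
#' @examples
#' acc <- accuracy(canonical_networks("T1"), "noise",
#'                 noise_config(error_prob = 0.01, replicates = 200, seed = 1))
#' acc$accuracy
accuracy <- function(network, condition = c("noise", "async"), noise,
                     init = NULL, generations = 4) {
  condition <- match.arg(condition)
  if (is.null(init)) init <- c(1, rep(0, network$n_genes - 1))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  std <- standard_state(network, init, generations)
  reps <- noise$replicates
  hits <- 0L
  for (r in seq_len(reps)) {
    fin <- if (condition == "noise")
      noisy_simulate(network, init, noise, generations)
    else
      async_simulate(network, init, noise, generations)
    if (nrow(fin$S) == nrow(std) && identical(fin$S, std)) hits <- hits + 1L
  }
  structure(list(accuracy = hits / reps,
                 ci = wilson_interval(hits, reps),
                 replicates = reps, condition = condition, noise = noise),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("Accuracy (%s): %.3f  [%.3f, %.3f]  (%d replicates)\n",
              x$condition, x$accuracy, x$ci["lower"], x$ci["upper"],
              x$replicates))
  invisible(x)
}
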