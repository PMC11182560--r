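# Hill regulation terms: activator x^h / (K^h + x^h), inhibitor
# K^h / (K^h + x^h).  Neighbour inputs are the per-gene sums of contacting
# cells' levels, the continuous analogue of the Boolean contact sums.
hill_act <- function(x, K, h) x^h / (K^h + x^h)
hill_inh <- function(x, K, h) K^h / (K^h + x^h)

#' Default continuous-model parameters
#'
#' Production and degradation are scaled to one, so steady levels lie in
#' `[0, 1]` and a fully expressed gene sits near 1.  Hill thresholds are
#' per edge (`K_intra[p, q]`, `K_inter[p, q]`; scalars are recycled):
#' intracellular terms switch near `K_intra = 0.4`, making
#' self-activation bistable with a sizable re-ignition barrier, and
#' same-gene intercellular terms switch at `K_inter = 1.2` — between one
#' and two saturated neighbour levels, so a single fully-ON neighbour does
#' not trip lateral inhibition (and does not destabilize adjacent ON
#' pairs) but two neighbours do.  Cross-gene intercellular terms (e.g.
#' the activation of gene B by neighbouring A in T1) switch at `0.5`,
#' within reach of a single neighbour.  The Hill coefficient 4 gives the
#' sharp, switch-like regulation the Boolean model idealizes.  The set was
#' frozen from the module's parameter scan as the regime in which the
#' thresholded steady states of O1/O2 (generation 3) and T1 (generation
#' 4) coincide with the Boolean fixed points.
#'
#' @param n_genes gene count used to shape the threshold matrices.
#' @return Named list: `production`, `degradation`, `K_intra` (n x n),
#'   `K_inter` (n x n), `hill`.
#' @export
continuous_defaults <- function(n_genes = 2) {
  K_inter <- matrix(0.5, n_genes, n_genes)
  diag(K_inter) <- 1.2
  list(production = 1, degradation = 1,
       K_intra = matrix(0.4, n_genes, n_genes),
       K_inter = K_inter, hill = 4)
}

#' Build the continuous (Hill-ODE) counterpart of a Boolean network
#'
#' Maps each nonzero edge of the signed-ternary topology to a Hill term:
#' positive edges become activating terms, negative edges inhibitory ones;
#' intracellular edges read the cell's own levels and intercellular edges
#' the summed levels of contacting neighbours.  Per gene, the terms are
#' combined through an `AND` gate (product) or an `OR` gate (normalized
#' sum), scaling a constant production rate that is opposed by linear
#' degradation:
#' `d g / dt = production * gate(terms) - degradation * g`.
#'
#' A gene with no incoming edges is constitutively produced at the full
#' rate; this is how the biased-rule network O2 is rendered (its `+1`
#' update bias becomes constitutive expression shaped only by lateral
#' inhibition).
#'
#' @param network a [genetic_network()] topology.
#' @param gates character vector, one per gene (recycled): `"AND"`
#'   (product of all Hill terms), `"OR"` (normalized sum), or `"AUTO_OR"`
#'   (the product of the intracellular terms OR the product of the
#'   intercellular terms, averaged — an autoregulatory maintenance branch
#'   in parallel with a signal-driven branch, used for the bistable gene B
#'   of T6).
#' @param params parameter list as [continuous_defaults()].
#' @return An object of class `continuous_network` with the topology,
#'   gates, parameters and a vectorized right-hand-side function
#'   `rhs(S)` over an m x n concentration matrix.
#' @export
#' @examples
#' cn <- build_continuous(canonical_networks("O1"), gates = "AND")
build_continuous <- function(network, gates = "AND",
                             params = continuous_defaults(network$n_genes)) {
  n <- network$n_genes
  gates <- toupper(rep_len(gates, n))
  if (!all(gates %in% c("AND", "OR", "AUTO_OR")))
    stop("gates must be AND, OR or AUTO_OR")
  Kii <- params$K_intra
  Kij <- params$K_inter
  if (length(Kii) == 1) Kii <- matrix(Kii, n, n)
  if (length(Kij) == 1) Kij <- matrix(Kij, n, n)
  stopifnot(params$production > 0, params$degradation > 0,
            all(Kii > 0), all(Kij > 0), params$hill >= 1,
            all(dim(Kii) == n), all(dim(Kij) == n))
  params$K_intra <- Kii
  params$K_inter <- Kij
  wi <- network$w_intra
  wt <- network$w_inter
  h <- params$hill

  rhs <- function(S) {
    m <- nrow(S)
    nbr <- line_neighbor_sum(S)
    D <- matrix(0, m, n)
    for (p in seq_len(n)) {
      intra <- NULL
      inter <- NULL
      for (q in seq_len(n)) {
        if (wi[p, q] == 1)
          intra <- cbind(intra, hill_act(S[, q], Kii[p, q], h))
        if (wi[p, q] == -1)
          intra <- cbind(intra, hill_inh(S[, q], Kii[p, q], h))
        if (wt[p, q] == 1)
          inter <- cbind(inter, hill_act(nbr[, q], Kij[p, q], h))
        if (wt[p, q] == -1)
          inter <- cbind(inter, hill_inh(nbr[, q], Kij[p, q], h))
      }
      terms <- cbind(intra, inter)
      gate_val <- if (is.null(terms)) rep(1, m)
      else if (gates[p] == "AND") apply(terms, 1, prod)
      else if (gates[p] == "OR") rowMeans(terms)
      else {  # AUTO_OR: intracellular branch OR intercellular branch
        br <- cbind(if (is.null(intra)) NULL else apply(intra, 1, prod),
                    if (is.null(inter)) NULL else apply(inter, 1, prod))
        rowMeans(br)
      }
      D[, p] <- params$production * gate_val - params$degradation * S[, p]
    }
    D
  }
  structure(list(network = network, gates = gates, params = params,
                 n_genes = n, rhs = rhs),
            class = "continuous_network")
}

#' @export
print.continuous_network <- function(x, ...) {
  nm <- x$network$name
  cat(sprintf("Continuous (Hill-ODE) network%s: %d gene%s, gates %s\n",
              if (is.null(nm)) "" else paste0(" '", nm, "'"),
              x$n_genes, if (x$n_genes > 1) "s" else "",
              paste(x$gates, collapse = "/")))
  invisible(x)
}

# Relax an m x n concentration matrix to steady state with deSolve::lsoda.
relax_continuous <- function(cnet, S, horizon = 60, atol = 1e-8,
                             steady_tol = 1e-5) {
  m <- nrow(S)
  n <- ncol(S)
  f <- function(t, y, parms) {
    list(as.vector(cnet$rhs(matrix(y, m, n))))
  }
  out <- deSolve::lsoda(as.vector(S), c(0, horizon), f, NULL,
                        atol = atol, rtol = 1e-7)
  Sf <- matrix(out[nrow(out), -1], m, n)
  converged <- max(abs(cnet$rhs(Sf))) < steady_tol
  list(S = Sf, converged = converged)
}

#' Grow a tissue under the continuous model
#'
#' Alternates relaxation to steady state (within a generation) with
#' simultaneous division in which daughters inherit their mother's
#' concentrations — the continuous counterpart of the division-decision
#' loop.  Each generation's steady concentrations are recorded, along with
#' their thresholded Boolean shadow (per gene, levels above half of the
#' gene's maximal attained steady level count as ON; the fraction is
#' configurable).
#'
#' @param cnet a [build_continuous()] network.
#' @param init initial concentration vector of the founding cell.
#' @param generations generations to grow.
#' @param horizon integration time per generation.
#' @param threshold_frac ON threshold as a fraction of each gene's maximal
#'   steady level (default 0.5).
#' @return An object of class `continuous_trajectory`: list with
#'   `levels` (per-generation steady concentration matrices), `shadow`
#'   (per-generation binary matrices), `converged` (per-generation flags;
#'   non-convergence within the horizon is flagged, not an error),
#'   `thresholds`, `cnet`.
#' @export
#' @examples
#' cn <- build_continuous(canonical_networks("O1"), "AND")
#' gr <- grow_continuous(cn, init = 1, generations = 3)
#' gr$shadow[[3]]  # 1 0 0 1
grow_continuous <- function(cnet, init, generations, horizon = 60,
                            threshold_frac = 0.5) {
  n <- cnet$n_genes
  if (length(init) != n) stop("init must have one level per gene")
  S <- rbind(init); dimnames(S) <- NULL
  levels <- vector("list", generations)
  converged <- logical(generations)
  for (g in seq_len(generations)) {
    rl <- relax_continuous(cnet, S, horizon)
    S <- rl$S
    converged[g] <- rl$converged
    levels[[g]] <- S
    if (g < generations)
      S <- S[rep(seq_len(nrow(S)), each = 2), , drop = FALSE]
  }
  all_lv <- do.call(rbind, levels)
  gmin <- apply(all_lv, 2, min)
  gmax <- apply(all_lv, 2, max)
  # ON threshold placed across each gene's attained steady-state range
  thr <- gmin + threshold_frac * pmax(gmax - gmin, 1e-12)
  shadow <- lapply(levels, function(M)
    matrix(as.numeric(sweep(M, 2, thr) > 0), nrow(M), n))
  structure(list(levels = levels, shadow = shadow, converged = converged,
                 thresholds = thr, cnet = cnet),
            class = "continuous_trajectory")
}

#' Noise resistance of a continuous pattern
#'
#' The noise-resistance score lambda of a generation's pattern: the
#' largest perturbation amplitude such that, when i.i.d. uniform
#' `[-lambda, lambda]` perturbations are added to the stable
#' concentrations (clamped at zero) and the tissue relaxed again, the
#' thresholded pattern is retained in at least `retention` of the
#' perturbed trials.  Found by bisection on the amplitude.  The retention
#' criterion (95%, 200 trials) is this package's operational definition of
#' the score.
#'
#' @param cnet a [build_continuous()] network.
#' @param init founding-cell concentrations.
#' @param generation which generation's pattern to probe.
#' @param trials perturbed relaxations per tested amplitude.
#' @param retention required retention fraction.
#' @param lambda_max upper end of the bisection bracket.
#' @param tol bisection tolerance on lambda.
#' @param horizon relaxation time per trial.
#' @param seed integer seed.
#' @return A list of class `noise_resistance`: `lambda`, `generation`,
#'   `pattern` (the reference thresholded pattern), `trials`, `retention`.
#' @export
noise_resistance <- function(cnet, init, generation, trials = 200,
                             retention = 0.95, lambda_max = 1, tol = 0.02,
                             horizon = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gr <- grow_continuous(cnet, init, generation, horizon)
  S0 <- gr$levels[[generation]]
  if (!gr$converged[generation])
    stop("no stable pattern at generation ", generation)
  thr <- gr$thresholds
  ref <- gr$shadow[[generation]]
  m <- nrow(S0); n <- ncol(S0)
  retained <- function(lambda) {
    if (lambda == 0) return(1)
    hits <- 0L
    for (i in seq_len(trials)) {
      P <- S0 + matrix(stats::runif(m * n, -lambda, lambda), m, n)
      P[P < 0] <- 0
      Sf <- relax_continuous(cnet, P, horizon)$S
      shadow <- matrix(as.numeric(sweep(Sf, 2, thr) > 0), m, n)
      if (identical(shadow, ref)) hits <- hits + 1L
    }
    hits / trials
  }
  lo <- 0
  hi <- lambda_max
  if (retained(hi) >= retention) {
    lo <- hi
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (retained(mid) >= retention) lo <- mid else hi <- mid
    }
  }
  structure(list(lambda = lo, generation = generation, pattern = ref,
                 trials = trials, retention = retention),
            class = "noise_resistance")
}

#' Canonical continuous-model configurations
#'
#' Ready-built Hill-ODE systems for the networks the continuous analysis
#' focuses on: `"O1-AND"`, `"O1-OR"` (single gene, both gate logics),
#' `"O2"` (constitutive variant, OR gate), `"T1"` (gene A and B both
#' AND), `"T1-OR"` (gene B through OR), and `"T6"` (T1 plus intracellular
#' self-activation of B, combined through the `AUTO_OR` gate with a B
#' switch threshold of 0.25 — low enough, relative to the gate's halved
#' production ceiling, for the self-maintenance branch to be bistable).
#'
#' @param name configuration name.
#' @return A [build_continuous()] network.
#' @export
canonical_continuous <- function(name = c("O1-AND", "O1-OR", "O2", "T1",
                                          "T1-OR", "T6")) {
  name <- match.arg(name)
  switch(name,
    "O1-AND" = build_continuous(canonical_networks("O1"), "AND"),
    "O1-OR" = build_continuous(canonical_networks("O1"), "OR"),
    "O2" = build_continuous(canonical_networks("O2"), "OR"),
    "T1" = build_continuous(canonical_networks("T1"), c("AND", "AND")),
    "T1-OR" = build_continuous(canonical_networks("T1"), c("AND", "OR")),
    "T6" = {
      p <- continuous_defaults(2)
      p$K_intra[2, 2] <- 0.25
      build_continuous(canonical_networks("T6"), c("AND", "AUTO_OR"), p)
    })
}

#' @export
print.noise_resistance <- function(x, ...) {
  cat(sprintf("Noise resistance: lambda = %.3f at generation %d (%d trials, %.0f%% retention)\n",
              x$lambda, x$generation, x$trials, 100 * x$retention))
  invisible(x)
}
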