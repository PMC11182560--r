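# Independent brute-force oracle for the synchronous update: loops over
# cells, genes and explicit left/right neighbours, evaluating the
# weighted-sum step rule literally.  Kept free of the package's
# matrix-based implementation.
oracle_update <- function(S, w_intra, w_inter, bias = 0) {
  m <- nrow(S)
  n <- ncol(S)
  out <- S
  for (i in seq_len(m)) {
    for (p in seq_len(n)) {
      h <- bias
      for (q in seq_len(n)) {
        h <- h + w_intra[p, q] * S[i, q]
        if (i > 1) h <- h + w_inter[p, q] * S[i - 1, q]
        if (i < m) h <- h + w_inter[p, q] * S[i + 1, q]
      }
      out[i, p] <- if (h > 0) 1 else if (h < 0) 0 else S[i, p]
    }
  }
  out
}

# Entropy oracle: direct -sum p log2 p over a label vector.
oracle_entropy <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# Enumerate all binary state matrices of m cells x n genes.
all_states <- function(m, n) {
  grid <- expand.grid(rep(list(0:1), m * n))
  lapply(seq_len(nrow(grid)), function(i) matrix(as.numeric(grid[i, ]), m, n))
}

# Literal basin enumeration for tiny systems: iterate the oracle update
# from every state, following until a fixed point or revisit.
oracle_basins <- function(net, m) {
  states <- all_states(m, net$n_genes)
  keys <- vapply(states, paste, "", collapse = "")
  fp_counts <- list()
  cycle_mass <- 0
  for (S in states) {
    seen <- character(0)
    cur <- S
    repeat {
      k <- paste(cur, collapse = "")
      nxt <- oracle_update(cur, net$w_intra, net$w_inter,
                           if (net$rule_variant == "biased_plus_one") 1 else 0)
      if (identical(nxt, cur)) {
        fp_counts[[k]] <- (fp_counts[[k]] %||% 0) + 1
        break
      }
      if (k %in% seen) {  # entered a cycle of period > 1
        cycle_mass <- cycle_mass + 1
        break
      }
      seen <- c(seen, k)
      cur <- nxt
    }
  }
  list(fp_counts = fp_counts, cycle_mass = cycle_mass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tissue_labels <- function(tissue) {
  n <- ncol(tissue$S)
  codes <- as.integer(tissue$S %*% 2^(seq_len(n) - 1))
  if (n == 2) c("Y", "G", "R", "B")[codes + 1] else as.character(codes)
}
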