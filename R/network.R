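#' Construct a genetic network
#'
#' A genetic network is the genome shared by every cell of a
#' division-decision system: an intracellular weight matrix, an
#' intercellular weight matrix, and the update-rule variant.  Entry
#' `w_intra[p, q]` is the signed-ternary regulation of gene `p` by gene `q`
#' inside the same cell; `w_inter[p, q]` is the regulation of gene `p` in a
#' cell by gene `q` in a contacting neighbour.  The intercellular matrix
#' applies identically to the left and right neighbour (no left/right
#' asymmetry is representable), so a single matrix is stored.
#'
#' @param w_intra n x n matrix with entries in `{-1, 0, 1}`.
#' @param w_inter n x n matrix with entries in `{-1, 0, 1}`, same n.
#' @param rule_variant `"threshold_zero"` (step function with threshold 0 and
#'   ties keeping the current state) or `"biased_plus_one"` (the same step
#'   function applied to the weighted sum plus one).
#' @param name optional label used in printing.
#'
#' @return An object of class `genetic_network` with fields `n_genes`,
#'   `w_intra`, `w_inter`, `rule_variant`, `name`.
#' @seealso [canonical_networks()], [update_tissue()], [network_id()]
#' @export
#' @examples
#' o1 <- genetic_network(matrix(1), matrix(-1), name = "O1")
#' o1
genetic_network <- function(w_intra, w_inter,
                            rule_variant = c("threshold_zero", "biased_plus_one"),
                            name = NULL) {
  rule_variant <- match.arg(rule_variant)
  w_intra <- as.matrix(w_intra)
  w_inter <- as.matrix(w_inter)
  n <- nrow(w_intra)
  if (ncol(w_intra) != n || !all(dim(w_inter) == c(n, n)))
    stop("w_intra and w_inter must be square matrices of equal size")
  if (!all(w_intra %in% c(-1, 0, 1)) || !all(w_inter %in% c(-1, 0, 1)))
    stop("network weights must be in {-1, 0, 1}")
  storage.mode(w_intra) <- "double"
  storage.mode(w_inter) <- "double"
  structure(
    list(n_genes = n, w_intra = w_intra, w_inter = w_inter,
         rule_variant = rule_variant, name = name),
    class = "genetic_network"
  )
}

#' @export
print.genetic_network <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("Genetic network%s: %d gene%s, rule = %s\n", nm, x$n_genes,
              if (x$n_genes > 1) "s" else "", x$rule_variant))
  genes <- gene_labels(x$n_genes)
  cat("  intracellular (rows = target, cols = source):\n")
  print_signed(x$w_intra, genes)
  cat("  intercellular (from contacting neighbours):\n")
  print_signed(x$w_inter, genes)
  invisible(x)
}

print_signed <- function(w, genes) {
  m <- matrix(sprintf("%+d", as.integer(w)), nrow(w), ncol(w),
              dimnames = list(genes, genes))
  m[w == 0] <- " ."
  print(m, quote = FALSE)
}

gene_labels <- function(n) LETTERS[seq_len(n)]

#' Swap genes of a network
#'
#' Applies a permutation of the gene labels to both weight matrices
#' (rows and columns together).  The two-gene maximal-information networks
#' come in gene-swapped pairs (T1 and T1'), and the screening module's
#' gene-permutation symmetry tests rely on this operation.
#'
#' @param network a [genetic_network()].
#' @param perm integer permutation of `1:n_genes`; default swaps the first
#'   two genes.
#' @return The permuted `genetic_network`.
#' @export
permute_genes <- function(network, perm = NULL) {
  n <- network$n_genes
  if (is.null(perm)) {
    if (n < 2) stop("default permutation needs at least two genes")
    perm <- c(2L, 1L, seq_len(n)[-(1:2)])
  }
  if (!identical(sort(as.integer(perm)), seq_len(n)))
    stop("perm must be a permutation of 1:n_genes")
  genetic_network(network$w_intra[perm, perm, drop = FALSE],
                  network$w_inter[perm, perm, drop = FALSE],
                  network$rule_variant,
                  name = if (is.null(network$name)) NULL
                         else paste0(network$name, "~perm"))
}

# Canonical matrices frozen from the package's own exhaustive screens:
# T2-T4 are the three two-gene networks reaching 2.0 bit under the
# biased (+1) rule, in canonical id order; T5 is the lower-id member of the
# pair producing four stripes in the fixed-boundary-cell screen.
canonical_defs <- function() {
  m <- function(...) matrix(c(...), 2, 2, byrow = TRUE)
  list(
    O1 = list(wi = matrix(1), wt = matrix(-1), rule = "threshold_zero"),
    O2 = list(wi = matrix(0), wt = matrix(-1), rule = "biased_plus_one"),
    T1 = list(wi = m(1, 0, 0, 0), wt = m(-1, 0, 1, -1), rule = "threshold_zero"),
    `T1'` = list(wi = m(0, 0, 0, 1), wt = m(-1, 1, 0, -1), rule = "threshold_zero"),
    T2 = list(wi = m(0, -1, -1, 1), wt = m(-1, 1, -1, 0), rule = "biased_plus_one"),
    T3 = list(wi = m(0, -1, 0, 0), wt = m(-1, 1, -1, 0), rule = "biased_plus_one"),
    T4 = list(wi = m(0, 1, -1, 1), wt = m(-1, -1, 0, -1), rule = "biased_plus_one"),
    T5 = list(wi = m(-1, -1, 0, 0), wt = m(1, 0, 1, -1), rule = "threshold_zero"),
    T6 = list(wi = m(1, 0, 0, 1), wt = m(-1, 0, 1, -1), rule = "threshold_zero")
  )
}

#' Canonical division-decision networks
#'
#' Returns the named networks highlighted by the single- and two-gene
#' screens:
#' * `O1` - single gene, intracellular self-activation and intercellular
#'   (lateral) inhibition; the unique 1.0-bit network under the
#'   threshold-zero rule.
#' * `O2` - single gene, lateral inhibition with no self-activation, under
#'   the biased `+1` rule (the `+1` acts as constitutive drive); the unique
#'   1.0-bit network under that rule.
#' * `T1` - two genes: intracellular self-activation of A, lateral
#'   inhibition of A by A, lateral activation of B by A, lateral inhibition
#'   of B by B; reaches 2.0 bit from inits (1,0) and (1,1).
#' * `T1'` - T1 with genes A and B swapped.
#' * `T2`, `T3`, `T4` - the three 2.0-bit networks under the biased rule.
#' * `T5` - produces a four-striped 9-cell pattern in the fixed-cell model.
#' * `T6` - T1 plus intracellular self-activation of B (used by the
#'   continuous module, where it makes B bistable).
#'
#' @param name optional network name; if omitted, the full named list is
#'   returned.
#' @return A `genetic_network`, or a named list of them.
#' @export
#' @examples
#' canonical_networks("T1")
canonical_networks <- function(name = NULL) {
  defs <- canonical_defs()
  build <- function(nm) {
    d <- defs[[nm]]
    genetic_network(d$wi, d$wt, d$rule, name = nm)
  }
  if (is.null(name)) {
    nets <- lapply(names(defs), build)
    names(nets) <- names(defs)
    return(nets)
  }
  if (!name %in% names(defs))
    stop("unknown canonical network: ", name,
         " (available: ", paste(names(defs), collapse = ", "), ")")
  build(name)
}

#' Encode / decode a network as a canonical integer id
#'
#' The `2 n^2` ternary edge weights (intracellular matrix row-major, then
#' intercellular matrix row-major) are read as base-3 digits (`weight + 1`,
#' most significant first), giving a bijection between networks of a fixed
#' gene count and `0 : (3^(2 n^2) - 1)`.  For one gene there are 9 ids, for
#' two genes 6561.
#'
#' @param network a [genetic_network()].
#' @return `network_id()`: a non-negative integer id.
#' @export
network_id <- function(network) {
  digits <- c(t(network$w_intra), t(network$w_inter)) + 1
  sum(digits * 3^(rev(seq_along(digits)) - 1))
}

#' @rdname network_id
#' @param id integer id in `0 : (3^(2 n_genes^2) - 1)`.
#' @param n_genes number of genes.
#' @param rule_variant update-rule variant for the decoded network.
#' @return `decode_network()`: the `genetic_network` with that id.
#' @export
decode_network <- function(id, n_genes,
                           rule_variant = c("threshold_zero", "biased_plus_one")) {
  rule_variant <- match.arg(rule_variant)
  k <- 2L * n_genes^2
  if (id < 0 || id >= 3^k) stop("id out of range for ", n_genes, " gene(s)")
  digits <- integer(k)
  x <- id
  for (j in k:1) {
    digits[j] <- x %% 3
    x <- x %/% 3
  }
  w <- digits - 1
  wi <- matrix(w[seq_len(n_genes^2)], n_genes, n_genes, byrow = TRUE)
  wt <- matrix(w[n_genes^2 + seq_len(n_genes^2)], n_genes, n_genes, byrow = TRUE)
  genetic_network(wi, wt, rule_variant)
}

#' Read and write network files
#'
#' Networks are serialized as a small JSON object with fields `n_genes`,
#' `w_intra` (row-major), `w_inter` (row-major), `rule_variant` and
#' optionally `name`; the round trip is lossless.
#'
#' @param network a [genetic_network()].
#' @param path file path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns the `genetic_network`.
#' @export
write_network <- function(network, path) {
  obj <- list(
    n_genes = network$n_genes,
    w_intra = as.integer(t(network$w_intra)),
    w_inter = as.integer(t(network$w_inter)),
    rule_variant = network$rule_variant
  )
  if (!is.null(network$name)) obj$name <- network$name
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$n_genes
  genetic_network(matrix(obj$w_intra, n, n, byrow = TRUE),
                  matrix(obj$w_inter, n, n, byrow = TRUE),
                  obj$rule_variant,
                  name = obj$name)
}
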