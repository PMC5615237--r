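# Bridging edge lists and the dense symmetric matrices the indirect-removal
# operators work on.

#' Construct a score matrix
#'
#' @param M Symmetric numeric matrix with finite entries.
#' @param proteins Protein identifiers indexing rows/columns.
#' @param diagonal `"zero"` or `"unit"` — the diagonal convention the matrix
#'   obeys (zero for deconvolution input, unit for silencer input).
#' @return Object of class `score_matrix`.
#' @export
score_matrix <- function(M, proteins, diagonal = c("zero", "unit")) {
  diagonal <- match.arg(diagonal)
  M <- as.matrix(M)
  stopifnot(nrow(M) == ncol(M), length(proteins) == nrow(M))
  if (!all(is.finite(M))) stop("score matrix entries must be finite")
  if (!isTRUE(all.equal(M, t(M), tolerance = 0, check.attributes = FALSE))) {
    stop("score matrix must be exactly symmetric")
  }
  want <- if (diagonal == "zero") 0 else 1
  if (any(diag(M) != want)) {
    stop("diagonal violates the '", diagonal, "' convention")
  }
  dimnames(M) <- list(proteins, proteins)
  structure(list(proteins = as.character(proteins), M = M,
                 diagonal = diagonal),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("Score matrix: %d proteins, %s diagonal\n",
              length(x$proteins), x$diagonal))
  invisible(x)
}

#' Embed a scored network in a dense symmetric matrix
#'
#' Off-diagonal entries are normalized scores in \[0, 1\]; absent pairs are
#' 0. Two normalizations are available:
#'
#' * `"positive"` (default): scores clamped at zero and divided by the
#'   maximum. A log-odds score at or below zero carries no evidence of
#'   association, so it contributes zero observed correlation; for scores
#'   that are nonnegative by construction (Dice, hypergeometric) this is a
#'   plain rescaling that preserves the meaningful zero.
#' * `"minmax"`: `(score - min) / (max - min)`, mapping the weakest present
#'   edge to 0 and the strongest to 1 regardless of sign.
#'
#' If all present scores are equal (and, for `"positive"`, positive), every
#' present edge maps to 1. The protein index is the lexicographically sorted
#' universe of the network's proteins.
#'
#' @param net A non-empty [scored_network()].
#' @param diagonal Diagonal convention of the result (see [score_matrix()]).
#' @param normalization `"positive"` or `"minmax"`.
#' @return A [score_matrix()].
#' @export
network_to_matrix <- function(net, diagonal = c("zero", "unit"),
                              normalization = c("positive", "minmax")) {
  diagonal <- match.arg(diagonal)
  normalization <- match.arg(normalization)
  stopifnot(inherits(net, "scored_network"))
  if (nrow(net) == 0L) stop("cannot embed an empty network")
  proteins <- sort(unique(c(net$protein_a, net$protein_b)), method = "radix")
  rng <- range(net$score)
  w <- if (normalization == "positive") {
    if (rng[2] > 0) pmax(net$score, 0) / rng[2] else rep(0, nrow(net))
  } else if (rng[1] == rng[2]) {
    rep(1, nrow(net))
  } else {
    (net$score - rng[1]) / (rng[2] - rng[1])
  }
  M <- matrix(0, length(proteins), length(proteins))
  i <- match(net$protein_a, proteins)
  j <- match(net$protein_b, proteins)
  M[cbind(i, j)] <- w
  M[cbind(j, i)] <- w
  if (diagonal == "unit") diag(M) <- 1
  score_matrix(M, proteins, diagonal)
}

#' Extract a ranked network from a score matrix
#'
#' Off-diagonal upper-triangle entries become edges in canonical ranking
#' order. By default only nonzero entries are kept; if `keep_pairs` is given
#' (a two-column data frame or a [scored_network()]/[reference_set()]),
#' exactly those pairs are reported — zeros included — so a refined network
#' can be ranked over the initial network's full candidate universe.
#'
#' @param S A [score_matrix()].
#' @param keep_pairs Optional pair restriction.
#' @param method Provenance tag for the resulting network.
#' @return A [scored_network()].
#' @export
matrix_to_network <- function(S, keep_pairs = NULL, method = "refined") {
  stopifnot(inherits(S, "score_matrix"))
  if (is.null(keep_pairs)) {
    up <- upper.tri(S$M)
    idx <- which(up & S$M != 0, arr.ind = TRUE)
    return(scored_network(S$proteins[idx[, 1L]], S$proteins[idx[, 2L]],
                          S$M[idx], method = method))
  }
  if (inherits(keep_pairs, "reference_set")) keep_pairs <- keep_pairs$pairs
  a <- pmin(keep_pairs[[1L]], keep_pairs[[2L]])
  b <- pmax(keep_pairs[[1L]], keep_pairs[[2L]])
  i <- match(a, S$proteins)
  j <- match(b, S$proteins)
  if (anyNA(i) || anyNA(j)) stop("keep_pairs names proteins absent from the matrix")
  scored_network(a, b, S$M[cbind(i, j)], method = method)
}
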