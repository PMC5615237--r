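# Phase II: recover the direct-association matrix S from the observed
# correlation matrix G. The observed matrix is modelled as the sum of direct
# effects plus effects mediated through direct neighbours, i.e. the
# transitive-closure series G = S + S^2 + S^3 + ... = S (I - S)^-1; both
# operators below invert that relationship in closed form.

#' Network deconvolution
#'
#' Spectral inversion of the transitive-closure series. Steps: (1) with
#' `alpha < 1`, keep only the top `ceiling(alpha * nnz)` off-diagonal entries
#' by magnitude (the rest are zeroed symmetrically); (2) eigendecompose
#' `G = V L V'` on the symmetric path; (3) unless `force_no_scaling`, divide
#' all eigenvalues by `m = max(lp * (1 - beta) / beta, |ln| * (1 + beta) /
#' beta, 1)` where `lp` is the largest positive and `ln` the most negative
#' eigenvalue, which guarantees the transformed spectrum lies in
#' `[-beta, beta]`; (4) map each eigenvalue through `l / (1 + l)`;
#' (5) reconstruct, re-symmetrize and zero the diagonal.
#'
#' With scaling disabled the operator is an exact inverse: if
#' `G = S (I - S)^-1` for any symmetric `S` with spectral radius below 1,
#' the result is `S`.
#'
#' @param G A zero-diagonal [score_matrix()], or a plain symmetric numeric
#'   matrix (any diagonal; used when `G` is itself an exact transitive
#'   closure, whose diagonal carries part of the spectrum).
#' @param beta Target spectral bound, in (0, 1). Default 0.99.
#' @param alpha Fraction of off-diagonal entries retained, in (0, 1\].
#'   Default 1 (keep all).
#' @param force_no_scaling Skip the eigenvalue rescaling step (used when `G`
#'   is already a valid transitive closure).
#' @return A zero-diagonal [score_matrix()] of direct-association scores.
#' @export
deconvolve_nd <- function(G, beta = 0.99, alpha = 1,
                          force_no_scaling = FALSE) {
  if (inherits(G, "score_matrix")) {
    if (G$diagonal != "zero") stop("deconvolution expects a zero-diagonal matrix")
    M <- G$M
    proteins <- G$proteins
  } else {
    M <- as.matrix(G)
    if (!all(is.finite(M))) stop("matrix entries must be finite")
    if (!isTRUE(all.equal(M, t(M), tolerance = 0, check.attributes = FALSE))) {
      stop("deconvolution expects a symmetric matrix")
    }
    proteins <- rownames(M) %||% sprintf("V%d", seq_len(nrow(M)))
  }
  if (!(beta > 0 && beta < 1)) stop("beta must be in (0, 1)")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (alpha < 1) {
    up <- which(upper.tri(M) & M != 0)
    keep_n <- ceiling(alpha * length(up))
    if (keep_n < length(up)) {
      drop <- up[order(abs(M[up]), decreasing = TRUE)][-seq_len(keep_n)]
      M[drop] <- 0
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
    }
  }
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  if (!all(is.finite(lam))) stop("eigendecomposition failed: non-finite spectrum")
  if (!force_no_scaling) {
    lp <- if (any(lam > 0)) max(lam) else 0
    ln <- if (any(lam < 0)) abs(min(lam)) else 0
    m <- max(lp * (1 - beta) / beta, ln * (1 + beta) / beta, 1)
    lam <- lam / m
  }
  if (any(abs(1 + lam) < .Machine$double.eps)) {
    stop("eigenvalue at -1: deconvolution transform undefined")
  }
  lam_dir <- lam / (1 + lam)
  S <- e$vectors %*% (lam_dir * t(e$vectors))
  S <- (S + t(S)) / 2
  diag(S) <- 0
  score_matrix(S, proteins, "zero")
}

#' Silencer transform
#'
#' Closed-form suppression of indirect correlation contributions:
#' `S = (G - I + D((G - I) G)) G^-1`, where `D(.)` zeroes everything but the
#' diagonal of its argument. If `G` is numerically singular (reciprocal
#' condition number below 1e-12) the inverse is taken of
#' `G + ridge_eps * I` instead, with a message. The result is symmetrized as
#' `(S + S') / 2` with zero diagonal; off-diagonal magnitudes are the
#' direct-interaction scores.
#'
#' On two nodes the transform is a fixed point: the off-diagonal entry `g`
#' (|g| < 1) is returned exactly.
#'
#' @param G A unit-diagonal [score_matrix()] or plain symmetric matrix with
#'   unit diagonal.
#' @param ridge_eps Ridge added to the diagonal when `G` is ill-conditioned.
#'   Default `1e-8 * trace(G) / n`.
#' @return A zero-diagonal [score_matrix()].
#' @export
silence <- function(G, ridge_eps = NULL) {
  if (inherits(G, "score_matrix")) {
    M <- G$M
    proteins <- G$proteins
  } else {
    M <- as.matrix(G)
    if (!isTRUE(all.equal(M, t(M), tolerance = 0, check.attributes = FALSE))) {
      stop("the silencer expects a symmetric matrix")
    }
    proteins <- rownames(M) %||% sprintf("V%d", seq_len(nrow(M)))
  }
  if (any(diag(M) != 1)) stop("the silencer expects a unit-diagonal matrix")
  n <- nrow(M)
  if (is.null(ridge_eps)) ridge_eps <- 1e-8 * sum(diag(M)) / n
  I <- diag(n)
  Minv <- if (rcond(M) >= 1e-12) {
    solve(M)
  } else {
    message("ill-conditioned correlation matrix: ridge of ", ridge_eps,
            " applied before inversion")
    solve(M + ridge_eps * I)
  }
  A <- M - I
  S <- (A + diag(diag(A %*% M), n)) %*% Minv
  S <- (S + t(S)) / 2
  diag(S) <- 0
  score_matrix(S, proteins, "zero")
}

#' Refine a scored network by removing indirect associations
#'
#' Runs the full phase-II bridge: embed the network in a dense matrix
#' ([network_to_matrix()]), apply the chosen operator, and extract a
#' re-ranked network. For the silencer, whose closed form presumes a total
#' correlation matrix `G = I + C` generated by a convergent series (so
#' `C` must have spectral radius below 1 and `G` must be invertible), the
#' off-diagonal part is rescaled to spectral radius `target_radius` before
#' the unit diagonal is added; deconvolution needs no such step because its
#' `beta` scaling plays the same role internally. Silencer scores are ranked
#' by magnitude. By default the refined network is restricted to the initial
#' network's candidate pairs, so initial and filtered rankings cover the
#' same universe.
#'
#' @param net A non-empty [scored_network()].
#' @param method `"nd"` (network deconvolution) or `"silencer"`.
#' @param beta,alpha Deconvolution parameters (see [deconvolve_nd()]).
#' @param ridge_eps Silencer ridge (see [silence()]).
#' @param target_radius Spectral radius the silencer's off-diagonal part is
#'   scaled to, in (0, 1). Default 0.5.
#' @param normalization Score-to-weight mapping (see [network_to_matrix()]).
#' @param restrict_to_initial Rank the refined scores over exactly the
#'   initial edges (default `TRUE`).
#' @return A [scored_network()] tagged `"<initial method>+<method>"`.
#' @export
refine_network <- function(net, method = c("nd", "silencer"),
                           beta = 0.99, alpha = 1, ridge_eps = NULL,
                           target_radius = 0.5,
                           normalization = c("positive", "minmax"),
                           restrict_to_initial = TRUE) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  stopifnot(inherits(net, "scored_network"))
  tag <- paste0(network_method(net), "+", method)
  S <- if (method == "nd") {
    deconvolve_nd(network_to_matrix(net, "zero", normalization),
                  beta = beta, alpha = alpha)
  } else {
    if (!(target_radius > 0 && target_radius < 1)) {
      stop("target_radius must be in (0, 1)")
    }
    G <- network_to_matrix(net, "zero", normalization)
    rad <- max(abs(eigen(G$M, symmetric = TRUE, only.values = TRUE)$values))
    if (rad > 0) G$M <- G$M * (target_radius / rad)
    diag(G$M) <- 1
    G$diagonal <- "unit"
    out <- silence(G, ridge_eps = ridge_eps)
    out$M <- abs(out$M)
    out
  }
  keep <- if (restrict_to_initial) net[, c("protein_a", "protein_b")] else NULL
  matrix_to_network(S, keep_pairs = keep, method = tag)
}
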