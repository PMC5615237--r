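# Phase I: qualitative co-occurrence scoring of candidate protein pairs.
# All four methods score every pair co-occurring at least once in any role
# (the matrix-model candidate universe) and are symmetric in the pair.

#' Socioaffinity score
#'
#' Log-odds of observed over expected co-retrieval, summing two spoke terms
#' and one matrix term:
#' `SA(i,j) = ln(s_ij/E[s_ij]) + ln(s_ji/E[s_ji]) + ln(m_ij/E[m_ij])`.
#' Under the random-assortment null, `E[s_ij] = f_j * sum(size_k; bait_k = i)`
#' with `f_j = r_j / T` the background prey frequency, and
#' `E[m_ij] = f_i * f_j * sum(size_k * (size_k - 1))`. A term whose observed
#' count is zero contributes zero (scores stay finite; explicit
#' absence-of-retrieval evidence is the purification-enrichment score's job).
#'
#' @param counts A [cooccurrence_counts()] object, with `T > 0`.
#' @return A [scored_network()] over all pairs with `k_ij >= 1`.
#' @export
score_sa <- function(counts) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  if (counts$T <= 0) stop("socioaffinity is undefined when no preys were retrieved")
  cp <- candidate_pairs(counts)
  f <- counts$r / counts$T
  ssb <- counts$sumsize_bait
  term <- function(obs, expd) ifelse(obs > 0, log(obs / expd), 0)
  sa <- term(cp$s_ij, f[cp$j] * ssb[cp$i]) +
    term(cp$s_ji, f[cp$i] * ssb[cp$j]) +
    term(cp$m, f[cp$i] * f[cp$j] * counts$M2)
  scored_network(counts$proteins[cp$i], counts$proteins[cp$j], sa,
                 method = "sa")
}

#' Purification enrichment score
#'
#' Bayesian log-odds accumulating per-purification presence/absence evidence.
#' With smoothed background frequency
#' `f_j = (r_j + pseudo/n_proteins) / (T + pseudo)`, the spoke term for bait
#' `i` toward `j` sums `ln(r / f_j)` over bait-`i` purifications retrieving
#' `j` and `ln((1 - r)/(1 - f_j))` over those that do not (no term when `i`
#' was never a bait). The matrix term is `m_ij * ln(r / (f_i * f_j * Sbar))`
#' with `Sbar` the mean of `size_k * (size_k - 1)` over purifications, and
#' contributes zero when `m_ij = 0`. `PE(i,j)` is the sum of both spoke
#' directions and the matrix term.
#'
#' @param counts A [cooccurrence_counts()] object.
#' @param r Assumed retrieval probability of a true interactor, in (0, 1).
#' @param pseudo Pseudocount for background-frequency smoothing, `>= 0`.
#' @return A [scored_network()] over all pairs with `k_ij >= 1`.
#' @export
score_pe <- function(counts, r = 0.5, pseudo = 20) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  if (!(r > 0 && r < 1)) stop("retrieval probability r must be in (0, 1)")
  if (pseudo < 0) stop("pseudo must be >= 0")
  cp <- candidate_pairs(counts)
  if (nrow(cp) == 0L) {
    return(scored_network(character(), character(), numeric(), method = "pe"))
  }
  n <- length(counts$proteins)
  f <- (counts$r + pseudo / n) / (counts$T + pseudo)
  b <- counts$b
  spoke <- function(i, j, s_ij) {
    ifelse(b[i] > 0,
           s_ij * log(r / f[j]) + (b[i] - s_ij) * log((1 - r) / (1 - f[j])),
           0)
  }
  sbar <- counts$M2 / counts$N
  mat <- ifelse(cp$m > 0, cp$m * log(r / (f[cp$i] * f[cp$j] * sbar)), 0)
  pe <- spoke(cp$i, cp$j, cp$s_ij) + spoke(cp$j, cp$i, cp$s_ji) + mat
  scored_network(counts$proteins[cp$i], counts$proteins[cp$j], pe,
                 method = "pe")
}

#' Dice coefficient score
#'
#' Purification-membership overlap: `DC(i,j) = 2 k_ij / (occ_i + occ_j)`,
#' in (0, 1] over the candidate universe.
#'
#' @param counts A [cooccurrence_counts()] object.
#' @return A [scored_network()] over all pairs with `k_ij >= 1`.
#' @export
score_dc <- function(counts) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  cp <- candidate_pairs(counts)
  dc <- 2 * cp$k / (counts$occ[cp$i] + counts$occ[cp$j])
  scored_network(counts$proteins[cp$i], counts$proteins[cp$j], dc,
                 method = "dc")
}

# Upper tail P(X >= k), X ~ Hypergeometric(N population, K successes,
# n draws). Symmetric under swapping K and n.
hyper_tail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric co-purification score
#'
#' Significance of purification-level co-membership: with `X` the overlap of
#' a random `occ_j`-subset of the `N` purifications with the fixed `occ_i`
#' ones containing `i`, the score is `-log10 P(X >= k_ij)`. The tail is
#' symmetric in the pair. P-values are clamped below at `p_floor` so extreme
#' enrichment stays finite.
#'
#' @param counts A [cooccurrence_counts()] object.
#' @param p_floor Smallest admissible p-value (default `1e-300`).
#' @return A [scored_network()] over all pairs with `k_ij >= 1`; scores
#'   `>= 0`.
#' @export
score_hart <- function(counts, p_floor = 1e-300) {
  stopifnot(inherits(counts, "cooccurrence_counts"), p_floor > 0)
  cp <- candidate_pairs(counts)
  p <- hyper_tail(cp$k, counts$occ[cp$i], counts$occ[cp$j], counts$N)
  scored_network(counts$proteins[cp$i], counts$proteins[cp$j],
                 -log10(pmax(p, p_floor)), method = "hart")
}

#' Score a purification dataset with a named method
#'
#' Convenience dispatcher over the four co-occurrence scores.
#'
#' @param dataset An [apms_dataset()].
#' @param method One of `"sa"`, `"pe"`, `"dc"`, `"hart"`.
#' @param ... Method parameters (`r`, `pseudo` for `"pe"`; `p_floor` for
#'   `"hart"`).
#' @return A [scored_network()].
#' @export
score_network <- function(dataset, method = c("sa", "pe", "dc", "hart"),
                          ...) {
  method <- match.arg(method)
  counts <- cooccurrence_counts(dataset)
  switch(method,
         sa = score_sa(counts),
         pe = score_pe(counts, ...),
         dc = score_dc(counts),
         hart = score_hart(counts, ...))
}
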