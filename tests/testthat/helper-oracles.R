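# Independent straight-line oracles: naive quadratic loops over the raw
# purification records, kept deliberately separate from the package's
# vectorized implementations.

oracle_counts <- function(ds) {
  prot <- ds$proteins
  n <- length(prot)
  zero <- matrix(0, n, n, dimnames = list(prot, prot))
  s <- zero; m <- zero; k <- zero
  occ <- stats::setNames(numeric(n), prot)
  b <- occ; r <- occ
  for (p in ds$purifications) {
    memb <- c(p$bait, p$preys)
    b[p$bait] <- b[p$bait] + 1
    for (x in memb) occ[x] <- occ[x] + 1
    for (y in p$preys) {
      r[y] <- r[y] + 1
      s[p$bait, y] <- s[p$bait, y] + 1
    }
    for (x in memb) for (y in memb) if (x != y) k[x, y] <- k[x, y] + 1
    for (x in p$preys) for (y in p$preys) if (x != y) m[x, y] <- m[x, y] + 1
  }
  list(proteins = prot, N = ds$N, b = b, occ = occ, r = r,
       T = sum(r), s = s, m = m, k = k,
       sizes = vapply(ds$purifications, function(p) length(p$preys),
                      numeric(1)))
}

oracle_pairs <- function(oc) {
  out <- list()
  for (i in seq_along(oc$proteins)) {
    for (j in seq_along(oc$proteins)) {
      if (i < j && oc$k[i, j] >= 1) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  out
}

oracle_sa <- function(ds) {
  oc <- oracle_counts(ds)
  f <- oc$r / oc$T
  m2 <- sum(oc$sizes * (oc$sizes - 1))
  baits <- vapply(ds$purifications, function(p) p$bait, character(1))
  scores <- c()
  for (p in oracle_pairs(oc)) {
    i <- oc$proteins[p[1]]; j <- oc$proteins[p[2]]
    sumsize_i <- sum(oc$sizes[baits == i])
    sumsize_j <- sum(oc$sizes[baits == j])
    v <- 0
    if (oc$s[i, j] > 0) v <- v + log(oc$s[i, j] / (f[j] * sumsize_i))
    if (oc$s[j, i] > 0) v <- v + log(oc$s[j, i] / (f[i] * sumsize_j))
    if (oc$m[i, j] > 0) v <- v + log(oc$m[i, j] / (f[i] * f[j] * m2))
    scores[paste0(i, "\r", j)] <- v
  }
  scores
}

# PE oracle accumulates per-purification presence/absence terms one
# purification at a time (the definition), not via the closed-form counts.
oracle_pe <- function(ds, r = 0.5, pseudo = 20) {
  oc <- oracle_counts(ds)
  n <- length(oc$proteins)
  f <- (oc$r + pseudo / n) / (oc$T + pseudo)
  sbar <- sum(oc$sizes * (oc$sizes - 1)) / oc$N
  scores <- c()
  for (p in oracle_pairs(oc)) {
    i <- oc$proteins[p[1]]; j <- oc$proteins[p[2]]
    v <- 0
    for (pur in ds$purifications) {
      if (pur$bait == i) {
        v <- v + if (j %in% pur$preys) log(r / f[j]) else
          log((1 - r) / (1 - f[j]))
      }
      if (pur$bait == j) {
        v <- v + if (i %in% pur$preys) log(r / f[i]) else
          log((1 - r) / (1 - f[i]))
      }
    }
    if (oc$m[i, j] > 0) v <- v + oc$m[i, j] * log(r / (f[i] * f[j] * sbar))
    scores[paste0(i, "\r", j)] <- v
  }
  scores
}

oracle_dc <- function(ds) {
  oc <- oracle_counts(ds)
  scores <- c()
  for (p in oracle_pairs(oc)) {
    i <- oc$proteins[p[1]]; j <- oc$proteins[p[2]]
    scores[paste0(i, "\r", j)] <- 2 * oc$k[i, j] / (oc$occ[i] + oc$occ[j])
  }
  scores
}

# Hypergeometric upper tail from first principles (explicit binomial sums).
oracle_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

oracle_hart <- function(ds, p_floor = 1e-300) {
  oc <- oracle_counts(ds)
  scores <- c()
  for (p in oracle_pairs(oc)) {
    i <- oc$proteins[p[1]]; j <- oc$proteins[p[2]]
    pv <- oracle_hyper_tail(oc$k[i, j], oc$occ[i], oc$occ[j], oc$N)
    scores[paste0(i, "\r", j)] <- -log10(max(pv, p_floor))
  }
  scores
}

# Exhaustive enumeration of the hypergeometric tail: overlap of a fixed
# K-subset with every n-subset of 1..N.
enum_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (n == 0 || K == 0) return(0)
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2L, function(s) sum(s <= K)) >= k)
}

# Small random qualitative AP-MS dataset.
random_dataset <- function(n_purif = 30, n_prot = 15, seed = 1,
                           mean_preys = 3) {
  set.seed(seed)
  prot <- sprintf("X%02d", seq_len(n_prot))
  purs <- lapply(seq_len(n_purif), function(p) {
    bait <- sample(prot, 1)
    n_prey <- min(stats::rpois(1, mean_preys), n_prot - 1L)
    list(id = sprintf("e%03d", p), bait = bait,
         preys = sample(setdiff(prot, bait), n_prey))
  })
  apms_dataset(purs)
}

pair_keys_df <- function(df) {
  paste0(pmin(df[[1L]], df[[2L]]), "\r", pmax(df[[1L]], df[[2L]]))
}

net_lookup <- function(net) {
  stats::setNames(net$score, paste0(net$protein_a, "\r", net$protein_b))
}

expect_net_equals_oracle <- function(net, oracle_scores, tol = 1e-10) {
  got <- net_lookup(net)
  expect_setequal(names(got), names(oracle_scores))
  expect_lt(max(abs(got[names(oracle_scores)] - oracle_scores), 0), tol)
}

random_symmetric <- function(n, radius = NULL, seed = 1, zero_diag = TRUE) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n, n)
  A <- (A + t(A)) / 2
  if (zero_diag) diag(A) <- 0
  if (!is.null(radius)) A <- A * (radius / max(abs(eigen(A)$values)))
  A
}
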