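test_that("network embedding normalizes scores and obeys diagonal conventions", {
  net <- scored_network(c("A", "A", "B"), c("B", "C", "C"), c(2, 1, 0))
  for (norm in c("minmax", "positive")) {
    G <- network_to_matrix(net, "zero", normalization = norm)
    expect_equal(G$M["A", "B"], 1)   # both mappings: min is 0, max is 2
    expect_equal(G$M["A", "C"], 0.5)
    expect_equal(G$M["B", "C"], 0)
    expect_identical(G$M, t(G$M))
    expect_equal(diag(G$M), c(A = 0, B = 0, C = 0))
  }
  Gu <- network_to_matrix(net, "unit")
  expect_equal(diag(Gu$M), c(A = 1, B = 1, C = 1))

  # single edge: max = min maps to 1 under both conventions
  single <- scored_network("A", "B", 7)
  expect_equal(network_to_matrix(single, "zero")$M["A", "B"], 1)
  expect_equal(network_to_matrix(single, "zero",
                                 normalization = "minmax")$M["A", "B"], 1)

  # negative log-odds carry no positive evidence under "positive"
  neg <- scored_network(c("A", "A"), c("B", "C"), c(3, -2))
  expect_equal(network_to_matrix(neg, "zero")$M["A", "C"], 0)
  expect_equal(network_to_matrix(neg, "zero",
                                 normalization = "minmax")$M["A", "C"], 0)

  expect_error(network_to_matrix(scored_network(character(), character(),
                                                numeric())),
               "empty")
})

test_that("deconvolution maps the zero matrix to zero and is monotone on 2 nodes", {
  z <- score_matrix(matrix(0, 3, 3), c("A", "B", "C"), "zero")
  expect_equal(deconvolve_nd(z)$M, z$M, ignore_attr = TRUE)

  prev <- -Inf
  for (w in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    G <- score_matrix(matrix(c(0, w, w, 0), 2), c("A", "B"), "zero")
    cur <- deconvolve_nd(G, force_no_scaling = TRUE)$M[1, 2]
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("unscaled deconvolution inverts the transitive-closure series exactly", {
  for (seed in 1:5) {
    n <- sample(5:20, 1)
    G_dir <- random_symmetric(n, radius = 0.4, seed = seed)
    G_obs <- G_dir %*% solve(diag(n) - G_dir)
    G_obs <- (G_obs + t(G_obs)) / 2
    rec <- deconvolve_nd(G_obs, force_no_scaling = TRUE)
    expect_lt(max(abs(rec$M - G_dir)), 1e-8)
  }
})

test_that("deconvolution scaling keeps the transformed spectrum within [-beta, beta]", {
  for (beta in c(0.5, 0.9, 0.99)) {
    G <- score_matrix(abs(random_symmetric(12, seed = 8)), sprintf("P%d", 1:12),
                      "zero")
    S <- deconvolve_nd(G, beta = beta)
    expect_true(all(is.finite(S$M)))
    # the transform applied to the scaled input spectrum stays in [-beta, beta]
    lam <- eigen(G$M, symmetric = TRUE, only.values = TRUE)$values
    m <- max(max(lam) * (1 - beta) / beta,
             abs(min(lam)) * (1 + beta) / beta, 1)
    expect_true(all(abs((lam / m) / (1 + lam / m)) <= beta + 1e-12))
  }
  expect_error(deconvolve_nd(score_matrix(matrix(0, 2, 2), c("A", "B"),
                                          "zero"), beta = 1.5),
               "beta")
})

test_that("deconvolution alpha keeps only the strongest entries", {
  M <- matrix(0, 4, 4)
  M[upper.tri(M)] <- c(0.9, 0.5, 0.1, 0.8, 0.2, 0.7)
  M <- M + t(M)
  G <- score_matrix(M, sprintf("P%d", 1:4), "zero")
  kept <- deconvolve_nd(G, alpha = 0.5)
  dropped <- deconvolve_nd(score_matrix(
    replace(M, abs(M) < 0.7, 0), sprintf("P%d", 1:4), "zero"))
  expect_equal(kept$M, dropped$M, tolerance = 1e-12)
})

test_that("silencer identities hold: silence(I) = 0 and the 2-node fixed point", {
  I3 <- diag(3)
  dimnames(I3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(silence(I3)$M, I3 * 0, ignore_attr = TRUE)

  for (g in c(-0.8, -0.3, 0.2, 0.6, 0.95)) {
    G <- matrix(c(1, g, g, 1), 2)
    expect_equal(silence(G)$M[1, 2], g, tolerance = 1e-12)
  }
})

test_that("silencer equals a literal transcription of its closed form", {
  for (seed in 1:5) {
    C <- random_symmetric(6, radius = 0.45, seed = 100 + seed)
    G <- diag(6) + C
    S <- silence(G)
    # transcription oracle
    Ginv <- solve(G)
    A <- G - diag(6)
    ref <- (A + diag(diag(A %*% G), 6)) %*% Ginv
    ref <- (ref + t(ref)) / 2
    diag(ref) <- 0
    expect_lt(max(abs(S$M - ref)), 1e-10)
  }
})

test_that("silencer enforces its contract and ridges singular input", {
  expect_error(silence(matrix(c(0, 1, 1, 0), 2)), "unit-diagonal")
  ones <- matrix(1, 3, 3)  # exactly singular
  expect_message(S <- silence(ones), "ridge")
  expect_true(all(is.finite(S$M)))
})

test_that("matrix extraction honors keep_pairs and canonical ranking", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.3
  M[1, 3] <- M[3, 1] <- 0.1
  S <- score_matrix(M, c("A", "B", "C"), "zero")
  net <- matrix_to_network(S)
  expect_equal(net$protein_b, c("B", "C"))
  expect_equal(net$score, c(0.3, 0.1))

  kept <- matrix_to_network(S, keep_pairs = data.frame(a = "A", b = "B"))
  expect_equal(nrow(kept), 1L)
  # restriction reports requested pairs even when their entry is zero
  full <- matrix_to_network(S, keep_pairs = data.frame(
    a = c("A", "A", "B"), b = c("B", "C", "C")))
  expect_equal(nrow(full), 3L)
  expect_equal(net_lookup(full)[["B\rC"]], 0)

  empty <- matrix_to_network(score_matrix(matrix(0, 2, 2), c("A", "B"),
                                          "zero"))
  expect_equal(nrow(empty), 0L)
})

test_that("refine_network restricts to the initial universe and tags provenance", {
  ds <- random_dataset(40, 15, seed = 21)
  init <- score_network(ds, "hart")
  for (m in c("nd", "silencer")) {
    filt <- refine_network(init, m)
    expect_equal(nrow(filt), nrow(init))
    expect_setequal(network_pair_keys(filt), network_pair_keys(init))
    expect_equal(network_method(filt), paste0("hart+", m))
  }
  # unrestricted extraction reports every nonzero refined entry, including
  # pairs outside the initial candidate universe
  unrestricted <- refine_network(init, "nd", restrict_to_initial = FALSE)
  expect_true(all(unrestricted$score != 0))
})

test_that("refinement improves the mean rank of direct edges for PE and Hart", {
  mean_rank <- function(net, dkeys) {
    mean(match(dkeys, network_pair_keys(net)), na.rm = TRUE)
  }
  for (m in c("pe", "hart")) {
    gains <- matrix(NA_real_, 10, 2, dimnames = list(NULL, c("nd", "silencer")))
    for (s in 1:10) {
      sim <- simulate_apms(sim_config(seed = s))
      dkeys <- pair_keys_df(sim$truth$direct_edges)
      init <- score_network(sim$dataset, m)
      for (rf in colnames(gains)) {
        gains[s, rf] <- mean_rank(init, dkeys) -
          mean_rank(refine_network(init, rf), dkeys)
      }
    }
    expect_gte(mean(gains[, "nd"]), 0)
    expect_gte(mean(gains[, "silencer"]), 0)
  }
})
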