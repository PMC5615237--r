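toy_dataset <- function() {
  apms_dataset(list(
    list(id = "p1", bait = "A", preys = c("B", "C")),
    list(id = "p2", bait = "B", preys = "A")))
}

test_that("co-occurrence counts match hand counts on the toy dataset", {
  cc <- cooccurrence_counts(toy_dataset())
  expect_equal(cc$s["A", "B"], 1)
  expect_equal(cc$s["B", "A"], 1)
  expect_equal(cc$k["A", "B"], 2)
  expect_equal(cc$m["A", "B"], 0)
  expect_equal(cc$T, 3)

  # a third purification creates two co-prey events for B-C
  cc2 <- cooccurrence_counts(apms_dataset(c(
    toy_dataset()$purifications,
    list(list(id = "p3", bait = "D", preys = c("B", "C"))))))
  expect_equal(cc2$m["B", "C"], 2)
  expect_equal(cc2$k["B", "C"], 2)
})

test_that("counts equal a naive quadratic recount on random datasets", {
  off_diag <- function(M) {
    M <- as.matrix(M)
    diag(M) <- 0
    M
  }
  for (seed in 1:4) {
    ds <- random_dataset(50, 20, seed = seed)
    cc <- cooccurrence_counts(ds)
    oc <- oracle_counts(ds)
    expect_equal(off_diag(cc$s), oc$s, ignore_attr = TRUE)
    expect_equal(off_diag(cc$m), oc$m, ignore_attr = TRUE)
    expect_equal(off_diag(cc$k), oc$k, ignore_attr = TRUE)
    expect_equal(cc$b, oc$b)
    expect_equal(cc$occ, oc$occ)
    expect_equal(cc$r, oc$r)
    expect_equal(cc$T, oc$T)
    # type invariants
    expect_true(all(as.matrix(cc$k) <= outer(oc$occ, oc$occ, pmin)))
    expect_true(all(as.matrix(cc$m) <= as.matrix(cc$k)))
    expect_equal(sum(cc$r), cc$T)
  }
})

test_that("candidate universe excludes pairs that never co-occur", {
  ds <- apms_dataset(list(
    list(id = "p1", bait = "A", preys = "B"),
    list(id = "p2", bait = "C", preys = "D")))
  for (net in list(score_sa(cooccurrence_counts(ds)),
                   score_dc(cooccurrence_counts(ds)))) {
    expect_equal(nrow(net), 2L)
    expect_false("A\rC" %in% names(net_lookup(net)))
  }
})

test_that("socioaffinity is zero for a lone purification with one prey", {
  ds <- apms_dataset(list(list(id = "p1", bait = "A", preys = "B")))
  expect_equal(net_lookup(score_sa(cooccurrence_counts(ds)))[["A\rB"]], 0)
})

test_that("socioaffinity errors when no preys were ever retrieved", {
  ds <- apms_dataset(list(list(id = "p1", bait = "A", preys = character())))
  expect_error(score_sa(cooccurrence_counts(ds)), "no preys")
})

test_that("purification-enrichment spoke term cancels when background equals r", {
  # pseudo = 0 leaves f_B = r_B / T = 1/2 = r; bait A run once retrieving B,
  # B never bait, no co-prey events: every PE term is exactly zero
  ds <- apms_dataset(list(
    list(id = "p1", bait = "A", preys = "B"),
    list(id = "p2", bait = "C", preys = "D")))
  pe <- net_lookup(score_pe(cooccurrence_counts(ds), r = 0.5, pseudo = 0))
  expect_equal(pe[["A\rB"]], 0)
})

test_that("purification-enrichment rejects an out-of-range retrieval probability", {
  cc <- cooccurrence_counts(toy_dataset())
  expect_error(score_pe(cc, r = 0), "in \\(0, 1\\)")
  expect_error(score_pe(cc, r = 1.2), "in \\(0, 1\\)")
})

test_that("Dice coefficient matches hand values and stays in (0, 1]", {
  # i and j always co-occurring -> 1; partial overlap -> 2k/(occ_i+occ_j)
  ds <- apms_dataset(list(
    list(id = "p1", bait = "A", preys = "B"),
    list(id = "p2", bait = "A", preys = "B"),
    list(id = "p3", bait = "B", preys = "A"),
    list(id = "p4", bait = "A", preys = "C"),
    list(id = "p5", bait = "C", preys = character())))
  dc <- net_lookup(score_dc(cooccurrence_counts(ds)))
  expect_equal(dc[["A\rB"]], 2 * 3 / (4 + 3))
  expect_equal(dc[["A\rC"]], 2 * 1 / (4 + 2))
  for (seed in 1:3) {
    v <- score_dc(cooccurrence_counts(random_dataset(30, 12, seed)))$score
    expect_true(all(v > 0 & v <= 1))
  }
})

test_that("hypergeometric score reproduces the enumerable 2-overlap case", {
  # N=4 purifications, occ_i = occ_j = 2, overlap 2:
  # P = C(2,2) C(2,0) / C(4,2) = 1/6
  ds <- apms_dataset(list(
    list(id = "p1", bait = "A", preys = "B"),
    list(id = "p2", bait = "B", preys = "A"),
    list(id = "p3", bait = "C", preys = character()),
    list(id = "p4", bait = "D", preys = character())))
  hart <- net_lookup(score_hart(cooccurrence_counts(ds)))
  expect_equal(hart[["A\rB"]], -log10(1 / 6), tolerance = 1e-12)
})

test_that("hypergeometric p-values are clamped at the configured floor", {
  p <- apmsdirect:::hyper_tail(400, 400, 400, 400)
  expect_equal(p, 1)
  # an extreme score cannot exceed -log10(p_floor)
  ds <- random_dataset(40, 10, seed = 3)
  net <- score_hart(cooccurrence_counts(ds), p_floor = 1e-4)
  expect_true(all(net$score <= 4 + 1e-12))
})

test_that("all four scores agree with naive loop oracles on random data", {
  for (seed in 1:3) {
    ds <- random_dataset(25, 12, seed = seed)
    cc <- cooccurrence_counts(ds)
    expect_net_equals_oracle(score_sa(cc), oracle_sa(ds))
    expect_net_equals_oracle(score_pe(cc), oracle_pe(ds))
    expect_net_equals_oracle(score_dc(cc), oracle_dc(ds))
    expect_net_equals_oracle(score_hart(cc), oracle_hart(ds))
  }
})

test_that("scores are invariant under purification permutation", {
  ds <- random_dataset(30, 12, seed = 11)
  set.seed(5)
  ds_perm <- apms_dataset(ds$purifications[sample(ds$N)])
  for (m in c("sa", "pe", "dc", "hart")) {
    expect_equal(net_lookup(score_network(ds, m)),
                 net_lookup(score_network(ds_perm, m)))
  }
})

test_that("Dice and hypergeometric scores are monotone in the overlap", {
  for (N in c(10, 25)) {
    occ_i <- 6; occ_j <- 4
    k <- 1:4
    dc <- 2 * k / (occ_i + occ_j)
    hart <- -log10(apmsdirect:::hyper_tail(k, occ_i, occ_j, N))
    expect_true(all(diff(dc) > 0))
    expect_true(all(diff(hart) > 0))
    # tail symmetry under swapping successes and draws
    expect_equal(apmsdirect:::hyper_tail(k, occ_i, occ_j, N),
                 apmsdirect:::hyper_tail(k, occ_j, occ_i, N))
  }
})
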