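# Synthetic AP-MS data with known ground truth. The generator emulates the
# two noise mechanisms that dominate qualitative bait-prey data: indirect
# co-complex retrieval (preys pulled down via intermediate proteins) and
# non-specific contaminants recurring across unrelated purifications.

#' Configuration for the synthetic AP-MS generator
#'
#' Defaults describe a small but structured screen: 10 protein complexes of
#' 3-6 members, 300 purifications with baits drawn from complex members, a
#' pool of 40 recurring contaminants, direct partners retrieved with
#' probability 0.8 and indirect (co-complex, non-adjacent) partners with
#' probability 0.4, and on average 2 contaminant preys per purification.
#'
#' @param n_complexes Number of protein complexes.
#' @param complex_size_range Integer `c(min, max)` complex size; `min >= 2`.
#' @param n_contaminants Size of the contaminant pool.
#' @param n_purifications Number of purifications to simulate.
#' @param p_direct Retrieval probability of a bait's direct partners.
#' @param p_indirect Retrieval probability of co-complex non-adjacent
#'   partners; must satisfy `0 <= p_indirect < p_direct <= 1`.
#' @param contaminant_rate Poisson mean of contaminant preys per
#'   purification.
#' @param p_extra_edge Probability of each non-spanning-tree within-complex
#'   edge (complex wiring density beyond connectivity).
#' @param seed Integer seed; the whole generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_complexes = 10, complex_size_range = c(3L, 6L),
                       n_contaminants = 40, n_purifications = 300,
                       p_direct = 0.8, p_indirect = 0.4,
                       contaminant_rate = 2, p_extra_edge = 0.3,
                       seed = 1L) {
  stopifnot(n_complexes >= 1, n_contaminants >= 0, n_purifications >= 1,
            length(complex_size_range) == 2L,
            p_extra_edge >= 0, p_extra_edge <= 1, contaminant_rate >= 0)
  if (complex_size_range[1] < 2 ||
      complex_size_range[1] > complex_size_range[2]) {
    stop("complex_size_range must be an increasing pair with min >= 2")
  }
  if (!(p_indirect >= 0 && p_indirect < p_direct && p_direct <= 1)) {
    stop("need 0 <= p_indirect < p_direct <= 1")
  }
  structure(list(n_complexes = as.integer(n_complexes),
                 complex_size_range = as.integer(complex_size_range),
                 n_contaminants = as.integer(n_contaminants),
                 n_purifications = as.integer(n_purifications),
                 p_direct = p_direct, p_indirect = p_indirect,
                 contaminant_rate = contaminant_rate,
                 p_extra_edge = p_extra_edge, seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a ground-truth complex landscape
#'
#' Each complex receives a fresh set of member proteins (complexes are
#' disjoint) wired as a connected random graph: a uniform random spanning
#' tree attachment plus each remaining within-complex pair independently
#' with probability `p_extra_edge`. Direct edges are the union of complex
#' graphs; indirect pairs are co-complex pairs without a direct edge;
#' contaminants are a disjoint protein pool.
#'
#' @param config A [sim_config()].
#' @return Object of class `apms_truth` with `complexes` (list of member
#'   vectors), `adjacency` (named list: direct neighbours per member),
#'   `direct_edges` and `indirect_pairs` (two-column data frames),
#'   and `contaminants` (character vector).
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  szr <- config$complex_size_range
  complexes <- vector("list", config$n_complexes)
  ea <- character(0)
  eb <- character(0)
  ia <- character(0)
  ib <- character(0)
  next_id <- 1L
  for (c_i in seq_len(config$n_complexes)) {
    size <- if (szr[1] == szr[2]) szr[1] else sample(szr[1]:szr[2], 1L)
    members <- sprintf("P%03d", next_id:(next_id + size - 1L))
    next_id <- next_id + size
    complexes[[c_i]] <- members
    adj <- matrix(FALSE, size, size)
    for (v in 2:size) {  # spanning tree: attach each node to an earlier one
      u <- if (v == 2L) 1L else sample(v - 1L, 1L)
      adj[u, v] <- TRUE
    }
    extra <- which(upper.tri(adj) & !adj)
    if (length(extra) > 0L) {
      adj[extra[stats::runif(length(extra)) < config$p_extra_edge]] <- TRUE
    }
    idx <- which(adj, arr.ind = TRUE)
    ea <- c(ea, members[idx[, 1L]])
    eb <- c(eb, members[idx[, 2L]])
    nidx <- which(upper.tri(adj) & !adj, arr.ind = TRUE)
    ia <- c(ia, members[nidx[, 1L]])
    ib <- c(ib, members[nidx[, 2L]])
  }
  contaminants <- if (config$n_contaminants > 0) {
    sprintf("CT%03d", seq_len(config$n_contaminants))
  } else {
    character(0)
  }
  members_all <- unlist(complexes, use.names = FALSE)
  adjacency <- stats::setNames(vector("list", length(members_all)),
                               members_all)
  for (e in seq_along(ea)) {
    adjacency[[ea[e]]] <- c(adjacency[[ea[e]]], eb[e])
    adjacency[[eb[e]]] <- c(adjacency[[eb[e]]], ea[e])
  }
  structure(list(complexes = complexes,
                 adjacency = adjacency,
                 direct_edges = data.frame(protein_a = pmin(ea, eb),
                                           protein_b = pmax(ea, eb),
                                           stringsAsFactors = FALSE),
                 indirect_pairs = data.frame(protein_a = pmin(ia, ib),
                                             protein_b = pmax(ia, ib),
                                             stringsAsFactors = FALSE),
                 contaminants = contaminants),
            class = "apms_truth")
}

#' @export
print.apms_truth <- function(x, ...) {
  cat(sprintf(paste0("Ground truth: %d complexes, %d direct edges, ",
                     "%d indirect pairs, %d contaminants\n"),
              length(x$complexes), nrow(x$direct_edges),
              nrow(x$indirect_pairs), length(x$contaminants)))
  invisible(x)
}

#' Simulate purifications from a ground-truth landscape
#'
#' Each purification draws a bait uniformly from the complex members. Preys
#' are the bait's direct neighbours, each retrieved independently with
#' `p_direct`; its co-complex non-adjacent partners, each with `p_indirect`;
#' plus a Poisson(`contaminant_rate`) number of contaminants drawn without
#' replacement under Zipf(1) propensities over the contaminant pool (a few
#' sticky proteins recur in many purifications, the hallmark of non-specific
#' binding). Deterministic given the config seed.
#'
#' @param truth An [build_truth()] result consistent with `config`.
#' @param config The [sim_config()] used to build `truth`.
#' @return An [apms_dataset()].
#' @export
simulate_purifications <- function(truth, config) {
  stopifnot(inherits(truth, "apms_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  members <- unlist(truth$complexes, use.names = FALSE)
  complex_of <- rep(seq_along(truth$complexes), lengths(truth$complexes))
  names(complex_of) <- members
  n_ct <- length(truth$contaminants)
  zipf <- if (n_ct > 0) 1 / seq_len(n_ct) else numeric(0)
  baits <- sample(members, config$n_purifications, replace = TRUE)
  purs <- vector("list", config$n_purifications)
  for (p in seq_len(config$n_purifications)) {
    bait <- baits[p]
    direct <- truth$adjacency[[bait]]
    comember <- setdiff(truth$complexes[[complex_of[[bait]]]],
                        c(bait, direct))
    preys <- c(direct[stats::runif(length(direct)) < config$p_direct],
               comember[stats::runif(length(comember)) < config$p_indirect])
    if (n_ct > 0 && config$contaminant_rate > 0) {
      n_hit <- min(stats::rpois(1L, config$contaminant_rate), n_ct)
      if (n_hit > 0) {
        preys <- c(preys, sample(truth$contaminants, n_hit, prob = zipf))
      }
    }
    purs[[p]] <- list(id = sprintf("sim%04d", p), bait = bait, preys = preys)
  }
  apms_dataset(purs)
}

#' Simulate a complete synthetic AP-MS study
#'
#' Convenience wrapper: builds the ground truth and the purification dataset
#' from one config.
#'
#' @param config A [sim_config()].
#' @return List with `truth`, `dataset` and `config`.
#' @export
simulate_apms <- function(config = sim_config()) {
  truth <- build_truth(config)
  list(truth = truth, dataset = simulate_purifications(truth, config),
       config = config)
}

#' Ground-truth direct edges as a reference set
#'
#' @param truth An [build_truth()] result.
#' @return A [reference_set()] named `"direct"`.
#' @export
truth_reference <- function(truth) {
  stopifnot(inherits(truth, "apms_truth"))
  reference_set(truth$direct_edges$protein_a, truth$direct_edges$protein_b,
                name = "direct")
}
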