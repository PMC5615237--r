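# Rank-based evaluation: top-k hit curves, normalized AUC, overlap counts.

#' Top-k hit curve of a ranked network against a reference set
#'
#' Edges are taken in canonical ranking order (descending score, lexicographic
#' tie-break); `y[k]` is the number of the top `k` pairs found in the
#' reference set. If `x_max` exceeds the number of edges it is truncated to
#' it, with a message.
#'
#' @param net A non-empty [scored_network()].
#' @param ref A [reference_set()].
#' @param x_max Evaluation depth (default 10000, the conventional reporting
#'   depth for genome-scale AP-MS rankings).
#' @return Object of class `hit_curve` with `x`, `y`, `x_max`, `y_max`.
#' @export
hit_curve <- function(net, ref, x_max = 10000) {
  stopifnot(inherits(net, "scored_network"), inherits(ref, "reference_set"))
  if (nrow(net) == 0L) stop("cannot evaluate an empty network")
  if (x_max < 1) stop("x_max must be a positive integer")
  if (x_max > nrow(net)) {
    message("x_max truncated to the ", nrow(net), " available edges")
    x_max <- nrow(net)
  }
  x_max <- as.integer(x_max)
  hits <- network_pair_keys(net)[seq_len(x_max)] %in% reference_pair_keys(ref)
  y <- cumsum(hits)
  structure(list(x = seq_len(x_max), y = y, x_max = x_max,
                 y_max = y[x_max]),
            class = "hit_curve")
}

#' @export
print.hit_curve <- function(x, ...) {
  cat(sprintf("Hit curve: %d of top %d ranked pairs in the reference set\n",
              x$y_max, x$x_max))
  invisible(x)
}

#' Normalized area under a hit curve
#'
#' Trapezoidal area under the piecewise-linear curve through `(0, 0)`,
#' `(1, y[1])`, ..., `(x_max, y[x_max])`, divided by `x_max * y_max`. A curve
#' with no hits scores 0 (the defined limit); the diagonal all-hit curve
#' scores 0.5; front-loaded hits approach 1.
#'
#' @param curve A [hit_curve()].
#' @return A number in \[0, 1\].
#' @export
normalized_auc <- function(curve) {
  stopifnot(inherits(curve, "hit_curve"))
  if (curve$y_max == 0) return(0)
  y <- c(0, curve$y)
  auc <- sum((y[-length(y)] + y[-1]) / 2)
  auc / (curve$x_max * curve$y_max)
}

#' Overlap (Venn-cell) counts among top-k pair sets
#'
#' Takes each network's top `k` pairs (a shallower network is truncated to
#' its own depth, with a message) and counts the pairs falling in every
#' membership cell of the Venn diagram over the networks.
#'
#' @param nets A named list of two or more [scored_network()]s. Unnamed lists
#'   are labelled by each network's method tag.
#' @param k Reporting depth per network.
#' @return A list with `cells` (named vector: counts per nonempty membership
#'   cell, names like `"sa&pe"`), `totals` (top-k size per network) and
#'   `union_size`.
#' @export
compare_networks <- function(nets, k) {
  stopifnot(is.list(nets), length(nets) >= 2L, k >= 1)
  if (is.null(names(nets))) {
    names(nets) <- vapply(nets, network_method, character(1))
  }
  tops <- lapply(names(nets), function(nm) {
    net <- nets[[nm]]
    stopifnot(inherits(net, "scored_network"))
    kk <- k
    if (nrow(net) < k) {
      message("network '", nm, "' truncated to its ", nrow(net), " edges")
      kk <- nrow(net)
    }
    network_pair_keys(net)[seq_len(kk)]
  })
  names(tops) <- names(nets)
  universe <- unique(unlist(tops, use.names = FALSE))
  memb <- vapply(tops, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(tops)))
  cell <- apply(memb, 1L, function(row) {
    paste(names(tops)[row], collapse = "&")
  })
  list(cells = c(table(cell)),
       totals = lengths(tops),
       union_size = length(universe))
}

#' Compare an initial and a refined ranking against a reference set
#'
#' Computes both hit curves at a common depth and their normalized AUCs, and
#' flags whether refinement strictly improved the ranking (`"up"`) or not
#' (`"down"`).
#'
#' @param initial,filtered [scored_network()]s covering the same candidate
#'   universe.
#' @param ref A [reference_set()].
#' @param x_max Evaluation depth (truncated to the shallower network).
#' @return A list with `initial` and `filtered` (each a list of `curve` and
#'   `nauc`) and `verdict` (`"up"` or `"down"`).
#' @export
compare_initial_vs_filtered <- function(initial, filtered, ref,
                                        x_max = 10000) {
  x_max <- min(x_max, nrow(initial), nrow(filtered))
  ci <- hit_curve(initial, ref, x_max)
  cf <- hit_curve(filtered, ref, x_max)
  ni <- normalized_auc(ci)
  nf <- normalized_auc(cf)
  list(initial = list(curve = ci, nauc = ni),
       filtered = list(curve = cf, nauc = nf),
       verdict = if (nf > ni) "up" else "down")
}

#' Precision of a pair set among a network's top-k ranks
#'
#' @param net A [scored_network()].
#' @param pairs A [reference_set()] or two-column data frame of true pairs.
#' @param k Depth (default: the number of true pairs).
#' @return Fraction of the top `k` ranked pairs that are true pairs.
#' @export
precision_at <- function(net, pairs, k = NULL) {
  stopifnot(inherits(net, "scored_network"))
  if (inherits(pairs, "reference_set")) pairs <- pairs$pairs
  truth <- pair_key(pairs[[1L]], pairs[[2L]])
  if (is.null(k)) k <- length(truth)
  k <- min(k, nrow(net))
  if (k == 0L) return(NA_real_)
  mean(network_pair_keys(net)[seq_len(k)] %in% truth)
}
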