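# Sufficient statistics for qualitative co-occurrence scoring.

#' Co-occurrence counts for a purification dataset
#'
#' Computes, exactly, every per-protein and per-pair statistic the four
#' co-occurrence scores consume:
#'
#' * `N` — number of purifications; `sizes` — prey-list size of each.
#' * `b` — purifications where a protein is the bait; `occ` — purifications
#'   containing it in any role; `r` — its prey-slot occurrences
#'   (each purification counted once); `T = sum(r)` — total prey slots.
#' * `s[i, j]` — directed spoke count: purifications with bait `i` retrieving
#'   prey `j`.
#' * `m[i, j]` — matrix count: purifications containing both `i` and `j` as
#'   preys (their bait is then necessarily a third protein, since a bait
#'   never sits in its own prey list).
#' * `k[i, j]` — co-membership count: purifications containing both in any
#'   role. Pairs with `k >= 1` form the candidate universe for scoring.
#'
#' Pair counts are held as sparse matrices indexed by the sorted protein
#' universe.
#'
#' @param dataset An [apms_dataset()].
#' @return Object of class `cooccurrence_counts`.
#' @export
cooccurrence_counts <- function(dataset) {
  stopifnot(inherits(dataset, "apms_dataset"))
  proteins <- dataset$proteins
  n <- length(proteins)
  N <- dataset$N
  bait_idx <- match(vapply(dataset$purifications, `[[`, character(1), "bait"),
                    proteins)
  preys <- lapply(dataset$purifications, `[[`, "preys")
  sizes <- lengths(preys)
  B <- Matrix::sparseMatrix(i = seq_len(N), j = bait_idx, x = 1,
                            dims = c(N, n))
  Y <- Matrix::sparseMatrix(i = rep.int(seq_len(N), sizes),
                            j = match(unlist(preys, use.names = FALSE),
                                      proteins),
                            x = 1, dims = c(N, n))
  P <- B + Y  # roles are disjoint within a purification
  dn <- list(proteins, proteins)
  s <- Matrix::crossprod(B, Y)
  m <- Matrix::crossprod(Y)
  k <- Matrix::crossprod(P)
  dimnames(s) <- dn
  dimnames(m) <- dn
  dimnames(k) <- dn
  structure(list(
    proteins = proteins,
    N = N,
    sizes = sizes,
    b = stats::setNames(Matrix::colSums(B), proteins),
    occ = stats::setNames(Matrix::colSums(P), proteins),
    r = stats::setNames(Matrix::colSums(Y), proteins),
    T = sum(sizes),
    M2 = sum(sizes * (sizes - 1)),
    sumsize_bait = stats::setNames(as.vector(Matrix::crossprod(B, sizes)),
                                   proteins),
    s = s,
    m = m,
    k = k
  ), class = "cooccurrence_counts")
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat(sprintf(paste0("Co-occurrence counts: %d purifications, %d proteins, ",
                     "%d prey slots, %d candidate pairs\n"),
              x$N, length(x$proteins), x$T, nrow(candidate_pairs(x))))
  invisible(x)
}

# Upper-triangle (i < j, lexicographic index order) pairs with k_ij >= 1,
# plus the per-pair counts every score needs.
candidate_pairs <- function(counts) {
  ku <- methods::as(Matrix::triu(counts$k, k = 1L), "TsparseMatrix")
  keep <- ku@x > 0
  i <- ku@i[keep] + 1L
  j <- ku@j[keep] + 1L
  data.frame(i = i, j = j, k = ku@x[keep],
             s_ij = counts$s[cbind(i, j)], s_ji = counts$s[cbind(j, i)],
             m = counts$m[cbind(i, j)])
}
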