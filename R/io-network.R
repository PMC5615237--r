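# Scored networks: symmetric weighted edge lists over unordered protein pairs.

pair_key <- function(a, b) {
  if (length(a) == 0L) return(character(0))  # paste0 would recycle to "\r"
  paste0(pmin(a, b), "\r", pmax(a, b))
}

#' Construct a scored protein-pair network
#'
#' A scored network is a symmetric weighted edge list over unordered protein
#' pairs. Pairs are stored with `protein_a < protein_b` lexicographically and
#' rows in canonical ranking order: descending score, ties broken by the
#' lexicographic pair. Self-pairs and duplicate pairs are rejected.
#'
#' @param protein_a,protein_b Character vectors of protein identifiers.
#' @param score Numeric scores (method-specific units; may be negative).
#' @param method Provenance tag, e.g. `"sa"` or `"sa+nd"`.
#' @return A data frame of class `scored_network` with columns `protein_a`,
#'   `protein_b`, `score`, and a `method` attribute.
#' @export
scored_network <- function(protein_a, protein_b, score,
                           method = "unspecified") {
  a <- as.character(protein_a)
  b <- as.character(protein_b)
  score <- as.numeric(score)
  stopifnot(length(a) == length(b), length(a) == length(score))
  if (any(a == b)) stop("self-pairs are not allowed in a scored network")
  if (any(!is.finite(score) & !is.na(score))) {
    stop("non-finite scores are not allowed")
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (anyDuplicated(paste0(lo, "\r", hi))) {
    stop("duplicate unordered pairs in scored network")
  }
  ord <- order(-score, lo, hi, method = "radix")
  structure(data.frame(protein_a = lo[ord], protein_b = hi[ord],
                       score = score[ord], row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("scored_network", "data.frame"),
            method = method)
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("Scored network [%s]: %d edges, %d proteins\n",
              attr(x, "method"), nrow(x),
              length(unique(c(x$protein_a, x$protein_b)))))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

network_method <- function(net) attr(net, "method")

network_pair_keys <- function(net) pair_key(net$protein_a, net$protein_b)

#' Write / read a scored network as TSV
#'
#' The file has a `protein_a TAB protein_b TAB score` header row; rows appear
#' in canonical ranking order and scores are serialized at full double
#' precision, so `read_network(write_network(net))` is the identity.
#'
#' @param net A [scored_network()].
#' @param path File path.
#' @param method Provenance tag attached on read.
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   [scored_network()].
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "scored_network"))
  rows <- sprintf("%s\t%s\t%.17g", net$protein_a, net$protein_b, net$score)
  writeLines(c("protein_a\tprotein_b\tscore", rows), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, method = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses =
                            c("character", "character", "numeric"))
  if (!identical(names(df), c("protein_a", "protein_b", "score"))) {
    stop("not a scored-network file: ", path)
  }
  if (any(is.na(df$score))) stop("NaN/missing score in ", path)
  scored_network(df$protein_a, df$protein_b, df$score, method = method)
}
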