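# Reference sets: experimentally validated binary interactions (e.g. Y2H,
# PCA, BGS collections) used as ground truth for ranking evaluation.

#' Construct a reference set of binary interactions
#'
#' @param protein_a,protein_b Character vectors naming interacting pairs.
#' @param name Label for the collection (e.g. `"Y2H"`).
#' @return Object of class `reference_set` with a deduplicated, self-pair-free
#'   data frame `pairs` (ordered `protein_a < protein_b`) and `name`.
#' @export
reference_set <- function(protein_a, protein_b, name = "reference") {
  a <- as.character(protein_a)
  b <- as.character(protein_b)
  stopifnot(length(a) == length(b))
  self <- a == b
  if (any(self)) {
    message(sum(self), " self-pair(s) dropped from reference set '",
            name, "'")
    a <- a[!self]
    b <- b[!self]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- if (length(lo) == 0L) logical(0) else
    !duplicated(paste0(lo, "\r", hi))
  ord <- order(lo[keep], hi[keep], method = "radix")
  structure(list(pairs = data.frame(protein_a = lo[keep][ord],
                                    protein_b = hi[keep][ord],
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 name = name),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set '%s': %d binary interactions\n",
              x$name, nrow(x$pairs)))
  invisible(x)
}

reference_pair_keys <- function(ref) {
  pair_key(ref$pairs$protein_a, ref$pairs$protein_b)
}

#' Read a reference pair list from a two-column TSV file
#'
#' Each non-comment row names one unordered validated interaction. Duplicates
#' (in either order) are collapsed; self-pairs are dropped with a message.
#' An empty file yields an empty reference set.
#'
#' @param path File path.
#' @param name Label for the collection.
#' @return A [reference_set()].
#' @export
read_reference_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) return(reference_set(character(), character(), name))
  fields <- lapply(strsplit(lines[keep], "\t", fixed = TRUE), trimws)
  bad <- which(lengths(fields) != 2L |
                 !vapply(fields, function(f) all(nzchar(f)), logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("malformed reference row at line %d of %s (expected 2 fields)",
                 keep[bad[1L]], path))
  }
  reference_set(vapply(fields, `[[`, character(1), 1L),
                vapply(fields, `[[`, character(1), 2L), name)
}

#' Write a reference set as two-column TSV
#'
#' @param ref A [reference_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  writeLines(paste(ref$pairs$protein_a, ref$pairs$protein_b, sep = "\t"),
             path)
  invisible(path)
}
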