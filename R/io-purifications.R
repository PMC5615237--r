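# Purification records: one AP-MS experiment = a bait plus its retrieved preys.

#' Construct an AP-MS purification dataset
#'
#' A purification dataset is an ordered list of purifications, each holding an
#' experiment identifier, a bait protein and a duplicate-free prey set. The
#' bait never appears in its own prey list: self-retrieval is structural (the
#' tagged protein is always recovered) and carries no interaction evidence, so
#' it is stripped at construction.
#'
#' @param purifications A list whose elements are lists with components
#'   `id` (string), `bait` (string) and `preys` (character vector).
#' @return An object of class `apms_dataset` with components `purifications`,
#'   `N` (number of purifications) and `proteins` (sorted union of all bait
#'   and prey identifiers).
#' @examples
#' ds <- apms_dataset(list(
#'   list(id = "p1", bait = "A", preys = c("B", "C")),
#'   list(id = "p2", bait = "B", preys = "A")
#' ))
#' ds$N
#' ds$proteins
#' @export
apms_dataset <- function(purifications) {
  if (!is.list(purifications) || length(purifications) == 0L) {
    stop("a purification dataset needs at least one purification")
  }
  purifications <- lapply(purifications, function(p) {
    bait <- trimws(as.character(p$bait))
    preys <- trimws(as.character(p$preys))
    preys <- unique(preys[nzchar(preys) & preys != bait])
    if (!nzchar(bait)) stop("purification with empty bait identifier")
    list(id = as.character(p$id), bait = bait,
         preys = sort(preys, method = "radix"))
  })
  baits <- vapply(purifications, `[[`, character(1), "bait")
  proteins <- sort(unique(c(baits, unlist(lapply(purifications, `[[`, "preys"),
                                          use.names = FALSE))),
                   method = "radix")
  structure(list(purifications = purifications,
                 N = length(purifications),
                 proteins = proteins),
            class = "apms_dataset")
}

#' @export
print.apms_dataset <- function(x, ...) {
  s <- dataset_summary(x)
  cat(sprintf(paste0("AP-MS purification dataset: %d purifications, ",
                     "%d baits, %d preys, %d proteins, %d bait-prey pairs\n"),
              s$n_purifications, s$n_baits, s$n_preys, s$n_proteins,
              s$n_bait_prey_pairs))
  invisible(x)
}

#' Summary statistics of a purification dataset
#'
#' The four statistics conventionally reported for a qualitative AP-MS data
#' set: purification count, distinct baits, distinct preys, total proteins,
#' and the number of distinct (bait, prey) pairs.
#'
#' @param dataset An [apms_dataset()].
#' @return A list with `n_purifications`, `n_baits`, `n_preys`, `n_proteins`
#'   and `n_bait_prey_pairs`.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "apms_dataset"))
  baits <- vapply(dataset$purifications, `[[`, character(1), "bait")
  preys <- unlist(lapply(dataset$purifications, `[[`, "preys"),
                  use.names = FALSE)
  bp <- unlist(lapply(dataset$purifications,
                      function(p) paste0(p$bait, "\r", p$preys)),
               use.names = FALSE)
  list(n_purifications = dataset$N,
       n_baits = length(unique(baits)),
       n_preys = length(unique(preys)),
       n_proteins = length(dataset$proteins),
       n_bait_prey_pairs = length(unique(bp)))
}

#' Read purification records from a tab-delimited file
#'
#' Two dialects are supported. `"purification"` is the native format: one row
#' per purification, `experiment_id TAB bait TAB prey1 TAB prey2 ...` (zero
#' preys is legal). `"pairs"` is the common public-dump layout: one
#' `experiment_id TAB bait TAB prey` row per retrieved pair; rows sharing an
#' experiment id are merged into one purification. Lines starting with `#`
#' and blank lines are ignored. Identifiers are whitespace-trimmed,
#' case-sensitive and never remapped. A bait listed among its own preys is
#' dropped from the prey set.
#'
#' @param path Path to the file.
#' @param dialect `"purification"` (default) or `"pairs"`.
#' @return An [apms_dataset()].
#' @export
read_purifications <- function(path, dialect = c("purification", "pairs")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) stop("no purification records in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (dialect == "purification") {
    purs <- lapply(seq_along(keep), function(i) {
      f <- trimws(fields[[i]])
      if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
        stop(sprintf("malformed purification row at line %d of %s",
                     keep[i], path))
      }
      list(id = f[1L], bait = f[2L], preys = f[-(1:2)][nzchar(f[-(1:2)])])
    })
  } else {
    bad <- which(lengths(fields) != 3L)
    if (length(bad) > 0L) {
      stop(sprintf("malformed pair row at line %d of %s (expected 3 fields)",
                   keep[bad[1L]], path))
    }
    f <- lapply(fields, trimws)
    id <- vapply(f, `[[`, character(1), 1L)
    bait <- vapply(f, `[[`, character(1), 2L)
    prey <- vapply(f, `[[`, character(1), 3L)
    if (any(!nzchar(id) | !nzchar(bait) | !nzchar(prey))) {
      stop("pair row with empty field in ", path)
    }
    first <- !duplicated(id)
    bait_of <- stats::setNames(bait[first], id[first])
    if (any(bait != bait_of[id])) {
      i <- which(bait != bait_of[id])[1L]
      stop(sprintf("conflicting baits for experiment '%s' at line %d of %s",
                   id[i], keep[i], path))
    }
    purs <- lapply(unique(id), function(e) {
      list(id = e, bait = bait_of[[e]], preys = prey[id == e])
    })
  }
  apms_dataset(purs)
}

#' Write purification records in the native one-row-per-purification format
#'
#' @param dataset An [apms_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_purifications <- function(dataset, path) {
  stopifnot(inherits(dataset, "apms_dataset"))
  rows <- vapply(dataset$purifications, function(p) {
    paste(c(p$id, p$bait, p$preys), collapse = "\t")
  }, character(1))
  writeLines(c("# experiment_id\tbait\tpreys...", rows), path)
  invisible(path)
}
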