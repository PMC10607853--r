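#' Community table of counts with per-sample metadata
#'
#' The central container of the package: an integer matrix of read counts
#' with samples as rows and taxa (ASVs) as columns, together with a metadata
#' table giving, for every sample, its altitude (metres above sea level),
#' season (`"warm"` or `"cold"`) and site label.
#'
#' Invariants enforced at construction: counts are non-negative integers, no
#' sample row is entirely zero, sample and taxon identifiers are unique, and
#' metadata covers every sample. Taxa that are absent from every sample are
#' allowed (they arise naturally from subsetting and from simulation) and
#' are retained.
#'
#' @param counts numeric matrix, samples as rows, taxa as columns; dimnames
#'   required (sample ids as rownames, taxon ids as colnames).
#' @param metadata data.frame with columns `sample_id`, `altitude`,
#'   `season`, `site`; one row per sample of `counts` (order free).
#' @return an object of class `community_table`: a list with elements
#'   `counts` (integer matrix) and `metadata` (data.frame aligned to the
#'   rows of `counts`).
#' @examples
#' cts <- matrix(c(5L, 0L, 0L, 5L, 2L, 2L), nrow = 3, byrow = TRUE,
#'               dimnames = list(c("s1", "s2", "s3"), c("t1", "t2")))
#' md <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                  altitude = c(3118, 3363, 3550),
#'                  season = "warm", site = "A")
#' tab <- community_table(cts, md)
#' rowSums(tab$counts)
#' @export
community_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and taxon colnames")
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids")
  if (any(rowSums(counts) == 0)) stop("all-zero sample row(s) in counts")
  storage.mode(counts) <- "integer"

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "altitude", "season", "site")
  if (!all(req %in% names(metadata)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids in metadata")
  missing_md <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing_md))
    stop("metadata missing for sample(s): ", paste(head(missing_md, 5), collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), req, drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.numeric(metadata$altitude) || any(metadata$altitude <= 0))
    stop("altitude must be a positive number (m a.s.l.)")
  if (!all(metadata$season %in% c("warm", "cold")))
    stop('season must be "warm" or "cold"')

  structure(list(counts = counts, metadata = metadata),
            class = "community_table")
}

# internal: replace counts without re-running the zero-row check (used by
# filter_prevalence, which must keep the sample set unchanged)
replace_counts <- function(x, counts) {
  x$counts <- counts
  x
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x$counts), "samples x", ncol(x$counts), "taxa\n")
  cat("  altitudes:", paste(sort(unique(x$metadata$altitude)), collapse = ", "), "\n")
  cat("  seasons:  ", paste(sort(unique(x$metadata$season)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' Subset a community table by sample
#'
#' @param x a [community_table()].
#' @param samples character vector of sample ids (or logical/integer index
#'   on rows).
#' @return a `community_table` restricted to the requested samples; the
#'   taxon set is unchanged.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "community_table"))
  if (is.character(samples)) samples <- match(samples, rownames(x$counts))
  community_table(x$counts[samples, , drop = FALSE],
                  x$metadata[samples, , drop = FALSE])
}

#' Group labels for the samples of a community table
#'
#' @param x a [community_table()].
#' @param by metadata columns to combine (default altitude and season).
#' @return character vector, one label per sample, e.g. `"3118.warm"`.
#' @export
sample_groups <- function(x, by = c("altitude", "season")) {
  stopifnot(inherits(x, "community_table"))
  do.call(paste, c(x$metadata[by], sep = "."))
}
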