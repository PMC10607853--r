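#' Read a sample metadata table
#'
#' Expects a tab-separated file with header
#' `sample_id  altitude  season  site`.
#'
#' @param path file path.
#' @return data.frame with the four metadata columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "altitude", "season", "site")
  if (!all(req %in% names(md)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  md$altitude <- as.numeric(md$altitude)
  md
}

parse_count_matrix_tsv <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no data rows in count table: ", path)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in count table")
  rownames(m) <- ids
  m
}

#' Read a count table (TSV or BIOM) into a community table
#'
#' The table may have samples as rows or as columns; the orientation is
#' auto-detected by matching row/column identifiers against
#' `metadata$sample_id` (the orientation with the larger overlap wins, and a
#' taxa-by-samples table is transposed on load). BIOM input follows the BIOM
#' convention of observations (taxa) as rows; both the JSON (1.0) and HDF5
#' (2.1) serializations are accepted via the biomformat package.
#'
#' @param path path to the count file.
#' @param metadata metadata data.frame (as from [read_metadata()]) or a path
#'   to a metadata TSV.
#' @param format `"tsv"` or `"biom"`.
#' @return a [community_table()] with samples as rows, restricted to the
#'   samples present in both the counts and the metadata, in count-file
#'   order.
#' @export
read_count_table <- function(path, metadata, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (is.character(metadata)) metadata <- read_metadata(metadata)

  if (format == "tsv") {
    m <- parse_count_matrix_tsv(path)
  } else {
    b <- tryCatch(biomformat::read_biom(path),
                  error = function(e) biomformat::read_hdf5_biom(path))
    m <- t(as.matrix(biomformat::biom_data(b)))  # -> samples x taxa
  }

  if (anyDuplicated(rownames(m))) stop("duplicate row ids in count table")
  if (anyDuplicated(colnames(m))) stop("duplicate column ids in count table")
  if (anyNA(m)) stop("missing values in count table")
  if (any(m < 0)) stop("negative counts in count table")
  if (any(m != round(m))) stop("non-integer counts in count table")

  row_hits <- sum(rownames(m) %in% metadata$sample_id)
  col_hits <- sum(colnames(m) %in% metadata$sample_id)
  if (row_hits == 0 && col_hits == 0)
    stop("no id overlap between count table and metadata")
  if (col_hits > row_hits) m <- t(m)

  keep <- rownames(m) %in% metadata$sample_id
  m <- m[keep, , drop = FALSE]
  community_table(m, metadata[metadata$sample_id %in% rownames(m), , drop = FALSE])
}

#' Write a community table's counts to TSV or BIOM
#'
#' TSV output has samples as rows (first column `sample_id`); BIOM output is
#' the JSON (1.0) serialization with taxa as observations.
#'
#' @param x a [community_table()].
#' @param path output path.
#' @param format `"tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, format = c("tsv", "biom")) {
  stopifnot(inherits(x, "community_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(data = t(x$counts))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Write a metadata table to TSV
#'
#' @param metadata data.frame with `sample_id`, `altitude`, `season`, `site`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
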