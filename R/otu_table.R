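#' Construct a validated OTU count table
#'
#' An `otu_table` is an integer count matrix with samples as rows and OTUs as
#' columns. It is the central object every analysis stage consumes. The
#' constructor enforces the table invariants: counts are non-negative
#' integers, sample and OTU identifiers are unique and match the matrix
#' dimensions, and no sample is empty (total count of zero).
#'
#' @param counts numeric matrix of counts, samples x OTUs.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   `rownames(counts)`.
#' @param otu_ids character vector of OTU identifiers; defaults to
#'   `colnames(counts)`.
#' @return an `otu_table`: an integer-valued matrix with class `"otu_table"`,
#'   `rownames` = samples, `colnames` = OTUs.
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 3L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("OTU1", "OTU2")))
#' otu_table(m)
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be a numeric matrix", call. = FALSE)
  if (length(counts) == 0L) stop("empty OTU table", call. = FALSE)
  if (is.null(sample_ids) || is.null(otu_ids)) {
    stop("sample and OTU identifiers are required (row/column names)", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(counts) <- list(sample_ids, otu_ids)
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid count at sample '%s', OTU '%s': %s (counts must be non-negative integers)",
      sample_ids[bad[1, 1]], otu_ids[bad[1, 2]], format(counts[bad[1, , drop = FALSE]])),
      call. = FALSE)
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id: '", dup[1], "'", call. = FALSE)
  dup <- otu_ids[duplicated(otu_ids)]
  if (length(dup)) stop("duplicate OTU id: '", dup[1], "'", call. = FALSE)
  empty <- rowSums(counts) < 1
  if (any(empty)) {
    stop("sample(s) with zero total count: ",
         paste(sample_ids[empty], collapse = ", "), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("otu_table", "matrix", "array")
  counts
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, total count %s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Test or coerce OTU tables
#' @param x object to test.
#' @return `is_otu_table` returns a logical scalar.
#' @export
is_otu_table <- function(x) inherits(x, "otu_table")

# Subsetting preserves the class (and revalidates nothing: subsets of a valid
# table can only violate the non-empty-sample invariant, which downstream
# entry points check).
#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("otu_table", "matrix", "array")
  out
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table()].
#' @return numeric matrix of the same shape; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(is.matrix(table))
  m <- unclass(table)
  storage.mode(m) <- "double"
  sweep(m, 1, rowSums(m), "/")
}

#' Read an OTU count table from TSV
#'
#' The file must be tab-separated with one identifier axis in the header row
#' and the other in the first column; lines starting with `#` are ignored.
#' Because a transposed table is a silent, classic pipeline bug, the
#' orientation is never guessed: say which axis holds the samples.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples_rows"` if rows are samples, `"otus_rows"` if
#'   rows are OTUs (the table is transposed on read so rows are samples).
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("samples_rows", "otus_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty OTU table: ", path, call. = FALSE)
  # data.frame subsetting silently uniquifies duplicated column names, so the
  # header must be checked before the matrix is pulled out
  hdr <- names(df)[-1]
  dup <- hdr[duplicated(hdr)]
  if (length(dup)) {
    stop(if (orientation == "samples_rows") "duplicate OTU id: '" else
           "duplicate sample id: '", dup[1], "'", call. = FALSE)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
    }
    storage.mode(m) <- "double"
  }
  rownames(m) <- ids
  if (orientation == "otus_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table to TSV
#'
#' Samples are written as rows. `read_otu_table(path, "samples_rows")` is the
#' exact inverse.
#'
#' @param table an [otu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(is_otu_table(table))
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
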