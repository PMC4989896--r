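## Distance-matrix serialization: PHYLIP square format and TSV.

#' Write a dissimilarity matrix
#'
#' `write_phylip_matrix` emits the PHYLIP square distance-matrix format:
#' first line the number of samples, then one row per sample as
#' `label value ...`, labels padded (and, unless `relaxed`, truncated) to
#' 10 characters.  `write_tsv_matrix` emits a TSV with full labels in the
#' first row and column.
#'
#' @param m a `dissimilarity_matrix` or plain labelled symmetric matrix.
#' @param path output file.
#' @param relaxed allow labels longer than 10 characters (padded with a
#'   trailing space instead of truncated); non-standard but unambiguous.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path, relaxed = FALSE) {
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("S", seq_len(nrow(m)))
  if (!relaxed) labs <- substr(labs, 1L, 10L)
  labs <- formatC(labs, width = -10L)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    # explicit separator: a 10-character label would otherwise abut the data
    paste0(labs[i], " ", paste(sprintf("%.10f", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(sprintf("%5d", nrow(m)), rows), path)
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
write_tsv_matrix <- function(m, path) {
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("S", seq_len(nrow(m)))
  header <- paste(c("", labs), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labs[i], sprintf("%.10g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path file in PHYLIP square format (as written by
#'   [write_phylip_matrix()]).
#' @return labelled symmetric matrix.
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 2L)
    stop("malformed PHYLIP matrix (", path, "): bad sample count line")
  if (length(lines) != n + 1L)
    stop("malformed PHYLIP matrix (", path, "): expected ", n, " rows, found ",
         length(lines) - 1L)
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
    if (length(f) != n + 1L)
      stop("malformed PHYLIP matrix (", path, "): row ", i, " has ",
           length(f) - 1L, " values, expected ", n)
    labs[i] <- f[1]
    m[i, ] <- as.numeric(f[-1])
  }
  if (anyNA(m)) stop("malformed PHYLIP matrix (", path, "): non-numeric entry")
  dimnames(m) <- list(labs, labs)
  m
}

#' Read a TSV matrix written by [write_tsv_matrix()]
#'
#' @param path TSV file with labels in first row and column.
#' @return labelled matrix.
#' @export
read_tsv_matrix <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  dimnames(m) <- list(rownames(d), colnames(d))
  m
}

## file name stem for one measure: <prefix>.<measure>.<k>.<ext>
matrix_file_name <- function(prefix, measure, k, ext) {
  paste0(prefix, ".", measure, ".", k, ".", ext)
}
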