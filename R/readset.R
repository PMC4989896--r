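#' Read records and read sets
#'
#' A `read_record` is a single sequencing read: an identifier, a DNA sequence
#' over `{A,C,G,T,N}`, and one integer phred score per base.  A `read_set` is
#' the unit of comparison for all dissimilarity measures: a labelled
#' collection of reads, typically one FASTQ file (one sample).
#'
#' `M` is the number of original reads in the set, before any
#' reverse-complement supplementation, and `beta` the read length.  When read
#' lengths vary, `beta` is the mean length and `uniform_length` is `FALSE`;
#' window-count normalizations then use per-read lengths rather than
#' `M * (beta - k + 1)`.
#'
#' @param id character identifier.
#' @param sequence DNA string over `{A,C,G,T,N}` (lower case accepted,
#'   uppercased on construction).
#' @param qualities integer vector of phred scores, one per base, all `>= 0`.
#' @return `read_record()` returns an object of class `"read_record"`;
#'   `read_set()` an object of class `"read_set"`.
#' @examples
#' r <- read_record("r1", "ACGT", c(30, 30, 30, 30))
#' rs <- read_set(list(r), label = "sample1")
#' rs$M
#' @export
read_record <- function(id, sequence, qualities) {
  sequence <- toupper(sequence)
  if (grepl("U", sequence, fixed = TRUE))
    stop("sequence contains 'U': only DNA alphabet {A,C,G,T,N} is accepted")
  if (grepl("[^ACGTN]", sequence))
    stop("read '", id, "': sequence contains characters outside {A,C,G,T,N}")
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities))
    stop("read '", id, "': sequence length (", nchar(sequence),
         ") != number of quality scores (", length(qualities), ")")
  if (any(qualities < 0))
    stop("read '", id, "': negative phred score")
  structure(list(id = id, sequence = sequence, qualities = qualities),
            class = "read_record")
}

#' @param reads list of `read_record` objects.
#' @param label sample name.
#' @rdname read_record
#' @export
read_set <- function(reads, label = "sample") {
  stopifnot(is.list(reads))
  if (length(reads) == 0L) stop("read set '", label, "' is empty")
  lens <- vapply(reads, function(r) nchar(r$sequence), integer(1))
  structure(list(label = label,
                 reads = reads,
                 M = length(reads),
                 beta = mean(lens),
                 uniform_length = length(unique(lens)) == 1L),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set '%s': %d reads, mean length %.1f%s\n",
              x$label, x$M, x$beta,
              if (x$uniform_length) "" else " (heterogeneous)"))
  invisible(x)
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("read_record '%s': %s (Q: %s)\n", x$id, x$sequence,
              paste(x$qualities, collapse = ",")))
  invisible(x)
}

#' Convert a phred score to an error probability
#'
#' The phred scale defines `Q = -10 log10(p_error)`, so a score of 30 means a
#' 1-in-1000 chance that the base call is wrong.
#'
#' @param q numeric vector of phred scores, all `>= 0`.
#' @return `10^(-q/10)`, in `(0, 1]`.
#' @examples
#' quality_to_error_prob(30)  # 0.001
#' @export
quality_to_error_prob <- function(q) {
  if (any(q < 0)) stop("phred scores must be >= 0")
  10^(-q / 10)
}

#' Probability that an entire read is correct
#'
#' Assuming independent errors across positions, the probability that every
#' base of the read is called correctly is the product of
#' `1 - 10^(-Q(i)/10)` over all positions `i`.
#'
#' @param read a `read_record`.
#' @return probability in `[0, 1]`.
#' @export
read_correctness_prob <- function(read) {
  stopifnot(inherits(read, "read_record"))
  if (length(read$qualities) == 0L) stop("empty read")
  prod(1 - quality_to_error_prob(read$qualities))
}

#' Read a FASTQ file into a read set
#'
#' Only strict 4-line-per-record FASTQ is accepted (no line wrapping).
#' Qualities are decoded as `ASCII - phred_offset`; a decoded negative score
#' raises an error suggesting the other common offset.
#'
#' @param path path to an (optionally gzipped) FASTQ file.
#' @param phred_offset 33 (Sanger / Illumina 1.8+, the default) or 64.
#' @param label sample label; defaults to the file basename without extension.
#' @return a `read_set`.
#' @export
read_fastq <- function(path, phred_offset = 33, label = NULL) {
  if (!phred_offset %in% c(33L, 64L))
    stop("phred_offset must be 33 or 64")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTQ file: ", path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): number of lines (", length(lines),
         ") is not a multiple of 4; wrapped FASTQ is not supported")
  n <- length(lines) %/% 4L
  ids  <- sub("^@", "", sub("[ \t].*$", "", lines[seq(1L, by = 4L, length.out = n)]))
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(!startsWith(plus, "+")))
    stop("malformed FASTQ (", path, "): record ",
         which(!startsWith(plus, "+"))[1], " has no '+' separator line")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L)
    stop("malformed FASTQ (", path, "): record '", ids[bad[1]],
         "' (#", bad[1], "): sequence and quality lines differ in length")
  if (is.null(label)) label <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    q <- utf8ToInt(quals[i]) - phred_offset
    if (any(q < 0))
      stop("dialect error (", path, "): record '", ids[i],
           "' decodes to a negative phred score with offset ", phred_offset,
           "; try phred_offset = ", if (phred_offset == 33) 64 else 33)
    reads[[i]] <- read_record(ids[i], seqs[i], q)
  }
  read_set(reads, label = label)
}

#' Write a read set as FASTQ
#'
#' @param rs a `read_set`.
#' @param path output path.
#' @param phred_offset quality encoding offset (33 or 64).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path, phred_offset = 33) {
  stopifnot(inherits(rs, "read_set"))
  con <- file(path, "w")
  on.exit(close(con))
  out <- vapply(rs$reads, function(r) {
    paste0("@", r$id, "\n", r$sequence, "\n+\n",
           intToUtf8(r$qualities + phred_offset))
  }, character(1))
  writeLines(out, con)
  invisible(path)
}

#' Load a sample list (file of files)
#'
#' One line per sample: `path[TAB]label`.  The label is optional and defaults
#' to the file basename without its FASTQ extension.  Lines starting with
#' `#` and blank lines are ignored.  Relative paths are resolved against the
#' directory containing the list file.  The line order defines the
#' row/column order of all output matrices.
#'
#' @param path path to the list file.
#' @return data.frame with columns `path` and `label`.
#' @export
load_sample_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("sample list '", path, "' lists no files")
  parts <- strsplit(lines, "\t")
  paths <- vapply(parts, `[`, character(1), 1L)
  labels <- vapply(parts, function(p) {
    if (length(p) >= 2L && nzchar(p[2])) p[2]
    else sub("\\.(fastq|fq)(\\.gz)?$", "", basename(p[1]))
  }, character(1))
  base <- dirname(path)
  paths <- ifelse(file.exists(paths) | grepl("^/", paths),
                  paths, file.path(base, paths))
  missing <- which(!file.exists(paths))
  if (length(missing) > 0L)
    stop("sample list '", path, "', line entry ", missing[1],
         ": file not found: ", paths[missing[1]])
  if (anyDuplicated(labels))
    stop("sample list '", path, "': duplicate label '",
         labels[anyDuplicated(labels)], "'; matrix labels must be unique")
  data.frame(path = paths, label = labels, stringsAsFactors = FALSE)
}
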