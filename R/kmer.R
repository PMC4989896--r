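## k-mer counting over complement-supplemented read sets.
##
## Words are keyed internally by their 2-bit code (A=0, C=1, G=2, T=3, most
## significant digit first), stored in a double; exact up to k = 26.  All
## counting is done on the original reads only; strand symmetry is obtained
## by folding each word's tally with that of its reverse complement, which is
## numerically identical to counting over the supplemented read list (the
## complement read carries the reversed quality string, so a window and its
## mirrored window share the same correctness product).

.KMERQ_MAX_K <- 26L

.base_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut
})

## integer base codes (0..3, NA for N) for one string
encode_bases <- function(s) .base_lut[utf8ToInt(s)]

decode_kmer <- function(codes, k) {
  out <- character(length(codes))
  letters4 <- c("A", "C", "G", "T")
  for (i in seq_along(codes)) {
    c0 <- codes[i]
    d <- integer(k)
    for (j in k:1) {
      d[j] <- c0 %% 4
      c0 <- (c0 - d[j]) / 4
    }
    out[i] <- paste(letters4[d + 1], collapse = "")
  }
  out
}

encode_kmer <- function(words) {
  vapply(words, function(w) {
    b <- encode_bases(w)
    sum(b * 4^(rev(seq_along(b)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

## reverse-complement of 2-bit codes, vectorized
rc_codes <- function(codes, k) {
  res <- numeric(length(codes))
  c0 <- codes
  for (j in seq_len(k)) {
    d <- c0 %% 4
    c0 <- (c0 - d) / 4
    res <- res * 4 + (3 - d)
  }
  res
}

#' Reverse complement of a DNA string
#'
#' @param w character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements (`N` maps to `N`).
#' @examples
#' reverse_complement("AAC")  # "GTT"
#' @export
reverse_complement <- function(w) {
  if (any(grepl("[^ACGTNacgtn]", w)))
    stop("reverse_complement: characters outside {A,C,G,T,N}")
  x <- chartr("ACGTNacgtn", "TGCANtgcan", w)
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Supplement a read set with reverse complements
#'
#' Returns the joint set of the `M` original reads and their `M` reverse
#' complements.  Base `i` of a complement read derives from base
#' `len - 1 - i` of the original, so it inherits that base's quality: the
#' complement's quality vector is the reversal of the original's.  `M` and
#' `beta` of the returned set describe the original reads.
#'
#' @param rs a `read_set`.
#' @return a `read_set` with `2M` reads and `M`, `beta` of the original set.
#' @export
supplement_with_complements <- function(rs) {
  stopifnot(inherits(rs, "read_set"))
  comp <- lapply(rs$reads, function(r) {
    read_record(paste0(r$id, "_rc"),
                reverse_complement(r$sequence),
                rev(r$qualities))
  })
  out <- read_set(c(rs$reads, comp), label = rs$label)
  out$M <- rs$M          # M counts original reads only
  out$beta <- rs$beta
  out
}

#' Correctness probability of one word occurrence
#'
#' Probability that all `k` bases under a window are called correctly:
#' the product of `1 - 10^(-Q/10)` over the window's quality slice.
#'
#' @param qualities_slice integer vector of `k` phred scores.
#' @return probability in `[0, 1]`.
#' @export
occurrence_correctness <- function(qualities_slice) {
  prod(1 - quality_to_error_prob(qualities_slice))
}

## Shared single pass over the original reads of a read set.
## Returns observed word codes (original strand), their plain and
## quality-weighted tallies, the number of valid original windows, and
## strand-symmetrized nucleotide counts.
.scan_readset <- function(rs, k, weighted = TRUE) {
  lens <- vapply(rs$reads, function(r) nchar(r$sequence), integer(1))
  if (k < 1L) stop("k must be >= 1")
  if (k > .KMERQ_MAX_K) stop("k > ", .KMERQ_MAX_K, " is not supported")
  if (all(lens < k))
    stop("k = ", k, " exceeds every read length in '", rs$label, "'")
  ## concatenate with an N separator so windows never span two reads
  b <- encode_bases(paste(vapply(rs$reads, `[[`, character(1), "sequence"),
                          collapse = "N"))
  n <- length(b)
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) code <- code * 4 + b[(1L + j):(m + j)]
  valid <- !is.na(code)
  codes_obs <- code[valid]

  wts <- NULL
  if (weighted) {
    q <- unlist(lapply(rs$reads, function(r) c(r$qualities, 0L)),
                use.names = FALSE)
    q <- q[-length(q)]                     # drop trailing separator quality
    l1p <- log1p(-quality_to_error_prob(q))
    acc <- numeric(m)
    for (j in 0:(k - 1L)) acc <- acc + l1p[(1L + j):(m + j)]
    wts <- exp(acc[valid])
  }

  u <- sort(unique(codes_obs))
  idx <- match(codes_obs, u)
  cnt <- tabulate(idx, nbins = length(u))
  wsum <- NULL
  if (weighted) {
    wsum <- numeric(length(u))
    tmp <- rowsum(wts, idx)
    wsum[as.integer(rownames(tmp))] <- tmp[, 1]
  }

  nb <- tabulate(b + 1L, nbins = 4L)
  nuc <- nb + rev(nb)                      # fold in complement strand

  list(codes = u, count = cnt, wsum = wsum,
       windows = as.numeric(sum(valid)), nuc_counts = nuc)
}

## Fold original-strand tallies with their reverse complements; support of
## the supplemented set is union(u, rc(u)).
.fold_strands <- function(u, k, ...) {
  vecs <- list(...)
  rcu <- rc_codes(u, k)
  full <- sort(unique(c(u, rcu)))
  m1 <- match(full, u)
  m2 <- match(rc_codes(full, k), u)
  out <- lapply(vecs, function(v) {
    a <- ifelse(is.na(m1), 0, v[m1])
    b <- ifelse(is.na(m2), 0, v[m2])
    a + b
  })
  c(list(codes = full), out)
}

#' Count k-mer occurrences in a read set
#'
#' Counts every overlapping length-`k` window over the read set supplemented
#' with the reverse complements of its reads, so counts are
#' strand-symmetric: `counts[w] == counts[rc(w)]` for every word.  Windows
#' containing `N` are skipped entirely and excluded from the window totals.
#'
#' @param rs a `read_set`.
#' @param k word length (`1 <= k <= 26`).
#' @return an object of class `"kmer_counts"`: a list with elements
#'   \describe{
#'     \item{k}{word length.}
#'     \item{codes}{sorted 2-bit codes of the observed words.}
#'     \item{count}{occurrence counts `X_w` aligned with `codes`.}
#'     \item{windows}{number of valid windows over the original reads,
#'       `sum(len - k + 1)` minus skipped ambiguous windows; this is the
#'       `M(beta - k + 1)` factor of the expectation formulas.}
#'     \item{total_positions}{`2 * windows`, the number of counted windows
#'       over the supplemented set; equals `sum(count)`.}
#'     \item{nuc_counts}{strand-symmetrized A/C/G/T counts, for background
#'       estimation.}
#'   }
#' @seealso [count_kmers_weighted()], [kmer_count_table()]
#' @export
count_kmers <- function(rs, k) {
  sc <- .scan_readset(rs, k, weighted = FALSE)
  f <- .fold_strands(sc$codes, k, count = sc$count)
  structure(list(k = as.integer(k), codes = f$codes, count = f$count,
                 windows = sc$windows, total_positions = 2 * sc$windows,
                 nuc_counts = sc$nuc_counts, label = rs$label),
            class = "kmer_counts")
}

#' Count k-mers weighted by occurrence correctness
#'
#' As [count_kmers()], but each occurrence contributes its correctness
#' probability (the product of `1 - 10^(-Q/10)` over the window) instead of
#' 1.  The plain counts from the same pass are kept alongside so that
#' posterior quality expectations `(X^q_w + Y^q_w) / (X_w + Y_w)` can be
#' formed.
#'
#' @inheritParams count_kmers
#' @return an object of class `c("kmer_counts_q", "kmer_counts")` with the
#'   fields of [count_kmers()] plus `weighted`, the quality-weighted counts
#'   `X^q_w` aligned with `codes`.
#' @export
count_kmers_weighted <- function(rs, k) {
  sc <- .scan_readset(rs, k, weighted = TRUE)
  f <- .fold_strands(sc$codes, k, count = sc$count, weighted = sc$wsum)
  structure(list(k = as.integer(k), codes = f$codes, count = f$count,
                 weighted = f$weighted,
                 windows = sc$windows, total_positions = 2 * sc$windows,
                 nuc_counts = sc$nuc_counts, label = rs$label),
            class = c("kmer_counts_q", "kmer_counts"))
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("kmer_counts '%s': k=%d, %d distinct words, %d windows%s\n",
              x$label %||% "?", x$k, length(x$codes), x$total_positions,
              if (!is.null(x$weighted)) " (quality-weighted)" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count table as a named vector
#'
#' Convenience accessor returning counts keyed by word string.
#'
#' @param x a `kmer_counts` object.
#' @param weighted return quality-weighted counts instead of plain ones.
#' @return named numeric vector.
#' @export
kmer_count_table <- function(x, weighted = FALSE) {
  stopifnot(inherits(x, "kmer_counts"))
  v <- if (weighted) {
    if (is.null(x$weighted)) stop("no weighted counts in this object")
    x$weighted
  } else x$count
  stats::setNames(v, decode_kmer(x$codes, x$k))
}

#' Estimate an order-0 background model
#'
#' Tallies nucleotide frequencies over all reads of the given sets, pooled
#' and supplemented with reverse complements (so the frequencies are
#' strand-symmetric: `f(A) == f(T)`, `f(C) == f(G)`), and models the null
#' word probability `p_w` as the product of letter frequencies.  `N` bases
#' are excluded.
#'
#' @param readsets a `read_set`, a list of `read_set`s, or a list of
#'   `kmer_counts` objects (which carry their nucleotide tallies).
#' @return an object of class `"background_model"` with elements `order`
#'   (0) and `nucleotide_freqs` (named probabilities over A,C,G,T).
#' @export
estimate_background <- function(readsets) {
  if (inherits(readsets, "read_set") || inherits(readsets, "kmer_counts"))
    readsets <- list(readsets)
  if (length(readsets) == 0L) stop("no read sets given")
  nuc <- numeric(4)
  for (rs in readsets) {
    if (inherits(rs, "kmer_counts")) {
      nuc <- nuc + rs$nuc_counts
    } else if (inherits(rs, "read_set")) {
      b <- encode_bases(paste(vapply(rs$reads, `[[`, character(1), "sequence"),
                              collapse = ""))
      nb <- tabulate(b + 1L, nbins = 4L)
      nuc <- nuc + nb + rev(nb)
    } else stop("expected read_set or kmer_counts objects")
  }
  if (sum(nuc) == 0) stop("no unambiguous bases to estimate background from")
  background_model(nuc / sum(nuc))
}

#' @param nucleotide_freqs probabilities over A,C,G,T summing to 1.
#' @rdname estimate_background
#' @export
background_model <- function(nucleotide_freqs) {
  f <- as.numeric(nucleotide_freqs)
  stopifnot(length(f) == 4, all(f >= 0))
  if (abs(sum(f) - 1) > 1e-12) stop("nucleotide frequencies must sum to 1")
  structure(list(order = 0L,
                 nucleotide_freqs = stats::setNames(f, c("A", "C", "G", "T"))),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("background_model (order 0):",
      paste(sprintf("%s=%.4f", names(x$nucleotide_freqs),
                    x$nucleotide_freqs), collapse = " "), "\n")
  invisible(x)
}

#' Null word probabilities under a background model
#'
#' @param bg a `background_model`.
#' @param words word codes (numeric) or word strings (character).
#' @param k word length (required when `words` is numeric).
#' @return numeric vector of `p_w`.
#' @export
word_probability <- function(bg, words, k = NULL) {
  stopifnot(inherits(bg, "background_model"))
  if (is.character(words)) {
    k <- nchar(words[1])
    words <- encode_kmer(words)
  }
  if (is.null(k)) stop("k is required for coded words")
  p <- rep(1, length(words))
  c0 <- words
  for (j in seq_len(k)) {
    d <- c0 %% 4
    c0 <- (c0 - d) / 4
    p <- p * bg$nucleotide_freqs[d + 1]
  }
  unname(p)
}

#' Sequence length at which a k-mer is expected once
#'
#' Under a uniform model, words of length `log4(N)` are expected to occur
#' about once in a sequence of length `N`; shorter words recur, longer ones
#' are mostly absent.  Useful as a rule of thumb for choosing `k`.
#'
#' @param n sequence length in bases.
#' @return `log4(n)`.
#' @examples
#' expected_unique_kmer_length(5000)  # ~ 6.14
#' @export
expected_unique_kmer_length <- function(n) {
  stopifnot(n > 0)
  log(n, base = 4)
}
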