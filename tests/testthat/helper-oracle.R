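# Independent brute-force oracles: straight-from-the-formula
# implementations used to validate the streaming counters and the
# D2-family statistics on tiny instances.  They share no code with the
# package internals beyond the public occurrence_correctness /
# supplement_with_complements operations they are defined in terms of.

`%or0%` <- function(a, b) if (is.null(a)) b else a

# random read set; qualities uniform in [qmin, qmax], optional N bases
random_readset <- function(M, beta, label = "rnd", with_N = FALSE,
                           qmin = 2, qmax = 40, alphabet_bias = NULL) {
  letters4 <- c("A", "C", "G", "T")
  reads <- lapply(seq_len(M), function(i) {
    pool <- if (with_N) c(letters4, "N") else letters4
    prob <- if (is.null(alphabet_bias)) NULL else {
      p <- c(alphabet_bias, if (with_N) 0.05)
      p / sum(p)
    }
    s <- paste(sample(pool, beta, replace = TRUE, prob = prob), collapse = "")
    read_record(paste0("r", i), s, sample(qmin:qmax, beta, replace = TRUE))
  })
  read_set(reads, label = label)
}

# naive window-scan counts over the explicitly supplemented read list
oracle_counts <- function(rs, k) {
  supp <- supplement_with_complements(rs)
  plain <- list(); weighted <- list()
  windows <- 0L
  for (r in supp$reads) {
    L <- nchar(r$sequence)
    if (L < k) next
    for (i in seq_len(L - k + 1L)) {
      w <- substr(r$sequence, i, i + k - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      plain[[w]] <- (plain[[w]] %or0% 0) + 1
      weighted[[w]] <- (weighted[[w]] %or0% 0) +
        occurrence_correctness(r$qualities[i:(i + k - 1L)])
      windows <- windows + 1L
    }
  }
  words <- sort(names(plain))
  empty <- stats::setNames(numeric(0), character(0))
  list(plain = unlist(plain)[words] %or0% empty,
       weighted = unlist(weighted)[words] %or0% empty,
       total = windows)
}

# order-0 background frequencies over the supplemented pooled reads
oracle_freqs <- function(readsets) {
  tally <- c(A = 0, C = 0, G = 0, T = 0)
  for (rs in readsets) {
    supp <- supplement_with_complements(rs)
    for (r in supp$reads) {
      ch <- strsplit(r$sequence, "")[[1]]
      for (b in names(tally)) tally[b] <- tally[b] + sum(ch == b)
    }
  }
  tally / sum(tally)
}

oracle_pw <- function(word, freqs) {
  prod(freqs[strsplit(word, "")[[1]]])
}

# all eight statistics, straight from the formulas, summing over the words
# observed in at least one of the two samples
oracle_statistics <- function(rsx, rsy, k, literal_d2 = FALSE) {
  cx <- oracle_counts(rsx, k)
  cy <- oracle_counts(rsy, k)
  freqs <- oracle_freqs(list(rsx, rsy))
  words <- sort(union(names(cx$plain), names(cy$plain)))
  g <- function(v, w) if (w %in% names(v)) v[[w]] else 0
  X <- vapply(words, g, numeric(1), v = cx$plain)
  Y <- vapply(words, g, numeric(1), v = cy$plain)
  Xq <- vapply(words, g, numeric(1), v = cx$weighted)
  Yq <- vapply(words, g, numeric(1), v = cy$weighted)
  pw <- vapply(words, oracle_pw, numeric(1), freqs = freqs)
  pwb <- vapply(reverse_complement(words), oracle_pw, numeric(1), freqs = freqs)
  WX <- cx$total / 2   # original-strand valid windows
  WY <- cy$total / 2
  W <- sqrt(WX * WY)
  pp <- pw + pwb

  Xt <- X - WX * pp
  Yt <- Y - WY * pp
  ew <- (Xq + Yq) / (X + Y)
  Xqt <- Xq - WX * pp * ew
  Yqt <- Yq - WY * pp * ew

  D2 <- sum(X * Y)
  D2star <- sum(Xt * Yt / (W * pp))
  D2q <- sum(Xq * Yq)
  D2qstar <- sum(Xqt * Yqt / (W * pp * ew))
  half <- function(r) if (literal_d2) 0.5 * r else 0.5 * (1 - r)
  c(D2 = D2,
    D2star = D2star,
    D2q = D2q,
    D2qstar = D2qstar,
    d2 = half(D2 / (sqrt(sum(X^2)) * sqrt(sum(Y^2)))),
    d2star = half(W * D2star / (sqrt(sum(Xt^2 / pw)) * sqrt(sum(Yt^2 / pw)))),
    d2q = half(D2q / (sqrt(sum(Xq^2)) * sqrt(sum(Yq^2)))),
    d2qstar = half(W * D2qstar /
                     (sqrt(sum(Xqt^2 / pw)) * sqrt(sum(Yqt^2 / pw)))))
}

# package-side statistics for the same pair
package_statistics <- function(rsx, rsy, k, literal_d2 = FALSE) {
  ctx <- pair_context(count_kmers_weighted(rsx, k), count_kmers_weighted(rsy, k))
  kmerq:::pair_statistics(ctx, literal_d2 = literal_d2)
}
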