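## D2-family statistics for pairs of read sets.
##
## All statistics operate on strand-symmetric counts (see count_kmers) and a
## shared order-0 background model.  Word sums iterate over the words
## observed in at least one of the two samples: for unobserved words the
## posterior quality expectation (X^q+Y^q)/(X+Y) is 0/0, and their
## centralized products would contribute background-only signal, so they are
## excluded from all starred sums and self norms.

MEASURE_NAMES <- c("D2", "D2star", "D2q", "D2qstar",
                   "d2", "d2star", "d2q", "d2qstar")

#' Canonical measure names
#'
#' Maps user-facing spellings (`"d2*"`, `"d2q*"`, case variants) onto the
#' internal measure names used in matrices and file names.
#'
#' @param x character vector of measure names.
#' @return character vector of canonical names among
#'   `D2, D2star, D2q, D2qstar, d2, d2star, d2q, d2qstar`.
#' @export
canonical_measure <- function(x) {
  ## case is significant: "D2" is the raw statistic, "d2" the dissimilarity
  key <- gsub("\\*", "star", x)
  hit <- match(key, MEASURE_NAMES)
  if (anyNA(hit)) stop("unknown measure(s): ", paste(x[is.na(hit)], collapse = ", "),
                       " (expected among: ", paste(MEASURE_NAMES, collapse = ", "),
                       "; '*' may be written for 'star')")
  MEASURE_NAMES[hit]
}

#' Build the pairwise comparison context for two samples
#'
#' Aligns the counts of two samples on the union of their observed words and
#' attaches the background word probabilities.  All raw statistics and
#' normalized dissimilarities are computed from this context.
#'
#' @param cx,cy `kmer_counts_q` objects for the two samples (from
#'   [count_kmers_weighted()]), built with the same `k`.
#' @param background a `background_model`; by default estimated from the two
#'   samples pooled (strand-symmetric order-0 model).
#' @return an object of class `"pair_context"`: word codes (union support),
#'   aligned vectors `X`, `Y`, `Xq`, `Yq`, window totals `WX`, `WY`, and the
#'   null probabilities `pw` and `pw_bar`.
#' @export
pair_context <- function(cx, cy, background = NULL) {
  stopifnot(inherits(cx, "kmer_counts"), inherits(cy, "kmer_counts"))
  if (cx$k != cy$k) stop("count vectors built with different k")
  k <- cx$k
  if (is.null(background)) background <- estimate_background(list(cx, cy))
  codes <- sort(unique(c(cx$codes, cy$codes)))
  mx <- match(codes, cx$codes)
  my <- match(codes, cy$codes)
  take <- function(v, m) ifelse(is.na(m), 0, v[m])
  pw <- word_probability(background, codes, k)
  pwb <- word_probability(background, rc_codes(codes, k), k)
  structure(list(k = k, codes = codes,
                 X = take(cx$count, mx), Y = take(cy$count, my),
                 Xq = if (!is.null(cx$weighted)) take(cx$weighted, mx),
                 Yq = if (!is.null(cy$weighted)) take(cy$weighted, my),
                 WX = cx$windows, WY = cy$windows,
                 pw = pw, pw_bar = pwb,
                 background = background,
                 labels = c(cx$label %||% "X", cy$label %||% "Y")),
            class = "pair_context")
}

#' Centralize an observed count
#'
#' Subtracts the expected count under the null model,
#' `windows * (p_w + p_wbar)`, from the observed count.  `windows` is the
#' number of original-read windows (`M(beta - k + 1)` for uniform reads);
#' the `p_w + p_wbar` factor accounts for complement supplementation.
#'
#' @param count observed count (plain or quality-weighted).
#' @param windows window total of the sample.
#' @param p_pair `p_w + p_wbar` (optionally times a quality expectation).
#' @return centralized count; may be negative.
#' @export
centralized_count <- function(count, windows, p_pair) {
  stopifnot(all(windows > 0))
  count - windows * p_pair
}

#' Posterior quality expectation for a word
#'
#' Estimates `E(P_w) + E(P_wbar)` — the expected correctness of an
#' occurrence of `w` (strand-folded) — by the posterior relative frequency
#' `(X^q_w + Y^q_w) / (X_w + Y_w)` over both samples of a pair.
#'
#' @param ctx a `pair_context` with weighted counts.
#' @param w word string or code; defaults to all words in the context.
#' @return numeric vector in `(0, 1]`.
#' @export
expected_correctness_pair <- function(ctx, w = NULL) {
  stopifnot(inherits(ctx, "pair_context"))
  if (is.null(ctx$Xq)) stop("context has no quality-weighted counts")
  if (is.null(w)) {
    tot <- ctx$X + ctx$Y
    if (any(tot == 0)) stop("word with zero total count in context support")
    return((ctx$Xq + ctx$Yq) / tot)
  }
  if (is.character(w)) w <- encode_kmer(w)
  i <- match(w, ctx$codes)
  if (anyNA(i)) stop("word not observed in either sample: E(P_w) undefined")
  (ctx$Xq[i] + ctx$Yq[i]) / (ctx$X[i] + ctx$Y[i])
}

## shared guard for starred statistics
.check_background <- function(ctx) {
  pp <- ctx$pw + ctx$pw_bar
  bad <- pp <= 0 & (ctx$X + ctx$Y) > 0
  if (any(bad))
    stop("background model assigns probability 0 to an observed word (",
         decode_kmer(ctx$codes[which(bad)[1]], ctx$k),
         "): background inconsistent with data")
  pp
}

#' Raw D2-family statistics for a pair of read sets
#'
#' `d2_raw` is the inner product of the two count vectors.  `d2star_raw`
#' centralizes each count by its null expectation and scales by the
#' expectation; `d2q_raw`/`d2qstar_raw` are the quality-weighted analogues
#' in which each occurrence contributes its correctness probability and the
#' centralization carries the posterior quality expectation.  Starred sums
#' run over words observed in at least one sample, with the symmetrized
#' window total `W = sqrt(WX * WY)` standing in for `M(beta - k + 1)` when
#' the samples differ in size.
#'
#' @param ctx a `pair_context`.
#' @return a single numeric value.
#' @export
d2_raw <- function(ctx) {
  stopifnot(inherits(ctx, "pair_context"))
  sum(ctx$X * ctx$Y)
}

#' @rdname d2_raw
#' @export
d2star_raw <- function(ctx) {
  stopifnot(inherits(ctx, "pair_context"))
  pp <- .check_background(ctx)
  Xt <- centralized_count(ctx$X, ctx$WX, pp)
  Yt <- centralized_count(ctx$Y, ctx$WY, pp)
  W <- sqrt(ctx$WX * ctx$WY)
  sum(Xt * Yt / (W * pp))
}

#' @rdname d2_raw
#' @export
d2q_raw <- function(ctx) {
  stopifnot(inherits(ctx, "pair_context"))
  if (is.null(ctx$Xq)) stop("context has no quality-weighted counts")
  sum(ctx$Xq * ctx$Yq)
}

#' @rdname d2_raw
#' @export
d2qstar_raw <- function(ctx) {
  stopifnot(inherits(ctx, "pair_context"))
  if (is.null(ctx$Xq)) stop("context has no quality-weighted counts")
  pp <- .check_background(ctx)
  ew <- expected_correctness_pair(ctx)
  Xt <- centralized_count(ctx$Xq, ctx$WX, pp * ew)
  Yt <- centralized_count(ctx$Yq, ctx$WY, pp * ew)
  W <- sqrt(ctx$WX * ctx$WY)
  sum(Xt * Yt / (W * pp * ew))
}

#' Map a raw statistic onto a [0,1] dissimilarity
#'
#' Computes `0.5 * (1 - raw / (sqrt(self_norm_X) * sqrt(self_norm_Y)))`:
#' 0 for identical profiles, 0.5 for orthogonal ones, 1 for perfectly
#' anti-correlated centralized profiles.  With `literal = TRUE` the
#' complement is not taken and the value is `0.5 * ratio` (a similarity,
#' 0.5 for identical profiles).
#'
#' @param raw raw statistic (already scaled by the window total where the
#'   starred definitions require it).
#' @param self_norm_X,self_norm_Y the matching self norms (`sum(X_w^2)` for
#'   d2; `sum(Xt_w^2 / p_w)` for the starred forms).
#' @param literal emit the uncomplemented half-ratio.
#' @return dissimilarity value.
#' @export
normalize_to_dissimilarity <- function(raw, self_norm_X, self_norm_Y,
                                       literal = FALSE) {
  if (self_norm_X <= 0 || self_norm_Y <= 0)
    stop("empty k-mer profile: zero self norm")
  ratio <- raw / (sqrt(self_norm_X) * sqrt(self_norm_Y))
  if (literal) 0.5 * ratio else 0.5 * (1 - ratio)
}

## All eight statistics for one pair, in one pass over the context.
pair_statistics <- function(ctx, literal_d2 = FALSE) {
  pp <- .check_background(ctx)
  W <- sqrt(ctx$WX * ctx$WY)

  D2 <- sum(ctx$X * ctx$Y)
  d2 <- normalize_to_dissimilarity(D2, sum(ctx$X^2), sum(ctx$Y^2),
                                   literal = literal_d2)

  Xt <- centralized_count(ctx$X, ctx$WX, pp)
  Yt <- centralized_count(ctx$Y, ctx$WY, pp)
  D2star <- sum(Xt * Yt / (W * pp))
  d2star <- normalize_to_dissimilarity(W * D2star,
                                       sum(Xt^2 / ctx$pw), sum(Yt^2 / ctx$pw),
                                       literal = literal_d2)

  D2q <- sum(ctx$Xq * ctx$Yq)
  d2q <- normalize_to_dissimilarity(D2q, sum(ctx$Xq^2), sum(ctx$Yq^2),
                                    literal = literal_d2)

  ew <- (ctx$Xq + ctx$Yq) / (ctx$X + ctx$Y)
  Xqt <- centralized_count(ctx$Xq, ctx$WX, pp * ew)
  Yqt <- centralized_count(ctx$Yq, ctx$WY, pp * ew)
  D2qstar <- sum(Xqt * Yqt / (W * pp * ew))
  d2qstar <- normalize_to_dissimilarity(W * D2qstar,
                                        sum(Xqt^2 / ctx$pw), sum(Yqt^2 / ctx$pw),
                                        literal = literal_d2)

  c(D2 = D2, D2star = D2star, D2q = D2q, D2qstar = D2qstar,
    d2 = d2, d2star = d2star, d2q = d2q, d2qstar = d2qstar)
}

#' All-pairs dissimilarity matrices
#'
#' Counts k-mers once per sample (plain and quality-weighted in the same
#' pass) and evaluates the requested statistics for every unordered pair.
#' By default the background model of each pair is estimated from the two
#' samples pooled; with `background = "global"` a single model over all
#' samples is used.  The diagonal of the raw D-type matrices holds the self
#' statistic; d-type diagonals are 0.
#'
#' @param samples list of `read_set` objects, or a data.frame as returned by
#'   [load_sample_list()] (paths are then read one at a time).
#' @param k word length.
#' @param measures character vector of measure names (see
#'   [canonical_measure()]); default all eight.
#' @param background `"pooled"` (per pair, the default) or `"global"`.
#' @param literal_d2 use the uncomplemented half-ratio form for d-type
#'   values (see [normalize_to_dissimilarity()]).
#' @param phred_offset FASTQ quality offset, used when `samples` is a file
#'   table.
#' @param verbose log per-sample counting progress to standard error.
#' @return named list of `dissimilarity_matrix` objects, one per measure.
#' @export
pairwise_matrices <- function(samples, k, measures = MEASURE_NAMES,
                              background = c("pooled", "global"),
                              literal_d2 = FALSE, phred_offset = 33,
                              verbose = FALSE) {
  background <- match.arg(background)
  measures <- canonical_measure(measures)
  if (is.data.frame(samples)) {
    labs <- samples$label
    counts <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      if (verbose) message("counting ", k, "-mers in ", samples$path[i])
      rs <- read_fastq(samples$path[i], phred_offset = phred_offset,
                       label = samples$label[i])
      counts[[i]] <- count_kmers_weighted(rs, k)
    }
  } else {
    stopifnot(all(vapply(samples, inherits, logical(1), "read_set")))
    labs <- vapply(samples, `[[`, character(1), "label")
    counts <- lapply(seq_along(samples), function(i) {
      if (verbose) message("counting ", k, "-mers in ", labs[i])
      count_kmers_weighted(samples[[i]], k)
    })
  }
  n <- length(counts)
  if (n < 2L) stop("need at least 2 samples")
  if (anyDuplicated(labs)) stop("duplicate sample labels")

  bg <- if (background == "global") estimate_background(counts) else NULL
  vals <- array(0, dim = c(n, n, length(MEASURE_NAMES)),
                dimnames = list(labs, labs, MEASURE_NAMES))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ctx <- pair_context(counts[[i]], counts[[j]], background = bg)
      st <- pair_statistics(ctx, literal_d2 = literal_d2)
      if (i == j) st[c("d2", "d2star", "d2q", "d2qstar")] <-
          if (literal_d2) 0.5 else 0
      vals[i, j, ] <- st
      vals[j, i, ] <- st
    }
  }
  out <- lapply(measures, function(m)
    dissimilarity_matrix(vals[, , m], measure = m, k = k))
  names(out) <- measures
  out
}

#' Dissimilarity matrix container
#'
#' A symmetric labelled matrix for one measure at one word length.
#'
#' @param values n-by-n numeric matrix with dimnames.
#' @param measure measure name.
#' @param k word length.
#' @return object of class `"dissimilarity_matrix"` (a matrix with
#'   attributes `measure` and `k`).
#' @export
dissimilarity_matrix <- function(values, measure, k) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("S", seq_len(nrow(values)))
  if (nrow(values) != ncol(values) ||
      max(abs(values - t(values))) > 1e-10)
    stop("dissimilarity matrix must be symmetric")
  structure(values, measure = measure, k = as.integer(k),
            class = c("dissimilarity_matrix", "matrix", "array"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("%s dissimilarity matrix (k=%d), %d samples\n",
              attr(x, "measure"), attr(x, "k"), nrow(x)))
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x), dimnames = dimnames(x))
  print(y, ...)
  invisible(x)
}
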