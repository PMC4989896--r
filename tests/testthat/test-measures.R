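# helper: context from two tiny literal read sets
.toy_ctx <- function(sx, sy, qx = NULL, qy = NULL, k = 2) {
  mk <- function(s, q, lab) {
    reads <- lapply(seq_along(s), function(i) {
      qq <- if (is.null(q)) rep(40L, nchar(s[i])) else q[[i]]
      read_record(paste0(lab, i), s[i], qq)
    })
    read_set(reads, lab)
  }
  pair_context(count_kmers_weighted(mk(sx, qx, "x"), k),
               count_kmers_weighted(mk(sy, qy, "y"), k))
}

test_that("d2_raw is the inner product over the union support", {
  X <- c(AA = 2, AC = 1); Y <- c(AA = 1, AC = 3)
  ctx <- list(X = unname(X), Y = unname(Y))
  class(ctx) <- "pair_context"
  expect_equal(d2_raw(ctx), 5)
  ctx2 <- list(X = c(2, 0), Y = c(0, 3))
  class(ctx2) <- "pair_context"
  expect_equal(d2_raw(ctx2), 0)   # disjoint supports
  ctx3 <- list(X = c(2, 1), Y = c(2, 1))
  class(ctx3) <- "pair_context"
  expect_equal(d2_raw(ctx3), sum(c(2, 1)^2))
})

test_that("centralized_count subtracts the null expectation", {
  expect_equal(centralized_count(5, 460, 0.002), 4.08)
  expect_equal(centralized_count(0.92, 460, 0.002), 0)
  expect_equal(centralized_count(7, 460, 0), 7)
  # single-word starred toy from the centralized values: 4.08*2.04/0.92
  expect_equal(4.08 * 2.04 / (460 * 0.002), 9.047, tolerance = 1e-4)
})

test_that("expected correctness pair is the posterior occurrence mean", {
  ctx <- .toy_ctx("ACAC", "ACGT", qx = list(c(10L, 20L, 30L, 40L)),
                  qy = list(rep(30L, 4)))
  # brute-force: mean occurrence_correctness over all occurrences of the
  # word (both strands, both samples)
  brute_mean <- function(w, sets) {
    vals <- c()
    for (rs in sets) {
      supp <- supplement_with_complements(rs)
      for (r in supp$reads) {
        L <- nchar(r$sequence)
        for (i in seq_len(L - nchar(w) + 1L))
          if (substr(r$sequence, i, i + nchar(w) - 1L) == w)
            vals <- c(vals, occurrence_correctness(
              r$qualities[i:(i + nchar(w) - 1L)]))
      }
    }
    mean(vals)
  }
  sets <- list(
    read_set(list(read_record("x1", "ACAC", c(10L, 20L, 30L, 40L))), "x"),
    read_set(list(read_record("y1", "ACGT", rep(30L, 4))), "y"))
  for (w in c("AC", "GT"))
    expect_equal(expected_correctness_pair(ctx, w), brute_mean(w, sets),
                 tolerance = 1e-12)
  # perfect qualities give expectation 1
  ctx2 <- .toy_ctx("ACAC", "ACGT", qx = list(rep(93L, 4)), qy = list(rep(93L, 4)))
  expect_equal(unname(expected_correctness_pair(ctx2)),
               rep(1, length(ctx2$codes)), tolerance = 1e-8)
  expect_error(expected_correctness_pair(ctx, "GG"), "not observed")
})

test_that("all raw statistics match the brute-force oracle on random pairs", {
  set.seed(101)
  for (i in 1:15) {
    k <- sample(1:3, 1)
    rsx <- random_readset(sample(2:4, 1), sample((k + 1):12, 1), "x", qmin = 3)
    rsy <- random_readset(sample(2:4, 1), sample((k + 1):12, 1), "y", qmin = 3)
    want <- oracle_statistics(rsx, rsy, k)
    if (any(!is.finite(want))) next  # degenerate draw (zero centralized norm)
    got <- package_statistics(rsx, rsy, k)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("quality degeneracy: perfect qualities collapse q onto plain", {
  set.seed(55)
  rsx <- random_readset(3, 20, "x", qmin = 80, qmax = 93)
  rsy <- random_readset(3, 20, "y", qmin = 80, qmax = 93)
  st <- package_statistics(rsx, rsy, 2)
  expect_equal(st[["D2q"]], st[["D2"]], tolerance = 1e-3)
  expect_equal(st[["d2qstar"]], st[["d2star"]], tolerance = 1e-3)
})

test_that("normalization maps identity, orthogonality and anti-correlation", {
  expect_equal(normalize_to_dissimilarity(6, 6, 6), 0)       # identical
  expect_equal(normalize_to_dissimilarity(0, 4, 9), 0.5)     # orthogonal
  expect_equal(normalize_to_dissimilarity(-6, 6, 6), 1)      # anti-correlated
  expect_equal(normalize_to_dissimilarity(6, 6, 6, literal = TRUE), 0.5)
  expect_error(normalize_to_dissimilarity(1, 0, 2), "empty k-mer profile")
})

test_that("pairwise matrices are symmetric, zero-diagonal and label-stable", {
  set.seed(77)
  sets <- lapply(1:4, function(i) random_readset(4, 25, paste0("s", i)))
  mats <- pairwise_matrices(sets, k = 3)
  expect_named(mats, kmerq:::MEASURE_NAMES)
  for (m in names(mats)) {
    mm <- mats[[m]]
    expect_equal(dim(mm), c(4, 4))
    expect_lt(max(abs(mm - t(mm))), 1e-10)
  }
  for (m in c("d2", "d2star", "d2q", "d2qstar")) {
    expect_equal(unname(diag(mats[[m]])), rep(0, 4))
    expect_true(all(mats[[m]] >= 0 & mats[[m]] <= 1))
  }
  # raw diagonal holds the self statistic
  ctx <- pair_context(count_kmers_weighted(sets[[1]], 3),
                      count_kmers_weighted(sets[[1]], 3))
  expect_equal(mats$D2[1, 1], d2_raw(ctx))

  # duplicated sample has d2 distance 0 to its twin
  mats2 <- pairwise_matrices(c(sets[1], list({
    tw <- sets[[1]]; tw$label <- "twin"; tw
  }), sets[2]), k = 3)
  expect_equal(mats2$d2["s1", "twin"], 0, tolerance = 1e-12)

  # reordering input permutes rows/columns only
  mats3 <- pairwise_matrices(sets[c(3, 1, 4, 2)], k = 3)
  lb <- rownames(mats$d2star)
  expect_equal(mats3$d2star[lb, lb], mats$d2star[lb, lb], tolerance = 1e-12)
})

test_that("literal d2 formula flag emits the half-ratio form", {
  set.seed(31)
  rsx <- random_readset(3, 15, "x")
  rsy <- random_readset(3, 15, "y")
  st <- package_statistics(rsx, rsy, 2, literal_d2 = TRUE)
  stn <- package_statistics(rsx, rsy, 2)
  expect_equal(st[["d2"]], 0.5 - stn[["d2"]], tolerance = 1e-12)
  mats <- pairwise_matrices(list(rsx, rsy), 2, literal_d2 = TRUE)
  expect_equal(unname(diag(mats$d2)), c(0.5, 0.5))
})

test_that("background options: global model differs but stays valid", {
  set.seed(13)
  sets <- lapply(1:3, function(i)
    random_readset(4, 30, paste0("s", i),
                   alphabet_bias = c(1, 1, 1, i)))   # different compositions
  mp <- pairwise_matrices(sets, 3, measures = "d2star")$d2star
  mg <- pairwise_matrices(sets, 3, measures = "d2star",
                          background = "global")$d2star
  expect_false(isTRUE(all.equal(mp[1, 2], mg[1, 2])))
  expect_lt(max(abs(mg - t(mg))), 1e-10)
})

test_that("noise discrimination: same-source pairs are closer in d2", {
  set.seed(2024)
  src <- random_sequence(5000, seed = 91)
  div <- local({   # ~70 PAM of point substitutions
    b <- kmerq:::encode_bases(src)
    hit <- which(runif(length(b)) < 0.7)
    b[hit] <- (b[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
    paste(c("A", "C", "G", "T")[b + 1], collapse = "")
  })
  wins <- 0L; trials <- 100L
  seeds <- kmerq:::derive_seeds(500, 3 * trials)
  for (t in seq_len(trials)) {
    a1 <- sample_reads(src, 40, 100, 0.01, seed = seeds[3 * t - 2], label = "a1")
    a2 <- sample_reads(src, 40, 100, 0.01, seed = seeds[3 * t - 1], label = "a2")
    b1 <- sample_reads(div, 40, 100, 0.01, seed = seeds[3 * t], label = "b1")
    m <- pairwise_matrices(list(a1, a2, b1), 5, measures = "d2")$d2
    if (m["a1", "a2"] < m["a1", "b1"] && m["a1", "a2"] < m["a2", "b1"])
      wins <- wins + 1L
  }
  expect_gte(wins / trials, 0.95)
})

test_that("matrix serialization round-trips in both dialects", {
  set.seed(6)
  sets <- lapply(1:3, function(i) random_readset(3, 20, paste0("sample_", i)))
  m <- pairwise_matrices(sets, 2, measures = "d2")$d2
  fp <- tempfile(fileext = ".phylip"); ft <- tempfile(fileext = ".tsv")
  write_phylip_matrix(m, fp)
  write_tsv_matrix(m, ft)
  mp <- read_phylip_matrix(fp)
  mt <- read_tsv_matrix(ft)
  expect_equal(mp, m, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rownames(mt), rownames(m))
  expect_equal(mt, m, tolerance = 1e-9, ignore_attr = TRUE)
  # phylip labels truncated at 10 chars unless relaxed
  expect_equal(rownames(mp)[1], "sample_1")
  long <- m; rownames(long) <- colnames(long) <- paste0("verylonglabel_", 1:3)
  write_phylip_matrix(long, fp)
  expect_equal(rownames(read_phylip_matrix(fp))[1], "verylongla")
  write_phylip_matrix(long, fp, relaxed = TRUE)
  expect_equal(rownames(read_phylip_matrix(fp))[1], "verylonglabel_1")
  expect_error(read_phylip_matrix(ft), "malformed PHYLIP")
})
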