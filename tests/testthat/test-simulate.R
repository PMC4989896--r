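test_that("random_sequence is seeded, composed as requested", {
  s1 <- random_sequence(100, seed = 5)
  s2 <- random_sequence(100, seed = 5)
  expect_identical(s1, s2)
  expect_equal(nchar(s1), 100)
  expect_false(identical(random_sequence(100, seed = 6), s1))
  expect_false(grepl("[^GC]", random_sequence(200, gc = 1, seed = 1)))
  gcfrac <- mean(strsplit(random_sequence(1e5, gc = 0.5, seed = 2), "")[[1]]
                 %in% c("G", "C"))
  expect_lt(abs(gcfrac - 0.5), 0.01)
})

test_that("evolve_family honors its contract", {
  fam0 <- evolve_family(4, 500, relatedness = 0, seed = 3)
  expect_length(unique(fam0$sequences), 1)   # no divergence
  expect_equal(sort(fam0$tree$tip.label), sort(names(fam0$sequences)))

  # two leaves, relatedness r: expected mismatch fraction ~ 2r/100
  mism <- vapply(1:40, function(s) {
    fam <- evolve_family(2, 2000, relatedness = 10, seed = s)
    a <- strsplit(fam$sequences[[1]], "")[[1]]
    b <- strsplit(fam$sequences[[2]], "")[[1]]
    mean(a != b)
  }, numeric(1))
  # each site flips with p = 0.1 per branch; observed mismatch after two
  # independent branches: 2p(1-p) + p^2 * (2/3 chance of differing)
  p <- 0.1
  expected <- 2 * p * (1 - p) + p^2 * 2 / 3
  expect_lt(abs(mean(mism) - expected), 0.01)

  # indel_rate 0 preserves length exactly; indels change it
  expect_true(all(nchar(evolve_family(5, 800, 20, seed = 9)$sequences) == 800))
  fam_id <- evolve_family(5, 800, 20, indel_rate = 0.05, seed = 9)
  expect_false(all(nchar(fam_id$sequences) == 800))

  # determinism
  expect_identical(evolve_family(6, 300, 30, seed = 4)$sequences,
                   evolve_family(6, 300, 30, seed = 4)$sequences)
})

test_that("sample_reads: exact substrings at zero error, calibrated else", {
  src <- random_sequence(1500, seed = 10)
  rs0 <- sample_reads(src, 30, 60, mismatch_prob = 0, seed = 1, label = "s")
  rc_src <- reverse_complement(src)
  for (r in rs0$reads)
    expect_true(grepl(r$sequence, src, fixed = TRUE) ||
                  grepl(r$sequence, rc_src, fixed = TRUE))
  expect_true(all(unlist(lapply(rs0$reads, `[[`, "qualities")) == 93L))

  # mismatch 0.1: emitted Q is exactly 10, observed error rate ~0.1
  M <- 400; beta <- 100
  rs <- sample_reads(src, M, beta, mismatch_prob = 0.1, seed = 2, label = "s")
  expect_true(all(unlist(lapply(rs$reads, `[[`, "qualities")) == 10L))
  # reconstruct the true source windows from the seeded stream (the
  # generator draws starts, then strands, before injecting errors)
  truth <- local({
    set.seed(2)
    starts <- sample.int(nchar(src) - beta + 1L, M, replace = TRUE)
    fwd <- runif(M) < 0.5
    w <- substring(src, starts, starts + beta - 1L)
    w[!fwd] <- reverse_complement(w[!fwd])
    w
  })
  nb <- M * beta
  err <- sum(vapply(seq_len(M), function(i)
    sum(utf8ToInt(truth[i]) != utf8ToInt(rs$reads[[i]]$sequence)), numeric(1)))
  phat <- err / nb
  # errors replace a base with a *different* base, so every hit is visible
  sigma <- sqrt(0.1 * 0.9 / nb)
  expect_lt(abs(phat - 0.1), 3 * sigma)

  # determinism of FASTQ output
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(sample_reads(src, 20, 50, 0.05, seed = 77, label = "d"), f1)
  write_fastq(sample_reads(src, 20, 50, 0.05, seed = 77, label = "d"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ramp profile emits calibrated, position-varying qualities", {
  src <- random_sequence(3000, seed = 21)
  rs <- sample_reads(src, 4000, 100, mismatch_prob = 0.05, profile = "ramp",
                     ramp_factor = 5, seed = 31, label = "ramp")
  Q <- rs$reads[[1]]$qualities
  expect_gt(Q[1], Q[100])         # 5' end cleaner than 3' end
  expect_gt(length(unique(Q)), 3)
  # calibration: empirical error rate among bases emitted with score q lies
  # within one phred unit of 10^(-q/10), pooled over >= 1e5 bases per score
  M <- 4000; beta <- 100
  truth <- local({
    set.seed(31)
    starts <- sample.int(nchar(src) - beta + 1L, M, replace = TRUE)
    fwd <- runif(M) < 0.5
    w <- substring(src, starts, starts + beta - 1L)
    w[!fwd] <- reverse_complement(w[!fwd])
    w
  })
  errpos <- numeric(beta); npos <- numeric(beta)
  for (i in seq_len(M)) {
    errpos <- errpos + (utf8ToInt(truth[i]) != utf8ToInt(rs$reads[[i]]$sequence))
    npos <- npos + 1
  }
  rate_by_q <- tapply(errpos, Q, sum) / tapply(npos, Q, sum)
  n_by_q <- tapply(npos, Q, sum)
  checked <- 0L
  for (qv in names(rate_by_q)) {
    q <- as.integer(qv)
    if (n_by_q[[qv]] < 20000) next   # too few bases for a stable rate
    expect_gte(rate_by_q[[qv]], 10^(-(q + 1) / 10))
    expect_lte(rate_by_q[[qv]], 10^(-(q - 1) / 10))
    checked <- checked + 1L
  }
  expect_gte(checked, 2L)
})

test_that("metagenome mixtures follow the abundance profile", {
  g <- c(A = random_sequence(4000, seed = 1), B = random_sequence(4000, seed = 2))
  spec <- metagenome_spec(g, c(0.9, 0.1))
  mg <- make_metagenome(spec, 10000, 80, mismatch_prob = 0, seed = 5, label = "m")
  expect_equal(mg$M, 10000)
  srcA <- sum(grepl("_A_", vapply(mg$reads, `[[`, character(1), "id"), fixed = TRUE))
  sigma <- sqrt(10000 * 0.9 * 0.1)
  expect_lt(abs(srcA - 9000), 3 * sigma)

  # same spec and seed -> identical FASTQ
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(make_metagenome(spec, 100, 50, 0.01, seed = 9), f1)
  write_fastq(make_metagenome(spec, 100, 50, 0.01, seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))

  # single genome at weight 1 behaves like sample_reads
  one <- metagenome_spec(g["A"], 1)
  mg1 <- make_metagenome(one, 50, 60, 0, seed = 3)
  for (r in mg1$reads)
    expect_true(grepl(r$sequence, g[["A"]], fixed = TRUE) ||
                  grepl(r$sequence, reverse_complement(g[["A"]]), fixed = TRUE))

  expect_error(metagenome_spec(g, c(0.5, 0.4)), "sum to 1")
  # shared-genome pair construction
  pair <- make_metagenome_pair(n_genomes = 4, genome_length = 500, shared = 2,
                               seed = 8)
  expect_length(intersect(names(pair$A$genomes), names(pair$B$genomes)), 2)
})

test_that("benchmarks are deterministic and well-shaped", {
  res1 <- run_phylogeny_benchmark(n_sequences = 5, root_length = 1500,
                                  relatedness = 20, M = 60, beta = 80,
                                  mismatch_prob = 0.02, k = 5,
                                  replicates = 2, seed = 12)
  res2 <- run_phylogeny_benchmark(n_sequences = 5, root_length = 1500,
                                  relatedness = 20, M = 60, beta = 80,
                                  mismatch_prob = 0.02, k = 5,
                                  replicates = 2, seed = 12)
  expect_identical(res1, res2)
  expect_equal(nrow(res1$summary), 4)   # one row per measure
  expect_equal(dim(res1$rf), c(2, 4))

  # identical specs: types are indistinguishable -> near-zero separation
  # or outright classification failure
  g <- vapply(1:3, function(i) random_sequence(2000, seed = i), character(1))
  spec <- metagenome_spec(setNames(g, paste0("G", 1:3)))
  res <- run_metagenome_benchmark(spec, spec, samples_per_type = 3,
                                  reads_total = 400, beta = 80, k = 5,
                                  seed = 30)
  root_h <- max(res$dendrogram$height)
  sep <- if (is.na(res$height)) 0 else
    res$height - max(res$dendrogram$height[res$dendrogram$height < res$height])
  expect_lt(sep, 0.25 * root_h)
})
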