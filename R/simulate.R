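## Synthetic data: evolved sequence families on a known clock tree, reads
## with phred-calibrated substitution errors, and metagenome mixtures.
##
## Every generator is a pure function of its seed.  Child streams (per
## replicate, per sample) are derived by drawing 31-bit integers from the
## master stream, so nested calls are reproducible without sharing state.

## run code with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.BASES <- c("A", "C", "G", "T")

#' Random i.i.d. DNA sequence
#'
#' @param length number of bases.
#' @param gc GC fraction; G and C (and A and T) are equiprobable within
#'   their pair.
#' @param seed integer seed; the output is a pure function of it.
#' @return DNA string.
#' @export
random_sequence <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, paste(sample(.BASES, length, replace = TRUE, prob = p),
                        collapse = ""))
}

## apply point substitutions: each site flips with probability p to a
## uniformly chosen different base; seq given/returned as 0..3 codes
.mutate_codes <- function(b, p) {
  hit <- which(stats::runif(length(b)) < p)
  if (length(hit) > 0L)
    b[hit] <- (b[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  b
}

#' Evolve a family of sequences down a random clock tree
#'
#' Generates a random bifurcating ultrametric topology over `n_sequences`
#' leaves (sequential random joins; the j-th join at height `j/(n-1)`, root
#' at height 1) and evolves a common root sequence down it.  Substitutions
#' are Jukes-Cantor-style: along an edge of duration `t`, each site is hit
#' with probability `min(0.75, relatedness/100 * t)` and replaced by a
#' uniformly chosen different base; multiple hits accrue across successive
#' edges.  `relatedness` is a PAM-like load: two leaves joined at the root
#' are separated by `2 * relatedness` expected substitutions per 100 sites
#' (before multiple-hit correction).  Optional single-base indels at
#' `indel_rate` per site per unit time.
#'
#' @param n_sequences number of leaves (>= 2).
#' @param root_length root sequence length `N` in bases.
#' @param relatedness expected substitutions per 100 sites per unit tree
#'   height (default 70, a high divergence regime).
#' @param gc GC fraction of the root sequence.
#' @param indel_rate per-site, per-unit-height indel probability (default 0;
#'   insertions and deletions equally likely, single base).
#' @param seed integer seed.
#' @return list with `sequences` (named character vector, leaves
#'   `Seq01`, ...) and `tree` (the true `phylo` tree, branch lengths in
#'   height units).
#' @export
evolve_family <- function(n_sequences, root_length, relatedness = 70,
                          gc = 0.5, indel_rate = 0, seed = NULL) {
  stopifnot(n_sequences >= 2, root_length > 0, relatedness >= 0)
  with_seed(seed, {
    n <- n_sequences
    ## random-join ultrametric topology as an hclust-style merge list
    merge <- matrix(0L, n - 1L, 2L)
    height <- seq_len(n - 1L) / (n - 1L)
    pool <- -seq_len(n)
    for (s in seq_len(n - 1L)) {
      pick <- sample(length(pool), 2L)
      merge[s, ] <- pool[pick]
      pool <- c(pool[-pick], s)
    }
    labs <- sprintf("Seq%02d", seq_len(n))
    hc <- structure(list(merge = merge, height = height,
                         order = seq_len(n), labels = labs,
                         method = "average", call = quote(evolve_family())),
                    class = "hclust")
    tree <- ape::as.phylo(hc)
    ## as.phylo halves heights; restore time units
    tree$edge.length <- tree$edge.length * 2

    rate <- relatedness / 100
    root <- encode_bases(random_sequence(root_length, gc = gc))
    n_tips <- n
    seqs <- vector("list", n_tips + tree$Nnode)
    root_node <- n_tips + 1L
    seqs[[root_node]] <- root
    ## preorder: parents before children
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_edge <- tree$edge.length[e]
      b <- .mutate_codes(seqs[[parent]], min(0.75, rate * t_edge))
      if (indel_rate > 0) {
        p_id <- min(0.5, indel_rate * t_edge)
        del <- stats::runif(length(b)) < p_id / 2
        ins <- which(stats::runif(length(b)) < p_id / 2)
        if (length(ins) > 0L || any(del)) {
          pieces <- as.list(b[!del])
          b2 <- b[!del]
          for (i in ins) {
            pos <- min(i, length(b2))
            b2 <- append(b2, sample.int(4L, 1L) - 1L, after = pos)
          }
          b <- b2
        }
      }
      seqs[[child]] <- b
    }
    sequences <- vapply(seq_len(n_tips), function(i)
      paste(.BASES[seqs[[i]] + 1L], collapse = ""), character(1))
    names(sequences) <- tree$tip.label
    list(sequences = sequences, tree = tree)
  })
}

## per-position error probabilities for one read of length beta
.error_profile <- function(beta, mismatch_prob, profile, ramp_factor) {
  if (mismatch_prob == 0) return(rep(0, beta))
  switch(profile,
         constant = rep(mismatch_prob, beta),
         ramp = {
           if (beta == 1L) return(mismatch_prob)
           e <- 2 * (seq_len(beta) - 1L) / (beta - 1L) - 1
           pmin(0.75, mismatch_prob * ramp_factor^e)
         },
         stop("unknown error profile: ", profile))
}

#' Simulate reads from a sequence with calibrated qualities
#'
#' Draws `M` reads of length `beta` with uniform start positions, each from
#' a uniformly chosen strand (half the reads are reverse complements of
#' their source window).  Each base is then substituted by a uniformly
#' chosen different base with probability `p_i`, the per-position error
#' rate, and the emitted phred score is `round(-10 log10 p_i)` — qualities
#' are therefore calibrated and informative about the true errors, which is
#' what the quality-weighted measures exploit.
#'
#' With the default `profile = "constant"`, `p_i = mismatch_prob`
#' everywhere, so all emitted scores are equal; `profile = "ramp"` varies
#' the rate geometrically from `mismatch_prob / ramp_factor` at the 5' end
#' to `mismatch_prob * ramp_factor` at the 3' end (log-mean
#' `mismatch_prob`), emulating the quality decay of real instruments and
#' giving the quality scores per-base information content.
#'
#' @param sequence source DNA string.
#' @param M number of reads.
#' @param beta read length (`<= nchar(sequence)`).
#' @param mismatch_prob per-base substitution error rate (default 0.1).
#' @param profile `"constant"` (default) or `"ramp"`.
#' @param ramp_factor fold-change of the error ramp (default 5).
#' @param seed integer seed.
#' @param label sample label.
#' @return a `read_set` of `M` reads with quality strings.
#' @export
sample_reads <- function(sequence, M, beta, mismatch_prob = 0.1,
                         profile = c("constant", "ramp"), ramp_factor = 5,
                         seed = NULL, label = "sim") {
  profile <- match.arg(profile)
  N <- nchar(sequence)
  stopifnot(M >= 1, beta >= 1, beta <= N,
            mismatch_prob >= 0, mismatch_prob < 1)
  p_pos <- .error_profile(beta, mismatch_prob, profile, ramp_factor)
  Q <- ifelse(p_pos > 0, pmax(0L, as.integer(round(-10 * log10(pmax(p_pos, 1e-10))))), 93L)
  Q <- pmin(Q, 93L)
  with_seed(seed, {
    starts <- sample.int(N - beta + 1L, M, replace = TRUE)
    fwd <- stats::runif(M) < 0.5
    windows <- substring(sequence, starts, starts + beta - 1L)
    windows[!fwd] <- reverse_complement(windows[!fwd])
    b <- encode_bases(paste(windows, collapse = ""))
    b <- .mutate_codes(b, rep(p_pos, times = M))
    chars <- paste(.BASES[b + 1L], collapse = "")
    ends <- seq_len(M) * beta
    seqs <- substring(chars, ends - beta + 1L, ends)
    reads <- lapply(seq_len(M), function(i)
      read_record(sprintf("%s_r%05d", label, i), seqs[i], Q))
    read_set(reads, label = label)
  })
}

#' Specification of a metagenome mixture
#'
#' @param genomes named character vector of genome sequences.
#' @param weights relative abundances, one per genome, summing to 1
#'   (defaults to equal abundance).
#' @return object of class `"metagenome_spec"`.
#' @export
metagenome_spec <- function(genomes, weights = NULL) {
  stopifnot(length(genomes) >= 1)
  if (is.null(names(genomes)))
    names(genomes) <- sprintf("G%02d", seq_along(genomes))
  if (is.null(weights)) weights <- rep(1 / length(genomes), length(genomes))
  stopifnot(length(weights) == length(genomes), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("abundance weights must sum to 1")
  structure(list(genomes = genomes, weights = weights),
            class = "metagenome_spec")
}

#' Sample a metagenome read set from a mixture of genomes
#'
#' Each read's source genome is drawn from the abundance profile, then the
#' read is sampled as in [sample_reads()] (uniform start, either strand,
#' calibrated substitution errors).
#'
#' @param spec a [metagenome_spec()].
#' @param reads_total total number of reads.
#' @param beta read length.
#' @param mismatch_prob per-base error rate.
#' @param profile,ramp_factor error profile, see [sample_reads()].
#' @param seed integer seed.
#' @param label sample label.
#' @return a `read_set`.
#' @export
make_metagenome <- function(spec, reads_total, beta, mismatch_prob = 0.01,
                            profile = c("constant", "ramp"), ramp_factor = 5,
                            seed = NULL, label = "metagenome") {
  stopifnot(inherits(spec, "metagenome_spec"), reads_total >= 1)
  profile <- match.arg(profile)
  seeds <- derive_seeds(seed, length(spec$genomes) + 1L)
  src <- with_seed(seeds[1], sample.int(length(spec$genomes), reads_total,
                                        replace = TRUE, prob = spec$weights))
  parts <- vector("list", length(spec$genomes))
  for (g in seq_along(spec$genomes)) {
    ng <- sum(src == g)
    if (ng == 0L) next
    parts[[g]] <- sample_reads(spec$genomes[[g]], ng, beta,
                               mismatch_prob = mismatch_prob,
                               profile = profile, ramp_factor = ramp_factor,
                               seed = seeds[g + 1L],
                               label = paste0(label, "_", names(spec$genomes)[g]))
  }
  reads <- unlist(lapply(parts[!vapply(parts, is.null, logical(1))],
                         `[[`, "reads"), recursive = FALSE)
  read_set(reads, label = label)
}

#' Phylogeny-from-reads benchmark
#'
#' Full evaluation pipeline: evolve a sequence family with a known tree,
#' sample reads with errors and calibrated qualities from every leaf
#' sequence, compute all-pairs dissimilarity matrices, build a UPGMA tree
#' per measure, and score each against the true tree with the
#' Robinson-Foulds distance.  The pipeline is repeated `replicates` times
#' with fresh root sequences and the per-measure mean RF is reported.
#'
#' @param n_sequences,root_length,relatedness,gc family parameters, see
#'   [evolve_family()].
#' @param M,beta,mismatch_prob,profile,ramp_factor read sampling parameters,
#'   see [sample_reads()].
#' @param k word length.
#' @param measures d-type measures to evaluate (default all four).
#' @param replicates number of pipeline repetitions.
#' @param method `"upgma"` (default) or `"nj"`.
#' @param seed master seed; per-replicate streams are derived from it.
#' @return a list with `summary` (data.frame: measure, mean_rf) and `rf`
#'   (replicates-by-measures matrix of RF values).
#' @export
run_phylogeny_benchmark <- function(n_sequences = 10, root_length = 5000,
                                    relatedness = 70, gc = 0.5,
                                    M = 300, beta = 300, mismatch_prob = 0.1,
                                    profile = "constant", ramp_factor = 5,
                                    k = 7,
                                    measures = c("d2", "d2star", "d2q", "d2qstar"),
                                    replicates = 10, method = c("upgma", "nj"),
                                    seed = NULL) {
  method <- match.arg(method)
  measures <- canonical_measure(measures)
  seeds <- derive_seeds(seed, replicates)
  rf <- matrix(NA_real_, replicates, length(measures),
               dimnames = list(NULL, measures))
  for (r in seq_len(replicates)) {
    sub <- derive_seeds(seeds[r], n_sequences + 1L)
    fam <- evolve_family(n_sequences, root_length, relatedness, gc = gc,
                         seed = sub[1])
    sets <- lapply(seq_len(n_sequences), function(i)
      sample_reads(fam$sequences[[i]], M, beta, mismatch_prob,
                   profile = profile, ramp_factor = ramp_factor,
                   seed = sub[i + 1L], label = names(fam$sequences)[i]))
    mats <- pairwise_matrices(sets, k, measures = measures)
    for (m in measures) {
      est <- if (method == "upgma") upgma(mats[[m]])
             else neighbor_joining(mats[[m]])
      rf[r, m] <- robinson_foulds(est, fam$tree)
    }
  }
  list(summary = data.frame(measure = measures, mean_rf = colMeans(rf),
                            row.names = NULL),
       rf = rf)
}

#' Two-type metagenome clustering benchmark
#'
#' Samples `samples_per_type` replicate metagenomes from each of two
#' mixture specifications, computes the quality-weighted starred
#' dissimilarity matrix (`d2qstar` by default), clusters it with average
#' linkage (UPGMA), and reports the fraction of samples assigned to their
#' type when the dendrogram is cut in two, together with the height of the
#' node separating the types.
#'
#' @param specA,specB [metagenome_spec()] objects for the two types.
#' @param samples_per_type replicate metagenomes per type (default 5).
#' @param reads_total,beta,mismatch_prob,profile,ramp_factor read sampling
#'   parameters per sample.
#' @param k word length (default 8).
#' @param measure measure used for the matrix (default `"d2qstar"`).
#' @param seed master seed.
#' @return list with `accuracy` (fraction in `[0,1]`), `height` (merge
#'   height of the discriminating node, `NA` on failure), `matrix`, and
#'   `dendrogram`.
#' @export
run_metagenome_benchmark <- function(specA, specB, samples_per_type = 5,
                                     reads_total = 20000, beta = 150,
                                     mismatch_prob = 0.01,
                                     profile = "constant", ramp_factor = 5,
                                     k = 8, measure = "d2qstar",
                                     seed = NULL) {
  stopifnot(inherits(specA, "metagenome_spec"),
            inherits(specB, "metagenome_spec"))
  measure <- canonical_measure(measure)
  seeds <- derive_seeds(seed, 2L * samples_per_type)
  sets <- vector("list", 2L * samples_per_type)
  type <- character(2L * samples_per_type)
  for (i in seq_len(samples_per_type)) {
    sets[[i]] <- make_metagenome(specA, reads_total, beta, mismatch_prob,
                                 profile = profile, ramp_factor = ramp_factor,
                                 seed = seeds[i],
                                 label = sprintf("typeA_%02d", i))
    type[i] <- "A"
    j <- samples_per_type + i
    sets[[j]] <- make_metagenome(specB, reads_total, beta, mismatch_prob,
                                 profile = profile, ramp_factor = ramp_factor,
                                 seed = seeds[j],
                                 label = sprintf("typeB_%02d", i))
    type[j] <- "B"
  }
  mat <- pairwise_matrices(sets, k, measures = measure)[[measure]]
  hc <- upgma(mat)
  partition <- stats::setNames(type, vapply(sets, `[[`, character(1), "label"))
  list(accuracy = clustering_accuracy(hc, partition),
       height = discriminating_node_height(hc, partition),
       matrix = mat, dendrogram = hc)
}

#' Convenience builder for paired metagenome types
#'
#' Builds two [metagenome_spec()]s over synthetic random genomes with a
#' configurable number of shared genomes and optional distinct abundance
#' profiles, mirroring the three canonical designs: disjoint genome sets,
#' partially shared sets, and identical sets with different abundances.
#'
#' @param n_genomes genomes per type (default 10).
#' @param genome_length genome length in bases (default 50000).
#' @param shared number of genomes common to both types (0 to `n_genomes`).
#' @param weightsA,weightsB abundance profiles (default equal).
#' @param gc GC fraction of the synthetic genomes.
#' @param seed integer seed.
#' @return list with elements `A` and `B`, both `metagenome_spec`.
#' @export
make_metagenome_pair <- function(n_genomes = 10, genome_length = 50000,
                                 shared = 0, weightsA = NULL, weightsB = NULL,
                                 gc = 0.5, seed = NULL) {
  stopifnot(shared >= 0, shared <= n_genomes)
  n_total <- 2L * n_genomes - shared
  seeds <- derive_seeds(seed, n_total)
  genomes <- vapply(seq_len(n_total), function(i)
    random_sequence(genome_length, gc = gc, seed = seeds[i]), character(1))
  names(genomes) <- sprintf("G%02d", seq_len(n_total))
  idxA <- seq_len(n_genomes)
  idxB <- c(seq_len(shared), n_genomes + seq_len(n_genomes - shared))
  list(A = metagenome_spec(genomes[idxA], weightsA),
       B = metagenome_spec(genomes[idxB], weightsB))
}
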