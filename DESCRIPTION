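Package: kmerq
Title: Quality-Weighted Alignment-Free Comparison of Sequencing Read Sets
Version: 0.1.0
Authors@R:
    person("kmerq", "developers", email = "kmerq@example.org", role = c("aut", "cre"))
Description: Alignment-free dissimilarity measures for comparing sets of
    sequencing reads directly from FASTQ files, without assembly or a
    reference genome.  Implements the classical D2 and background-centralized
    D2* word-count statistics for strand-symmetric read sets, together with
    their quality-weighted counterparts in which every k-mer occurrence is
    weighted by its correctness probability derived from phred quality
    scores.  Includes normalized d-type dissimilarities in [0,1], UPGMA and
    neighbor-joining tree construction, Robinson-Foulds tree comparison,
    dendrogram separation diagnostics for two-class designs, a calibrated
    read-set and metagenome-mixture simulator, and a command-line interface
    producing PHYLIP and TSV distance matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
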