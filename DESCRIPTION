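Package: purgetigs
Title: K-Mer Spectra Based Haplotig Purging for Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and removes haplotigs (allelic variants assembled as
    separate scaffolds) from draft genome assemblies using k-mer spectra.
    Canonical k-mers from the whole-genome sequencing reads are compared to
    k-mers in the assembly; the read k-mer spectrum is decomposed into
    error, heterozygous and homozygous components to obtain homozygous
    coverage bounds; scaffolds whose median assembly k-mer copy number is
    two and whose median read k-mer multiplicity falls within the
    homozygous bounds are flagged as putative haplotigs and removed when
    they are contained, at a minimum identity and query coverage, within a
    longer scaffold of the same assembly. Includes a diploid genome and
    short-read simulator with truth labels, per-scaffold GC/coverage
    screening tables, and before/after copy-number validation that no
    single-copy homozygous content is lost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
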