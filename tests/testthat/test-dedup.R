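make_profiles <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r$id, length = 10000, gc_fraction = 0.4,
               n_kmers = if (is.null(r$n_kmers)) 9000 else r$n_kmers,
               median_read_mult = r$mult, median_asm_copy = r$copy,
               stringsAsFactors = FALSE)
  }))
}

test_that("flagging requires copy 2 and read coverage inside the bounds", {
  prof <- make_profiles(
    list(id = "hap_in_band", copy = 2, mult = 30),
    list(id = "single_copy", copy = 1, mult = 30),
    list(id = "copy2_high_cov", copy = 2, mult = 55),
    list(id = "copy2_low_cov", copy = 2, mult = 10),
    list(id = "repeat3", copy = 3, mult = 30),
    list(id = "no_kmers", copy = 2, mult = 30, n_kmers = 0))
  flagged <- flag_haplotigs(prof, c(21, 39), dedup_params())
  expect_equal(flagged, "hap_in_band")
  # aggressive mode also takes higher copy numbers
  flagged2 <- flag_haplotigs(prof, c(21, 39),
                             dedup_params(copy_at_least = TRUE))
  expect_setequal(flagged2, c("hap_in_band", "repeat3"))
  # bounds are inclusive
  edge <- make_profiles(list(id = "lo", copy = 2, mult = 21),
                        list(id = "hi", copy = 2, mult = 39))
  expect_setequal(flag_haplotigs(edge, c(21, 39), dedup_params()),
                  c("lo", "hi"))
})

test_that("removal thresholds are inclusive at exactly (0.75, 0.25)", {
  p <- dedup_params()
  expect_true(hit_passes(0.75, 0.25, p))
  expect_false(hit_passes(0.7499, 0.25, p))
  expect_false(hit_passes(0.75, 0.2499, p))
  expect_true(hit_passes(0.99, 0.9, p))
  expect_false(hit_passes(0.74, 0.90, p))
})

test_that("deduplicate removes a planted haplotig and keeps the rest", {
  sim <- small_sim(seed = 61)
  res <- deduplicate(sim$data$assembly, sim$data$reads, dedup_params())
  truth <- sim$data$truth
  dec <- res$report$decisions
  m <- merge(truth, dec, by.x = "record_id", by.y = "scaffold_id")
  haplotigs <- m$role == "haplotig"
  expect_gt(sum(haplotigs), 0)
  expect_gte(mean(m$removed[haplotigs]), 0.9)
  expect_false(any(m$removed[!haplotigs]))
  # partition invariant, order stability, base conservation
  expect_setequal(c(names(res$kept), names(res$removed)),
                  names(sim$data$assembly))
  expect_identical(names(res$kept),
                   setdiff(names(sim$data$assembly), names(res$removed)))
  expect_equal(res$report$bases_removed,
               sum(nchar(sim$data$assembly)) - sum(nchar(res$kept)))
  expect_equal(res$report$n_removed, length(res$removed))
  # removed decisions carry a qualifying best hit
  rem <- dec[dec$removed, ]
  expect_true(all(rem$identity >= 0.75 & rem$query_coverage >= 0.25))
  expect_true(all(rem$reason == "removed"))
  expect_true(all(dec$reason[!dec$flagged] == "not_flagged"))
})

test_that("lowering thresholds never shrinks the removed set", {
  sim <- small_sim(seed = 62, genome_length = 15e4)
  strict <- deduplicate(sim$data$assembly, sim$data$reads,
                        dedup_params(min_identity = 0.95,
                                     min_query_coverage = 0.8))
  loose <- deduplicate(sim$data$assembly, sim$data$reads,
                       dedup_params(min_identity = 0.75,
                                    min_query_coverage = 0.25))
  expect_true(all(names(strict$removed) %in% names(loose$removed)))
})

test_that("a haploid assembly with matching reads flags nothing", {
  for (seed in 63:64) {
    spec <- simulation_spec(genome_length = 15e4, het_rate = 0,
                            segment_length_mean = 2e4,
                            haplotig_fraction = 0, depth = 40, seed = seed)
    sim <- simulate_dataset(spec)
    rt <- count_kmers(sim$reads, 27)
    at <- count_kmers(sim$assembly, 27)
    fit <- fit_spectrum(kmer_spectrum(rt), 2)
    prof <- profile_scaffolds(sim$assembly, rt, at)
    expect_length(flag_haplotigs(prof, c(fit$hom_lower, fit$hom_upper),
                                 dedup_params()), 0L)
  }
})

test_that("validate_dedup bookkeeping follows single k-mer moves", {
  cells <- data.frame(copy = c(0L, 1L, 2L), multiplicity = c(30L, 30L, 30L),
                      count = c(5, 100, 10))
  mk <- function(cells) structure(list(cells = cells, assembly_only = 0,
                                       k = 27L, max_copy = 10L),
                                  class = "spectra_cn")
  before <- mk(cells)
  v <- validate_dedup(before, before, c(21, 39))
  expect_equal(v$duplicated_hom_before, v$duplicated_hom_after)
  expect_equal(v$lost_single_copy, 0)
  expect_true(v$pass)

  # one copy-2 k-mer resolved to copy 1: duplication shrinks, nothing lost
  after <- mk(data.frame(copy = c(0L, 1L, 2L),
                         multiplicity = c(30L, 30L, 30L),
                         count = c(5, 101, 9)))
  v2 <- validate_dedup(before, after, c(21, 39))
  expect_equal(v2$duplicated_hom_before - v2$duplicated_hom_after, 1)
  expect_equal(v2$lost_single_copy, 0)
  expect_true(v2$pass)

  # k-mers dropping to copy 0 inside the band count as lost
  lostm <- mk(data.frame(copy = c(0L, 1L, 2L),
                         multiplicity = c(30L, 30L, 30L),
                         count = c(7, 98, 10)))
  v3 <- validate_dedup(before, lostm, c(21, 39))
  expect_equal(v3$lost_single_copy, 2)
  expect_false(v3$pass) # 2 / 115 is far above the 0.5% tolerance

  # multiplicity outside the band is ignored
  out <- mk(data.frame(copy = 0L, multiplicity = 10L, count = 1e6))
  v4 <- validate_dedup(before, out, c(21, 39))
  expect_equal(v4$lost_single_copy, 0)
})

test_that("validate_dedup refuses mismatched k", {
  mk <- function(k) structure(list(cells = data.frame(copy = 1L,
                                                      multiplicity = 30L,
                                                      count = 1),
                                   assembly_only = 0, k = k,
                                   max_copy = 10L),
                              class = "spectra_cn")
  expect_error(validate_dedup(mk(27L), mk(21L), c(21, 39)), "different k")
})

test_that("deduplicate rejects empty inputs", {
  expect_error(deduplicate(character(0), c(r = "ACGT")), "empty assembly")
  expect_error(deduplicate(c(a = "ACGT"), character(0)), "empty read")
})

test_that("dedup outputs write the full file set", {
  sim <- small_sim(seed = 65, genome_length = 1e5)
  res <- deduplicate(sim$data$assembly, sim$data$reads, dedup_params())
  prefix <- file.path(withr::local_tempdir(), "run")
  paths <- write_dedup_outputs(res, prefix)
  expect_true(all(file.exists(paths)))
  kept <- read_fasta(paths[["kept"]])
  expect_identical(kept, res$kept)
  rep <- read.table(paths[["report"]], sep = "\t", header = TRUE)
  expect_equal(nrow(rep), length(sim$data$assembly))
  run <- jsonlite::read_json(paths[["params"]])
  expect_equal(run$min_identity, 0.75)
  expect_equal(run$n_removed, res$report$n_removed)
})
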