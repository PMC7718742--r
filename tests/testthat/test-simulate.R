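test_that("zero heterozygosity yields identical haplotypes", {
  spec <- simulation_spec(genome_length = 5e4, het_rate = 0, seed = 71)
  haps <- simulate_diploid(spec)
  expect_identical(haps$hap_a, haps$hap_b)
  expect_length(haps$variants, 0L)
})

test_that("all simulator stages are deterministic per seed", {
  spec <- simulation_spec(genome_length = 5e4, segment_length_mean = 1e4,
                          depth = 5, seed = 72)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(a$assembly, b$assembly)
  expect_identical(a$truth, b$truth)
  expect_identical(a$reads, b$reads)
  # and a different seed changes the genome
  spec2 <- simulation_spec(genome_length = 5e4, segment_length_mean = 1e4,
                           depth = 5, seed = 73)
  expect_false(identical(simulate_diploid(spec2)$hap_a, a$haplotypes$hap_a))
})

test_that("written outputs are byte-stable for a fixed seed", {
  spec <- simulation_spec(genome_length = 3e4, segment_length_mean = 1e4,
                          depth = 4, seed = 74)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(spec, file.path(d1, "x"))
  simulate_dataset(spec, file.path(d2, "x"))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "x.reads.fastq")))
})

test_that("substitution count matches the binomial expectation", {
  spec <- simulation_spec(genome_length = 1e6, het_rate = 0.01, seed = 75)
  haps <- simulate_diploid(spec)
  expect_lt(abs(length(haps$variants) - 10000), 300) # 3 binomial sd
  # variants are 0-based positions where the haplotypes differ
  v <- haps$variants[1:50] + 1L
  expect_true(all(substring(haps$hap_a, v, v) != substring(haps$hap_b, v, v)))
})

test_that("GC content matches the generator target", {
  spec <- simulation_spec(genome_length = 2e5, gc = 0.6, seed = 76)
  haps <- simulate_diploid(spec)
  comp <- table(strsplit(haps$hap_a, "")[[1]])
  gc <- (comp[["G"]] + comp[["C"]]) / sum(comp)
  expect_lt(abs(gc - 0.6), 0.01)
})

test_that("haplotig_fraction 0 produces a purely primary assembly", {
  spec <- simulation_spec(genome_length = 1e5, haplotig_fraction = 0,
                          segment_length_mean = 2e4, seed = 77)
  mock <- build_mock_assembly(simulate_diploid(spec), spec)
  expect_true(all(mock$truth$role == "primary"))
  expect_equal(paste(mock$assembly, collapse = ""),
               simulate_diploid(spec)$hap_a)
})

test_that("haplotig_fraction 1 pairs every variant-bearing segment", {
  spec <- simulation_spec(genome_length = 2e5, haplotig_fraction = 1,
                          het_rate = 0.01, segment_length_mean = 2e4,
                          seed = 78)
  haps <- simulate_diploid(spec)
  mock <- build_mock_assembly(haps, spec)
  tr <- mock$truth
  prim <- tr[tr$role == "primary", ]
  haplo <- tr[tr$role == "haplotig", ]
  # at 1% het every >= 5 kb segment carries variants, so every primary pairs
  expect_equal(nrow(haplo), nrow(prim))
  for (i in seq_len(nrow(haplo))) {
    p <- prim[prim$record_id == haplo$partner_id[i], ]
    expect_equal(nrow(p), 1L)
    # haplotig interval nests in the partner's and is shorter or equal
    expect_gte(haplo$start[i], p$start)
    expect_lte(haplo$end[i], p$end)
    expect_lte(haplo$end[i] - haplo$start[i], p$end - p$start)
    # sequence really comes from haplotype B at those coordinates
    expect_identical(mock$assembly[[haplo$record_id[i]]],
                     substr(haps$hap_b, haplo$start[i] + 1L, haplo$end[i]))
  }
  # trimming stays in the specified 30-90% range
  frac <- (haplo$end - haplo$start) /
    (prim$end[match(haplo$partner_id, prim$record_id)] -
     prim$start[match(haplo$partner_id, prim$record_id)])
  expect_true(all(frac >= 0.3 - 1e-6 & frac <= 0.9 + 1e-6))
})

test_that("planted haplotig count follows the thinning probability", {
  spec <- simulation_spec(genome_length = 1e6, haplotig_fraction = 0.3,
                          het_rate = 0.01, segment_length_mean = 2e4,
                          seed = 79)
  mock <- build_mock_assembly(simulate_diploid(spec), spec)
  n_prim <- sum(mock$truth$role == "primary")
  n_hap <- sum(mock$truth$role == "haplotig")
  sd3 <- 3 * sqrt(n_prim * 0.3 * 0.7)
  expect_lt(abs(n_hap - 0.3 * n_prim), sd3)
})

test_that("segment lengths respect the truncation rules", {
  spec <- simulation_spec(genome_length = 5e5, segment_length_mean = 1e4,
                          seed = 80)
  mock <- build_mock_assembly(simulate_diploid(spec), spec)
  tr <- mock$truth[mock$truth$role == "primary", ]
  lens <- tr$end - tr$start
  expect_true(all(lens >= 5000))
  expect_true(all(lens <= 10 * 1e4 + 5000))
  expect_equal(sum(lens), 5e5)
})

test_that("read volume and error content match the depth arithmetic", {
  spec <- simulation_spec(genome_length = 1e5, depth = 40, error_rate = 0,
                          seed = 81)
  haps <- simulate_diploid(spec)
  reads <- simulate_reads(haps, spec)
  expect_lt(abs(sum(nchar(reads)) - 40 * 1e5) / (40 * 1e5), 0.01)
  # with zero error every read is an exact substring of its haplotype
  meta <- strsplit(names(reads)[1:20], "_")
  for (i in 1:20) {
    hap <- if (meta[[i]][1] == "A") haps$hap_a else haps$hap_b
    start <- as.integer(meta[[i]][3])
    expect_identical(unname(reads[i]), substr(hap, start + 1L, start + 100L))
  }
})

test_that("read errors appear at the requested rate", {
  spec <- simulation_spec(genome_length = 1e5, depth = 10,
                          error_rate = 0.01, het_rate = 0, seed = 82)
  haps <- simulate_diploid(spec)
  reads <- simulate_reads(haps, spec)
  mism <- vapply(seq_along(reads), function(i) {
    meta <- strsplit(names(reads)[i], "_")[[1]]
    start <- as.integer(meta[3])
    truth <- substr(haps$hap_a, start + 1L, start + 100L)
    sum(strsplit(reads[[i]], "")[[1]] != strsplit(truth, "")[[1]])
  }, numeric(1))
  # errors always substitute a different base, so mismatch rate == error rate
  rate <- sum(mism) / sum(nchar(reads))
  expect_lt(abs(rate - 0.01) / 0.01, 0.1)
})

test_that("reads longer than the genome are rejected", {
  spec <- simulation_spec(genome_length = 5e4, read_length = 60000,
                          seed = 83)
  haps <- list(hap_a = strrep("ACGT", 12500), hap_b = strrep("ACGT", 12500))
  expect_error(simulate_reads(haps, spec), "read_length")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(simulation_spec(seed = 1, het_rate = 0.2), "het_rate")
  expect_error(simulation_spec(seed = 1, haplotig_fraction = 2),
               "haplotig_fraction")
  expect_error(simulation_spec(seed = 1, depth = 0), "depth")
  expect_error(simulation_spec(genome_length = 1e4), "seed")
})
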