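#' Specification for a synthetic diploid dataset
#'
#' Describes the study conditions for the simulator: a diploid genome with
#' i.i.d. base composition and substitution-only heterozygosity, a mock
#' assembly in which every segment of haplotype A becomes a primary contig
#' and a fraction of variant-bearing segments additionally emit a trimmed
#' haplotype-B copy (a planted haplotig), and single-end short reads drawn
#' uniformly from both haplotypes with uniform substitution errors.
#'
#' All stochastic outputs are pure functions of this spec; the seed is
#' mandatory. Stage streams derive from it by fixed offsets (genome
#' `seed`, assembly `seed + 1`, reads `seed + 2`), so the stages can be
#' re-run independently yet reproducibly.
#'
#' @param genome_length Haploid genome length in bp.
#' @param gc Target GC fraction of the genome.
#' @param het_rate Per-base heterozygosity probability (0--0.05).
#' @param segment_length_mean Mean contig segment length in bp; segment
#'   lengths are Exponential, truncated to `[5000, 10 * mean]`.
#' @param haplotig_fraction Probability that a variant-bearing segment also
#'   emits a haplotig copy.
#' @param depth Total read depth over both haplotypes.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error probability of reads.
#' @param seed Integer seed, mandatory, below 2^31 - 16.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(genome_length = 5e6, gc = 0.32, het_rate = 0.01,
                            segment_length_mean = 5e4,
                            haplotig_fraction = 0.3, depth = 40,
                            read_length = 100L, error_rate = 0.005, seed) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 16L)
    stop("seed must be a non-negative integer below 2^31 - 16")
  if (het_rate < 0 || het_rate > 0.05)
    stop("het_rate must be in [0, 0.05]")
  if (haplotig_fraction < 0 || haplotig_fraction > 1)
    stop("haplotig_fraction must be in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  structure(list(genome_length = as.numeric(genome_length), gc = gc,
                 het_rate = het_rate,
                 segment_length_mean = as.numeric(segment_length_mean),
                 haplotig_fraction = haplotig_fraction, depth = depth,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = seed),
            class = "simulation_spec")
}

#' Simulate a diploid genome
#'
#' Haplotype A is drawn i.i.d. with `P(G or C) = gc`; haplotype B equals A
#' with independent Bernoulli(`het_rate`) substitutions to a uniformly
#' chosen different base. Deterministic per seed.
#'
#' @param spec A [simulation_spec()].
#' @return List with `hap_a`, `hap_b` (strings) and `variants`, the
#'   0-based positions where the haplotypes differ.
#' @export
simulate_diploid <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  p <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, L, replace = TRUE, prob = p)
  b <- a
  het <- which(stats::runif(L) < spec$het_rate)
  if (length(het) > 0L) {
    # uniformly one of the three other bases
    shift <- sample.int(3L, length(het), replace = TRUE)
    code <- match(a[het], bases) - 1L
    b[het] <- bases[((code + shift) %% 4L) + 1L]
  }
  list(hap_a = paste(a, collapse = ""), hap_b = paste(b, collapse = ""),
       variants = het - 1L)
}

#' Build a mock assembly with planted haplotigs
#'
#' Cuts the genome into segments with Exponential(`segment_length_mean`)
#' lengths truncated to `[5000, 10 * mean]`. Every segment emits haplotype
#' A as a primary contig; with probability `haplotig_fraction` -- and only
#' if the segment carries at least one variant -- a trimmed haplotype-B
#' copy spanning a random 30--90% sub-interval is emitted as a haplotig.
#' Variant-free duplicates are never planted: an exact repeat is not the
#' pathology this pipeline resolves.
#'
#' @param haplotypes Output of [simulate_diploid()].
#' @param spec The same [simulation_spec()].
#' @return List with `assembly` (named character vector, primaries then
#'   haplotigs in genome order) and `truth`, a data frame with columns
#'   `record_id`, `role` (`primary`/`haplotig`), `haplotype`, `start`,
#'   `end` (0-based half-open genome coordinates), `partner_id`.
#' @export
build_mock_assembly <- function(haplotypes, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  L <- spec$genome_length
  mean_len <- spec$segment_length_mean
  lens <- numeric(0)
  total <- 0
  while (total < L) {
    l <- round(min(max(stats::rexp(1L, 1 / mean_len), 5000), 10 * mean_len))
    if (total + l > L) l <- L - total
    lens <- c(lens, l)
    total <- total + l
  }
  # a trailing stub below the 5 kb floor merges into the previous segment
  n <- length(lens)
  if (n > 1L && lens[n] < 5000) {
    lens[n - 1L] <- lens[n - 1L] + lens[n]
    lens <- lens[-n]
    n <- n - 1L
  }
  ends <- cumsum(lens)
  starts <- ends - lens # 0-based
  variants <- haplotypes$variants

  ids <- character(0); seqs <- character(0)
  truth <- vector("list", 0L)
  for (i in seq_len(n)) {
    s <- starts[i]; e <- ends[i]
    pid <- sprintf("ctg%04d", i)
    ids <- c(ids, pid)
    seqs <- c(seqs, substr(haplotypes$hap_a, s + 1L, e))
    truth[[length(truth) + 1L]] <- data.frame(
      record_id = pid, role = "primary", haplotype = "A",
      start = s, end = e, partner_id = NA_character_,
      stringsAsFactors = FALSE)
    nvar <- sum(variants >= s & variants < e)
    if (nvar > 0L && stats::runif(1L) < spec$haplotig_fraction) {
      frac <- stats::runif(1L, 0.3, 0.9)
      hlen <- max(1L, round(frac * (e - s)))
      hs <- s + sample.int(e - s - hlen + 1L, 1L) - 1L
      hid <- sprintf("hap%04d", i)
      ids <- c(ids, hid)
      seqs <- c(seqs, substr(haplotypes$hap_b, hs + 1L, hs + hlen))
      truth[[length(truth) + 1L]] <- data.frame(
        record_id = hid, role = "haplotig", haplotype = "B",
        start = hs, end = hs + hlen, partner_id = pid,
        stringsAsFactors = FALSE)
    }
  }
  names(seqs) <- ids
  list(assembly = seqs, truth = do.call(rbind, truth))
}

#' Simulate single-end short reads from a diploid genome
#'
#' Reads of `read_length` are sampled uniformly from both haplotypes
#' (`depth / 2` each) with independent per-base substitution errors at
#' `error_rate`. Read ids encode the source haplotype and 0-based start
#' position (`A_r12_3456`), carrying truth labels for debugging.
#' Deterministic per seed.
#'
#' @param haplotypes Output of [simulate_diploid()].
#' @param spec The same [simulation_spec()].
#' @return Named character vector of read sequences.
#' @export
simulate_reads <- function(haplotypes, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  L <- nchar(haplotypes$hap_a)
  if (spec$read_length > L)
    stop("read_length exceeds genome_length")
  n_per <- round(spec$depth / 2 * L / spec$read_length)
  res <- sim_reads_cpp(c(haplotypes$hap_a, haplotypes$hap_b), c("A", "B"),
                       c(n_per, n_per), spec$read_length, spec$error_rate,
                       spec$seed + 2)
  stats::setNames(res$seq, res$id)
}

#' Run the full simulator and write its outputs
#'
#' Convenience wrapper: simulates the diploid genome, the mock assembly
#' with planted haplotigs, and the reads; optionally writes haplotypes and
#' assembly as FASTA, reads as FASTQ and truth labels as TSV under
#' `prefix`.
#'
#' @param spec A [simulation_spec()].
#' @param prefix Output path prefix, or `NULL` to skip writing.
#' @return List with `haplotypes`, `assembly`, `truth`, `reads`.
#' @export
simulate_dataset <- function(spec, prefix = NULL) {
  haps <- simulate_diploid(spec)
  mock <- build_mock_assembly(haps, spec)
  reads <- simulate_reads(haps, spec)
  if (!is.null(prefix)) {
    write_fasta(c(hapA = haps$hap_a, hapB = haps$hap_b),
                paste0(prefix, ".haplotypes.fasta"))
    write_fasta(mock$assembly, paste0(prefix, ".assembly.fasta"))
    write_fastq(reads, paste0(prefix, ".reads.fastq"))
    utils::write.table(mock$truth, paste0(prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(haplotypes = haps, assembly = mock$assembly, truth = mock$truth,
       reads = reads)
}
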