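# Naive reference implementations used as independent oracles, and small
# fixture builders. Everything here is deliberately brute force.

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# per-window enumeration; canonical = lexicographic min of k-mer and revcomp
naive_count_kmers <- function(seqs, k) {
  tally <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      canon <- min(w, revcomp_chr(w))
      tally[[canon]] <- (if (is.null(tally[[canon]])) 0 else tally[[canon]]) + 1
    }
  }
  keys <- sort(ls(tally))
  data.frame(kmer = keys,
             count = vapply(keys, function(x) tally[[x]], numeric(1),
                            USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

naive_spectrum <- function(count_df) {
  tab <- table(count_df$count)
  data.frame(multiplicity = as.integer(names(tab)),
             count = as.numeric(tab))
}

# per-scaffold window medians, lower-middle convention
naive_scaffold_medians <- function(scaffold, count_df, k) {
  n <- nchar(scaffold)
  vals <- integer(0)
  if (n >= k) {
    lookup <- stats::setNames(count_df$count, count_df$kmer)
    for (i in seq_len(n - k + 1L)) {
      w <- substr(scaffold, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      canon <- min(w, revcomp_chr(w))
      hit <- lookup[canon]
      vals <- c(vals, if (is.na(hit)) 0L else as.integer(hit))
    }
  }
  if (length(vals) == 0L) return(0)
  sort(vals)[ceiling(length(vals) / 2)]
}

mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  bases <- c("A", "C", "G", "T")
  if (length(idx) > 0L) {
    shift <- sample.int(3L, length(idx), replace = TRUE)
    v[idx] <- bases[((match(v[idx], bases) - 1L + shift) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

# small diploid dataset used by several module tests (cheap to recompute)
small_sim <- function(seed = 1, genome_length = 2e5, het_rate = 0.01,
                      depth = 40, haplotig_fraction = 0.3) {
  spec <- simulation_spec(genome_length = genome_length, het_rate = het_rate,
                          segment_length_mean = 2e4,
                          haplotig_fraction = haplotig_fraction,
                          depth = depth, seed = seed)
  list(spec = spec, data = simulate_dataset(spec))
}
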