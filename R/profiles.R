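#' Per-scaffold k-mer coverage and composition profiles
#'
#' For every scaffold, looks the multiset of its k-mer windows up in the
#' read table and in the assembly table and reports the median of each
#' (read multiplicity is 0 for k-mers absent from the reads), together with
#' length, GC fraction and the number of valid (N-free) windows. Scaffolds
#' shorter than `k` or consisting only of `N` have `n_kmers = 0` and
#' medians 0; downstream flagging ignores them.
#'
#' Medians use the lower-middle value for even window counts, so they stay
#' integral and the "assembly copy equals 2" haplotig predicate is exact.
#'
#' @param assembly Named character vector of scaffold sequences.
#' @param read_table `kmer_table` of the sequencing reads.
#' @param asm_table `kmer_table` of this same assembly.
#' @return Data frame with columns `id`, `length`, `gc_fraction`,
#'   `n_kmers`, `median_read_mult`, `median_asm_copy`; attribute `k`.
#' @export
profile_scaffolds <- function(assembly, read_table, asm_table) {
  stopifnot(is.character(assembly),
            inherits(read_table, "kmer_table"),
            inherits(asm_table, "kmer_table"))
  if (read_table$k != asm_table$k)
    stop("read and assembly tables use different k (",
         read_table$k, " vs ", asm_table$k, ")")
  comp <- seq_composition(unname(assembly))
  acgt <- rowSums(comp[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, rowSums(comp[, c("G", "C"), drop = FALSE]) / acgt, 0)
  n <- length(assembly)
  n_kmers <- integer(n)
  med_read <- numeric(n)
  med_asm <- numeric(n)
  for (i in seq_len(n)) {
    rm <- kc_lookup(read_table$ptr, assembly[[i]])
    am <- kc_lookup(asm_table$ptr, assembly[[i]])
    n_kmers[i] <- length(rm)
    med_read[i] <- median_low(rm)
    med_asm[i] <- median_low(am)
  }
  out <- data.frame(id = names(assembly), length = nchar(assembly),
                    gc_fraction = gc, n_kmers = n_kmers,
                    median_read_mult = med_read, median_asm_copy = med_asm,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "k") <- read_table$k
  out
}

# lower-middle median: integral for integer input
median_low <- function(x) {
  n <- length(x)
  if (n == 0L) return(0)
  sort(x, method = "quick")[ceiling(n / 2)]
}

#' GC/coverage screening table for contaminant inspection
#'
#' The per-scaffold table behind a GC-vs-coverage ("blobplot"-style)
#' screen, without taxonomy: one row per scaffold with its GC fraction and
#' median read k-mer multiplicity as the coverage proxy, plus robust
#' z-scores of both against the length-weighted assembly distribution.
#' Scaffolds far from the assembly mode in this plane (symbionts,
#' contaminants) stand out as large `|gc_z|` or `|coverage_z|`.
#'
#' Coverage here is k-mer based, not read-alignment based; it serves the
#' same screening role without requiring an external aligner.
#'
#' @param profiles Output of [profile_scaffolds()].
#' @return Data frame `id`, `length`, `gc_fraction`, `coverage`,
#'   `coverage_z`, `gc_z`.
#' @export
gc_coverage_table <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  w <- profiles$length
  gc_med <- weighted_median(profiles$gc_fraction, w)
  cov_med <- weighted_median(profiles$median_read_mult, w)
  gc_mad <- 1.4826 * weighted_median(abs(profiles$gc_fraction - gc_med), w)
  cov_mad <- 1.4826 * weighted_median(abs(profiles$median_read_mult - cov_med), w)
  zsafe <- function(x, center, scale) {
    if (scale <= 0) return(rep(0, length(x)))
    (x - center) / scale
  }
  data.frame(id = profiles$id, length = profiles$length,
             gc_fraction = profiles$gc_fraction,
             coverage = profiles$median_read_mult,
             coverage_z = zsafe(profiles$median_read_mult, cov_med, cov_mad),
             gc_z = zsafe(profiles$gc_fraction, gc_med, gc_mad),
             row.names = NULL, stringsAsFactors = FALSE)
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Write per-scaffold profiles to TSV
#'
#' @param profiles Output of [profile_scaffolds()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  k <- attr(profiles, "k")
  writeLines(sprintf("# per-scaffold k-mer profiles, k=%s",
                     if (is.null(k)) "NA" else k), con)
  utils::write.table(profiles, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
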