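#' Decompose a read k-mer spectrum into coverage components
#'
#' Fits a mixture of Gaussian components to the k-mer multiplicity
#' histogram above the sequencing-error region, the classical decomposition
#' of a whole-genome-sequencing k-mer spectrum: an error mode at very low
#' multiplicity, a heterozygous peak near half the genomic k-mer depth, the
#' homozygous peak at full depth, and optionally repeat components at
#' integer multiples. The homozygous component anchors the coverage bounds
#' used to flag haplotigs (see [homozygous_bounds()]).
#'
#' The error cutoff is the first local minimum of the histogram scanning up
#' from multiplicity 1 (fallback 3 when the histogram is monotone).
#' Components are fitted as Gaussians by bounded least squares on the
#' histogram counts over the window from the cutoff to four times the
#' homozygous peak location; this histogram-level fit is deterministic.
#' When the global histogram mode sits near half of a second local maximum
#' (a heterozygosity-dominated spectrum), the upper peak is taken as the
#' homozygous anchor.
#'
#' @param spec A `kmer_spectrum` from [kmer_spectrum()].
#' @param n_components Number of mixture components, 2--4. Two (het + hom)
#'   fits typical diploid short-read spectra; add components for
#'   repeat-rich genomes.
#' @return A `spectrum_fit`: list with `k`, `error_cutoff`, `components`
#'   (data frame `mean`, `sd`, `weight`, ordered by mean), `hom_index`,
#'   `hom_lower`, `hom_upper`.
#' @export
fit_spectrum <- function(spec, n_components = 2L) {
  stopifnot(inherits(spec, "kmer_spectrum"))
  if (n_components < 2L || n_components > 4L)
    stop("n_components must be between 2 and 4")
  if (nrow(spec) == 0L) stop("empty spectrum")

  mmax <- max(spec$multiplicity)
  counts <- numeric(mmax)
  counts[spec$multiplicity] <- spec$count

  cutoff <- error_cutoff(counts)
  if (cutoff >= mmax || sum(counts[(cutoff):mmax]) <= 0)
    stop("degenerate spectrum: no k-mer mass above the error cutoff; ",
         "deeper read coverage is needed to resolve coverage peaks")

  anchor <- hom_anchor(counts, cutoff)
  hi <- min(mmax, max(4L * anchor, cutoff + 4L))
  m <- seq(cutoff, hi)
  y <- counts[m]
  if (sum(y) <= 0)
    stop("degenerate spectrum: no k-mer mass above the error cutoff; ",
         "deeper read coverage is needed to resolve coverage peaks")

  init_means <- anchor * c(0.5, 1, 2, 3)[seq_len(n_components)]
  peak_h <- max(y)
  start <- unlist(lapply(seq_len(n_components), function(j) {
    mu <- init_means[j]
    sd0 <- max(1, mu / 4)
    c(mu = mu, sd = sd0, w = peak_h * sd0 * sqrt(2 * pi) / j)
  }))
  lower <- rep(c(cutoff * 0.5, 0.3, 0), n_components)
  upper <- rep(c(hi * 1.5, hi, Inf), n_components)

  mix_density <- function(par, m) {
    rowSums(vapply(seq_len(length(par) / 3), function(j) {
      mu <- par[3 * j - 2]; sd <- par[3 * j - 1]; w <- par[3 * j]
      w * stats::dnorm(m, mu, sd)
    }, numeric(length(m))))
  }
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(par) mix_density(par, m) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  par <- fit$par
  comp <- data.frame(
    mean = par[seq(1, length(par), by = 3)],
    sd = par[seq(2, length(par), by = 3)],
    weight = par[seq(3, length(par), by = 3)]
  )
  # drop components the optimizer emptied or collapsed onto a neighbor
  comp <- comp[comp$weight > 1e-6 * sum(comp$weight), , drop = FALSE]
  comp <- comp[order(comp$mean), , drop = FALSE]
  keep <- c(TRUE, diff(comp$mean) > 1e-6)
  comp <- comp[keep, , drop = FALSE]
  rownames(comp) <- NULL
  if (nrow(comp) == 0L) stop("spectrum fit collapsed; no components retained")

  hom_index <- which.min(abs(comp$mean - anchor))
  out <- structure(list(k = attr(spec, "k"), error_cutoff = cutoff,
                        components = comp, hom_index = hom_index,
                        hom_lower = NA_real_, hom_upper = NA_real_),
                   class = "spectrum_fit")
  b <- homozygous_bounds(out)
  out$hom_lower <- b[[1L]]
  out$hom_upper <- b[[2L]]
  out
}

# First local minimum of the histogram scanning from m = 1; the valley
# between the sequencing-error mode and the genomic peaks. Fallback 3 when
# the histogram never turns upward.
error_cutoff <- function(counts) {
  n <- length(counts)
  for (m in seq_len(n - 1L)) {
    if (counts[m + 1L] > counts[m]) return(m)
  }
  min(3L, n)
}

# Location anchoring the homozygous component. Usually the global mode
# above the cutoff; but when heterozygous content dominates the spectrum
# the global mode is the half-depth peak, recognizable by a second local
# maximum near twice its position carrying substantial mass.
hom_anchor <- function(counts, cutoff) {
  n <- length(counts)
  region <- seq(cutoff, n)
  mhat <- region[which.max(counts[region])]
  lo <- max(cutoff, floor(1.6 * mhat))
  hi <- min(n, ceiling(2.6 * mhat))
  if (hi <= lo + 1L) return(mhat)
  sub <- seq(lo, hi)
  cand <- sub[which.max(counts[sub])]
  interior <- cand > lo && cand < hi
  if (interior && counts[cand] >= 0.2 * counts[mhat]) cand else mhat
}

#' Homozygous-coverage bounds from a spectrum fit
#'
#' The interval of read k-mer multiplicities attributed to homozygous
#' single-copy genome content: mean +/- 3 sd of the homozygous component,
#' truncated where a neighboring component stops being negligible, and
#' never below the error cutoff. Truncation uses a posterior-purity rule:
#' the band only includes multiplicities where the homozygous component
#' carries at least `purity` (default 90%) of the fitted mixture density
#' relative to each adjacent component. The naive alternative -- cutting at
#' the equal-density crossing -- still admits a sizeable tail of the
#' heterozygous peak, because at the crossing half the k-mers are
#' heterozygous. A degenerate zero-sd component yields
#' `(mean - 1, mean + 1)`.
#'
#' @param fit A `spectrum_fit` from [fit_spectrum()].
#' @param purity Minimum posterior fraction of the homozygous component at
#'   the band edges, relative to the neighboring component, in (0.5, 1).
#' @return Numeric vector `c(lower, upper)` in multiplicity units.
#' @export
homozygous_bounds <- function(fit, purity = 0.9) {
  stopifnot(inherits(fit, "spectrum_fit"), purity > 0.5, purity < 1)
  comp <- fit$components
  i <- fit$hom_index
  mu <- comp$mean[i]; sd <- comp$sd[i]
  if (sd <= 0) return(c(mu - 1, mu + 1))
  lower <- max(fit$error_cutoff, mu - 3 * sd)
  upper <- mu + 3 * sd
  ratio <- purity / (1 - purity) # hom density must exceed neighbor by this
  dens <- function(j, x) comp$weight[j] * stats::dnorm(x, comp$mean[j], comp$sd[j])
  if (i > 1L) {
    xs <- seq(comp$mean[i - 1L], mu, by = 0.01)
    over <- xs[ratio * dens(i - 1L, xs) > dens(i, xs)]
    if (length(over) > 0L) lower <- max(lower, max(over))
  }
  if (i < nrow(comp)) {
    xs <- seq(mu, comp$mean[i + 1L], by = 0.01)
    over <- xs[ratio * dens(i + 1L, xs) > dens(i, xs)]
    if (length(over) > 0L) upper <- min(upper, min(over))
  }
  if (lower >= upper) { lower <- mu - 1; upper <- mu + 1 }
  c(lower, upper)
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("spectrum_fit: k=%d, error cutoff %d\n", x$k, x$error_cutoff))
  comp <- x$components
  for (j in seq_len(nrow(comp)))
    cat(sprintf("  component %d: mean %.2f, sd %.2f, weight %.3g%s\n", j,
                comp$mean[j], comp$sd[j], comp$weight[j],
                if (j == x$hom_index) "  [homozygous]" else ""))
  cat(sprintf("  homozygous bounds: [%.2f, %.2f]\n", x$hom_lower, x$hom_upper))
  invisible(x)
}

#' Serialize a spectrum fit to TSV
#'
#' @param fit A `spectrum_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_fit <- function(fit, path) {
  stopifnot(inherits(fit, "spectrum_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d error_cutoff=%d hom_lower=%.4f hom_upper=%.4f",
                     fit$k, fit$error_cutoff, fit$hom_lower, fit$hom_upper),
             con)
  df <- cbind(component = seq_len(nrow(fit$components)), fit$components,
              homozygous = seq_len(nrow(fit$components)) == fit$hom_index)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
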