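#' Parameters for the haplotig-purging pipeline
#'
#' Defaults encode the pipeline's standard rule set: a scaffold is a putative
#' haplotig when its median assembly k-mer copy number equals 2 and its
#' median read k-mer multiplicity lies within the homozygous coverage
#' bounds; it is removed when it aligns to another, strictly longer
#' scaffold with at least 75% identity and 25% query coverage (both
#' thresholds inclusive).
#'
#' @param k K-mer length for counting and profiling (odd, `<= 31`).
#' @param target_copy Assembly copy number that flags a haplotig
#'   (default 2: the two-haplotype pathology).
#' @param copy_at_least If `TRUE`, flag scaffolds with median copy
#'   `>= target_copy` instead of exactly equal (aggressive mode).
#' @param min_identity Minimum containment identity for removal.
#' @param min_query_coverage Minimum query coverage for removal.
#' @param max_copy Clip value for spectra-cn matrices.
#' @param anchor_k,anchor_w Minimizer anchor length and window for
#'   containment detection.
#' @param min_chain_anchors Minimum anchors per containment chain.
#' @param n_components Mixture components for the spectrum fit.
#' @return A `dedup_params` list.
#' @export
dedup_params <- function(k = 27L, target_copy = 2L, copy_at_least = FALSE,
                         min_identity = 0.75, min_query_coverage = 0.25,
                         max_copy = 10L, anchor_k = 15L, anchor_w = 10L,
                         min_chain_anchors = 3L, n_components = 2L) {
  k <- check_k(k)
  if (target_copy < 2L) stop("target_copy must be >= 2")
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  if (min_query_coverage <= 0 || min_query_coverage > 1)
    stop("min_query_coverage must be in (0, 1]")
  structure(list(k = k, target_copy = as.integer(target_copy),
                 copy_at_least = isTRUE(copy_at_least),
                 min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 max_copy = as.integer(max_copy),
                 anchor_k = as.integer(anchor_k),
                 anchor_w = as.integer(anchor_w),
                 min_chain_anchors = as.integer(min_chain_anchors),
                 n_components = as.integer(n_components)),
            class = "dedup_params")
}

#' Flag putative haplotigs from scaffold profiles
#'
#' A scaffold is flagged when its median assembly k-mer copy number equals
#' the target copy (2 by default), its median read k-mer multiplicity lies
#' within the homozygous coverage bounds, and it has at least one valid
#' k-mer window.
#'
#' @param profiles Output of [profile_scaffolds()].
#' @param bounds Numeric `c(lower, upper)` from [homozygous_bounds()].
#' @param params A [dedup_params()] list.
#' @return Character vector of flagged scaffold ids.
#' @export
flag_haplotigs <- function(profiles, bounds, params = dedup_params()) {
  stopifnot(is.data.frame(profiles), length(bounds) == 2L,
            bounds[1L] < bounds[2L])
  copy_ok <- if (params$copy_at_least)
    profiles$median_asm_copy >= params$target_copy
  else
    profiles$median_asm_copy == params$target_copy
  cov_ok <- profiles$median_read_mult >= bounds[1L] &
    profiles$median_read_mult <= bounds[2L]
  profiles$id[copy_ok & cov_ok & profiles$n_kmers > 0L]
}

# removal rule: inclusive at both thresholds ("at least")
hit_passes <- function(identity, query_coverage, params) {
  identity >= params$min_identity &
    query_coverage >= params$min_query_coverage
}

#' Remove haplotigs from an assembly
#'
#' Runs the full purging pipeline: count canonical k-mers in the reads and
#' the assembly, decompose the read spectrum to obtain the homozygous
#' coverage bounds, profile every scaffold, flag putative haplotigs, test
#' each flagged scaffold (in ascending length order) for containment
#' within any strictly longer scaffold of the assembly, and remove it when
#' the best hit reaches the identity and query-coverage thresholds. The
#' assembly k-mer table is not recomputed between removals: one pass over
#' the draft assembly.
#'
#' @param assembly Named character vector of scaffold sequences.
#' @param reads Named character vector of read sequences.
#' @param params A [dedup_params()] list.
#' @return List with `kept` and `removed` (named character vectors
#'   partitioning the input in input order) and `report`, a `dedup_report`
#'   containing parameters, bounds, per-scaffold decisions, before/after
#'   spectra-cn matrices and the validation metrics of [validate_dedup()].
#' @export
deduplicate <- function(assembly, reads, params = dedup_params()) {
  stopifnot(inherits(params, "dedup_params"))
  if (length(assembly) == 0L) stop("empty assembly")
  if (length(reads) == 0L) stop("empty read set")

  asm_table <- count_kmers(assembly, params$k)
  read_table <- count_kmers(reads, params$k)
  fit <- fit_spectrum(kmer_spectrum(read_table), params$n_components)
  bounds <- c(fit$hom_lower, fit$hom_upper)
  profiles <- profile_scaffolds(assembly, read_table, asm_table)
  flagged <- flag_haplotigs(profiles, bounds, params)
  before <- spectra_cn(read_table, asm_table, params$max_copy)

  decisions <- data.frame(
    scaffold_id = profiles$id, length = profiles$length,
    gc_fraction = profiles$gc_fraction,
    median_read_mult = profiles$median_read_mult,
    median_asm_copy = profiles$median_asm_copy,
    flagged = profiles$id %in% flagged, removed = FALSE,
    reason = "not_flagged", target_id = NA_character_,
    identity = NA_real_, query_coverage = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  decisions$reason[decisions$flagged] <- "flagged_no_hit"

  if (length(flagged) > 0L) {
    index <- index_minimizers(assembly, params$anchor_k, params$anchor_w)
    ord <- flagged[order(nchar(assembly[flagged]), flagged)]
    for (id in ord) {
      hits <- find_containments(assembly[id], index,
                                min_chain_anchors = params$min_chain_anchors,
                                only_longer = TRUE, query_id = id)
      if (nrow(hits) == 0L) next
      best <- hits[1L, ]
      row <- which(decisions$scaffold_id == id)
      decisions$target_id[row] <- best$target_id
      decisions$identity[row] <- best$identity
      decisions$query_coverage[row] <- best$query_coverage
      if (hit_passes(best$identity, best$query_coverage, params)) {
        decisions$removed[row] <- TRUE
        decisions$reason[row] <- "removed"
      }
    }
  }

  removed_ids <- decisions$scaffold_id[decisions$removed]
  kept <- assembly[!(names(assembly) %in% removed_ids)]
  removed <- assembly[names(assembly) %in% removed_ids]

  after <- if (length(kept) > 0L)
    spectra_cn(read_table, count_kmers(kept, params$k), params$max_copy)
  else
    NULL
  validation <- if (is.null(after)) NULL else
    validate_dedup(before, after, bounds)

  report <- structure(list(
    params = params, bounds = bounds, fit = fit, decisions = decisions,
    n_removed = sum(decisions$removed),
    bases_removed = sum(decisions$length[decisions$removed]),
    before = before, after = after, validation = validation
  ), class = "dedup_report")
  list(kept = kept, removed = removed, report = report)
}

#' Validate that deduplication lost no single-copy homozygous content
#'
#' Compares read-vs-assembly copy-number matrices from before and after
#' removal. Within the homozygous multiplicity band:
#' `duplicated_hom` is the distinct k-mer mass at assembly copy >= 2
#' (should shrink -- that mass is the haplotig pathology), and
#' `lost_single_copy` is the increase of mass at assembly copy 0 (content
#' newly missing from the assembly -- should be essentially zero).
#' Validation passes when duplicated homozygous mass does not increase and
#' the lost fraction of the homozygous band is at most 0.005.
#'
#' @param before,after `spectra_cn` objects sharing `k`, built against the
#'   same read table.
#' @param bounds Homozygous bounds `c(lower, upper)`.
#' @return List with `duplicated_hom_before`, `duplicated_hom_after`,
#'   `lost_single_copy`, `hom_band_mass`, `lost_fraction`, `pass`.
#' @export
validate_dedup <- function(before, after, bounds) {
  stopifnot(inherits(before, "spectra_cn"), inherits(after, "spectra_cn"))
  if (before$k != after$k)
    stop("before/after matrices use different k (",
         before$k, " vs ", after$k, ")")
  band_mass <- function(mat, copy_sel) {
    cells <- mat$cells
    in_band <- cells$multiplicity >= bounds[1L] &
      cells$multiplicity <= bounds[2L]
    sum(cells$count[in_band & copy_sel(cells$copy)])
  }
  dup_before <- band_mass(before, function(cp) cp >= 2L)
  dup_after <- band_mass(after, function(cp) cp >= 2L)
  zero_before <- band_mass(before, function(cp) cp == 0L)
  zero_after <- band_mass(after, function(cp) cp == 0L)
  hom_mass <- band_mass(before, function(cp) rep(TRUE, length(cp)))
  lost <- max(0, zero_after - zero_before)
  lost_frac <- if (hom_mass > 0) lost / hom_mass else 0
  list(duplicated_hom_before = dup_before,
       duplicated_hom_after = dup_after,
       lost_single_copy = lost,
       hom_band_mass = hom_mass,
       lost_fraction = lost_frac,
       pass = dup_after <= dup_before && lost_frac <= 0.005)
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("dedup_report: %d scaffolds, %d flagged, %d removed (%.2f Mb)\n",
              nrow(x$decisions), sum(x$decisions$flagged), x$n_removed,
              x$bases_removed / 1e6))
  cat(sprintf("  homozygous bounds: [%.2f, %.2f]\n",
              x$bounds[1L], x$bounds[2L]))
  if (!is.null(x$validation)) {
    v <- x$validation
    cat(sprintf("  duplicated hom k-mers: %s -> %s; lost single-copy fraction %.3g (%s)\n",
                format(v$duplicated_hom_before, big.mark = ","),
                format(v$duplicated_hom_after, big.mark = ","),
                v$lost_fraction, if (v$pass) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Write the full set of deduplication outputs
#'
#' Emits `<prefix>.kept.fasta`, `<prefix>.removed.fasta`,
#' `<prefix>.report.tsv` (one decision row per scaffold),
#' `<prefix>.spectra_cn_before.tsv`, `<prefix>.spectra_cn_after.tsv` and
#' `<prefix>.params.json` (parameters, bounds and removal totals).
#'
#' @param result The list returned by [deduplicate()].
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of paths written.
#' @export
write_dedup_outputs <- function(result, prefix) {
  rep <- result$report
  paths <- c(kept = paste0(prefix, ".kept.fasta"),
             removed = paste0(prefix, ".removed.fasta"),
             report = paste0(prefix, ".report.tsv"),
             before = paste0(prefix, ".spectra_cn_before.tsv"),
             after = paste0(prefix, ".spectra_cn_after.tsv"),
             params = paste0(prefix, ".params.json"))
  write_fasta(result$kept, paths[["kept"]])
  write_fasta(result$removed, paths[["removed"]])
  utils::write.table(rep$decisions, paths[["report"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_spectra_cn(rep$before, paths[["before"]])
  if (!is.null(rep$after)) write_spectra_cn(rep$after, paths[["after"]])
  run <- c(unclass(rep$params),
           list(hom_lower = rep$bounds[1L], hom_upper = rep$bounds[2L],
                n_removed = rep$n_removed,
                bases_removed = rep$bases_removed,
                validation = rep$validation))
  jsonlite::write_json(run, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
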