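#' Count canonical k-mers of a sequence collection
#'
#' Counts every k-length window over `A`,`C`,`G`,`T`; windows containing `N`
#' are skipped entirely. Counting is strand-canonical: a k-mer and its
#' reverse complement are collapsed onto the lexicographically smaller of
#' the two, so reads and assembly are comparable regardless of strand.
#'
#' @param records Named character vector of sequences (see [read_fasta()]).
#' @param k Odd k-mer length, between 1 and 31 (packed 2 bits/base into a
#'   64-bit word). Default 27, the usual choice for read-vs-assembly
#'   spectra at short-read scale.
#' @return A `kmer_table` object with fields `k`, `n_distinct`, `n_total`.
#' @examples
#' count_kmers(c(s1 = "ACGTA"), k = 3)
#' @export
count_kmers <- function(records, k = 27L) {
  k <- check_k(k)
  stopifnot(is.character(records))
  ptr <- kc_build(unname(records), k)
  new_kmer_table(ptr)
}

check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k))
    stop("k must be a single integer")
  k <- as.integer(k)
  if (k < 1L || k > 31L) stop("k must be between 1 and 31")
  if (k %% 2L == 0L) stop("k must be odd (canonical k-mers need a strand-unambiguous center)")
  k
}

new_kmer_table <- function(ptr) {
  st <- kc_stats(ptr)
  structure(list(k = st$k, n_distinct = st$n_distinct, n_total = st$n_total,
                 ptr = ptr),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k=%d, %s distinct canonical k-mers, %s total\n",
              x$k, format(x$n_distinct, big.mark = ","),
              format(x$n_total, big.mark = ",")))
  invisible(x)
}

#' @method as.data.frame kmer_table
#' @export
as.data.frame.kmer_table <- function(x, ...) {
  kc_export(x$ptr)
}

#' K-mer spectrum (multiplicity histogram) of a count table
#'
#' @param table A `kmer_table` from [count_kmers()].
#' @return A `kmer_spectrum`: data frame with columns `multiplicity` and
#'   `count` (number of distinct k-mers seen that many times), plus
#'   attributes `k` and `n_distinct`.
#' @export
kmer_spectrum <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  hist <- kc_spectrum(table$ptr)
  structure(hist, k = table$k, n_distinct = table$n_distinct,
            class = c("kmer_spectrum", "data.frame"))
}

#' Read-vs-assembly copy-number matrix (spectra-cn)
#'
#' Joint histogram of distinct read k-mers by (assembly copy number, read
#' multiplicity). Row `copy = 0` is content present in the reads but
#' missing from the assembly; `copy = 1` is single-copy assembled content;
#' higher rows are duplicated assembly content. Copies above `max_copy`
#' accumulate in the `max_copy` row. K-mers present only in the assembly
#' are tallied separately in `assembly_only`.
#'
#' @param read_table,asm_table `kmer_table`s built with the same `k` from
#'   the reads and the assembly respectively.
#' @param max_copy Clip value for the assembly-copy dimension (default 10).
#' @return A `spectra_cn` object: list with `cells` (data frame `copy`,
#'   `multiplicity`, `count`), `assembly_only`, `k`, `max_copy`.
#' @export
spectra_cn <- function(read_table, asm_table, max_copy = 10L) {
  stopifnot(inherits(read_table, "kmer_table"),
            inherits(asm_table, "kmer_table"))
  if (read_table$k != asm_table$k)
    stop("read and assembly tables use different k (",
         read_table$k, " vs ", asm_table$k, ")")
  if (max_copy < 1L) stop("max_copy must be >= 1")
  res <- kc_spectra_cn(read_table$ptr, asm_table$ptr, as.integer(max_copy))
  structure(list(cells = res$cells, assembly_only = res$assembly_only,
                 k = read_table$k, max_copy = as.integer(max_copy)),
            class = "spectra_cn")
}

#' @export
print.spectra_cn <- function(x, ...) {
  tot <- sum(x$cells$count)
  by_copy <- tapply(x$cells$count, x$cells$copy, sum)
  cat(sprintf("spectra_cn: k=%d, %s distinct read k-mers\n",
              x$k, format(tot, big.mark = ",")))
  for (cp in names(by_copy))
    cat(sprintf("  assembly copy %s: %s k-mers (%.1f%%)\n", cp,
                format(by_copy[[cp]], big.mark = ","),
                100 * by_copy[[cp]] / tot))
  cat(sprintf("  assembly-only k-mers: %s\n",
              format(x$assembly_only, big.mark = ",")))
  invisible(x)
}

#' Serialize a k-mer count table to TSV
#'
#' Writes the sorted two-column (`kmer`, `count`) representation. Intended
#' for modest tables; a full short-read table can run to tens of millions
#' of rows.
#'
#' @param table A `kmer_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_table"))
  df <- kc_export(table$ptr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d", table$k), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a k-mer count table written by [write_kmer_table()]
#'
#' @param path Path to the TSV.
#' @return A `kmer_table`.
#' @export
read_kmer_table <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# k=\\d+$", header))
    stop("missing '# k=' header in ", path)
  k <- as.integer(sub("^# k=", "", header))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          colClasses = c("character", "numeric"))
  new_kmer_table(kc_from_pairs(df$kmer, df$count, k))
}

#' Serialize a spectra-cn matrix to TSV
#'
#' One row per (assembly copy, read multiplicity) cell; a comment header
#' records `k`, `max_copy` and the assembly-only count.
#'
#' @param mat A `spectra_cn` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectra_cn <- function(mat, path) {
  stopifnot(inherits(mat, "spectra_cn"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d max_copy=%d assembly_only=%.0f",
                     mat$k, mat$max_copy, mat$assembly_only), con)
  utils::write.table(mat$cells, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a spectra-cn matrix written by [write_spectra_cn()]
#'
#' @param path Path to the TSV.
#' @return A `spectra_cn` object.
#' @export
read_spectra_cn <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^# k=(\\d+) max_copy=(\\d+) assembly_only=(\\d+)$",
                          header))[[1L]]
  if (length(m) != 4L) stop("missing spectra_cn header in ", path)
  cells <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L)
  structure(list(cells = cells, assembly_only = as.numeric(m[4L]),
                 k = as.integer(m[2L]), max_copy = as.integer(m[3L])),
            class = "spectra_cn")
}
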