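#' Read a FASTA file of sequences
#'
#' Sequence collections are represented throughout the package as named
#' character vectors: names are record ids (the first whitespace-delimited
#' token of each header) and values are uppercase nucleotide strings over
#' `A`, `C`, `G`, `T`, `N`. Any other character (IUPAC ambiguity codes,
#' stray symbols) is mapped to `N` rather than rejected, so that real
#' assemblies never abort k-mer extraction.
#'
#' @param path Path to a FASTA file, plain or gzip-compressed.
#' @return Named character vector of uppercase sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a scaffold", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_fasta_leader(path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  normalize_records(seqs, ids, path)
}

# A sequence line before any header is a malformed FASTA; report the line.
check_fasta_leader <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  i <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return(invisible(TRUE))
    i <- i + 1L
    line <- sub("\r$", "", line)
    if (nzchar(trimws(line))) {
      if (!startsWith(line, ">"))
        stop("malformed FASTA: sequence before header at line ", i,
             " of ", path)
      return(invisible(TRUE))
    }
  }
}

normalize_records <- function(seqs, ids, path) {
  seqs <- toupper(gsub("[ \t\r]", "", seqs))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(!nzchar(ids)))
    stop("empty record id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate record id in ", path, ": ",
         ids[duplicated(ids)][1L])
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", ids[!nzchar(seqs)][1L], "' in ", path)
  names(seqs) <- ids
  seqs
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' The format is autodetected from the first byte (`@` for FASTQ, `>` for
#' FASTA); gzip compression is transparent. Quality strings are discarded;
#' sequences are normalized exactly as in [read_fasta()].
#'
#' @param path Path to a FASTQ or FASTA file, plain or gzipped.
#' @return Named character vector of uppercase read sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  first <- readBin(con, "raw", n = 1L)
  close(con)
  if (length(first) == 0L) return(stats::setNames(character(0), character(0)))
  ch <- rawToChar(first)
  if (ch == ">") return(read_fasta(path))
  if (ch != "@") stop("unrecognized read format (first byte '", ch,
                      "') in ", path)
  read_fastq(path)
}

# 4-line FASTQ parser; validates the sequence/quality length contract that
# format-agnostic readers silently skip.
read_fastq <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- sub("\r$", "", lines)
  while (length(lines) > 0L && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ (", length(lines), " lines) in ", path)
  n <- length(lines) %/% 4L
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0L)
    stop("malformed FASTQ: header missing '@' at line ", (bad[1L] - 1L) * 4L + 1L,
         " of ", path)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L)
    stop("malformed FASTQ: separator missing '+' at line ", (bad[1L] - 1L) * 4L + 3L,
         " of ", path)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0L)
    stop("FASTQ record ", bad[1L], " in ", path,
         ": sequence and quality lengths differ")
  ids <- vapply(strsplit(substring(hdr, 2L), "[ \t]"), `[`, character(1), 1L)
  normalize_records(seqs, ids, path)
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 80 columns. `read_fasta(write_fasta(x))`
#' round-trips ids and sequences losslessly.
#'
#' @param records Named character vector of sequences.
#' @param path Output path (gzip if it ends in `.gz`).
#' @param width Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 80L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(records) == 0L) return(invisible(path))
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("records must be a named character vector with non-empty ids")
  chunks <- lapply(seq_along(records), function(i) {
    s <- records[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    c(paste0(">", ids[i]), substring(s, starts, pmin(starts + width - 1L, n)))
  })
  writeLines(unlist(chunks), con)
  invisible(path)
}

#' Write reads to a FASTQ file
#'
#' Emits constant quality `I` for every base (the simulator does not model
#' base qualities).
#'
#' @param records Named character vector of read sequences.
#' @param path Output path (gzip if it ends in `.gz`).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(records) == 0L) return(invisible(path))
  qual <- vapply(nchar(records), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(records)),
                           unname(records), "+", qual))
  writeLines(lines, con)
  invisible(path)
}
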