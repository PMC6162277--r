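## Plain-text IO for the package's artifact formats. Sequence input is
## normalized to upper case on read.

#' Read sequences from FASTA or FASTQ
#'
#' @param path file path (FASTA or FASTQ; gzipped accepted).
#' @return Named character vector of upper-case sequences.
#' @export
read_seqs <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  if (fmt == "fastq") {
    r <- read_fastq(path)
    setNames(r$seq, r$id)
  } else {
    read_fasta(path)
  }
}

#' Read / write FASTA
#'
#' @param path file path.
#' @return `read_fasta`: named character vector (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @param x named character vector of sequences.
#' @param width line-wrap width.
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unlist(x))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Four-line records; sequence is normalized to upper case on read (a
#' documented normalization, so round-trips of mixed-case input compare
#' equal after the first write).
#'
#' @param path file path (plain or gzipped).
#' @return `read_fastq`: a `fastq_records` data frame (`id`, `seq`,
#'   `qual`).
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L)
    stop("malformed FASTQ (", path, "): ", length(ln),
         " lines is not a multiple of 4")
  ids <- ln[seq(1L, length(ln), by = 4L)]
  plus <- ln[seq(3L, length(ln), by = 4L)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0L)
    stop("malformed FASTQ record ", bad[1], " (line ", (bad[1] - 1L) * 4L + 1L,
         ") in ", path)
  out <- data.frame(id = sub("^@", "", ids),
                    seq = toupper(ln[seq(2L, length(ln), by = 4L)]),
                    qual = ln[seq(4L, length(ln), by = 4L)])
  class(out) <- c("fastq_records", "data.frame")
  out
}

#' @param records a `fastq_records` data frame.
#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(rbind(paste0("@", records$id), records$seq, "+",
                     records$qual)), con)
  invisible(path)
}

#' Read / write a k-mer set file
#'
#' One upper-case word per line, sorted; an optional second tab-separated
#' column carries per-k-mer species support.
#'
#' @param path file path.
#' @return `read_kmer_set`: a [kmer_set()]; when the file has a support
#'   column it is attached as attribute `support` (named by word).
#' @export
read_kmer_set <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) == 0L) stop("empty k-mer set file: ", path)
  parts <- strsplit(ln, "\t", fixed = TRUE)
  words <- toupper(vapply(parts, `[[`, "", 1L))
  ks <- kmer_set(words)
  if (all(lengths(parts) >= 2L)) {
    sup <- as.integer(vapply(parts, `[[`, "", 2L))
    attr(ks, "support") <- setNames(sup, words)
  }
  ks
}

#' @param kmers a [kmer_set()] (or codes plus `k`).
#' @param support optional integer vector parallel to the set's words.
#' @param k word length when `kmers` are bare codes.
#' @rdname read_kmer_set
#' @export
write_kmer_set <- function(kmers, path, support = NULL, k = NULL) {
  ks <- kmer_set(kmers, k)
  words <- kmer_decode(ks)
  ln <- if (is.null(support)) words else {
    if (!is.null(names(support))) support <- support[words]
    paste(words, as.integer(support), sep = "\t")
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read / write BED (0-based half-open intervals)
#'
#' @param path file path.
#' @return `read_bed`: data frame with `chrom`, `start`, `end` and, when
#'   present, `name`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("malformed BED (", path, "): need >= 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  df[, seq_len(min(4L, ncol(df))), drop = FALSE]
}

#' @param df data frame with `chrom`, `start`, `end` (+ optional `name`).
#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "label"), names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a plain TSV with header
#'
#' @param path file path.
#' @return `read_tsv`: data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @param df data frame.
#' @rdname read_tsv
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP positions from a 2-column TSV or a minimal VCF
#'
#' TSV columns are `scaffold`, `position` (0-based). VCF `POS` is 1-based
#' and converted to 0-based on read.
#'
#' @param path file path.
#' @return Data frame with `scaffold` and 0-based `position`.
#' @export
read_snp_positions <- function(path) {
  ln <- readLines(path)
  if (any(startsWith(ln, "##")) || any(startsWith(ln, "#CHROM"))) {
    body <- ln[!startsWith(ln, "#")]
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L)) stop("malformed VCF line in ", path)
    data.frame(scaffold = vapply(parts, `[[`, "", 1L),
               position = as.integer(vapply(parts, `[[`, "", 2L)) - 1L)
  } else {
    body <- ln[nzchar(ln) & !startsWith(ln, "#")]
    if (length(body) > 0L && grepl("scaffold", body[1], ignore.case = TRUE))
      body <- body[-1]
    parts <- strsplit(body, "\t", fixed = TRUE)
    data.frame(scaffold = vapply(parts, `[[`, "", 1L),
               position = as.integer(vapply(parts, `[[`, "", 2L)))
  }
}
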