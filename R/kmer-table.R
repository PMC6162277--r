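#' k-mer coordinate space
#'
#' Fixes the word length and the strand convention used by every k-mer
#' container in the package. Words are stored canonically: a word and its
#' reverse complement are collapsed to the lexicographically smaller of the
#' two, so a single table covers both strands. Internally words are packed
#' 2 bits per base into a double-representable integer code, which bounds k
#' at 26.
#'
#' @param k word length in bases, between 1 and 26 (default 16).
#' @return An object of class `kmer_space`.
#' @export
kmer_space <- function(k = 16L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 26L)
    stop("k must be an integer in [1, 26]")
  structure(list(k = k, strand = "canonical"), class = "kmer_space")
}

#' @export
print.kmer_space <- function(x, ...) {
  cat(sprintf("<kmer_space> k = %d, %s strand convention\n", x$k, x$strand))
  invisible(x)
}

.as_k <- function(space) {
  if (inherits(space, "kmer_space")) space$k else kmer_space(space)$k
}

## Accept character vectors, XStringSet-likes, fastq record frames, or a
## path to a FASTA/FASTQ file, and return a plain character vector of
## sequences.
.as_sequences <- function(x) {
  if (is.data.frame(x) && !is.null(x$seq)) return(x$seq)
  if (methods::is(x, "XStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1L && nchar(x) < 4096 && file.exists(x))
    return(read_seqs(x))
  if (is.character(x)) return(x)
  stop("cannot interpret input as nucleotide sequences")
}

#' Count canonical k-mers
#'
#' Counts every k-length window over the A/C/G/T alphabet in a set of
#' sequences or reads, collapsing each word with its reverse complement
#' (canonical form). Windows containing any other symbol (N and friends)
#' are skipped, not substituted. Multiplicities saturate at 2^32 - 1; if
#' saturation occurs it is recorded on the returned object.
#'
#' @param x sequences: a character vector, a `DNAStringSet`, a
#'   `fastq_records` frame, or a path to a FASTA/FASTQ file.
#' @param space a [kmer_space()] or an integer k.
#' @param sample label for the sample the counts describe.
#' @param source `"reads"` or `"assembly"`.
#' @return A `kmer_count_table`: sorted numeric codes with multiplicities.
#' @examples
#' count_kmers("ACGT", 4)          # palindromic: one canonical word
#' count_kmers("AAAAA", 4)         # two windows of AAAA
#' @export
count_kmers <- function(x, space = kmer_space(), sample = "sample",
                        source = c("reads", "assembly")) {
  source <- match.arg(source)
  k <- .as_k(space)
  seqs <- .as_sequences(x)
  if (length(seqs) == 0L) stop("empty input: nothing to count")
  res <- .cpp_count_kmers(seqs, k)
  if (res$n_windows == 0)
    stop("k = ", k, " is longer than every input sequence")
  if (isTRUE(res$saturated))
    warning("k-mer multiplicities saturated at 2^32 - 1 for sample ", sample)
  structure(
    list(k = k, code = res$code, count = res$count, sample = sample,
         source = source, saturated = isTRUE(res$saturated)),
    class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat(sprintf("<kmer_count_table> sample %s (%s): %s distinct %d-mers, total %s\n",
              x$sample, x$source, format(length(x$code), big.mark = ","),
              x$k, format(sum(x$count), big.mark = ",")))
  invisible(x)
}

#' @export
length.kmer_count_table <- function(x) length(x$code)

#' A plain set of canonical k-mers
#'
#' @param kmers character words or numeric canonical codes.
#' @param k word length; inferred from character input.
#' @return A `kmer_set` (sorted unique canonical codes plus k).
#' @export
kmer_set <- function(kmers, k = NULL) {
  if (is.character(kmers)) {
    if (length(kmers) > 0L) {
      lens <- unique(nchar(kmers))
      if (length(lens) > 1L) stop("k-mers have mixed lengths")
      if (!is.null(k) && length(lens) == 1L && lens != k)
        stop("word length does not match k")
      k <- if (is.null(k)) lens else as.integer(k)
      codes <- .cpp_encode_kmers(kmers, TRUE)
      if (anyNA(codes)) stop("non-ACGT symbols in k-mer words")
    } else {
      if (is.null(k)) stop("k required for an empty set")
      codes <- numeric(0)
    }
  } else if (inherits(kmers, "kmer_set")) {
    return(kmers)
  } else if (inherits(kmers, "sex_specific_set")) {
    return(kmer_set(kmers$code, kmers$k))
  } else {
    if (is.null(k)) stop("k must be given with numeric codes")
    codes <- as.numeric(kmers)
  }
  structure(list(k = as.integer(k), code = sort(unique(codes))),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> %s canonical %d-mers\n",
              format(length(x$code), big.mark = ","), x$k))
  invisible(x)
}

#' @export
length.kmer_set <- function(x) length(x$code)

#' Decode packed k-mer codes back to words
#'
#' @param codes numeric canonical codes (or a `kmer_set`).
#' @param k word length (taken from the set when given one).
#' @return Character vector of words.
#' @export
kmer_decode <- function(codes, k = NULL) {
  if (inherits(codes, "kmer_set")) { k <- codes$k; codes <- codes$code }
  if (is.null(k)) stop("k required")
  .cpp_decode_kmers(as.numeric(codes), as.integer(k))
}

#' Encode k-mer words to packed canonical codes
#'
#' @param words character words over A/C/G/T.
#' @param canonical collapse each word with its reverse complement
#'   (default TRUE).
#' @return Numeric codes; NA for words with non-ACGT symbols.
#' @export
kmer_encode <- function(words, canonical = TRUE) {
  .cpp_encode_kmers(words, canonical)
}

## Internal: extract sorted codes from the various k-mer carriers.
.codes_of <- function(x) {
  if (inherits(x, "kmer_set") || inherits(x, "kmer_count_table") ||
      inherits(x, "sex_specific_set")) return(x$code)
  if (is.numeric(x)) return(x)
  if (is.character(x)) return(sort(.cpp_encode_kmers(x, TRUE)))
  stop("cannot extract k-mer codes from object of class ", class(x)[1])
}

.k_of <- function(x, default = NULL) {
  if (!is.null(x$k)) x$k else default
}
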