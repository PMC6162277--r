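#' Multiplicity histogram of a k-mer count table
#'
#' @param table a `kmer_count_table`.
#' @return Data frame with columns `multiplicity` (1..max observed) and
#'   `n_kmers` (number of distinct canonical k-mers at that multiplicity;
#'   dense, zeros included).
#' @export
kmer_histogram <- function(table) {
  stopifnot(inherits(table, "kmer_count_table"))
  m <- max(table$count)
  data.frame(multiplicity = seq_len(m),
             n_kmers = tabulate(table$count, nbins = m))
}

#' Genome-specific error cutoff from a k-mer multiplicity histogram
#'
#' Short-read k-mer histograms are bimodal: a spike at low multiplicity from
#' sequencing errors and a coverage peak at the sample's k-mer depth. K-mers
#' below the valley between the two modes are presumed error-derived and
#' discarded. The cutoff is the multiplicity at the first minimum between 1
#' and the main coverage peak, clamped to `range` (default 3..15, matching
#' the usual working range for 20-90x genomes).
#'
#' @param histogram a `kmer_count_table`, or a data frame as returned by
#'   [kmer_histogram()], or a bare numeric vector `h[m]` = number of
#'   distinct k-mers at multiplicity m.
#' @param sample label carried onto the result.
#' @param range clamp interval for the cutoff.
#' @return An `error_cutoff` with fields `sample`, `cutoff`, `histogram`.
#' @export
select_error_cutoff <- function(histogram, sample = "sample",
                                range = c(3L, 15L)) {
  if (inherits(histogram, "kmer_count_table")) {
    sample <- histogram$sample
    histogram <- kmer_histogram(histogram)
  }
  h <- if (is.data.frame(histogram)) {
    v <- numeric(max(histogram$multiplicity))
    v[histogram$multiplicity] <- histogram$n_kmers
    v
  } else as.numeric(histogram)
  if (length(h) == 0L || all(h == 0)) stop("empty histogram")
  ## main coverage peak: the most populated multiplicity >= 3; a histogram
  ## that never rises again after multiplicity 2 has no coverage peak and
  ## signals insufficient coverage.
  rises <- which(diff(h) > 0)           # m where h[m+1] > h[m]
  if (length(h) < 3L || length(rises) == 0L || all(rises + 1L <= 2L))
    stop("no coverage peak above multiplicity 2: coverage too low to ",
         "separate errors from signal")
  peak <- which.max(h[3:length(h)]) + 2L
  valley <- which.min(h[seq_len(max(peak - 1L, 1L))])[1]
  cutoff <- min(max(as.integer(valley), as.integer(range[1])),
                as.integer(range[2]))
  structure(list(sample = sample, cutoff = cutoff,
                 histogram = data.frame(multiplicity = seq_along(h),
                                        n_kmers = h)),
            class = "error_cutoff")
}

#' @export
print.error_cutoff <- function(x, ...) {
  cat(sprintf("<error_cutoff> sample %s: cutoff %d\n", x$sample, x$cutoff))
  invisible(x)
}

.as_cutoff <- function(cutoff) {
  if (inherits(cutoff, "error_cutoff")) cutoff$cutoff else as.integer(cutoff)
}

#' Sex-specific k-mer set for one species
#'
#' K-mers observed at or above the error cutoff in the focal sex's read set
#' and effectively absent (count below `opposite_presence_min`) in the
#' opposite sex of the same species. The default `opposite_presence_min = 1`
#' implements strict absence — any single occurrence in the opposite sex
#' excludes the k-mer; set it to 2 to tolerate isolated opposite-sex
#' sequencing errors. The opposite-sex table is used unfiltered.
#'
#' @param focal,opposite `kmer_count_table`s for the two sexes (same k).
#' @param cutoff an `error_cutoff` or integer multiplicity threshold applied
#'   to the focal table.
#' @param opposite_presence_min minimum opposite-sex count that counts as
#'   "present" (default 1).
#' @param species species label (defaults to the focal sample label).
#' @param focal_sex `"male"` or `"female"`.
#' @return A `sex_specific_set` with sorted canonical codes.
#' @export
sex_specific_set <- function(focal, opposite, cutoff,
                             opposite_presence_min = 1L,
                             species = focal$sample,
                             focal_sex = c("male", "female")) {
  stopifnot(inherits(focal, "kmer_count_table"),
            inherits(opposite, "kmer_count_table"))
  focal_sex <- match.arg(focal_sex)
  if (focal$k != opposite$k)
    stop("mismatched k: focal ", focal$k, " vs opposite ", opposite$k)
  cut <- .as_cutoff(cutoff)
  opposite_presence_min <- as.integer(opposite_presence_min)
  keep <- focal$code[focal$count >= cut]
  present <- opposite$code[opposite$count >= opposite_presence_min]
  code <- keep[!(keep %in% present)]
  structure(list(k = focal$k, species = species, focal_sex = focal_sex,
                 code = code, cutoff = cut,
                 opposite_presence_min = opposite_presence_min),
            class = "sex_specific_set")
}

#' @export
print.sex_specific_set <- function(x, ...) {
  cat(sprintf("<sex_specific_set> %s %s: %s %d-mers (cutoff %d, opp-min %d)\n",
              x$species, x$focal_sex, format(length(x$code), big.mark = ","),
              x$k, x$cutoff, x$opposite_presence_min))
  invisible(x)
}

#' @export
length.sex_specific_set <- function(x) length(x$code)

#' Cross-species survival curve of sex-specific k-mers
#'
#' For each n, the number of k-mers that are sex-specific in at least n of
#' the per-species sets. Under an XY system shared across a genus the
#' male-specific curve plateaus at the conserved Y-specific content while
#' the female-specific curve decays to zero before all species are
#' required. The default is order-free ("in >= n species"); `ordered = TRUE`
#' instead intersects the sets cumulatively in the order given.
#'
#' @param sets list of `sex_specific_set`s, one per species, all with the
#'   same `focal_sex` and k.
#' @param ordered use fixed-order cumulative intersection instead of the
#'   order-free ">= n species" count.
#' @return A `survival_curve`: data frame with `n_species`, `count`, plus
#'   attributes `direction` and `ordered`.
#' @export
survival_curve <- function(sets, ordered = FALSE) {
  if (length(sets) < 2L) stop("need sex-specific sets from >= 2 species")
  stopifnot(all(vapply(sets, inherits, TRUE, "sex_specific_set")))
  sexes <- unique(vapply(sets, `[[`, "", "focal_sex"))
  if (length(sexes) != 1L)
    stop("mixed focal_sex: survival curves are per direction")
  ks <- unique(vapply(sets, `[[`, 1L, "k"))
  if (length(ks) != 1L) stop("mixed k among sets")
  n <- length(sets)
  if (ordered) {
    cur <- sets[[1]]$code
    count <- numeric(n)
    count[1] <- length(cur)
    for (i in seq_len(n)[-1]) {
      cur <- cur[cur %in% sets[[i]]$code]
      count[i] <- length(cur)
    }
  } else {
    v <- sort(unlist(lapply(sets, `[[`, "code"), use.names = FALSE))
    memb <- rle(v)$lengths
    per_n <- tabulate(memb, nbins = n)
    count <- rev(cumsum(rev(per_n)))
  }
  structure(data.frame(n_species = seq_len(n), count = count),
            direction = paste0(sexes, "-specific"), ordered = ordered,
            class = c("survival_curve", "data.frame"))
}

#' Genus-conserved sex-specific k-mer set
#'
#' Intersects the per-species male-specific sets and then removes any k-mer
#' present in any female count table — including tables from species for
#' which no male sample exists, so a female-only species still vetoes
#' candidates.
#'
#' @param male_sets list of `sex_specific_set`s (focal sex male), one per
#'   species with a male sample.
#' @param female_tables list of `kmer_count_table`s, one per species
#'   (unfiltered).
#' @param opposite_presence_min minimum female count that counts as present.
#' @return A [kmer_set()] of genus-conserved male-specific k-mers.
#' @export
genus_conserved_set <- function(male_sets, female_tables,
                                opposite_presence_min = 1L) {
  if (length(male_sets) == 0L || length(female_tables) == 0L)
    stop("need at least one male set and one female table")
  stopifnot(all(vapply(male_sets, inherits, TRUE, "sex_specific_set")),
            all(vapply(female_tables, inherits, TRUE, "kmer_count_table")))
  k <- male_sets[[1]]$k
  cons <- male_sets[[1]]$code
  for (s in male_sets[-1]) {
    if (s$k != k) stop("mixed k among male sets")
    cons <- cons[cons %in% s$code]
  }
  m <- as.integer(opposite_presence_min)
  for (tab in female_tables) {
    if (tab$k != k) stop("mixed k between male sets and female tables")
    present <- tab$code[tab$count >= m]
    cons <- cons[!(cons %in% present)]
  }
  kmer_set(cons, k)
}

#' Select reads carrying query k-mers
#'
#' Keeps every read that contains at least one query k-mer on either strand
#' (queries are canonical). With mates supplied, a hit in either member of
#' a pair keeps both. Input order is preserved.
#'
#' @param reads a `fastq_records` frame (or character vector of sequences).
#' @param kmers a [kmer_set()], `sex_specific_set`, character words, or
#'   numeric codes (then `k` is required).
#' @param mates optional `fastq_records` parallel to `reads` (mate pairs).
#' @param k word length when `kmers` are bare codes.
#' @return The selected subset of `reads` (and, as attribute `mates`, the
#'   corresponding mate subset when mates were given).
#' @export
select_reads_with_kmers <- function(reads, kmers, mates = NULL, k = NULL) {
  ks <- if (is.numeric(kmers)) kmer_set(kmers, k) else kmer_set(kmers, k)
  seqs <- .as_sequences(reads)
  if (length(seqs) > 0L && min(nchar(seqs)) < ks$k)
    warning("some reads are shorter than k and can never match")
  hit <- .cpp_reads_with_kmers(seqs, ks$code, ks$k)
  if (!is.null(mates)) {
    mseqs <- .as_sequences(mates)
    if (length(mseqs) != length(seqs))
      stop("mates must parallel reads one to one")
    hit <- hit | .cpp_reads_with_kmers(mseqs, ks$code, ks$k)
  }
  out <- if (is.data.frame(reads)) reads[hit, , drop = FALSE] else reads[hit]
  if (is.data.frame(out)) rownames(out) <- NULL
  if (!is.null(mates)) {
    msel <- if (is.data.frame(mates)) mates[hit, , drop = FALSE] else mates[hit]
    if (is.data.frame(msel)) rownames(msel) <- NULL
    attr(out, "mates") <- msel
  }
  out
}
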