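## Localization of conserved sex-specific k-mers onto contigs/scaffolds.
## Matching is exact and canonical (both strands), by construction of the
## conserved sets.

.as_contigs <- function(contigs) {
  if (methods::is(contigs, "XStringSet"))
    contigs <- setNames(as.character(contigs), names(contigs))
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_fasta(contigs)
  if (!is.character(contigs)) stop("cannot interpret contigs")
  if (length(contigs) == 0L) return(character(0))
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  toupper(contigs)
}

## Normalize the k-mer query to (codes, k, support): accepts kmer_set (with
## optional support attribute), data.frame(kmer, support), words, or codes.
.as_query <- function(kmers, k = NULL, support = NULL) {
  if (is.data.frame(kmers)) {
    support <- kmers$support
    ks <- kmer_set(as.character(kmers$kmer))
    sup <- setNames(as.integer(support), as.character(kmers$kmer))
    codes <- kmer_encode(names(sup))
    return(list(k = ks$k, code = sort(unique(codes)),
                support = setNames(as.integer(sup), codes)))
  }
  sup_attr <- attr(kmers, "support")
  ks <- kmer_set(kmers, k)
  sup <- NULL
  if (!is.null(support)) {
    if (is.null(names(support))) stop("support must be named by k-mer word")
    sup <- setNames(as.integer(support), kmer_encode(names(support)))
  } else if (!is.null(sup_attr)) {
    sup <- setNames(as.integer(sup_attr), kmer_encode(names(sup_attr)))
  }
  list(k = ks$k, code = ks$code, support = sup)
}

#' Match k-mers exactly against contigs
#'
#' Reports every exact occurrence of each query k-mer on either strand of
#' each contig (queries are canonical; a k-mer occurring at several sites
#' is reported at every site). Strand is `+` when the forward word at the
#' site is the canonical orientation.
#'
#' @param kmers a [kmer_set()], `sex_specific_set`, character words,
#'   numeric codes (then give `k`), or a data frame with columns `kmer`
#'   and `support`.
#' @param contigs named character vector, `DNAStringSet`, or FASTA path.
#' @param k word length when `kmers` are bare codes.
#' @param support optional named (by word) per-k-mer species support,
#'   carried through to the hit table.
#' @return A list of `kmer_match_profile`s, one per contig, each with
#'   `contig`, `length`, and a `hits` data frame (`pos` 0-based, `strand`,
#'   `kmer`, `support`).
#' @export
match_kmers <- function(kmers, contigs, k = NULL, support = NULL) {
  q <- .as_query(kmers, k, support)
  contigs <- .as_contigs(contigs)
  lapply(seq_along(contigs), function(i) {
    seq <- contigs[[i]]
    wc <- .cpp_window_codes(seq, q$k)
    hit <- !is.na(wc$code) & (wc$code %in% q$code)
    pos <- which(hit) - 1L
    code <- wc$code[hit]
    strand <- ifelse(wc$fwd[hit], "+", "-")
    hits <- data.frame(pos = pos, strand = strand,
                       kmer = kmer_decode(code, q$k))
    hits$support <- if (!is.null(q$support))
      unname(q$support[as.character(code)]) else rep(NA_integer_, nrow(hits))
    structure(list(contig = names(contigs)[i], length = nchar(seq),
                   k = q$k, hits = hits),
              class = "kmer_match_profile")
  })
}

#' @export
print.kmer_match_profile <- function(x, ...) {
  cat(sprintf("<kmer_match_profile> %s (%s bp): %d hit(s)\n",
              x$contig, format(x$length, big.mark = ","), nrow(x$hits)))
  invisible(x)
}

#' Percentage of k-mers covered by a contig set, by species support
#'
#' For each support threshold n, the percentage of the >= n-species k-mer
#' set with at least one exact hit anywhere in the contig set (both
#' strands).
#'
#' @param kmers_by_support named list mapping a support threshold n to the
#'   k-mer set specific in >= n species ([kmer_set()]s, words, or codes
#'   with `k`).
#' @param contigs named character vector, `DNAStringSet`, or FASTA path.
#' @param k word length when sets are bare codes.
#' @return Data frame with `support` and `percent_matched`.
#' @export
coverage_percent <- function(kmers_by_support, contigs, k = NULL) {
  contigs <- .as_contigs(contigs)
  if (length(contigs) == 0L) stop("empty contig set")
  sets <- lapply(kmers_by_support, kmer_set, k = k)
  if (length(sets) == 0L || all(lengths(lapply(sets, `[[`, "code")) == 0L))
    stop("empty k-mer sets")
  kk <- unique(vapply(sets, `[[`, 1L, "k"))
  if (length(kk) != 1L) stop("mixed k among sets")
  universe <- .cpp_count_kmers(unname(contigs), kk)$code
  pct <- vapply(sets, function(s) {
    if (length(s$code) == 0L) return(NA_real_)
    100 * mean(s$code %in% universe)
  }, 1.0)
  data.frame(support = as.integer(names(kmers_by_support)),
             percent_matched = unname(pct))
}

#' k-mer density track along a contig, stratified by species support
#'
#' Tiles the contig with fixed windows (a final partial window is dropped)
#' and reports hits-per-bp for each minimum species-support threshold —
#' the numeric form of a density heat track.
#'
#' @param profile a `kmer_match_profile` from [match_kmers()].
#' @param window window size in bp.
#' @param thresholds support thresholds; defaults to 1..max observed
#'   support (a single `1` when support is absent).
#' @return A `density_track`: window starts plus a windows x thresholds
#'   matrix of densities (k-mers/bp).
#' @export
density_track <- function(profile, window = 1000L, thresholds = NULL) {
  stopifnot(inherits(profile, "kmer_match_profile"))
  if (window <= 0L) stop("window must be > 0")
  sup <- profile$hits$support
  if (all(is.na(sup))) sup <- rep(1L, nrow(profile$hits))
  if (is.null(thresholds)) {
    thresholds <- if (length(sup) > 0L) seq_len(max(sup, 1L)) else 1L
  }
  starts <- seq.int(0L, profile$length - window, by = window)
  if (profile$length < window) starts <- integer(0)
  vals <- sapply(thresholds, function(n) {
    p <- profile$hits$pos[sup >= n]
    if (length(starts) == 0L) return(numeric(0))
    counts <- tabulate(findInterval(p, c(starts, starts[length(starts)] +
                                           window)),
                       nbins = length(starts) + 1L)[seq_along(starts)]
    counts / window
  })
  vals <- matrix(vals, nrow = length(starts),
                 dimnames = list(NULL, paste0("support>=", thresholds)))
  structure(list(contig = profile$contig, window = as.integer(window),
                 starts = starts, thresholds = as.integer(thresholds),
                 values = vals),
            class = "density_track")
}

#' @export
print.density_track <- function(x, ...) {
  cat(sprintf("<density_track> %s: %d windows of %d bp x %d thresholds\n",
              x$contig, length(x$starts), x$window, length(x$thresholds)))
  invisible(x)
}

#' Select phased Y-haplotype scaffolds by k-mer counts
#'
#' A scaffold is selected when one haplotype carries at least `min_kmers`
#' male-specific k-mers and at least `ratio_min` times more than the other
#' haplotype (a zero opposite count passes the ratio). Ties at or above
#' `min_kmers` are rejected — neither haplotype dominates — and logged.
#'
#' @param pairs data frame with columns `scaffold`, `hapA_kmer_count`,
#'   `hapB_kmer_count` (or `hapA`/`hapB`).
#' @param min_kmers minimum k-mers in the winning haplotype (default 100).
#' @param ratio_min minimum ratio of the winning to the losing haplotype
#'   (default 6).
#' @return The input with `selected` (logical) and `assigned_haplotype`
#'   (`"A"`, `"B"`, or `"none"`).
#' @export
select_haplotype_scaffolds <- function(pairs, min_kmers = 100L,
                                       ratio_min = 6) {
  nm <- names(pairs)
  a <- pairs[[if ("hapA_kmer_count" %in% nm) "hapA_kmer_count" else "hapA"]]
  b <- pairs[[if ("hapB_kmer_count" %in% nm) "hapB_kmer_count" else "hapB"]]
  if (any(a < 0) || any(b < 0)) stop("k-mer counts must be >= 0")
  hi <- pmax(a, b); lo <- pmin(a, b)
  tie <- a == b
  sel <- !tie & hi >= min_kmers & (lo == 0 | hi >= ratio_min * lo)
  if (any(tie & hi >= min_kmers))
    message(sum(tie & hi >= min_kmers),
            " scaffold(s) rejected on tied haplotype counts")
  pairs$selected <- sel
  pairs$assigned_haplotype <- ifelse(!sel, "none", ifelse(a > b, "A", "B"))
  pairs
}

#' Consensus substitution set against a reference sequence
#'
#' Records SNP positions whose reference base is to be replaced by a
#' sex-specific allele; construction verifies every `ref` base against the
#' reference so stale coordinates fail fast.
#'
#' @param reference reference nucleotide sequence (single string).
#' @param substitutions data frame with `pos` (0-based), `ref`, `alt`.
#' @return A `consensus_substitution`.
#' @export
consensus_substitution <- function(reference, substitutions) {
  reference <- toupper(reference)
  stopifnot(all(c("pos", "ref", "alt") %in% names(substitutions)))
  if (nrow(substitutions) > 0L) {
    at <- substr(rep(reference, nrow(substitutions)),
                 substitutions$pos + 1L, substitutions$pos + 1L)
    bad <- which(at != toupper(substitutions$ref))
    if (length(bad) > 0L)
      stop("ref base mismatch at 0-based position ",
           substitutions$pos[bad[1]], ": reference has ", at[bad[1]],
           ", substitution claims ", substitutions$ref[bad[1]],
           " (stale coordinates?)")
  }
  structure(list(reference = reference, substitutions = substitutions),
            class = "consensus_substitution")
}

#' Apply consensus substitutions
#'
#' @param cons a [consensus_substitution()].
#' @return The reference with every substitution applied; differs from the
#'   reference exactly at the substituted positions.
#' @export
apply_substitutions <- function(cons) {
  stopifnot(inherits(cons, "consensus_substitution"))
  v <- strsplit(cons$reference, "", fixed = TRUE)[[1]]
  v[cons$substitutions$pos + 1L] <- toupper(cons$substitutions$alt)
  paste(v, collapse = "")
}
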