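## Copies-per-genome from read depth normalized to a diploid (2N) baseline,
## plus the RNA-seq control-scaffold expression normalization.

#' Alignment-free region depth from a k-mer count table
#'
#' Mean per-position count of the sample's canonical k-mers exactly
#' matching the region sequence — a desk-scale surrogate for aligned read
#' depth. Absolute values are in k-mer-coverage units (about
#' `depth * (read_length - k + 1) / read_length` for reads), but the unit
#' cancels in any ratio to a baseline computed the same way.
#'
#' @param table `kmer_count_table` built from the sample's reads.
#' @param region_seq nucleotide sequence of the region.
#' @return Mean per-position k-mer count (positions whose window contains
#'   non-ACGT symbols are skipped).
#' @export
kmer_region_depth <- function(table, region_seq) {
  stopifnot(inherits(table, "kmer_count_table"))
  wc <- .cpp_window_codes(toupper(region_seq), table$k)
  codes <- wc$code[!is.na(wc$code)]
  if (length(codes) == 0L) stop("region shorter than k or all-N")
  i <- match(codes, table$code)
  counts <- ifelse(is.na(i), 0, table$count[i])
  mean(counts)
}

#' Per-sample depth profile over candidate and control regions
#'
#' @param sample sample label.
#' @param sex `"male"`, `"female"` or `"hermaphrodite"`.
#' @param regions data frame with `contig`, `start`, `end`, `mean_depth`
#'   (0-based half-open intervals).
#' @param baseline_regions control (non-sex-linked) regions, same columns.
#' @return A `depth_profile`.
#' @export
depth_profile <- function(sample, sex, regions, baseline_regions) {
  need <- c("contig", "start", "end", "mean_depth")
  stopifnot(all(need %in% names(regions)),
            all(need %in% names(baseline_regions)))
  if (any(regions$mean_depth < 0) || any(baseline_regions$mean_depth < 0))
    stop("depths must be >= 0")
  structure(list(sample = sample, sex = sex, regions = regions,
                 baseline_regions = baseline_regions),
            class = "depth_profile")
}

#' Depth profile computed alignment-free from region sequences
#'
#' @param table `kmer_count_table` from the sample's reads.
#' @param regions named character vector of candidate region sequences.
#' @param controls named character vector of control region sequences.
#' @param sample,sex labels (default from the table).
#' @return A `depth_profile` with k-mer-unit depths.
#' @export
depth_profile_from_kmers <- function(table, regions, controls,
                                     sample = table$sample, sex = NA) {
  mk <- function(seqs) {
    if (length(seqs) == 0L)
      return(data.frame(contig = character(0), start = integer(0),
                        end = integer(0), mean_depth = numeric(0)))
    data.frame(
      contig = names(seqs),
      start = 0L, end = nchar(seqs),
      mean_depth = vapply(seqs, function(s) kmer_region_depth(table, s), 1.0),
      row.names = NULL)
  }
  depth_profile(sample, sex, mk(regions), mk(controls))
}

#' Diploid baseline depth of a sample
#'
#' Median of the control-region mean depths; the median resists
#' contamination of the control set by high-copy repeats.
#'
#' @param profile a `depth_profile`.
#' @return Scalar baseline depth (2N level).
#' @export
baseline_depth <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  if (nrow(profile$baseline_regions) == 0L) stop("no control regions")
  median(profile$baseline_regions$mean_depth)
}

#' Call copies per genome from region depth
#'
#' `copies_raw = 2 * region_depth / baseline` (baseline is the 2N level);
#' the integer call uses half-integer band boundaries, e.g. raw between
#' 0.5 (inclusive) and 1.5 (exclusive) calls 1.
#'
#' @param region_depth mean depth over the region.
#' @param baseline diploid baseline depth (> 0).
#' @return List with `copies_raw` and `copies_called`.
#' @export
call_copies <- function(region_depth, baseline) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  raw <- 2 * region_depth / baseline
  list(copies_raw = raw, copies_called = pmax(0L, as.integer(floor(raw + 0.5))))
}

#' Copy-number profile for every region of a depth profile
#'
#' Regions shorter than 200 bp are flagged low-confidence (too few
#' positions for a stable mean) but still reported.
#'
#' @param profile a `depth_profile`.
#' @return A `copy_number_profile`: per-region `copies_raw`,
#'   `copies_called`, `low_confidence`, plus the baseline used.
#' @export
copy_number_profile <- function(profile) {
  base <- baseline_depth(profile)
  cc <- call_copies(profile$regions$mean_depth, base)
  regions <- profile$regions
  regions$copies_raw <- cc$copies_raw
  regions$copies_called <- cc$copies_called
  regions$low_confidence <- (regions$end - regions$start) < 200L
  structure(list(sample = profile$sample, sex = profile$sex,
                 baseline = base, regions = regions),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("<copy_number_profile> %s (%s), baseline %.2f\n",
              x$sample, x$sex, x$baseline))
  print(x$regions[, c("contig", "copies_raw", "copies_called",
                      "low_confidence")])
  invisible(x)
}

#' Mean raw copy number across male samples, per region
#'
#' @param profiles list of `copy_number_profile`s; entries with a known
#'   non-male sex are dropped.
#' @return Data frame with `contig` and `mean_copies_raw`.
#' @export
mean_male_copy <- function(profiles) {
  stopifnot(all(vapply(profiles, inherits, TRUE, "copy_number_profile")))
  sexes <- vapply(profiles, function(p) as.character(p$sex)[1], "")
  keep <- is.na(sexes) | sexes == "male"
  profiles <- profiles[keep]
  if (length(profiles) == 0L) stop("no male profiles")
  mats <- lapply(profiles, function(p)
    setNames(p$regions$copies_raw, p$regions$contig))
  regions <- names(mats[[1]])
  if (length(regions) == 0L)
    return(data.frame(contig = character(0), mean_copies_raw = numeric(0)))
  vals <- matrix(vapply(mats, function(m) m[regions], numeric(length(regions))),
                 nrow = length(regions))
  data.frame(contig = regions, mean_copies_raw = rowMeans(vals))
}

#' Normalize expression to a non-sex-linked control scaffold
#'
#' `normalized = (fragment_count / feature_length_kb) /
#' control_fragments_per_kb`: fragments per kb of feature, in units of the
#' control scaffold's fragments per kb.
#'
#' @param fragment_count fragments mapped to the feature.
#' @param feature_length_kb feature length in kb (> 0).
#' @param control_fragments_per_kb control scaffold density (> 0).
#' @param sample,feature labels.
#' @return An `expression_record`.
#' @export
normalize_expression <- function(fragment_count, feature_length_kb,
                                 control_fragments_per_kb,
                                 sample = "sample", feature = "feature") {
  if (feature_length_kb <= 0) stop("feature length must be > 0 kb")
  if (control_fragments_per_kb <= 0) stop("control density must be > 0")
  structure(list(sample = sample, feature = feature,
                 fragment_count = fragment_count,
                 feature_length_kb = feature_length_kb,
                 control_fragments_per_kb = control_fragments_per_kb,
                 normalized_value = (fragment_count / feature_length_kb) /
                   control_fragments_per_kb),
            class = "expression_record")
}

#' @export
print.expression_record <- function(x, ...) {
  cat(sprintf("<expression_record> %s %s: %.4g (control-normalized)\n",
              x$sample, x$feature, x$normalized_value))
  invisible(x)
}
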