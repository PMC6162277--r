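## k-mer length calibration: SNP spacing, clustering, and the sliding-window
## scan for fully conserved k-length sites.

#' SNP track for one scaffold
#'
#' Holds called SNP positions (0-based) and an optional mask of excluded
#' positions (annotated repeats, excess-coverage sites). SNP calling itself
#' is upstream of this package; tracks are typically ingested with
#' [read_snp_positions()].
#'
#' @param scaffold label.
#' @param length scaffold length in bp.
#' @param snp_positions 0-based positions, need not be sorted.
#' @param mask 0-based positions excluded from conserved-site counting.
#' @return A `snp_track`.
#' @export
snp_track <- function(scaffold, length, snp_positions, mask = integer(0)) {
  snp_positions <- sort(unique(as.integer(snp_positions)))
  if (any(snp_positions < 0L) || any(snp_positions >= length))
    stop("SNP positions must lie in [0, length)")
  structure(list(scaffold = as.character(scaffold),
                 length = as.integer(length),
                 snp_positions = snp_positions,
                 mask = sort(unique(as.integer(mask)))),
            class = "snp_track")
}

#' Average spacing between SNPs
#'
#' @param total_nonrep_bp non-repetitive bases surveyed.
#' @param n_snps number of SNPs called in them (> 0).
#' @return bp per SNP (`total_nonrep_bp / n_snps`).
#' @examples
#' snp_spacing(1780052, 107692)  # ~16.5 bp per SNP
#' @export
snp_spacing <- function(total_nonrep_bp, n_snps) {
  if (n_snps <= 0) stop("n_snps must be > 0")
  total_nonrep_bp / n_snps
}

#' Fraction of SNPs within d bp of another SNP
#'
#' Nearest-neighbour interpretation: a SNP counts if its closest other SNP
#' lies at distance <= d.
#'
#' @param snp_positions >= 2 positions (one scaffold).
#' @param d distance threshold in bp (default 16).
#' @return Proportion in [0, 1].
#' @export
fraction_snps_within <- function(snp_positions, d = 16L) {
  p <- sort(unique(as.numeric(snp_positions)))
  if (length(p) < 2L) stop("need >= 2 SNP positions")
  gaps <- diff(p)
  nn <- pmin(c(Inf, gaps), c(gaps, Inf))
  mean(nn <= d)
}

#' Simulate SNP positions with optional clustering
#'
#' Places `n` SNPs on `[0, length)`. The clustering knob lays a
#' `cluster_frac` share of the SNPs down as anchor + companion pairs at
#' most `d` bp apart (the rest uniform), so at low density the fraction of
#' SNPs whose nearest neighbour is within `d` approximates the knob. This
#' is the placement model the genus simulator's clustering knob shares,
#' exposed standalone for calibration experiments.
#'
#' @param length scaffold length (bp).
#' @param n number of SNPs.
#' @param cluster_frac target fraction of SNPs within `d` of another.
#' @param d clustering distance (bp).
#' @param seed integer seed.
#' @return Sorted 0-based positions (duplicates collapse, so the returned
#'   count may be slightly below `n`).
#' @export
simulate_snp_positions <- function(length, n, cluster_frac = 0, d = 16L,
                                   seed = 1L) {
  withr::with_seed(seed,
    sort(unique(.cluster_positions(length, n, cluster_frac, d) - 1L)))
}

#' Sliding-window scan for fully conserved k-length sites
#'
#' Tiles each scaffold with `window`-bp windows every `step` bp (from
#' position 0; a final partial window is dropped). A *site* is a start
#' position whose k-length window contains no SNP and no masked base and
#' lies fully inside the window. A window *fails* when its site count
#' (doubled under `both_strands`, since every conserved site is conserved
#' on both strands) is below `min_sites`.
#'
#' @param track a [snp_track()] or list of them (windows never span
#'   scaffold boundaries).
#' @param window,step window and step size in bp (defaults 500/250).
#' @param k site length in bp (default 16); must be <= window.
#' @param min_sites failure threshold (use 20 per strand, 40 when
#'   `both_strands`).
#' @param both_strands double site counts to cover both orientations.
#' @return A `window_scan_result` with `n_windows`, `n_failing` and the
#'   per-window site counts.
#' @export
window_scan <- function(track, window = 500L, step = 250L, k = 16L,
                        min_sites = 20L, both_strands = FALSE) {
  if (inherits(track, "snp_track")) track <- list(track)
  stopifnot(all(vapply(track, inherits, TRUE, "snp_track")))
  if (step <= 0L) stop("step must be > 0")
  if (window < k) stop("window must be >= k")
  per <- lapply(track, function(tr) {
    L <- tr$length
    if (L < window) {
      return(data.frame(scaffold = character(0), start = integer(0),
                        sites = integer(0)))
    }
    bad <- logical(L)
    bad[tr$snp_positions + 1L] <- TRUE
    bad[tr$mask[tr$mask < L] + 1L] <- TRUE
    cb <- c(0L, cumsum(bad))
    n_sites_pos <- L - k + 1L                  # candidate site starts
    p <- seq_len(n_sites_pos) - 1L             # 0-based
    ok <- (cb[p + k + 1L] - cb[p + 1L]) == 0L  # no bad base in [p, p+k)
    cok <- c(0L, cumsum(ok))
    starts <- seq.int(0L, L - window, by = step)
    lo <- starts                               # first site start in window
    hi <- starts + window - k                  # last site start in window
    sites <- cok[hi + 2L] - cok[lo + 1L]
    data.frame(scaffold = tr$scaffold, start = starts, sites = sites)
  })
  win <- do.call(rbind, per)
  mult <- if (both_strands) 2L else 1L
  win$sites <- win$sites * mult
  structure(list(window = as.integer(window), step = as.integer(step),
                 k = as.integer(k), min_sites = as.integer(min_sites),
                 both_strands = both_strands,
                 n_windows = nrow(win),
                 n_failing = sum(win$sites < min_sites),
                 windows = win),
            class = "window_scan_result")
}

#' @export
print.window_scan_result <- function(x, ...) {
  cat(sprintf(paste0("<window_scan_result> %d windows (%d bp / step %d), ",
                     "k = %d, min_sites = %d%s: %d failing\n"),
              x$n_windows, x$window, x$step, x$k, x$min_sites,
              if (x$both_strands) " (both strands)" else "", x$n_failing))
  invisible(x)
}

#' Empirical miss probability of the window scan
#'
#' With zero failing windows the scan only bounds the probability that a
#' window of this size lacks enough conserved sites: the bound is
#' `1 / n_windows` (flagged `"bound"`). With failures the point estimate
#' `n_failing / n_windows` is returned (flagged `"estimate"`).
#'
#' @param scan a `window_scan_result` (or `n_windows` with `n_failing`).
#' @param n_failing used when `scan` is a bare window count.
#' @return Numeric probability with attribute `type` = "bound"/"estimate".
#' @examples
#' miss_probability(11483, 0)   # < 8.7e-5
#' @export
miss_probability <- function(scan, n_failing = NULL) {
  if (inherits(scan, "window_scan_result")) {
    nw <- scan$n_windows; nf <- scan$n_failing
  } else {
    nw <- scan; nf <- n_failing
    if (is.null(nf)) stop("n_failing required with a bare window count")
  }
  if (nw <= 0) stop("n_windows must be > 0")
  if (nf == 0) structure(1 / nw, type = "bound")
  else structure(nf / nw, type = "estimate")
}

#' Full k-mer length calibration report
#'
#' Combines the SNP-spacing rate, the clustering fraction, the window scan
#' and the miss-probability bound for a candidate k.
#'
#' @param tracks a [snp_track()] or list of them.
#' @param total_nonrep_bp non-repetitive bases surveyed; defaults to the
#'   summed track lengths minus masked positions.
#' @param d clustering distance for the within-d fraction.
#' @inheritParams window_scan
#' @return A `calibration_report`.
#' @export
calibration_report <- function(tracks, total_nonrep_bp = NULL, d = 16L,
                               window = 500L, step = 250L, k = 16L,
                               min_sites = 20L, both_strands = FALSE) {
  if (inherits(tracks, "snp_track")) tracks <- list(tracks)
  n_snps <- sum(vapply(tracks, function(t) length(t$snp_positions), 1L))
  if (is.null(total_nonrep_bp))
    total_nonrep_bp <- sum(vapply(tracks, function(t)
      t$length - length(t$mask), 1L))
  wins <- window_scan(tracks, window, step, k, min_sites, both_strands)
  fr <- {
    per <- vapply(tracks, function(t) {
      if (length(t$snp_positions) < 2L) return(NA_real_)
      fraction_snps_within(t$snp_positions, d)
    }, 1.0)
    w <- vapply(tracks, function(t) length(t$snp_positions), 1L)
    if (all(is.na(per))) NA_real_ else
      sum(per * w, na.rm = TRUE) / sum(w[!is.na(per)])
  }
  structure(list(total_nonrep_bp = total_nonrep_bp, n_snps = n_snps,
                 bp_per_snp = snp_spacing(total_nonrep_bp, n_snps),
                 frac_within_d = fr, d = d, windows = wins,
                 miss_probability_bound = miss_probability(wins)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  mp <- x$miss_probability_bound
  cat(sprintf("<calibration_report> %s bp / %s SNPs = %.1f bp per SNP\n",
              format(x$total_nonrep_bp, big.mark = ","),
              format(x$n_snps, big.mark = ","), x$bp_per_snp))
  cat(sprintf("  %.0f%% of SNPs within %d bp of another\n",
              100 * x$frac_within_d, x$d))
  cat(sprintf("  %d/%d windows failing; miss probability %s %.2g\n",
              x$windows$n_failing, x$windows$n_windows,
              if (attr(mp, "type") == "bound") "<" else "=", mp))
  invisible(x)
}
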