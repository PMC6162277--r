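#' Short-read simulation specification
#'
#' Coverage is the expected per-base depth of the *sample*. For a diploid
#' `sample_genome` a diploid locus is covered `coverage` times in total, so
#' each haplotype is sampled at `coverage / 2` and a hemizygous region sits
#' at half the autosomal depth; a bare vector of sequences is treated as
#' haploid and each sequence is sampled at the full `coverage`.
#' Substitution errors are i.i.d. per base; qualities are a fixed Phred+33
#' 'I' (Q40), since no downstream stage is quality-aware.
#'
#' @param read_length read length in bp.
#' @param coverage expected per-base sample depth (fold, > 0).
#' @param error_rate per-base substitution probability, in [0, 0.1).
#' @param paired simulate read pairs from fragments of `insert_size` bp
#'   (the second mate is the reverse complement of the fragment end).
#' @param insert_size fragment length for paired mode (default 400 bp,
#'   a typical short-insert library).
#' @param seed integer seed.
#' @return A `read_sim_spec`.
#' @export
read_sim_spec <- function(read_length = 100L, coverage = 30,
                          error_rate = 0.005, paired = FALSE,
                          insert_size = 400L, seed = 1L) {
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("read_length must be >= 1")
  if (coverage <= 0) stop("coverage must be > 0")
  if (error_rate < 0 || error_rate >= 0.1)
    stop("error_rate must be in [0, 0.1)")
  if (paired && insert_size < 2L * read_length)
    stop("insert_size must be >= 2 * read_length")
  structure(list(read_length = read_length, coverage = coverage,
                 error_rate = error_rate, paired = paired,
                 insert_size = as.integer(insert_size),
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

## Draw n substrings of width w starting at 0-based positions `starts` from
## integer-coded haplotype hap, apply i.i.d. substitution errors, return a
## list of integer matrices (reads in rows).
.slice_reads <- function(hap, starts, w, error_rate, revcomp = FALSE) {
  n <- length(starts)
  idx <- outer(starts, seq_len(w) - 1L, `+`) + 1L
  m <- matrix(hap[idx], nrow = n)
  if (revcomp) m <- 3L - m[, rev(seq_len(w)), drop = FALSE]
  if (error_rate > 0 && n > 0L) {
    err <- which(runif(n * w) < error_rate)
    if (length(err) > 0L)
      m[err] <- (m[err] + sample.int(3L, length(err), replace = TRUE)) %% 4L
  }
  m
}

.mat2strings <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) .BASES[m[, j] + 1L]))
}

#' Simulate error-bearing short reads from a diploid sample genome
#'
#' Reads start uniformly along each haplotype; the number of reads per
#' haplotype is set so the expected per-base sample depth equals
#' `spec$coverage` (each haplotype of a diploid `sample_genome` at half;
#' bare sequences at full coverage). Because fixed-length reads start
#' uniformly inside the sequence, the terminal `read_length - 1` bases of
#' each haplotype are progressively under-covered (as on a real linear
#' chromosome); regions of interest should sit in the interior.
#' Deterministic given `spec$seed`; the same seed yields byte-identical
#' FASTQ.
#'
#' @param sample a `sample_genome` from [simulate_genus()], or a named
#'   character vector of haplotype sequences.
#' @param spec a [read_sim_spec()].
#' @return A `fastq_records` data frame (`id`, `seq`, `qual`); in paired
#'   mode mates alternate `/1`, `/2` and are also available split via
#'   attributes `mate1`/`mate2` row indices.
#' @export
simulate_reads <- function(sample, spec = read_sim_spec()) {
  stopifnot(inherits(spec, "read_sim_spec"))
  diploid <- inherits(sample, "sample_genome")
  haps <- if (diploid) sample$haplotypes else as.list(sample)
  per_copy_cov <- if (diploid) spec$coverage / 2 else spec$coverage
  label <- if (diploid)
    paste0(sample$species, "_", substr(sample$sex, 1, 1)) else "sample"
  rl <- spec$read_length
  if (any(nchar(unlist(haps)) < rl))
    stop("read_length exceeds a haplotype length")
  if (spec$paired && any(nchar(unlist(haps)) < spec$insert_size))
    stop("insert_size exceeds a haplotype length")
  withr::with_seed(spec$seed, {
    per_hap <- lapply(seq_along(haps), function(i) {
      s <- haps[[i]]
      L <- nchar(s)
      hap <- match(strsplit(s, "", fixed = TRUE)[[1]], .BASES) - 1L
      bases_per_unit <- if (spec$paired) 2L * rl else rl
      n <- max(0L, as.integer(round(L * per_copy_cov / bases_per_unit)))
      if (n == 0L) return(NULL)
      if (spec$paired) {
        fs <- sample.int(L - spec$insert_size + 1L, n, replace = TRUE) - 1L
        m1 <- .slice_reads(hap, fs, rl, spec$error_rate)
        m2 <- .slice_reads(hap, fs + spec$insert_size - rl, rl,
                           spec$error_rate, revcomp = TRUE)
        id <- sprintf("%s_h%d_%d", label, i, seq_len(n))
        list(id = c(rbind(paste0(id, "/1"), paste0(id, "/2"))),
             seq = c(rbind(.mat2strings(m1), .mat2strings(m2))))
      } else {
        st <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
        m1 <- .slice_reads(hap, st, rl, spec$error_rate)
        list(id = sprintf("%s_h%d_%d", label, i, seq_len(n)),
             seq = .mat2strings(m1))
      }
    })
    per_hap <- per_hap[!vapply(per_hap, is.null, TRUE)]
    id <- unlist(lapply(per_hap, `[[`, "id"), use.names = FALSE)
    sq <- unlist(lapply(per_hap, `[[`, "seq"), use.names = FALSE)
    out <- data.frame(id = id, seq = sq,
                      qual = strrep("I", rl))
    class(out) <- c("fastq_records", "data.frame")
    if (spec$paired) {
      attr(out, "mate1") <- seq(1L, nrow(out), by = 2L)
      attr(out, "mate2") <- seq(2L, nrow(out), by = 2L)
    }
    out
  })
}
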