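# Independent brute-force oracles. These deliberately share no code path
# with the package: plain string handling, Biostrings for translation, and
# naive enumeration throughout.

or_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# naive canonical k-mer counting over a character vector of sequences
or_count_kmers <- function(seqs, k) {
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, 1:(n - k + 1), k:n)
    w[!grepl("[^ACGT]", w)]
  }))
  canon <- vapply(words, function(w) min(w, or_revcomp(w)), "",
                  USE.NAMES = FALSE)
  table(canon)
}

# naive exact-occurrence scan of query words (and their reverse
# complements) against one contig; returns 0-based positions
or_match_positions <- function(words, contig) {
  k <- nchar(words[1])
  n <- nchar(contig)
  if (n < k) return(integer(0))
  win <- substring(contig, 1:(n - k + 1), k:n)
  targets <- unique(c(words, vapply(words, or_revcomp, "")))
  which(win %in% targets) - 1L
}

# per-substitution enumeration of NG86 synonymous sites for one codon,
# using Biostrings' genetic code (stop-excluded denominators)
or_codon_S <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  stopifnot(aa != "*")
  s_tot <- 0
  for (p in 1:3) {
    syn <- 0; nonstop <- 0
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (gc[[mut]] == "*") next
      nonstop <- nonstop + 1
      if (gc[[mut]] == aa) syn <- syn + 1
    }
    s_tot <- s_tot + if (nonstop > 0) syn / nonstop else 0
  }
  s_tot
}

or_site_counts <- function(seq) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  S <- sum(vapply(codons, or_codon_S, 1.0))
  c(S = S, N = n - S)
}

# recursive pathway enumeration of (sd, nd) between two codons
or_pairwise_diff <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(diffpos) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, through_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(sd = sd, nd = nd, ok = !through_stop)
      return()
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      syn <- gc[[cur]] == gc[[nxt]]
      recurse(nxt, setdiff(remaining, p), sd + as.numeric(syn),
              nd + as.numeric(!syn), through_stop || gc[[nxt]] == "*")
    }
  }
  recurse(a, diffpos, 0, 0, FALSE)
  ok <- vapply(paths, `[[`, TRUE, "ok")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, 1.0, "sd")),
    nd = mean(vapply(use, `[[`, 1.0, "nd")))
}

# independent NG86: pS/pN from the oracles above, own JC correction
or_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  sa <- or_site_counts(seq_a); sb <- or_site_counts(seq_b)
  d <- rowSums(vapply(seq_along(ca), function(i)
    or_pairwise_diff(ca[i], cb[i]), c(sd = 0, nd = 0)))
  pS <- d[["sd"]] / mean(c(sa[["S"]], sb[["S"]]))
  pN <- d[["nd"]] / mean(c(sa[["N"]], sb[["N"]]))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  c(dS = jc(pS), dN = jc(pN))
}

# random stop-free in-frame sequence
or_random_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# naive window scan: per window, per candidate site, scan for SNPs/mask
or_window_scan_fail <- function(positions, len, window, step, k, min_sites) {
  bad <- logical(len)
  bad[positions + 1] <- TRUE
  starts <- seq(0, len - window, by = step)
  fails <- 0L
  sites_per <- integer(length(starts))
  for (wi in seq_along(starts)) {
    w0 <- starts[wi]
    sites <- 0L
    for (p in w0:(w0 + window - k)) {
      if (!any(bad[(p + 1):(p + k)])) sites <- sites + 1L
    }
    sites_per[wi] <- sites
    if (sites < min_sites) fails <- fails + 1L
  }
  list(n_windows = length(starts), n_failing = fails, sites = sites_per)
}
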