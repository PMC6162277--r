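## Nei-Gojobori synonymous/nonsynonymous rate estimation with Jukes-Cantor
## correction, per-gene summaries against an outgroup, and relative
## clade-depth statistics on ultrametric trees.
##
## Stop handling follows the SNAP-style convention: substitutions creating
## a stop codon are excluded from the site denominators and pathways
## passing through a stop are excluded from the difference average (falling
## back to all pathways only when every pathway is excluded). Under this
## convention every codon position keeps site weight 1, so S + N = 3 x
## number of codons exactly.

## Standard genetic code, rows/columns in T, C, A, G order.
.GC_TCAG <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.molevol_env <- new.env(parent = emptyenv())

## 64-codon machinery indexed by code = 16*b1 + 4*b2 + b3 + 1 over
## A=0, C=1, G=2, T=3.
.codon_tables <- function() {
  if (!is.null(.molevol_env$AA64)) return(.molevol_env)
  tcag <- c("T", "C", "A", "G")
  codons_tcag <- paste0(rep(tcag, each = 16),
                        rep(rep(tcag, each = 4), times = 4),
                        rep(tcag, times = 16))
  aa_by_codon <- setNames(strsplit(.GC_TCAG, "")[[1]], codons_tcag)
  acgt <- c("A", "C", "G", "T")
  codons_acgt <- paste0(rep(acgt, each = 16),
                        rep(rep(acgt, each = 4), times = 4),
                        rep(acgt, times = 16))
  AA64 <- unname(aa_by_codon[codons_acgt])
  ## fractional synonymous sites per codon (NA for stops)
  S64 <- rep(NA_real_, 64)
  for (ci in 1:64) {
    if (AA64[ci] == "*") next
    b <- c((ci - 1) %/% 16, ((ci - 1) %/% 4) %% 4, (ci - 1) %% 4)
    s_tot <- 0
    for (p in 1:3) {
      syn <- 0L; nonstop <- 0L
      for (nb in setdiff(0:3, b[p])) {
        b2 <- b; b2[p] <- nb
        aa <- AA64[16 * b2[1] + 4 * b2[2] + b2[3] + 1]
        if (aa == "*") next
        nonstop <- nonstop + 1L
        if (aa == AA64[ci]) syn <- syn + 1L
      }
      s_tot <- s_tot + if (nonstop > 0L) syn / nonstop else 0
    }
    S64[ci] <- s_tot
  }
  .molevol_env$AA64 <- AA64
  .molevol_env$S64 <- S64
  .molevol_env$CODONS <- codons_acgt
  .molevol_env
}

## codon strings -> codes 1..64 (NA for non-ACGT)
.codon_codes <- function(codons) {
  b <- matrix(match(unlist(strsplit(codons, "", fixed = TRUE)),
                    c("A", "C", "G", "T")) - 1L,
              nrow = 3)
  16L * b[1, ] + 4L * b[2, ] + b[3, ] + 1L
}

.split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' In-frame codon alignment
#'
#' Validates equal lengths and frame, drops every codon column containing
#' a gap or ambiguity character in any sequence (SNAP-style handling is
#' version-dependent, so the rule here is fixed and documented), and
#' rejects alignments with internal stop codons after dropping.
#'
#' @param sequences named character vector (or list) of aligned, in-frame
#'   nucleotide sequences; a trailing stop codon shared by all sequences
#'   is removed.
#' @return A `codon_alignment` with `codons` (matrix sequences x columns of
#'   3-letter strings) and `dropped_columns` (1-based codon column
#'   indices).
#' @export
codon_alignment <- function(sequences) {
  nms <- names(sequences)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("sequences must be named")
  sequences <- setNames(vapply(sequences, toupper, "", USE.NAMES = FALSE),
                        nms)
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences differ in aligned length")
  if (lens %% 3 != 0) stop("aligned length is not a multiple of 3")
  tb <- .codon_tables()
  cod <- t(vapply(sequences, .split_codons,
                  character(lens / 3)))
  if (lens / 3 == 1L) cod <- matrix(cod, nrow = length(sequences),
                                    dimnames = list(names(sequences), NULL))
  clean <- !grepl("[^ACGT]", cod)
  keep <- apply(matrix(clean, nrow = length(sequences)), 2, all)
  dropped <- which(!keep)
  cod <- cod[, keep, drop = FALSE]
  ## drop a shared terminal stop, then refuse internal stops
  if (ncol(cod) > 0L) {
    codes_last <- .codon_codes(cod[, ncol(cod)])
    if (all(tb$AA64[codes_last] == "*")) cod <- cod[, -ncol(cod), drop = FALSE]
  }
  if (ncol(cod) > 0L) {
    codes <- matrix(.codon_codes(as.vector(cod)), nrow = nrow(cod))
    if (any(tb$AA64[codes] == "*")) {
      bad <- which(matrix(tb$AA64[codes] == "*", nrow = nrow(cod)),
                   arr.ind = TRUE)
      stop("internal stop codon in ", rownames(cod)[bad[1, 1]],
           " at codon column ", bad[1, 2])
    }
  }
  structure(list(codons = cod, n_codons = ncol(cod),
                 dropped_columns = dropped),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d sequences x %d codons (%d column(s) dropped)\n",
              nrow(x$codons), x$n_codons, length(x$dropped_columns)))
  invisible(x)
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Each codon position contributes `n_syn / n_nonstop` synonymous sites,
#' where the three possible point substitutions at the position are
#' classified against the genetic code and substitutions creating stop
#' codons are excluded from the denominator; `S` sums these over the
#' sequence and `N = 3 * n_codons - S`.
#'
#' @param sequence in-frame nucleotide string, a character vector of
#'   codons, or one row of a [codon_alignment()].
#' @return List with `S`, `N`, and `n_codons`.
#' @examples
#' codon_sites("ATG")  # Met: S = 0, N = 3
#' codon_sites("GAT")  # Asp: S = 1/3
#' @export
codon_sites <- function(sequence) {
  tb <- .codon_tables()
  codons <- if (length(sequence) == 1L && nchar(sequence[1]) > 3L)
    .split_codons(sequence) else toupper(sequence)
  if (any(grepl("[^ACGT]", codons)))
    stop("non-ACGT base: ambiguous columns must be dropped upstream")
  codes <- .codon_codes(codons)
  if (any(tb$AA64[codes] == "*"))
    stop("internal stop codon")
  S <- sum(tb$S64[codes])
  list(S = S, N = 3 * length(codes) - S, n_codons = length(codes))
}

.PERMS <- list(matrix(1L, 1, 1),
               matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE),
               matrix(c(1L,2L,3L, 1L,3L,2L, 2L,1L,3L, 2L,3L,1L,
                        3L,1L,2L, 3L,2L,1L), 6, 3, byrow = TRUE))

#' Pathway-averaged synonymous/nonsynonymous differences between codons
#'
#' Classifies the differences between two codons along every minimal
#' substitution pathway (1, 2 or 6 orderings), averaging uniformly over
#' pathways. Pathways passing through a stop codon are excluded; when
#' every pathway is excluded the average falls back to all pathways (steps
#' to or from a stop counting as nonsynonymous).
#'
#' @param codon_a,codon_b 3-letter codon strings (stop-free).
#' @return Numeric `c(sd, nd)`; `sd + nd` equals the number of differing
#'   positions.
#' @examples
#' pairwise_differences("GAT", "GAC")  # one synonymous difference
#' @export
pairwise_differences <- function(codon_a, codon_b) {
  tb <- .codon_tables()
  a <- .codon_codes(toupper(codon_a)); b <- .codon_codes(toupper(codon_b))
  if (is.na(a) || is.na(b)) stop("non-ACGT base in codon")
  if (tb$AA64[a] == "*" || tb$AA64[b] == "*") stop("stop codon input")
  ba <- c((a - 1) %/% 16, ((a - 1) %/% 4) %% 4, (a - 1) %% 4)
  bb <- c((b - 1) %/% 16, ((b - 1) %/% 4) %% 4, (b - 1) %% 4)
  diffpos <- which(ba != bb)
  nd_pos <- length(diffpos)
  if (nd_pos == 0L) return(c(sd = 0, nd = 0))
  perms <- .PERMS[[nd_pos]]
  path_sd <- path_nd <- numeric(nrow(perms))
  path_ok <- logical(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    cur <- ba
    sdi <- ndi <- 0
    ok <- TRUE
    for (step in diffpos[perms[i, ]]) {
      nxt <- cur; nxt[step] <- bb[step]
      aa_cur <- tb$AA64[16 * cur[1] + 4 * cur[2] + cur[3] + 1]
      aa_nxt <- tb$AA64[16 * nxt[1] + 4 * nxt[2] + nxt[3] + 1]
      if (aa_nxt == "*") ok <- FALSE
      if (aa_cur == aa_nxt) sdi <- sdi + 1 else ndi <- ndi + 1
      cur <- nxt
    }
    path_sd[i] <- sdi; path_nd[i] <- ndi; path_ok[i] <- ok
  }
  use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
  c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) pairwise substitution rates
#'
#' Sums pathway-averaged synonymous/nonsynonymous differences over codons,
#' divides by pair-averaged site counts (`pS = sum(sd) / mean(S)`), and
#' applies the Jukes-Cantor correction `d = -3/4 ln(1 - 4p/3)`. A
#' proportion at or beyond the correction's domain (p >= 3/4) is flagged
#' saturated and the corresponding rate is NA — never silently clipped.
#'
#' @param alignment a [codon_alignment()] (or named sequences coercible to
#'   one).
#' @param pair character vector of two sequence labels.
#' @return A `pairwise_rates` object: `S_bar`, `N_bar`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`, `omega` (`dN/dS`, defined only when `dS > 0`), and
#'   saturation flags.
#' @export
ng86 <- function(alignment, pair) {
  if (!inherits(alignment, "codon_alignment"))
    alignment <- codon_alignment(alignment)
  if (length(pair) != 2L || !all(pair %in% rownames(alignment$codons)))
    stop("pair must name two sequences present in the alignment")
  ca <- alignment$codons[pair[1], ]
  cb <- alignment$codons[pair[2], ]
  sa <- codon_sites(ca); sb <- codon_sites(cb)
  S_bar <- (sa$S + sb$S) / 2
  N_bar <- (sa$N + sb$N) / 2
  Sd <- Nd <- 0
  for (i in which(ca != cb)) {
    d <- pairwise_differences(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S_bar > 0) Sd / S_bar else NA_real_
  pN <- if (N_bar > 0) Nd / N_bar else NA_real_
  dS <- .jc_correct(pS)
  dN <- .jc_correct(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(pair = pair, n_codons = length(ca),
                 S_bar = S_bar, N_bar = N_bar, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                 saturated_S = !is.na(pS) && pS >= 0.75,
                 saturated_N = !is.na(pN) && pN >= 0.75),
            class = "pairwise_rates")
}

#' @export
print.pairwise_rates <- function(x, ...) {
  cat(sprintf("<pairwise_rates> %s vs %s (%d codons)\n", x$pair[1], x$pair[2],
              x$n_codons))
  cat(sprintf("  pS = %.4f, pN = %.4f; dS = %.4f, dN = %.4f; omega = %.4f\n",
              x$pS, x$pN, x$dS, x$dN, x$omega))
  if (x$saturated_S || x$saturated_N)
    cat("  WARNING: saturated (p >= 3/4); corrected rate undefined\n")
  invisible(x)
}

#' Per-gene substitution-rate summary against an outgroup
#'
#' Computes NG86 rates of every species sequence against the designated
#' outgroup and summarizes dS, dN and omega with the mean and sample
#' (n - 1) standard deviation; omega is summarized over species with
#' defined dS > 0.
#'
#' @param alignment a [codon_alignment()] containing the outgroup.
#' @param outgroup_label outgroup sequence name.
#' @param species_labels species to summarize (default: all but the
#'   outgroup).
#' @param gene gene label carried onto the result.
#' @return A `gene_rate_summary` with the per-species rate table and the
#'   mean/SD summaries.
#' @export
gene_summary <- function(alignment, outgroup_label, species_labels = NULL,
                         gene = "gene") {
  if (!inherits(alignment, "codon_alignment"))
    alignment <- codon_alignment(alignment)
  labs <- rownames(alignment$codons)
  if (!outgroup_label %in% labs) stop("outgroup not present in alignment")
  if (is.null(species_labels)) species_labels <- setdiff(labs, outgroup_label)
  rates <- lapply(species_labels, function(sp)
    ng86(alignment, c(sp, outgroup_label)))
  tab <- data.frame(species = species_labels,
                    dS = vapply(rates, `[[`, 1.0, "dS"),
                    dN = vapply(rates, `[[`, 1.0, "dN"),
                    omega = vapply(rates, `[[`, 1.0, "omega"))
  if (all(is.na(tab$dS))) stop("all pairs saturated: no usable rates")
  okw <- !is.na(tab$omega)
  summ <- data.frame(
    stat = c("dS", "dN", "omega"),
    mean = c(mean(tab$dS, na.rm = TRUE), mean(tab$dN, na.rm = TRUE),
             if (any(okw)) mean(tab$omega[okw]) else NA_real_),
    sd = c(sd(tab$dS, na.rm = TRUE), sd(tab$dN, na.rm = TRUE),
           if (sum(okw) > 1L) sd(tab$omega[okw]) else NA_real_))
  structure(list(gene = gene, outgroup = outgroup_label, rates = tab,
                 summary = summ),
            class = "gene_rate_summary")
}

#' @export
print.gene_rate_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gene_rate_summary> %s vs outgroup %s (%d species)\n",
              x$gene, x$outgroup, nrow(x$rates)))
  cat(sprintf("  mean dS = %.3f (SD %.3f), mean dN = %.3f (SD %.3f), mean omega = %.3f\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2], s$mean[3]))
  invisible(x)
}

#' Relative depth of a clade in an ultrametric tree
#'
#' Age of the clade's most recent common ancestor as a proportion of the
#' root's age — the "time of origin as a fraction of time back to common
#' ancestry" statistic.
#'
#' @param tree rooted ultrametric `ape::phylo` with branch lengths.
#' @param clade_leaves tip labels of the (monophyletic) clade.
#' @param eps relative tolerance on ultrametricity (leaf-depth spread as a
#'   fraction of tree height).
#' @return Fraction between 0 and 1.
#' @export
relative_clade_depth <- function(tree, clade_leaves, eps = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  H <- max(depths[seq_len(ntip)])
  if (H <= 0) stop("tree has zero height")
  if (diff(range(depths[seq_len(ntip)])) > eps * H)
    stop("tree is not ultrametric within tolerance")
  if (!all(clade_leaves %in% tree$tip.label))
    stop("clade leaves not all present in tree")
  if (length(clade_leaves) == length(tree$tip.label)) return(1)
  if (length(clade_leaves) < 2L)
    stop("clade must contain >= 2 leaves (or all leaves)")
  if (!ape::is.monophyletic(tree, clade_leaves))
    stop("clade leaves are not monophyletic")
  mrca <- ape::getMRCA(tree, clade_leaves)
  (H - depths[mrca]) / H
}

#' Simulate codon sequences diverging from a common ancestor
#'
#' Evolves a stop-free ancestral codon sequence to an outgroup and to
#' `n_species` species copies on a star phylogeny by sequential point
#' substitution: proposals are uniform over sites and alternative bases;
#' synonymous proposals are always accepted, nonsynonymous proposals with
#' probability `omega`, and proposals creating stops never — the
#' generating process whose acceptance ratio NG86 estimates as dN/dS.
#'
#' @param n_species number of species copies.
#' @param n_codons sequence length in codons.
#' @param omega nonsynonymous acceptance probability (target dN/dS).
#' @param mu expected substitution proposals per nucleotide site per
#'   branch (each branch runs ancestor -> tip).
#' @param seed integer seed.
#' @param outgroup_label name for the outgroup sequence.
#' @return A [codon_alignment()] of `n_species + 1` sequences.
#' @export
simulate_codon_alignment <- function(n_species = 10L, n_codons = 500L,
                                     omega = 0.2, mu = 0.15, seed = 1L,
                                     outgroup_label = "outgroup") {
  tb <- .codon_tables()
  withr::with_seed(seed, {
    sense <- which(tb$AA64 != "*")
    anc_codes <- sample(sense, n_codons, replace = TRUE)
    anc <- unlist(strsplit(tb$CODONS[anc_codes], "", fixed = TRUE))
    anc_int <- match(anc, c("A", "C", "G", "T")) - 1L
    evolve <- function(v) {
      n <- length(v)
      n_prop <- rpois(1L, mu * n)
      for (e in seq_len(n_prop)) {
        pos <- sample.int(n, 1L)
        alt <- (v[pos] + sample.int(3L, 1L)) %% 4L
        ci <- (pos - 1L) %/% 3L
        idx <- ci * 3L + 1:3
        cur <- v[idx]; nxt <- cur; nxt[(pos - 1L) %% 3L + 1L] <- alt
        aa_cur <- tb$AA64[16 * cur[1] + 4 * cur[2] + cur[3] + 1]
        aa_nxt <- tb$AA64[16 * nxt[1] + 4 * nxt[2] + nxt[3] + 1]
        if (aa_nxt == "*") next
        if (aa_nxt != aa_cur && runif(1) > omega) next
        v[pos] <- alt
      }
      v
    }
    seqs <- c(setNames(list(evolve(anc_int)), outgroup_label),
              setNames(lapply(seq_len(n_species), function(i)
                evolve(anc_int)), paste0("sp", seq_len(n_species))))
    codon_alignment(vapply(seqs, function(v)
      paste(c("A", "C", "G", "T")[v + 1L], collapse = ""), ""))
  })
}
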