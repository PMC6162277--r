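## Synthetic dioecious genus: genomes, reads and ground truth.
##
## Sequences are held internally as integer vectors over 0:3 (A,C,G,T) and
## converted to strings only at the boundary; substitution is site-wise
## uniform per branch (Jukes-Cantor-like, no indels outside planted blocks).

.BASES <- c("A", "C", "G", "T")

.int2seq <- function(v) paste(.BASES[v + 1L], collapse = "")

.random_seq <- function(n) sample.int(4L, n, replace = TRUE) - 1L

## Site-wise substitution: each site mutates with probability p to one of
## the three other bases, uniformly. With cluster_frac > 0 that fraction of
## the substitutions is placed within cluster_d bp of an already placed one
## (SNP clustering knob); the rest are uniform.
## Clustered placement works in pairs: a `cluster_frac` share of the
## substitutions is laid down as anchor+companion pairs at most cluster_d
## apart, so the fraction of substitutions with a neighbour within
## cluster_d approximates the knob itself.
.cluster_positions <- function(n_sites, m, cluster_frac, cluster_d) {
  n_pair <- round(cluster_frac * m / 2)
  n_seed <- m - n_pair
  seeds <- sample.int(n_sites, n_seed, replace = FALSE)
  if (n_pair == 0L) return(seeds)
  anchor <- sample(seeds, min(n_pair, length(seeds)), replace = FALSE)
  off <- sample(c(-(1:cluster_d), 1:cluster_d), length(anchor),
                replace = TRUE)
  unique(c(seeds, pmin(pmax(anchor + off, 1L), n_sites)))
}

.mutate_seq <- function(v, p, cluster_frac = 0, cluster_d = 16L) {
  n <- length(v)
  if (p <= 0 || n == 0L) return(v)
  m <- rbinom(1L, n, p)
  if (m == 0L) return(v)
  pos <- if (cluster_frac > 0 && m >= 2L)
    .cluster_positions(n, m, cluster_frac, cluster_d)
  else sample.int(n, m, replace = FALSE)
  v[pos] <- (v[pos] + sample.int(3L, length(pos), replace = TRUE)) %% 4L
  v
}

#' Rescale a tree so male-male divergence hits a target SNP rate
#'
#' Branch lengths are taken as per-site substitution probabilities. Under
#' the site-wise uniform substitution model the probability that two tips
#' differ at a site is `3/4 * (1 - prod(1 - 4 b_i / 3))` over the branches
#' `b_i` on the path, times the same factor for each individual's private
#' heterozygosity layer. The tree is scaled so the mean of this probability
#' over all tip pairs equals `rate`.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param rate target expected pairwise per-bp difference rate between male
#'   individuals (default 1/16.5).
#' @param het_rate per-haplotype within-species substitution probability
#'   added on top of the tree (two layers separate any two individuals).
#' @return The tree with rescaled branch lengths.
#' @export
calibrate_tree_to_snp_rate <- function(tree, rate = 1 / 16.5, het_rate = 0) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (rate <= 0 || rate > 0.25)
    stop("rate must be in (0, 0.25]")
  qh <- (1 - 4 * het_rate / 3)^2
  if (3 / 4 * (1 - qh) >= rate)
    stop("het_rate alone already exceeds the target SNP rate")
  mean_diff <- function(s) {
    t2 <- tree
    t2$edge.length <- -log(pmax(1 - 4 * s * tree$edge.length / 3, 1e-12))
    d <- ape::cophenetic.phylo(t2)
    mean(3 / 4 * (1 - exp(-d[lower.tri(d)]) * qh))
  }
  s_max <- 0.75 / max(tree$edge.length) * 0.999
  f <- function(s) mean_diff(s) - rate
  if (f(s_max) < 0)
    stop("target SNP rate unreachable with this topology")
  s <- uniroot(f, c(1e-9, s_max), tol = 1e-12)$root
  tree$edge.length <- tree$edge.length * s
  tree
}

#' Specification of a synthetic dioecious genus
#'
#' Describes the stated world the simulator generates: n species diverged on
#' a rooted tree, each with a diploid autosome, an X/Y-shared region, a set
#' of Y-specific blocks carried hemizygously by every male and absent from
#' every female, optional blocks deleted from the X only, an optional exact
#' tandem repeat filling part of the autosome, and a target inter-male SNP
#' spacing (default one per 16.5 bp).
#'
#' @param n_species number of species (>= 2).
#' @param species_tree rooted `ape::phylo` with branch lengths and
#'   `n_species` tips; a unit-branch ladder tree is built when NULL.
#' @param autosome_length,xy_shared_length lengths in bp (> 0).
#' @param y_specific_blocks named list/vector of block lengths planted on
#'   the Y only (hemizygous in males, absent in females).
#' @param x_deletion_blocks named list/vector of lengths deleted from the X
#'   copy of the X/Y region only (so retained on the Y).
#' @param repeat_fraction proportion of the autosome filled with one exact
#'   tandem motif, in [0, 1).
#' @param snp_rate_target expected pairwise inter-male SNPs per bp; the
#'   tree is rescaled to hit it (default 1/16.5).
#' @param het_rate within-species per-haplotype polymorphism rate.
#' @param snp_cluster_frac fraction of substitutions placed within 16 bp of
#'   another (clustering overdispersion knob; default off).
#' @param include_hermaphrodite add an outgroup hermaphrodite control
#'   carrying two copies of the Y-specific blocks (for the 2N contrast).
#' @param seed integer seed making the genus reproducible.
#' @return A `genus_model`.
#' @export
genus_model <- function(n_species = 6L, species_tree = NULL,
                        autosome_length = 200000L, xy_shared_length = 10000L,
                        y_specific_blocks = c(Yblock = 5000L),
                        x_deletion_blocks = NULL,
                        repeat_fraction = 0,
                        snp_rate_target = 1 / 16.5,
                        het_rate = 1e-3,
                        snp_cluster_frac = 0,
                        include_hermaphrodite = TRUE,
                        seed = 1L) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("need n_species >= 2")
  if (autosome_length <= 0 || xy_shared_length <= 0)
    stop("all lengths must be > 0")
  if (snp_rate_target <= 0 || snp_rate_target > 0.25)
    stop("snp_rate_target must be in (0, 0.25]")
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)")
  y_specific_blocks <- unlist(y_specific_blocks)
  x_deletion_blocks <- unlist(x_deletion_blocks)
  if (length(y_specific_blocks) > 0 && is.null(names(y_specific_blocks)))
    names(y_specific_blocks) <- paste0("Y", seq_along(y_specific_blocks))
  if (length(x_deletion_blocks) > 0 && is.null(names(x_deletion_blocks)))
    names(x_deletion_blocks) <- paste0("XDEL", seq_along(x_deletion_blocks))
  if (any(y_specific_blocks <= 0) || any(x_deletion_blocks <= 0))
    stop("all block lengths must be > 0")
  if (sum(x_deletion_blocks) > xy_shared_length)
    stop("x_deletion_blocks longer than the X/Y region")
  if (is.null(species_tree)) {
    species_tree <- if (n_species == 2L)
      ape::read.tree(text = "(sp1:1,sp2:1);")
    else ape::stree(n_species, type = "left")
    species_tree$edge.length <- rep(1, nrow(species_tree$edge))
    species_tree$tip.label <- paste0("sp", seq_len(n_species))
  }
  if (length(species_tree$tip.label) != n_species)
    stop("tree has ", length(species_tree$tip.label), " leaves, expected ",
         n_species)
  if (any(species_tree$edge.length > 0))
    species_tree <- calibrate_tree_to_snp_rate(species_tree, snp_rate_target,
                                               het_rate)
  structure(list(n_species = n_species, species_tree = species_tree,
                 autosome_length = as.integer(autosome_length),
                 xy_shared_length = as.integer(xy_shared_length),
                 y_specific_blocks = y_specific_blocks,
                 x_deletion_blocks = x_deletion_blocks,
                 repeat_fraction = repeat_fraction,
                 snp_rate_target = snp_rate_target,
                 het_rate = het_rate,
                 snp_cluster_frac = snp_cluster_frac,
                 include_hermaphrodite = include_hermaphrodite,
                 seed = as.integer(seed)),
            class = "genus_model")
}

#' @export
print.genus_model <- function(x, ...) {
  cat(sprintf(paste0("<genus_model> %d species; autosome %s bp; X/Y %s bp; ",
                     "%d Y block(s) (%s bp); SNP rate target 1/%.1f bp\n"),
              x$n_species, format(x$autosome_length, big.mark = ","),
              format(x$xy_shared_length, big.mark = ","),
              length(x$y_specific_blocks),
              format(sum(x$y_specific_blocks), big.mark = ","),
              1 / x$snp_rate_target))
  invisible(x)
}

## Evolve a list of ancestral integer sequences down an ape tree; returns a
## list tip.label -> list of sequences.
.evolve_on_tree <- function(tree, anc, cluster_frac = 0) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  res <- vector("list", nt)
  names(res) <- tree$tip.label
  walk <- function(node, seqs) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 0L) { res[[tree$tip.label[node]]] <<- seqs; return() }
    for (child in kids) {
      b <- tree$edge.length[which(tree$edge[, 1] == node &
                                    tree$edge[, 2] == child)]
      mutated <- lapply(seqs, .mutate_seq, p = b, cluster_frac = cluster_frac)
      walk(child, mutated)
    }
  }
  walk(root, anc)
  res
}

#' Simulate a synthetic dioecious genus
#'
#' Generates one male and one female diploid genome per species (plus an
#' optional hermaphrodite outgroup control), diverged along the model's
#' species tree by site-wise substitution, with the model's Y-specific
#' blocks planted hemizygously on the Y, the X-deletion blocks removed from
#' the X only, and per-individual heterozygosity layered on every
#' haplotype. Ground truth is computed by exhaustive enumeration: for each
#' species, the k-mers occurring in its male genome and in no female genome
#' of the genus; the genus truth set is their intersection.
#'
#' All coordinates are 0-based half-open. Deterministic given
#' `model$seed`.
#'
#' @param model a [genus_model()].
#' @param k word length for the ground-truth k-mer sets (default 16).
#' @return A `genus_sim`: list with `model`, `samples` (named list of
#'   `sample_genome`s, e.g. `sp1_M`), and `truth` (per-species and genus
#'   truth `kmer_set`s, planted-block BED, repeat mask).
#' @export
simulate_genus <- function(model, k = 16L) {
  stopifnot(inherits(model, "genus_model"))
  k <- .as_k(k)
  withr::with_seed(model$seed, .simulate_genus_impl(model, k))
}

.simulate_genus_impl <- function(model, k) {
  A <- model$autosome_length
  X <- model$xy_shared_length
  ## ancestral sequences; repeats occupy the tail of the autosome
  n_rep <- as.integer(round(model$repeat_fraction * A))
  motif <- .random_seq(50L)
  auto_anc <- c(.random_seq(A - n_rep), rep_len(motif, n_rep))
  xy_anc <- .random_seq(X)
  yblk_anc <- lapply(model$y_specific_blocks, .random_seq)
  repeat_mask <- if (n_rep > 0L)
    data.frame(chrom = "autosome", start = A - n_rep, end = A)
  else data.frame(chrom = character(0), start = integer(0), end = integer(0))

  ## X-deletion slots inside the X/Y region, evenly spaced, recorded 0-based
  xdel <- model$x_deletion_blocks
  xdel_coords <- NULL
  if (length(xdel) > 0L) {
    gap <- (X - sum(xdel)) %/% (length(xdel) + 1L)
    start <- gap
    xdel_coords <- data.frame(label = names(xdel), start = NA_integer_,
                              end = NA_integer_)
    for (i in seq_along(xdel)) {
      xdel_coords$start[i] <- start
      xdel_coords$end[i] <- start + xdel[i]
      start <- start + xdel[i] + gap
    }
  }

  anc <- c(list(autosome = auto_anc, xy = xy_anc), yblk_anc)
  tips <- .evolve_on_tree(model$species_tree, anc, model$snp_cluster_frac)

  herm_seqs <- NULL
  if (model$include_hermaphrodite) {
    depth <- mean(ape::node.depth.edgelength(model$species_tree)[
      seq_along(model$species_tree$tip.label)])
    herm_seqs <- lapply(anc, .mutate_seq, p = min(depth, 0.7),
                        cluster_frac = model$snp_cluster_frac)
  }

  het <- model$het_rate
  nblk <- length(model$y_specific_blocks)
  blk_names <- names(model$y_specific_blocks)
  ## Y-specific blocks are inserted mid-way into the X/Y region so they sit
  ## in chromosomal context on both sides (a block at a chromosome end
  ## would be under-covered by uniformly placed reads, which real embedded
  ## sex-linked regions are not)
  mid <- X %/% 2L

  build_sample <- function(species, sex, seqs) {
    ## species-level component sequences -> individual haplotypes + het
    auto_s <- seqs$autosome
    xy_s <- seqs$xy
    blocks_s <- if (nblk > 0L) seqs[blk_names] else list()
    x_hap <- function() {
      v <- xy_s
      if (!is.null(xdel_coords))
        v <- v[-unlist(Map(function(s, e) seq.int(s + 1L, e),
                           xdel_coords$start, xdel_coords$end))]
      .mutate_seq(v, het)
    }
    y_hap <- function() .mutate_seq(
      c(xy_s[seq_len(mid)], unlist(blocks_s, use.names = FALSE),
        xy_s[seq.int(mid + 1L, X)]), het)
    blk_coords <- if (nblk > 0L) {
      ends <- mid + cumsum(lengths(blocks_s))
      list(start = c(mid, head(ends, -1L)), end = ends)
    }
    haps <- list(autosome_1 = .mutate_seq(auto_s, het),
                 autosome_2 = .mutate_seq(auto_s, het))
    blocks <- data.frame(label = character(0), chrom = character(0),
                         start = integer(0), end = integer(0))
    if (sex == "male") {
      haps$sex_1 <- x_hap()
      haps$sex_2 <- y_hap()
      if (nblk > 0L)
        blocks <- data.frame(label = blk_names, chrom = "sex_2",
                             start = blk_coords$start, end = blk_coords$end)
    } else if (sex == "female") {
      haps$sex_1 <- x_hap()
      haps$sex_2 <- x_hap()
    } else { # hermaphrodite: two copies of the block-bearing chromosome
      haps$sex_1 <- y_hap()
      haps$sex_2 <- y_hap()
      if (nblk > 0L)
        blocks <- data.frame(label = rep(blk_names, 2L),
                             chrom = rep(c("sex_1", "sex_2"), each = nblk),
                             start = rep(blk_coords$start, 2L),
                             end = rep(blk_coords$end, 2L))
    }
    structure(list(species = species, sex = sex,
                   haplotypes = lapply(haps, .int2seq),
                   blocks = blocks),
              class = "sample_genome")
  }

  samples <- list()
  for (sp in model$species_tree$tip.label) {
    samples[[paste0(sp, "_M")]] <- build_sample(sp, "male", tips[[sp]])
    samples[[paste0(sp, "_F")]] <- build_sample(sp, "female", tips[[sp]])
  }
  if (!is.null(herm_seqs))
    samples[["outgroup_H"]] <- build_sample("outgroup", "hermaphrodite",
                                            herm_seqs)

  truth <- .compute_truth(samples, k, model)
  truth$repeats <- repeat_mask
  structure(list(model = model, samples = samples, truth = truth),
            class = "genus_sim")
}

## Exhaustive ground truth from the haplotype sequences themselves.
.compute_truth <- function(samples, k, model) {
  sexes <- vapply(samples, `[[`, "", "sex")
  females <- samples[sexes == "female"]
  males <- samples[sexes == "male"]
  female_codes <- if (length(females) > 0L) {
    sort(unique(.cpp_count_kmers(
      unlist(lapply(females, function(s) unlist(s$haplotypes)),
             use.names = FALSE), k)$code))
  } else numeric(0)
  per_species <- lapply(males, function(s) {
    mc <- .cpp_count_kmers(unlist(s$haplotypes, use.names = FALSE), k)$code
    mc[!(mc %in% female_codes)]
  })
  names(per_species) <- vapply(males, `[[`, "", "species")
  genus <- Reduce(function(a, b) a[a %in% b], per_species)
  bed <- do.call(rbind, lapply(names(samples), function(nm) {
    b <- samples[[nm]]$blocks
    if (nrow(b) == 0L) return(NULL)
    cbind(sample = nm, b)
  }))
  if (is.null(bed))
    bed <- data.frame(sample = character(0), label = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0))
  list(k = k,
       per_species = lapply(per_species, kmer_set, k = k),
       genus = kmer_set(genus, k),
       bed = bed)
}

#' @export
print.genus_sim <- function(x, ...) {
  cat(sprintf("<genus_sim> %d species, %d samples; genus truth set: %s %d-mers\n",
              x$model$n_species, length(x$samples),
              format(length(x$truth$genus), big.mark = ","), x$truth$k))
  invisible(x)
}
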