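# Shared fixtures, built once per test run and memoized.

.fix_env <- new.env()

# small genus at the stated divergence regime (star tree so every species
# pair sits at the same expected divergence)
tiny_genus <- function() {
  if (is.null(.fix_env$tiny)) {
    tr <- ape::stree(3, type = "star")
    tr$edge.length <- rep(1, 3)
    tr$tip.label <- paste0("sp", 1:3)
    m <- genus_model(n_species = 3, species_tree = tr,
                     autosome_length = 20000L, xy_shared_length = 3000L,
                     y_specific_blocks = c(Y = 1500L), seed = 42L)
    .fix_env$tiny <- simulate_genus(m, k = 16)
  }
  .fix_env$tiny
}

# zero-divergence genus: all branch lengths 0, no heterozygosity, so every
# genome is identical except for the planted Y block
zero_div_genus <- function() {
  if (is.null(.fix_env$zero)) {
    tr <- ape::stree(3, type = "star")
    tr$edge.length <- rep(0, 3)
    tr$tip.label <- paste0("sp", 1:3)
    m <- genus_model(n_species = 3, species_tree = tr,
                     autosome_length = 10000L, xy_shared_length = 2000L,
                     y_specific_blocks = c(Y = 1000L), het_rate = 0,
                     seed = 7L)
    .fix_env$zero <- simulate_genus(m, k = 16)
  }
  .fix_env$zero
}

# count table for an arbitrary multiset of k-mers, via reads of exactly k
make_table <- function(words, counts, k = nchar(words[1]), sample = "s") {
  count_kmers(rep(words, times = counts), k, sample = sample)
}
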