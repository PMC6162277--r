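# genus simulator: model validation, divergence regime, truth sets, reads

test_that("model validation rejects inconsistent inputs", {
  expect_error(genus_model(n_species = 1), ">= 2")
  expect_error(genus_model(snp_rate_target = 0.3), "0, 0.25")
  expect_error(genus_model(autosome_length = 0), "> 0")
  tr <- ape::stree(4, "left"); tr$edge.length <- rep(1, nrow(tr$edge))
  expect_error(genus_model(n_species = 3, species_tree = tr), "leaves")
  expect_error(genus_model(xy_shared_length = 100,
                           x_deletion_blocks = c(d = 200)),
               "longer than")
})

test_that("zero divergence: genomes identical except the planted Y block", {
  sim <- zero_div_genus()
  m <- sim$samples$sp1_M; f <- sim$samples$sp1_F
  expect_identical(m$haplotypes$autosome_1, f$haplotypes$autosome_1)
  expect_identical(m$haplotypes$sex_1, f$haplotypes$sex_1)
  # Y = X/Y region with the block inserted at the midpoint (1000)
  x <- m$haplotypes$sex_1
  y <- m$haplotypes$sex_2
  expect_equal(nchar(y), 3000)
  expect_identical(substr(y, 1, 1000), substr(x, 1, 1000))
  expect_identical(substr(y, 2001, 3000), substr(x, 1001, 2000))
  expect_identical(sim$samples$sp1_M$haplotypes$sex_2,
                   sim$samples$sp2_M$haplotypes$sex_2)
  blk <- m$blocks[1, ]
  expect_equal(c(blk$start, blk$end), c(1000, 2000))
  # truth = k-mers of the block-bearing Y absent from the female genome
  # (block k-mers plus the insertion-junction k-mers)
  y_codes <- count_kmers(y, 16, source = "assembly")$code
  fem_codes <- count_kmers(unlist(f$haplotypes), 16, source = "assembly")$code
  expect_identical(sim$truth$genus$code,
                   sort(setdiff(y_codes, fem_codes)))
  # every k-mer fully inside the block is male-specific unless shared with
  # the background by chance
  blk_codes <- count_kmers(substr(y, blk$start + 1, blk$end), 16,
                           source = "assembly")$code
  expect_true(all(setdiff(blk_codes, fem_codes) %in% sim$truth$genus$code))
})

test_that("empty y_specific_blocks gives an empty truth set", {
  tr <- ape::stree(2, "star"); tr$edge.length <- c(0, 0)
  tr$tip.label <- c("sp1", "sp2")
  m <- genus_model(n_species = 2, species_tree = tr, autosome_length = 5000,
                   xy_shared_length = 1000, y_specific_blocks = NULL,
                   het_rate = 0, seed = 3)
  sim <- simulate_genus(m)
  expect_length(sim$truth$genus$code, 0)
})

test_that("branch calibration reproduces the target SNP spacing", {
  # star tree: every male pair at the same expected divergence L/16.5
  tr <- ape::stree(4, type = "star"); tr$edge.length <- rep(1, 4)
  tr$tip.label <- paste0("sp", 1:4)
  L <- 60000L
  m <- genus_model(n_species = 4, species_tree = tr, autosome_length = L,
                   xy_shared_length = 2000L, y_specific_blocks = c(Y = 1000L),
                   seed = 19)
  sim <- simulate_genus(m)
  p <- 1 / 16.5
  sdv <- sqrt(L * p * (1 - p))
  pairs <- combn(4, 2)
  seqs <- lapply(paste0("sp", 1:4), function(sp)
    strsplit(sim$samples[[paste0(sp, "_M")]]$haplotypes$autosome_1, "")[[1]])
  for (j in seq_len(ncol(pairs))) {
    obs <- sum(seqs[[pairs[1, j]]] != seqs[[pairs[2, j]]])
    expect_lt(abs(obs - L * p), 3 * sdv)
  }
})

test_that("truth-set soundness: in every male genome, in no female genome", {
  sim <- tiny_genus()
  k <- sim$truth$k
  truth <- sim$truth$genus$code
  expect_gt(length(truth), 0)
  for (sp in paste0("sp", 1:3)) {
    mg <- count_kmers(unlist(sim$samples[[paste0(sp, "_M")]]$haplotypes), k,
                      source = "assembly")
    expect_true(all(truth %in% mg$code))
    fg <- count_kmers(unlist(sim$samples[[paste0(sp, "_F")]]$haplotypes), k,
                      source = "assembly")
    expect_false(any(truth %in% fg$code))
  }
})

test_that("truth set is reproducible from error-free reads", {
  sim <- zero_div_genus()
  k <- sim$truth$k
  spec <- function(seed) read_sim_spec(coverage = 30, error_rate = 0,
                                       seed = seed)
  male_tabs <- lapply(1:3, function(i)
    count_kmers(simulate_reads(sim$samples[[paste0("sp", i, "_M")]],
                               spec(i)), k))
  fem_tabs <- lapply(1:3, function(i)
    count_kmers(simulate_reads(sim$samples[[paste0("sp", i, "_F")]],
                               spec(10 + i)), k))
  sets <- lapply(1:3, function(i)
    sex_specific_set(male_tabs[[i]], fem_tabs[[i]], cutoff = 1,
                     species = paste0("sp", i)))
  cons <- genus_conserved_set(sets, fem_tabs)
  expect_identical(cons$code, sim$truth$genus$code)
})

test_that("hemizygosity: planted-block depth is half the autosomal depth", {
  sim <- tiny_genus()
  m <- sim$samples$sp1_M
  reads <- simulate_reads(m, read_sim_spec(coverage = 40, error_rate = 0,
                                           seed = 9))
  tab <- count_kmers(reads, 16)
  blk <- m$blocks[1, ]
  block_seq <- substr(m$haplotypes$sex_2, blk$start + 1, blk$end)
  d_block <- kmer_region_depth(tab, block_seq)
  d_auto <- kmer_region_depth(tab, m$haplotypes$autosome_1)
  expect_lt(abs(d_block / d_auto - 0.5), 0.05)
})

test_that("read simulation: depth, determinism, degenerate cases", {
  withr::with_seed(1, {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  })
  # error-free 30x: every interior genomic k-mer appears in the reads
  # (the terminal read_length - 1 bases are edge-covered by construction
  # of uniform fixed-length read placement; documented)
  r <- simulate_reads(c(chr = s), read_sim_spec(coverage = 30, error_rate = 0,
                                                seed = 2))
  interior_k <- count_kmers(substr(s, 100, 9901), 16, source = "assembly")$code
  genome_k <- count_kmers(s, 16, source = "assembly")$code
  read_k <- count_kmers(r, 16)$code
  expect_true(all(interior_k %in% read_k))
  expect_gte(mean(genome_k %in% read_k), 0.998)

  # sparse sampling misses k-mers
  r2 <- simulate_reads(c(chr = s), read_sim_spec(coverage = 0.5, seed = 3))
  expect_false(all(genome_k %in% count_kmers(r2, 16)$code))

  # same seed -> byte-identical FASTQ
  spec <- read_sim_spec(coverage = 5, seed = 17)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(simulate_reads(c(chr = s), spec), f1)
  write_fastq(simulate_reads(c(chr = s), spec), f2)
  expect_identical(readLines(f1), readLines(f2))

  # paired mode: mates are reverse-complements drawn insert_size apart
  rp <- simulate_reads(c(chr = s), read_sim_spec(coverage = 2, error_rate = 0,
                                                 paired = TRUE, seed = 5))
  expect_equal(nrow(rp) %% 2, 0)
  r1 <- rp$seq[1]; r2m <- rp$seq[2]
  expect_true(grepl(r1, s, fixed = TRUE))
  expect_true(grepl(or_revcomp(r2m), s, fixed = TRUE))

  expect_error(simulate_reads(c(chr = "ACGT"), read_sim_spec()),
               "read_length exceeds")
  expect_error(read_sim_spec(error_rate = 0.2), "error_rate")
  expect_error(read_sim_spec(coverage = 0), "coverage")
})

test_that("simulation is reproducible given the model seed", {
  m <- genus_model(n_species = 2, autosome_length = 5000,
                   xy_shared_length = 1000, y_specific_blocks = c(Y = 500),
                   seed = 77)
  s1 <- simulate_genus(m)
  s2 <- simulate_genus(m)
  expect_identical(s1$samples$sp1_M$haplotypes, s2$samples$sp1_M$haplotypes)
  expect_identical(s1$truth$genus$code, s2$truth$genus$code)
})

test_that("hermaphrodite control carries two copies of the Y blocks", {
  sim <- tiny_genus()
  h <- sim$samples$outgroup_H
  expect_equal(h$sex, "hermaphrodite")
  expect_equal(nrow(h$blocks), 2)  # one per chromosome copy
  expect_identical(h$blocks$start, rep(1500L, 2))  # X/Y midpoint
})

test_that("repeat_fraction plants an exact tandem repeat and exports mask", {
  m <- genus_model(n_species = 2, autosome_length = 10000,
                   xy_shared_length = 1000, y_specific_blocks = c(Y = 500),
                   repeat_fraction = 0.2, het_rate = 0, seed = 5)
  sim <- simulate_genus(m)
  expect_equal(sim$truth$repeats$start, 8000)
  expect_equal(sim$truth$repeats$end, 10000)
})
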