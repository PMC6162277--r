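# exact k-mer matching, coverage percentages, density tracks, haplotype
# selection, consensus substitutions

test_that("k-mers drawn from a contig are all matched, strand-symmetrically", {
  withr::with_seed(11, {
    contig <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                    collapse = "")
    words <- substring(contig, seq(1, 2900, by = 100), seq(16, 2915, by = 100))
    prof <- match_kmers(kmer_set(words), c(ctg = contig))[[1]]
    expect_true(all(words %in% c(prof$hits$kmer,
                                 vapply(prof$hits$kmer, or_revcomp, ""))))
    expect_gte(nrow(prof$hits), length(words))

    rc <- match_kmers(kmer_set(words), c(ctg = or_revcomp(contig)))[[1]]
    expect_equal(nrow(rc$hits), nrow(prof$hits))
    expect_setequal(rc$hits$pos, nchar(contig) - 16 - prof$hits$pos)
  })
})

test_that("matching equals the brute-force substring scan", {
  withr::with_seed(13, {
    contig <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                    collapse = "")
    words <- c(substring(contig, c(5, 600, 4000), c(20, 615, 4015)),
               vapply(1:20, function(i)
                 paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE),
                       collapse = ""), ""))
    prof <- match_kmers(kmer_set(unique(words)), c(ctg = contig))[[1]]
    expect_identical(sort(prof$hits$pos),
                     sort(or_match_positions(unique(words), contig)))
  })
})

test_that("coverage percent by species-support threshold", {
  contig <- c(ctg = "ACGTACGGATCCGGATTTACGGCAATCC")
  inside <- substring(contig, 1:6, 8:13)   # 8-mers present
  absent <- c("AAAAAAAA", "CCAACCAA")      # distinct canonical forms
  by_sup <- list(`1` = c(inside[1:4], absent), `2` = inside[1:2])
  cov <- coverage_percent(by_sup, contig)
  expect_equal(cov$percent_matched, c(100 * 4 / 6, 100))
  # contigs containing every k-mer -> 100 everywhere
  cov2 <- coverage_percent(list(`1` = inside, `2` = inside[1:3]), contig)
  expect_equal(cov2$percent_matched, c(100, 100))
  # disjoint -> 0
  cov3 <- coverage_percent(list(`1` = absent), contig)
  expect_equal(cov3$percent_matched, 0)
  expect_error(coverage_percent(list(`1` = inside), character(0)), "empty")
})

test_that("density track: uniform hits, zeros, and stratification", {
  prof <- structure(list(contig = "c", length = 10000L, k = 16L,
                         hits = data.frame(pos = seq(0, 9900, by = 100),
                                           strand = "+", kmer = "X",
                                           support = rep(1L, 100))),
                    class = "kmer_match_profile")
  dt <- density_track(prof, window = 1000)
  expect_true(all(abs(dt$values[, 1] - 0.01) < 1e-12))

  empty <- structure(list(contig = "c", length = 5000L, k = 16L,
                          hits = data.frame(pos = integer(0),
                                            strand = character(0),
                                            kmer = character(0),
                                            support = integer(0))),
                     class = "kmer_match_profile")
  expect_true(all(density_track(empty, 1000)$values == 0))

  # stratification: density at support >= n+1 never exceeds that at >= n
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(10:100, 1)
      prof$hits <- data.frame(pos = sample(0:9984, n), strand = "+",
                              kmer = "X", support = sample(1:6, n, TRUE))
      v <- density_track(prof, 500)$values
      expect_true(all(apply(v, 1, function(row) all(diff(row) <= 1e-12))))
    }
  })
})

test_that("haplotype scaffold selection applies the 100 / 6x rule", {
  pairs <- data.frame(scaffold = c("s1", "s2", "s3", "s4", "s5"),
                      hapA_kmer_count = c(150, 99, 120, 0, 100),
                      hapB_kmer_count = c(10, 0, 30, 600, 100))
  sel <- suppressMessages(select_haplotype_scaffolds(pairs))
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(sel$assigned_haplotype, c("A", "none", "none", "B", "none"))
  expect_message(select_haplotype_scaffolds(pairs), "tied")

  # symmetry: swapping haplotypes only flips the assignment
  sw <- pairs
  sw$hapA_kmer_count <- pairs$hapB_kmer_count
  sw$hapB_kmer_count <- pairs$hapA_kmer_count
  sel2 <- suppressMessages(select_haplotype_scaffolds(sw))
  expect_equal(sel2$selected, sel$selected)
  expect_equal(sel2$assigned_haplotype[1], "B")
  expect_error(select_haplotype_scaffolds(
    data.frame(scaffold = "x", hapA_kmer_count = -1, hapB_kmer_count = 0)),
    ">= 0")
})

test_that("consensus substitutions apply exactly and verify the reference", {
  ref <- "ACGTACGTAC"
  cons0 <- consensus_substitution(ref, data.frame(pos = integer(0),
                                                  ref = character(0),
                                                  alt = character(0)))
  expect_identical(apply_substitutions(cons0), ref)

  subs <- data.frame(pos = c(0, 4, 9), ref = c("A", "A", "C"),
                     alt = c("G", "T", "T"))
  out <- apply_substitutions(consensus_substitution(ref, subs))
  expect_equal(sum(strsplit(out, "")[[1]] != strsplit(ref, "")[[1]]), 3)
  expect_equal(out, "GCGTTCGTAT")

  expect_error(consensus_substitution(ref, data.frame(pos = 1, ref = "A",
                                                      alt = "G")),
               "mismatch.*stale", ignore.case = TRUE)

  # random round-trip against a character-replacement oracle
  withr::with_seed(31, {
    for (i in 1:20) {
      r <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
      pos <- sample(0:199, 15)
      rv <- strsplit(r, "")[[1]]
      alt <- vapply(pos, function(p)
        sample(setdiff(c("A", "C", "G", "T"), rv[p + 1]), 1), "")
      out <- apply_substitutions(consensus_substitution(
        r, data.frame(pos = pos, ref = rv[pos + 1], alt = alt)))
      oracle <- rv; oracle[pos + 1] <- alt
      expect_identical(out, paste(oracle, collapse = ""))
    }
  })
})

test_that("planted-block localization on synthetic data", {
  sim <- tiny_genus()
  m <- sim$samples$sp1_M
  profs <- match_kmers(sim$truth$genus, unlist(m$haplotypes))
  hits <- do.call(rbind, lapply(profs, function(p)
    if (nrow(p$hits)) cbind(contig = p$contig, p$hits) else NULL))
  blk <- m$blocks[1, ]
  inside <- hits$contig == "sex_2" & hits$pos >= blk$start &
    hits$pos + 16 <= blk$end
  expect_gte(mean(inside), 0.95)
})
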