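# error cutoffs, sex-specific subtraction, survival curves, conserved sets,
# read selection

test_that("error cutoff finds the valley and clamps to [3, 15]", {
  # error mode at 1-2, coverage peak at 30, valley at 6
  h <- c(1000, 200, 60, 30, 12, 5, 9, 20, 60, 120, rep(200, 18), 900, 500)
  expect_equal(select_error_cutoff(h)$cutoff, 6L)

  # valley at 1 -> clamped up to 3
  h2 <- c(1, 5, 30, 100, 300, 100, 30)
  expect_equal(select_error_cutoff(h2)$cutoff, 3L)

  # valley beyond 15 -> clamped down to 15
  h3 <- c(1e6, rep(10, 16), 5, rep(10, 5), 1000, 2000, 1000)
  expect_equal(select_error_cutoff(h3)$cutoff, 15L)

  # monotone-decreasing histogram: pure error, no coverage peak
  expect_error(select_error_cutoff(c(1000, 300, 100, 30, 10, 3, 1)),
               "no coverage peak")
})

test_that("sex-specific subtraction keeps focal-only k-mers above cutoff", {
  foc <- make_table(c("AAAA", "ACGT", "CCCC"), c(10, 10, 10))
  opp <- make_table("ACGT", 10)
  s <- sex_specific_set(foc, opp, cutoff = 3, species = "sp", focal_sex = "male")
  expect_setequal(kmer_decode(s$code, 4), c("AAAA", "CCCC"))

  # focal == opposite -> empty
  s2 <- sex_specific_set(foc, foc, cutoff = 3)
  expect_length(s2$code, 0)

  # below-cutoff focal k-mers are discarded
  foc2 <- make_table(c("AAAA", "CCCC"), c(2, 10))
  s3 <- sex_specific_set(foc2, opp, cutoff = 3)
  expect_equal(kmer_decode(s3$code, 4), "CCCC")

  # mismatched k errors
  opp5 <- make_table("ACGTA", 5)
  expect_error(sex_specific_set(foc, opp5, 3), "mismatched k")
})

test_that("subtraction soundness holds for simulated tables", {
  sim <- tiny_genus()
  g <- sim$samples$sp1_M$haplotypes
  gf <- sim$samples$sp1_F$haplotypes
  tm <- count_kmers(unlist(g), 16, sample = "m", source = "assembly")
  tf <- count_kmers(unlist(gf), 16, sample = "f", source = "assembly")
  s <- sex_specific_set(tm, tf, cutoff = 1, opposite_presence_min = 1)
  present <- tf$code[tf$count >= 1]
  expect_false(any(s$code %in% present))
})

test_that("survival curve semantics and monotonicity", {
  mk <- function(words, sp) {
    tab <- make_table(words, rep(5, length(words)), sample = sp)
    sex_specific_set(tab, make_table("GGGG", 1), cutoff = 3, species = sp)
  }
  ident <- lapply(paste0("s", 1:3), function(sp)
    mk(c("AAAA", "AATT", "ACCA"), sp))
  sc <- survival_curve(ident)
  expect_equal(sc$count, c(3, 3, 3))

  disj <- list(mk("AAAA", "a"), mk("AATT", "b"), mk("ACCA", "c"))
  sc2 <- survival_curve(disj)
  expect_equal(sc2$count, c(3, 0, 0))

  # ordered (cumulative-intersection) mode
  part <- list(mk(c("AAAA", "AATT"), "a"), mk(c("AAAA", "ACCA"), "b"),
               mk("ACCA", "c"))
  expect_equal(survival_curve(part, ordered = TRUE)$count, c(2, 1, 0))
  expect_equal(survival_curve(part)$count, c(3, 2, 0))

  # property: non-increasing for random set families
  withr::with_seed(33, {
    for (rep in 1:20) {
      sets <- lapply(1:4, function(i) {
        n <- sample(5:40, 1)
        words <- unique(vapply(1:n, function(j)
          paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                collapse = ""), ""))
        mk6 <- make_table(words, rep(4, length(words)), sample = paste0("r", i))
        sex_specific_set(mk6, make_table("GGGGGG", 1), cutoff = 3,
                         species = paste0("r", i))
      })
      expect_true(all(diff(survival_curve(sets)$count) <= 0))
    }
  })

  expect_error(survival_curve(list(mk("AAAA", "x"))), ">= 2 species")
  f <- mk("AAAA", "y"); f$focal_sex <- "female"
  expect_error(survival_curve(list(mk("AAAA", "x"), f)), "mixed focal_sex")
})

test_that("genus-conserved set intersects males and vetoes on any female", {
  mk <- function(words, sp) {
    tab <- make_table(words, rep(5, length(words)), sample = sp)
    sex_specific_set(tab, make_table("GGGG", 1), cutoff = 3, species = sp)
  }
  males <- list(mk(c("AAAA", "AATT", "ACCA"), "a"),
                mk(c("AAAA", "AATT"), "b"))
  fem_empty <- list(make_table("GGGG", 1))
  cons <- genus_conserved_set(males, fem_empty)
  expect_setequal(kmer_decode(cons), c("AAAA", "AATT"))

  # adding a k-mer to one female table excludes it, even a female from a
  # species without a male sample
  fem2 <- list(make_table("GGGG", 1), make_table("AATT", 1, sample = "extraF"))
  cons2 <- genus_conserved_set(males, fem2)
  expect_equal(kmer_decode(cons2), "AAAA")

  # opposite_presence_min = 2 tolerates a single female occurrence
  cons3 <- genus_conserved_set(males, fem2, opposite_presence_min = 2)
  expect_setequal(kmer_decode(cons3), c("AAAA", "AATT"))

  expect_error(genus_conserved_set(list(), fem_empty), "at least one")
})

test_that("zero-divergence genus: subtraction recovers the exact truth set", {
  sim <- zero_div_genus()
  k <- sim$truth$k
  # per-species sets from the genomes themselves (cutoff 1: no errors)
  male_sets <- lapply(paste0("sp", 1:3), function(sp) {
    tm <- count_kmers(unlist(sim$samples[[paste0(sp, "_M")]]$haplotypes), k,
                      sample = sp, source = "assembly")
    tf <- count_kmers(unlist(sim$samples[[paste0(sp, "_F")]]$haplotypes), k,
                      sample = sp, source = "assembly")
    sex_specific_set(tm, tf, cutoff = 1, species = sp)
  })
  fem_tabs <- lapply(paste0("sp", 1:3), function(sp)
    count_kmers(unlist(sim$samples[[paste0(sp, "_F")]]$haplotypes), k,
                sample = sp, source = "assembly"))
  cons <- genus_conserved_set(male_sets, fem_tabs)
  expect_identical(cons$code, sim$truth$genus$code)
  # zero divergence: per-species sets all equal the genus set
  for (s in male_sets) expect_identical(s$code, sim$truth$genus$code)
})

test_that("read selection matches a brute-force substring scan", {
  withr::with_seed(55, {
    contig <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                    collapse = "")
    reads <- vapply(1:200, function(i) {
      if (i %% 2 == 0) substr(contig, i, i + 79)
      else paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
    }, "")
    words <- unique(substring(contig, seq(1, 300, by = 40),
                              seq(16, 315, by = 40)))
    sel <- select_reads_with_kmers(reads, kmer_set(words))
    brute <- vapply(reads, function(r)
      length(or_match_positions(words, r)) > 0, TRUE, USE.NAMES = FALSE)
    expect_identical(sel, reads[brute])

    # empty k-mer set selects nothing
    expect_length(select_reads_with_kmers(reads, kmer_set(character(0), 16)),
                  0)

    # keep pairs when either mate hits
    mates <- rev(reads)
    recs <- data.frame(id = paste0("r", seq_along(reads)), seq = reads,
                       qual = strrep("I", 80))
    mrecs <- data.frame(id = paste0("r", seq_along(reads)), seq = mates,
                        qual = strrep("I", 80))
    selp <- select_reads_with_kmers(recs, kmer_set(words), mates = mrecs)
    brute_pair <- brute | rev(brute)
    expect_equal(selp$seq, reads[brute_pair])
    expect_equal(attr(selp, "mates")$seq, mates[brute_pair])
  })
})
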