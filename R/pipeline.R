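#' Pipeline configuration
#'
#' One flat configuration object for the end-to-end run: simulate a genus,
#' sequence it, build sex-specific and genus-conserved k-mer sets, localize
#' them, and call copy number over the planted blocks. Every module default
#' is overridable here; values are validated against the owning module's
#' ranges at use.
#'
#' @param n_species,autosome_length,xy_shared_length,y_specific_blocks,
#'   x_deletion_blocks,repeat_fraction,snp_rate_target,het_rate see
#'   [genus_model()].
#' @param k k-mer length.
#' @param cutoff `"auto"` (histogram valley per sample) or an integer.
#' @param opposite_presence_min see [sex_specific_set()].
#' @param coverage,read_length,error_rate,paired,insert_size see
#'   [read_sim_spec()].
#' @param hap_min_kmers,hap_ratio see [select_haplotype_scaffolds()].
#' @param density_window window for [density_track()].
#' @param seed root seed; per-stage seeds are derived from it.
#' @param out_dir optional directory to write artifacts (FASTA, FASTQ,
#'   k-mer sets, BED, TSV, JSON manifest).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(n_species = 6L, autosome_length = 200000L,
                            xy_shared_length = 10000L,
                            y_specific_blocks = c(Yblock = 5000L),
                            x_deletion_blocks = NULL,
                            repeat_fraction = 0,
                            snp_rate_target = 1 / 16.5,
                            het_rate = 1e-3,
                            k = 16L, cutoff = "auto",
                            opposite_presence_min = 1L,
                            coverage = 30, read_length = 100L,
                            error_rate = 0.005, paired = FALSE,
                            insert_size = 400L,
                            hap_min_kmers = 100L, hap_ratio = 6,
                            density_window = 1000L,
                            seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  if (!identical(cutoff, "auto")) cfg$cutoff <- as.integer(cutoff)
  structure(cfg, class = "pipeline_config")
}

## Derived per-stage seeds, kept below 2^31.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483562L
}

#' Run the whole discovery pipeline on a simulated genus
#'
#' Stages, in order: genus simulation with ground truth; read simulation
#' per sample; k-mer counting and per-sample error cutoffs; per-species
#' male- and female-specific sets; survival curves in both directions; the
#' genus-conserved male-specific set; localization of the conserved set
#' onto the first male's genome with a density track and truth-BED
#' comparison; copy-number calls over the planted blocks for every male
#' and the hermaphrodite control. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress on stderr.
#' @return A `run_report` (see fields in the returned object), with every
#'   summary reproducible from the recorded manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) say("[%6.1fs] %s", proc.time()[["elapsed"]] - t0,
                              name)

  stage("simulate genus")
  model <- genus_model(
    n_species = config$n_species, autosome_length = config$autosome_length,
    xy_shared_length = config$xy_shared_length,
    y_specific_blocks = config$y_specific_blocks,
    x_deletion_blocks = config$x_deletion_blocks,
    repeat_fraction = config$repeat_fraction,
    snp_rate_target = config$snp_rate_target, het_rate = config$het_rate,
    seed = .stage_seed(config$seed, 1L))
  sim <- simulate_genus(model, k = config$k)

  stage("simulate reads + count k-mers")
  tables <- list()
  cutoffs <- list()
  reads_first_male <- NULL
  for (nm in names(sim$samples)) {
    spec <- read_sim_spec(read_length = config$read_length,
                          coverage = config$coverage,
                          error_rate = config$error_rate,
                          paired = config$paired,
                          insert_size = config$insert_size,
                          seed = .stage_seed(config$seed,
                                             2L + match(nm, names(sim$samples))))
    reads <- simulate_reads(sim$samples[[nm]], spec)
    if (is.null(reads_first_male) && sim$samples[[nm]]$sex == "male")
      reads_first_male <- reads
    tables[[nm]] <- count_kmers(reads, config$k, sample = nm)
    cutoffs[[nm]] <- if (identical(config$cutoff, "auto"))
      select_error_cutoff(tables[[nm]]) else
        structure(list(sample = nm, cutoff = as.integer(config$cutoff),
                       histogram = NULL), class = "error_cutoff")
  }

  stage("sex-specific subtraction")
  species <- sim$model$species_tree$tip.label
  male_sets <- list(); female_sets <- list()
  for (sp in species) {
    m <- paste0(sp, "_M"); f <- paste0(sp, "_F")
    male_sets[[sp]] <- sex_specific_set(
      tables[[m]], tables[[f]], cutoffs[[m]],
      opposite_presence_min = config$opposite_presence_min,
      species = sp, focal_sex = "male")
    female_sets[[sp]] <- sex_specific_set(
      tables[[f]], tables[[m]], cutoffs[[f]],
      opposite_presence_min = config$opposite_presence_min,
      species = sp, focal_sex = "female")
  }

  stage("survival curves + genus-conserved set")
  surv_male <- survival_curve(male_sets)
  surv_female <- survival_curve(female_sets)
  female_tables <- tables[paste0(species, "_F")]
  conserved <- genus_conserved_set(male_sets, female_tables,
                                   config$opposite_presence_min)

  truth <- sim$truth$genus
  recovery <- if (length(truth) > 0)
    mean(truth$code %in% conserved$code) else NA_real_
  false_in_female <- {
    fem_codes <- unique(unlist(lapply(female_tables, function(t)
      t$code[t$count >= 1]), use.names = FALSE))
    ## exhaustive genome-level check: conserved k-mers present in any
    ## female *genome* (not merely reads)
    fem_genomes <- unlist(lapply(sim$samples[vapply(sim$samples, `[[`, "",
                                                    "sex") == "female"],
                                 function(s) unlist(s$haplotypes)),
                          use.names = FALSE)
    fg <- .cpp_count_kmers(fem_genomes, config$k)$code
    sum(conserved$code %in% fg)
  }

  stage("localization")
  first_male <- sim$samples[[paste0(species[1], "_M")]]
  contigs <- unlist(first_male$haplotypes)
  ## per-k-mer species support for the union of male-specific k-mers
  support_tab <- {
    v <- sort(unlist(lapply(male_sets, `[[`, "code"), use.names = FALSE))
    r <- rle(v)
    setNames(r$lengths, r$values)
  }
  profiles <- match_kmers(conserved, contigs,
                          support = setNames(
                            unname(support_tab[as.character(conserved$code)]),
                            kmer_decode(conserved)))
  names(profiles) <- vapply(profiles, `[[`, "", "contig")
  truth_bed <- sim$truth$bed[sim$truth$bed$sample == paste0(species[1], "_M"), ]
  hits_all <- do.call(rbind, lapply(profiles, function(p)
    if (nrow(p$hits) > 0L) cbind(contig = p$contig, p$hits) else NULL))
  in_truth <- if (!is.null(hits_all) && nrow(hits_all) > 0L) {
    ok <- logical(nrow(hits_all))
    for (i in seq_len(nrow(truth_bed)))
      ok <- ok | (hits_all$contig == truth_bed$chrom[i] &
                    hits_all$pos >= truth_bed$start[i] &
                    hits_all$pos + config$k <= truth_bed$end[i])
    mean(ok)
  } else NA_real_
  dens <- if (length(profiles) > 0L)
    density_track(profiles[["sex_2"]], config$density_window) else NULL

  stage("copy number")
  y_hap <- first_male$haplotypes$sex_2
  blocks <- first_male$blocks
  cn_profiles <- list()
  for (nm in names(sim$samples)) {
    s <- sim$samples[[nm]]
    if (!s$sex %in% c("male", "hermaphrodite")) next
    ## regions: the sample's own planted-block sequence; controls: three
    ## slices of the sample's own autosome
    chrom <- if (s$sex == "male") "sex_2" else "sex_1"
    bl <- s$blocks[s$blocks$chrom == chrom, , drop = FALSE]
    regs <- setNames(lapply(seq_len(nrow(bl)), function(i)
      substr(s$haplotypes[[chrom]], bl$start[i] + 1L, bl$end[i])), bl$label)
    auto <- s$haplotypes$autosome_1
    L <- nchar(auto)
    ctrl <- setNames(lapply(0:2, function(i)
      substr(auto, 1L + i * (L %/% 3L), min(L, (i + 1L) * (L %/% 3L)))),
      paste0("autosome_ctrl", 1:3))
    dp <- depth_profile_from_kmers(tables[[nm]], unlist(regs), unlist(ctrl),
                                   sample = nm, sex = s$sex)
    cn_profiles[[nm]] <- copy_number_profile(dp)
  }
  male_cn <- mean_male_copy(cn_profiles[vapply(cn_profiles, function(p)
    identical(p$sex, "male"), TRUE)])

  report <- structure(list(
    config = config, model = model, sim = sim,
    tables = tables, cutoffs = cutoffs,
    male_sets = male_sets, female_sets = female_sets,
    survival = list(male = surv_male, female = surv_female),
    conserved = conserved,
    truth_recovery = recovery,
    false_kmers_in_female_genomes = false_in_female,
    localization = list(profiles = profiles, fraction_hits_in_truth = in_truth,
                        density = dens),
    copy_number = list(profiles = cn_profiles, mean_male = male_cn),
    manifest = list(package_version = as.character(utils::packageVersion("ykmer")),
                    seed = config$seed,
                    parameters = unclass(config)[setdiff(names(config),
                                                         "out_dir")],
                    timestamp = NA)),
    class = "run_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  stage("done")
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  for (nm in names(report$sim$samples)) {
    s <- report$sim$samples[[nm]]
    write_fasta(setNames(s$haplotypes,
                         paste0(nm, "_", names(s$haplotypes))),
                file.path(dir, paste0(nm, ".fasta")))
  }
  write_bed(cbind(report$sim$truth$bed[, c("chrom", "start", "end")],
                  name = paste(report$sim$truth$bed$sample,
                               report$sim$truth$bed$label, sep = ":")),
            file.path(dir, "truth_blocks.bed"))
  write_kmer_set(report$conserved, file.path(dir, "conserved_kmers.txt"))
  write_tsv(as.data.frame(report$survival$male),
            file.path(dir, "survival_male.tsv"))
  write_tsv(as.data.frame(report$survival$female),
            file.path(dir, "survival_female.tsv"))
  cn <- do.call(rbind, lapply(report$copy_number$profiles, function(p)
    cbind(sample = p$sample, sex = p$sex, p$regions)))
  write_tsv(cn, file.path(dir, "copy_number.tsv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  genus: %d species; truth set %s %d-mers\n",
              x$model$n_species, format(length(x$sim$truth$genus),
                                        big.mark = ","), x$config$k))
  cat(sprintf("  conserved set: %s k-mers; truth recovery %.2f%%; %d in female genomes\n",
              format(length(x$conserved), big.mark = ","),
              100 * x$truth_recovery, x$false_kmers_in_female_genomes))
  cat(sprintf("  localization: %.2f%% of hits inside planted blocks\n",
              100 * x$localization$fraction_hits_in_truth))
  mm <- x$copy_number$mean_male
  cat(sprintf("  copy number: mean male copies %s\n",
              paste(sprintf("%s=%.2f", mm$contig, mm$mean_copies_raw),
                    collapse = ", ")))
  invisible(x)
}
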