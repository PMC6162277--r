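---
title: "Discovering sex-linked regions with sex-specific k-mers"
author: "ykmer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked regions with sex-specific k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ykmer)
```

## The problem

In a dioecious genus with XY sex determination, every male carries a
non-recombining Y-specific region that no female carries. If dioecy arose
once in the genus ancestor, a core of that region should be shared by the
males of *all* species and absent from *all* females. `ykmer` implements a
reference-free way to find it: count the k-mers of one male and one female
genome per species, subtract the female's k-mers from the male's within
each species, intersect the survivors across species, and veto anything
seen in any female. The genus-conserved male-specific k-mers are then
localized onto contigs, the implicated regions are checked for
hemizygosity (1 copy per male genome) by depth, and candidate genes are
screened for selective constraint with synonymous/nonsynonymous rates.

## Choosing k: the calibration model

The method needs words long enough to be specific to one locus in a
~0.5-1 Gb genome but short enough that inter-species polymorphism does not
destroy them. The calibration stage works from the observed SNP process on
non-repetitive, non-sex-linked scaffolds:

* `snp_spacing(total_nonrep_bp, n_snps)` — the average spacing. The
  divergence regime this package targets is about one SNP per 16.5 bp
  among males across a genus; at that rate a 16 bp word straddles on
  average about one polymorphism, so *some* 16-mers break, but enough
  survive per locus.
* `fraction_snps_within(positions, d)` — nearest-neighbour clustering of
  SNPs. Clustered SNPs are good news for a k-mer method: they concentrate
  damage in fewer words.
* `window_scan(track, window = 500, step = 250, k = 16, min_sites = 20)` —
  tiles the calibration scaffolds and counts, per window, the start
  positions whose 16 bp window is fully conserved (no SNP, no masked
  base). A window with fewer than 20 such sites (40 counting both strands)
  would risk being invisible to the method.
* `miss_probability(scan)` — with zero failing windows the scan only
  bounds the failure probability by `1/n_windows`, flagged `"bound"`;
  with failures it returns the point estimate.

Windows are tiled per scaffold from position 0 and a final partial window
is dropped; this makes `n_windows` deterministic and keeps windows from
spanning scaffold boundaries. "Within d of each other" is interpreted as
nearest-neighbour distance ≤ d; a symmetric-pair interpretation differs
only at run edges.

## The k-mer core

K-mers are stored canonically (the lexicographic minimum of a word and its
reverse complement), packed 2 bits/base into a double-representable code,
which caps k at 26; counting is a small C++ routine. Windows containing N
are skipped, not substituted. Counts saturate at 2^32 − 1 and saturation
is flagged.

**Error cutoff.** Read k-mer histograms are bimodal: an error spike at
multiplicity 1-2 and a coverage peak near the sample's k-mer depth.
`select_error_cutoff()` takes the first minimum between 1 and the main
coverage peak, clamped to [3, 15] — the working range for the 20-90x
genomes this workflow targets. A histogram with no peak above multiplicity
2 signals insufficient coverage and is an error, not a silent guess. The
clamp floor matters: hemizygous k-mers sit at *half* the autosomal depth,
and an aggressive cutoff eats the left tail of their Poisson distribution
before it costs anything on diploid loci.

**Subtraction.** `sex_specific_set()` keeps k-mers at/above the cutoff in
the focal sex and below `opposite_presence_min` in the opposite sex of the
same species. The default `opposite_presence_min = 1` is strict absence,
matching the "absent from all" construction; 2 tolerates isolated
opposite-sex sequencing errors. The opposite-sex table is used unfiltered
(whether the original workflow filtered it first is not documented; both
are supported, unfiltered is the default).

**Survival and intersection.** `survival_curve()` counts k-mers
sex-specific in ≥ n species. Under male heterogamety the male curve
plateaus at the conserved Y core while the female curve decays to zero —
the package's primary qualitative diagnostic. The default is order-free
(the species ordering of a cumulative intersection is arbitrary); a
fixed-order mode is available behind `ordered = TRUE`.
`genus_conserved_set()` intersects the male sets, then vetoes any k-mer
present in any female table — including females of species with no male
sample, which still carry veto power.

## What the synthetic genus emulates

`genus_model()` + `simulate_genus()` generate the stated world every
downstream test runs against:

* n species (default 6) on a rooted tree; with no tree supplied, a ladder
  ("left") topology with unit branches is used and rescaled by
  `calibrate_tree_to_snp_rate()` so the *mean* pairwise male-male per-bp
  difference equals `snp_rate_target` (default 1/16.5). The rescaling is
  exact under the generator's site-wise substitution model, including the
  two per-individual heterozygosity layers.
* Diploid samples: a 200 kb autosome (default), a 10 kb X/Y-shared
  region, and Y-specific blocks (default one of 5 kb) carried once by
  every male, zero times by every female. Blocks are inserted at the
  midpoint of the X/Y region so they sit in chromosomal context: a block
  at a sequence end would be under-covered by uniformly placed reads, an
  artifact no real embedded sex-linked region shows.
* Within-species polymorphism at `het_rate` (default 1e-3 per haplotype)
  on every haplotype. Without it no female-private variation exists and
  the female survival curve could never decay, silencing the method's key
  negative control.
* Optional extras: blocks deleted from the X only (the X-deletion route
  to hemizygosity), a single exact tandem repeat filling
  `repeat_fraction` of the autosome with its mask exported, an SNP
  clustering knob (`snp_cluster_frac`, default off) implemented as
  anchor+companion pairs ≤ 16 bp apart so the knob approximates the
  recovered nearest-neighbour fraction, and a hermaphrodite outgroup
  control carrying *two* copies of the Y blocks for the 2N depth
  contrast.
* Ground truth by exhaustive enumeration: per species, the k-mers in the
  male genome and in no female genome of the genus; the genus set is
  their intersection. Planted coordinates are exported as BED (0-based
  half-open everywhere).

`simulate_reads()` draws uniform fixed-length reads (default 100 bp, 30x,
0.5% i.i.d. substitution error, fixed Q40 qualities). Coverage means
per-base *sample* depth: each haplotype of a diploid sample at
`coverage/2`, so hemizygous loci sit at half depth — which is exactly the
signal the copy-number stage reads out. Paired mode draws both ends of
~400 bp fragments. What the generator does **not** emulate: position- or
motif-dependent error profiles, quality ramps, indels, GC bias,
structural variation beyond the planted blocks, and coverage at sequence
termini (the last `read_length − 1` bases of a linear sequence ramp down
— regions of interest belong in the interior). A green test therefore
establishes correctness of the pipeline's logic under idealized noise,
not robustness to platform artifacts.

## Localization and copy number

`match_kmers()` reports every exact occurrence of the query k-mers on
both strands of a contig set; conserved k-mers are exact by construction,
so there is no approximate matching to blur the contract.
`coverage_percent()` gives the fraction of the ≥ n-species sets hit by a
contig collection; `density_track()` produces the k-mers/bp matrix
stratified by species support, whose rows are non-increasing across
support thresholds by construction. `select_haplotype_scaffolds()` applies
the phased-assembly rule — at least 100 male-specific k-mers and a ≥ 6x
imbalance between haplotypes; k-mers hitting both haplotypes count once
per haplotype, and exact ties are rejected (neither haplotype dominates)
and logged.

Copy number is computed alignment-free: `kmer_region_depth()` is the mean
per-position count of the sample's canonical k-mers along a region, in
units of k-mer coverage (`depth × (read_length − k + 1)/read_length`);
the unit cancels against a baseline computed the same way. The baseline
is the *median* of control-region depths (robust to a high-copy repeat
slipping into the controls), `copies_raw = 2 × depth / baseline`, and
integer calls use half-integer band boundaries ([0.5, 1.5) → 1). Regions
under 200 bp are flagged low-confidence rather than trusted. Expression
normalization divides a feature's fragments/kb by a non-sex-linked
control scaffold's fragments/kb.

## Substitution rates

`ng86()` implements the counting estimator of synonymous and
nonsynonymous divergence: fractional site counts per codon position,
pathway-averaged difference counts (1, 2 or 6 orderings), proportions
`pS = Σsd / S̄` with pair-averaged sites, and the Jukes-Cantor correction
`d = −3/4 ln(1 − 4p/3)`. Conventions, fixed and tested:

* Substitutions creating stop codons are excluded from the site
  denominators, and pathways through stops are excluded from the average
  (falling back to all pathways only when every one is excluded). Under
  this convention each position keeps site weight 1, so
  `S + N = 3 × codons` exactly.
* `p ≥ 3/4` is reported as saturated with an `NA` rate — never clipped. A
  single-codon GAT/GAC "alignment" saturates (`pS = 3`), a deliberate
  illustration of small-sample breakdown.
* Codon columns containing any gap or ambiguity are dropped whole before
  counting (reference implementations vary by version; this rule is
  fixed and documented). Universal genetic code; the table is internal
  but the machinery is code-table-driven.
* `gene_summary()` reports per-species rates against a designated
  outgroup with mean and sample (n−1) SD; ω is summarized over species
  with defined dS > 0. Species-vs-outgroup pairwise rates are the default
  mode; branch-based rates would require ancestral reconstruction, which
  is out of scope.

`relative_clade_depth()` gives the age of a clade's MRCA as a fraction of
the root age on an ultrametric tree — the "how far back did this gene
become sex-linked" statistic — with explicit monophyly and ultrametricity
checks.

`simulate_codon_alignment()` evolves a stop-free ancestor to an outgroup
and n species by sequential point proposals: synonymous changes always
accepted, nonsynonymous with probability ω, stops never. This is the
generating process whose acceptance ratio the estimator targets, so
parameter recovery (ω = 0.2 recovered within ±0.05 at 500 codons, 10
species) is a genuine closed loop, not a self-comparison: the test suite
additionally checks the estimator against a second, independently coded
implementation to 1e-12.

## Numerical and design choices

* k ≤ 26 so packed codes are exact doubles; k = 16 is the default and the
  calibrated choice at 1/16.5 bp divergence.
* All randomness flows through per-stage seeds derived from one root seed
  (`run_pipeline()`), so stage-level reruns are stable and a rerun with
  the same seed is byte-identical.
* The histogram valley, not a fixed multiplier of coverage, picks the
  error cutoff; with the package defaults (30x, 0.5% error) the valley
  lands at 3-4, which preserves ≥ 99% of hemizygous-depth k-mers per
  sample.
* Degenerate inputs fail loudly: empty histograms, saturated rate
  corrections, non-monophyletic clades, reference-base mismatches in
  consensus substitution (stale coordinates), FASTQ record structure.

## Known limitations

* Pure R + small C++ core: counting is comfortable to ~10^8 k-mer
  instances; it is not a disk-backed counter for ~10^9-scale genomes.
* Exact matching only; a conserved k-mer destroyed by a private SNP in
  the assembly used for localization is simply not matched.
* The simulator's idealized noise model (above).
* Copy-number depth is exact-k-mer based; highly repetitive regions
  inflate both signal and baseline and are better masked first.
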