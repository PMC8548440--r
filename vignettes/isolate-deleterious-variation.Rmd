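---
title: "Methods: deleterious exome variation in a recently isolated population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deleterious exome variation in a recently isolated population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

When a small population passes a recent bottleneck and practices
consanguinity, drift overwhelms selection: purifying selection is
relaxed, deleterious alleles that would stay rare in a large panmictic
population drift to intermediate frequency, and autozygosity exposes
recessive variants as homozygous derived genotypes. `isodist`
implements the summary statistics by which this signature is read from
a two-population exome design — an isolate against a larger reference —
together with a generator that simulates the contrast so every stage
can be verified without access to controlled human data.

# Data model

All analyses run on a polarized **genotype matrix** (samples x sites of
derived-allele dosages 0/1/2/NA) plus a **site table** carrying the
annotation consumed as input columns: ancestral allele, gene symbol,
consequence label (synonymous / missense / other), a GERP RS
conservation score, and optional CADD and PolyPhen categories. Scores
are inputs, never retrieved from services. A panel file maps samples to
populations.

Variant-level QC mirrors standard exome practice: per-genotype masking
below 5x depth or GQ 20 (skipped, and flagged, when the VCF lacks
DP/GQ), then removal of sites that are monomorphic dataset-wide, exceed
5% missingness, or fail an exact Hardy–Weinberg test at p < 1e-3 in at
least one panel population. The exact (enumeration) test is used rather
than the chi-square approximation because per-population sizes here are
small (8–50 diploids); the test is exposed as `hwe_exact_test()`.
Sample-level QC removes samples above 10% missingness or with
heterozygosity outside 4 SD of their population mean; a zero-SD
population flags no outliers. Genotype masking happens *before* the
missingness and HWE evaluations, mirroring the usual filter sequence.

Polarization keeps only sites with a known ancestral allele equal to
REF or ALT; ALT-ancestral sites have dosages flipped (d to 2 - d).
Ancestral alleles matching neither allele are conservatively dropped
and counted. Positions are 1-based VCF coordinates throughout.

# Statistics

**Diversity.** Per-site pairwise diversity uses the unbiased estimator
2c(2n-c) / (2n(2n-1)) with `c` the derived count and `2n` the
*non-missing* haplotype count at the site (per-site adjustment is the
standard unbiased choice under low missingness). Watterson's theta is
S/a1 with a1 the harmonic number over 2n-1 using the population's full
diploid count (a single global a1; per-site adjustment can be had by
masking). pi-var — mean per-variable-site heterozygosity — moves
*opposite* to theta-pi under drift: fewer segregating sites, each more
intermediate. Tajima's D uses the classical variance constants.
"Segregating sites carried per individual" is interpreted as the count
of segregating sites at which the individual carries at least one
derived allele; the definition is operational and kept in one place
(`segregating_site_summaries()`).

**Block bootstrap.** Sites in genomic order are cut into 1000
contiguous near-equal blocks; each replicate resamples 1000 blocks with
replacement. Intervals are the 0.025/0.975 replicate quantiles; a
two-sided p for a ratio is twice the smaller tail around 1. Resampling
blocks rather than sites keeps linked stretches together and so carries
demographic variance into the interval.

**Unfolded SFS.** Spectra are built on a seeded subsample of 8
individuals (18 for the two-population density test), drop sites with
any missing genotype in the subsample, remove the two fixed bins, and
normalize. Deleteriousness classes partition the score line with
left-closed intervals: neutral (< 2), moderate [2, 4), large [4, 6),
extreme (>= 6); PolyPhen uses the predictor's labels without "unknown";
CADD uses a configurable phred cut. The density-difference test
bootstraps individuals (1000 replicates at full scale), records
per-bin density differences over the first 10 bins, and compares
sequential classes by Welch t-tests on both the absolute and the signed
replicate summaries. The absolute version is the directional question
(does distortion grow with deleteriousness?); the signed version is the
calibrated null check, since absolute differences have class-size
dependent noise floors. Low-frequency (singletons + doubletons) versus
common (tripletons and up) proportions among deleterious segregating
sites get Wald 95% intervals, clipped to [0, 1].

**Load.** Per-individual burdens are N_alleles (summed derived dosage;
additive) and N_hom (homozygous-derived count; recessive). Population
contrasts are ratios of per-individual means over a category's sites,
with block-bootstrap intervals and p-values, significance
conventionally at p < 0.001; an optional consequence filter intersects
deleterious categories with missense sites and the neutral category
with synonymous sites. The selection-coefficient load assigns each
deleterious class a coefficient (4.5e-4, 4.5e-3, 1e-2 for moderate,
large, extreme), computes per-site load 2q(1-q)sh + sq^2 from the
population's derived frequency with h = 0.5 (additive) or 0
(recessive), and sums within classes. The neutral class has no
coefficient and is excluded.

**ROHs.** Sites are first LD-pruned (greedy left-to-right, 50-kb
windows advancing 5 SNPs, removing the later site of any pair with
dosage r^2 > 0.8). A run of homozygosity is a maximal run of
consecutive non-missing homozygous calls with zero heterozygotes, at
least 50 SNPs, spanning at least 1 Mb, split wherever consecutive SNPs
are over 1 Mb apart. With zero tolerated heterozygotes, sliding-window
calling reduces to maximal-run calling, which is what is implemented;
missing-call tolerance is exposed as a parameter but defaults to
strict. Lengths are end - start + 1 (inclusive); classes 1–2.5, 2.5–5
and > 5 Mb separate background from recent autozygosity. The
deleterious exposure of ROHs is the per-individual ratio of missense
homozygous-derived genotypes (by deleterious class) to synonymous
neutral homozygous-derived genotypes, inside versus outside ROH
regions, compared by paired t-tests.

**Differentiation and enrichment.** Per-site Fst is the two-population
Weir–Cockerham variance-component estimator including the observed-
heterozygosity term; monomorphic-in-both sites are undefined (NA),
never zero, and are excluded before quantiles. Mean pairwise Fst is the
ratio of summed components. Candidate subsets follow a fixed cascade —
missense, then deleteriousness category (three score classes, two
damaging PolyPhen labels), then the top 5% of that subset's own Fst
distribution (ties at the threshold kept), a sixth subset merging the
five before its own top-5% cut, and finally a strict derived-frequency
excess in the target population. Genes come from the annotation's gene
column only. Over-representation uses the hypergeometric upper tail
against the dataset's own gene universe with BH-FDR; tiers are FDR <
0.05, then p < 0.05 with enrichment ratio above the mean ratio of the
tested sets, then remaining p < 0.05. The "mean ratio" is taken over
tested sets (the configurable alternative being all catalog sets). The
catalog-bootstrap mode draws 1000 random gene lists of matched size,
flags traits whose observed count reaches their Q95, and supports both
the catalog's genes and the dataset universe as the source pool. Fst
peaks chain top-1% sites within 10 kb by single linkage, with pairwise
dosage r^2 reported.

# The generator

The study's real data are controlled-access; the generator therefore
*emulates the demographic contrast*, not the dataset. Ancestral derived
frequencies follow the neutral-equilibrium 1/i law on a 100-haplotype
grid; deleteriousness classes (mixture 0.63/0.25/0.09/0.03) are
down-weighted in frequency deterministically by 1/(1 + C s) with
C = 1000, giving mean reference frequencies that decrease from neutral
to extreme — selection is a frequency prior, not forward simulation,
to keep desk-scale runtime. The isolate's frequencies drift through a
binomial Wright–Fisher bottleneck (25 diploids for 40 generations by
default, removing about 55% of heterozygosity, the closed form
1 - (1 - 1/2N)^g). Isolate genotypes add explicit autozygous tracts:
alternating exponential tracts (mean 2.5 Mb) and gaps sized so tracts
cover an expected fraction f = 0.125 of each chromosome; inside a tract
the genotype is homozygous for a single allele draw, outside it is
binomial. Tract placement (rather than pedigree simulation) makes ROH
ground truth exact. Sample sizes default to 18 isolate vs 46 reference
diploids, matching the cohort sizes this design targets, on eight 25-Mb
chromosomes with 40,000 SNPs (about 200 SNPs/Mb, comfortably above the
density at which tract recovery is reliable). A planted high-drift
missense region (30 extreme-class sites across three gene symbols with
a +0.5 isolate frequency shift) exercises the candidate-subset and
enrichment stages end to end. Identical parameters and seed give
byte-identical files.

What the generator does *not* emulate: recombination maps and realistic
LD (background sites are drawn independently, so LD pruning removes
almost nothing), sequencing error, batch effects, or forward-in-time
selection. Passing tests therefore demonstrate correctness of the
statistics and the direction of demographic contrasts, not performance
on real exomes.

# Numerical choices and verification sizes

Bootstrap replicate counts default to the conventional 1000 x 1000 but
every stage exposes them; the package's own verification runs use 100
blocks x 200 replicates for calibration trials (200 replicates because
0.025/0.975 quantiles are noisy below that) and 1000 x 200 on the full
scenario. Null calibration uses 100 exchangeable-population trials of
1500 sites and 15 + 15 diploids for load-ratio interval coverage, 30
trials for the SFS sequential tests (on a population against itself,
where the resampling distribution is exchangeable), split-half
comparisons of one inbred group for ROH tests, and 100 random-query
meta-trials for the catalog bootstrap. The contrast scenario is
verified at the generator defaults above. Degenerate inputs follow
fixed rules: all-missing frequencies are NA (never zero), zero
denominators in ratios are NA and excluded from tests with a count,
zero-SD heterozygosity flags no one, and constant bootstrap statistics
give zero-width intervals.

# Worked example

```{r example}
library(isodist)

sim <- simulate_scenario(scenario_params(seed = 1), "scenario")
sc <- load_scenario(sim$paths)

syn <- mask_synonymous(sc$sites)
diversity_bootstrap(sc$gm, sc$panel, c("ISO", "REF"),
                    site_mask = syn, n_reps = 200, seed = 2)

load_ratio(sc$gm, sc$panel, "ISO", "REF", model = "recessive",
           n_reps = 200, seed = 3)
```

# Known limitations

The simulator's independence between sites understates the value of LD
pruning and block bootstrapping relative to real exomes. Partially
missing diploid calls are treated as missing genotypes. The Fst
estimator is the two-population form; multi-population designs must be
analysed pairwise. ROH detection assumes reasonably uniform SNP
density; exomes with large capture gaps should lower `max_gap` rather
than rely on the default 1 Mb.
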