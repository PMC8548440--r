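# isodist

Quantifying how recent isolation, genetic drift and inbreeding reshape
the distribution of putatively deleterious exome variation, in a
two-population design: a small isolate against a larger panmictic
reference.

## Who this is for

Population geneticists working with multi-sample exome VCFs of a
recently isolated (bottlenecked, consanguineous) cohort and a reference
cohort, who want the standard battery of drift-and-load summary
statistics with honest resampling inference — and a simulator of the
same demographic contrast so the whole pipeline can be validated
without controlled-access data.

## What it computes

Given a VCF, a sample→population panel, and a per-site annotation table
(ancestral allele, gene, consequence, GERP RS / CADD / PolyPhen
scores):

- **Variant store** — QC filtering (per-genotype DP/GQ masking,
  monomorphic / missingness / exact Hardy–Weinberg site filters, sample
  missingness and heterozygosity outliers) and polarization to derived
  allele dosages *q*.
- **Diversity** — θπ (per-site 2c(2n−c)/(2n(2n−1))), Watterson's θw =
  S/a₁, per-variable-site πvar, Tajima's D, segregating and private
  site counts, all with block-bootstrap 95% intervals (1000 contiguous
  blocks resampled 1000 times).
- **Unfolded SFS** — thinned spectra per deleteriousness class
  (neutral GERP < 2, moderate [2,4), large [4,6), extreme ≥ 6), a
  bootstrap density-difference test across classes, and
  low-frequency-vs-common deleterious proportions with Wald intervals.
- **Mutational load** — per-individual N_alleles (additive) and N_hom
  (recessive) burdens, between-population ratios with block-bootstrap
  p-values, and the selection-coefficient load 2q(1−q)sh + sq² with
  s ∈ {4.5e−4, 4.5e−3, 1e−2} per GERP class and h = 0.5 / 0.
- **ROHs** — LD pruning, runs of ≥50 consecutive homozygous SNPs
  spanning ≥1 Mb, length-class summaries (1–2.5 / 2.5–5 / >5 Mb), and
  missense/synonymous homozygote ratios inside vs outside ROHs.
- **Differentiation & enrichment** — per-site Weir–Cockerham Fst,
  high-Fst missense candidate subsets (top 5% per deleteriousness
  class, target-population frequency excess), hypergeometric ORA with
  FDR tiers, a Q95 catalog-bootstrap null, Fst peak chaining and LD r².
- **Simulator** — a two-population scenario with a 1/i ancestral
  frequency law, class-dependent frequency down-weighting, a binomial
  Wright–Fisher bottleneck, explicit autozygous tracts (exact ROH
  truth), and a planted high-drift missense gene region; deterministic
  given a seed.

## Worked example

```r
library(isodist)

sim <- simulate_scenario(scenario_params(seed = 1), "scenario")
sc  <- load_scenario(sim$paths)      # read VCF, annotate, polarize

syn <- mask_synonymous(sc$sites)
diversity_bootstrap(sc$gm, sc$panel, c("ISO", "REF"),
                    site_mask = syn, n_reps = 200, seed = 2)
#>   population statistic  estimate        lo        hi
#> 1        ISO  theta_pi 1895.0968 1845.7331 1943.2062
#> 2        ISO   theta_w 1281.4758 1250.6085 1311.3845
#> 3        ISO    pi_var    0.3566    0.3525    0.3604
#> 4        ISO tajimas_d    1.8288    1.7640    1.8878
#> 5        REF  theta_pi 4245.6567 4194.9311 4297.3181
#> 6        REF   theta_w 3944.7855 3928.8683 3961.2867
#> 7        REF    pi_var    0.2113    0.2090    0.2135
#> 8        REF tajimas_d    0.2627    0.2219    0.3014

load_ratio(sc$gm, sc$panel, "ISO", "REF", model = "recessive",
           n_reps = 200, seed = 3)
#> estimate 1.73739  [1.70038, 1.77081]  (200 reps, p = 0)
load_ratio(sc$gm, sc$panel, "ISO", "REF", model = "additive",
           n_reps = 200, seed = 3)
#> estimate 1.00209  [0.988429, 1.01565]  (200 reps, p = 0.72)
```

The isolate shows the textbook signature: lower synonymous θπ and θw
with non-overlapping intervals, *higher* per-variable-site diversity
(drifted sites sit at more intermediate frequency), strongly positive
Tajima's D, a 1.74× excess of homozygous derived genotypes under the
recessive model while the additive derived-allele burden stays at 1.00
— drift and autozygosity change how deleterious variation is packaged
into genotypes, not how much of it each genome carries.

A full run (QC → diversity → SFS → load → ROH → Fst/enrichment, every
table written with a manifest) is one call:

```r
run_pipeline(list(simulate = list(), target = "ISO", reference = "REF",
                  seed = 7, out = "run1"))
```

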