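Package: isodist
Title: Distribution of Deleterious Exome Variation in Isolated Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how recent isolation, genetic drift and
    inbreeding reshape the distribution of putatively deleterious exome
    variation in a two-population design (an isolate against a larger
    panmictic reference). Implements variant-level quality control and
    ancestral-allele polarization of multi-sample VCFs; unfolded site
    frequency spectra by deleteriousness class with bootstrap
    density-difference tests; nucleotide diversity, Watterson's theta and
    Tajima's D with block-bootstrap confidence intervals; per-individual
    derived-allele and homozygote burdens and population load ratios; a
    selection-coefficient load based on conservation-score categories;
    runs-of-homozygosity detection with ROH-conditioned homozygote ratios;
    per-site Weir-Cockerham Fst, candidate-subset construction, gene-set
    over-representation and bootstrap-null enrichment; and a deterministic
    two-population simulator that emulates the bottleneck-plus-inbreeding
    contrast so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
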