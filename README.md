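# medapop

Population-genomic characterization of wild medaka (*Oryzias latipes*)
founder panels and inbred strains, as an R package.

Establishing a near-isogenic panel from a wild population requires
knowing, before years of inbreeding are invested, that the founder
population is genetically suitable: free of strong substructure
(inbreeding coefficient *F* near zero), with LD that decays fast enough
for fine mapping, with interpretable patterns of coding variation and
selection, and without cryptic interbreeding with diverged populations.
medapop implements the full set of computations used to make that
assessment from resequencing data:

* **Reference patching** — single-base revision of an assembly from
  deep-coverage consensus calls (`N`-fill always; discrepant-base
  revision at a quality threshold, default 100), with concordance and
  ancestral-consistency validation metrics.
* **Diversity and inbreeding** — windowed heterozygosity profiles and
  block classification, *F* = 1 − H<sub>OBS</sub>/H<sub>EXP</sub> per
  locus, divergent-site heterozygote fractions, monoallelic fractions.
* **Coding effects** — strand/frame-aware SNP classification
  (nonsense > stop-loss > missense > synonymous across overlapping
  transcripts), codon-enumeration expected class fractions, and exact
  one-sided binomial depletion tests computed in log space.
* **LD** — r², D′ and LOD from phased haplotypes, windowed decay
  summaries with an explicit plateau rule, Gabriel confidence-interval
  haplotype blocks, and gene/exon co-localization of high-LD pairs.
* **Selection scans** — EHH, integrated haplotype scores
  iHS = ln(iHH<sub>A</sub>/iHH<sub>D</sub>) standardized within
  derived-allele-frequency bins, the composite windowed filter for sweep
  regions, and permutation enrichment in conserved intervals.
* **Introgression** — frequency-weighted ABBA–BABA D statistics with
  block-jackknife Z scores and a ghost-population control that restricts
  to sister-differentiating sites.
* **Phylogenetics and mitotyping** — Kimura two-parameter distances with
  saturation flags, neighbor-joining with midpoint rooting, majority-vote
  consensus, Gower clustering of genotypes, in-silico PCR, restriction
  digestion and RFLP mitotype assignment, D-loop sequence typing.
* **Demography and heritability** — parsing and scaling of PSMC output
  (years and diploid Ne from θ₀, μ and generation time), log₁₀-binned
  multi-individual summaries, and broad-sense heritability
  H² = SS<sub>strain</sub>/SS<sub>total</sub> of body-length-normalized
  morphometric traits.
* **Synthetic data** — a built-in sequentially-Markov coalescent
  simulator plus generators for trios, selective sweeps, admixed
  quartets, inbred lines, microsatellite panels, morphometric tables and
  consensus call sets with planted truth, so every stage is testable
  offline.

Functions take data frames (or the package's light `haplotype_set` /
`genotype_table` containers) and return tibbles; result objects have
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`s.

## A worked example

Simulate a wild-like population, plant a sweep, and scan it:

```r
library(medapop)

cfg  <- sim_config(seed = 1, sequence_length = 6e5, n_haplotypes = 48)
wild <- simulate_neutral_population(cfg)
wild
#> <haplotype_set> 48 haplotypes (24 samples) x 3980 sites on chr1

swept <- inject_sweep(wild, position = 3e5, target_freq = 0.7,
                      tract_mean_bp = 1e5, seed = 2)
background <- ihs_scan(wild, sites = seq(1, n_sites(wild), by = 10))
core <- attr(swept, "core_site")
std  <- standardize_ihs(ihs_scan(swept, sites = core),
                        reference = background)
std$std_ihs
#> [1] -5.178884
```

A standardized iHS of −5.2 at the planted core (against a neutral
background centered on zero with unit variance) is the long-derived-
haplotype signature the composite filter turns into candidate sweep
regions.  The same session can test for interbreeding:

```r
quart <- simulate_admixture(cfg, f = 0.2, seed = 3)
freqs <- quartet_freqs(quart$P1, quart$P2, quart$P3, quart$O)
tidy(d_statistic(site_patterns(freqs), block_size_bp = 5e4))
#> # A tibble: 1 x 6
#>        d     se     z  abba  baba subset
#>    <dbl>  <dbl> <dbl> <dbl> <dbl> <chr>
#> 1 0.0946 0.0224  4.21  41.6  34.5 all sites
```

D = 0.095 with Z ≈ 4 correctly flags the 20% admixture pulse the
simulation planted; at f = 0 the same pipeline returns |Z| < 3.

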