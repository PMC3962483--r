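---
title: "Methods: population-genomic characterization of a wild medaka founder panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic characterization of a wild medaka founder panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medapop)
library(dplyr)
```

medapop re-implements, as reusable and tested functions, the analyses used
to characterize a wild medaka (*Oryzias latipes*) population intended to
found a near-isogenic line panel, together with the companion analyses of
existing inbred strains: reference-assembly patching, heterozygosity and
inbreeding statistics, coding-effect depletion tests, linkage-disequilibrium
(LD) decay and haplotype blocks, EHH/iHS selection scans, ABBA--BABA
introgression tests, distance-based phylogenetics and mitotyping,
post-processing of PSMC demographic inference, and broad-sense heritability
of morphometric traits.  Every stage can be exercised end to end on
synthetic data produced by the package's own simulators, so the scientific
claims encoded in the test suite are reproducible without any sequence
download.

This vignette explains the models and the choices behind them.  It states
no empirical result that the package's tests and `scripts/acceptance.R` do
not themselves compute.

## The synthetic-data generator

### Neutral coalescent backbone

`simulate_neutral_population()` draws phased haplotypes under the
sequentially Markov coalescent (SMC): the genealogy at the left end of the
chromosome is a Kingman tree; recombination breakpoints arrive along the
sequence at rate $2 N_e r T$ per bp ($T$ = total branch length in units of
$2N_e$ generations), and at each breakpoint a uniformly chosen branch point
is pruned and re-coalesced into the remaining tree.  Mutations follow the
infinite-sites model.  Two properties matter for testing:

* the *marginal* tree at any single position is exactly
  Kingman-distributed, so single-site expectations are exact — the number
  of segregating sites has mean $\theta L \sum_{i<n} 1/i$
  (`expected_segregating_sites()`) and the folded site-frequency spectrum
  follows the standard neutral form; both are asserted against simulation
  in the test suite;
* correlations between neighbouring trees decay with recombination
  distance, giving realistic LD decay (median $r^2$ decreasing in
  distance), which the LD tests check as a monotonicity property.

The SMC approximation affects only long-range tree correlations; no test
or analysis here depends on those beyond monotone decay.

Defaults are the study conditions of the wild population: mutation rate
$\mu = 2.5\times10^{-8}$ per bp per generation, diploid effective size
$N_e = 15{,}000$, so that nucleotide heterozygosity
$4N_e\mu = 1.5\times10^{-3}$ — the level seen in a wild catch, three
orders of magnitude above a fully inbred strain.  The recombination rate
defaults to $r=\mu$; the study itself provides no direct recombination
estimate, and $r \approx \mu$ puts the simulated LD scale in the
kilobase range where the observed decay lives.

### Scenario generators

* **Trios** (`simulate_trios()`): founders are paired; each offspring
  receives one recombinant gamete per parent (Poisson crossovers on the
  physical map).  Offspring are Mendelian-consistent by construction and
  `mendel_check()` verifies zero errors genome-wide.
* **Selective sweeps** (`inject_sweep()`): rather than a forward
  simulation, a template carrier haplotype is copied onto each other
  carrier over a shared tract whose one-sided length is exponential with
  mean `tract_mean_bp`.  This reproduces the footprint iHS detects: long,
  low-diversity haplotypes around the selected allele.  The default tract
  mean of 200 kb follows the classical approximation for the extent of
  hitch-hiking, $s/(r \ln 2N_e s)$, at $s = 0.04$; tests on 600-kb regions
  use 100 kb (the same formula at $s \approx 0.02$) so that the EHH curve
  decays to its cutoff inside the simulated region.  Carrier count is
  `round(freq * n)` with ties rounded towards more carriers.
* **Admixture quartets** (`simulate_admixture()`): a per-site
  allele-frequency model rather than a genealogical one — the root derived
  frequency follows a $1/x$ spectrum, frequencies drift along the
  population tree as Balding–Nichols beta draws ($F_{st}$ 0.05 on the
  sister branches, 0.3 to the donor), and a fraction $f$ of the test
  population's lineages is drawn from the donor.  $f=0$ gives
  $E[D]=0$ by exchangeability of P1 and P2; $D$ increases monotonically in
  $f$.  Frequencies are all the D statistic consumes, so this model is
  sufficient and fast.
* **Inbred lines** (`simulate_inbred_line()`): literal brother–sister
  mating with recombinant gametes.  Heterozygosity decays at the classical
  full-sib rate $\lambda = (1+\sqrt 5)/4 \approx 0.809$ per generation
  (verified as a recovery test with four distinguishable founder alleles,
  so identity-by-state equals identity-by-descent), and residual
  heterozygosity remains arranged in contiguous blocks, which the
  windowed-heterozygosity profiler detects.
* **Microsatellites** (`simulate_microsatellites()`): genotypes are a
  mixture of Hardy–Weinberg draws and forced homozygotes with mixture
  weight `target_F`, making the expected inbreeding coefficient equal to
  the target by construction.
* **Morphometrics** (`simulate_morphometrics()`): lateral measures L1–L4
  and dorsal measures D1–D5 in pixels, with body lengths L4/D5 and ratio
  traits carrying a controlled between-strain variance fraction.
* **Consensus calls** (`simulate_consensus_calls()`): plants unresolved
  (`N`) and discrepant reference positions with qualities and keeps the
  truth table, the oracle for patch-recovery tests.

What passing tests show — and do not show.  The generators emulate the
*statistical* structure the analyses assume (drift, recombination,
pedigree transmission, inbreeding decay, admixture asymmetry).  They do
not emulate sequencing error, alignment artifacts, genotype-caller bias,
reference bias, or gene conversion; agreement on synthetic data therefore
validates the estimators, not the robustness of any upstream calling
pipeline.

## Reference patching

`patch_reference()` revises single bases of a reference from
deep-coverage consensus calls: `N` positions with a defined call are
always filled; discrepant positions are revised only at quality ≥ 100 in
thresholded mode and unconditionally in unthresholded mode.  Ambiguous
(two-base) consensus calls never revise — validation work on such sites
shows they frequently carry traces of both sequences, so ambiguity maps
to "no revision".  Validation metrics: concordance of revised bases with
an independent genotype panel (all-samples and any-sample fractions) and
the fold change in agreement with an outgroup-defined ancestral base
(`ancestral_consistency_fold()`, with a guarded zero denominator).
`supplement_from_strains()` fills positions that remain undefined when at
least `min_strains_agreeing` strain consensus sets agree (default: all of
them).  Patching is idempotent and length-preserving; unthresholded
records are a superset of thresholded ones.

## Heterozygosity, blocks and F

`window_heterozygosity()` counts heterozygous genotypes per window
(default 50 kb, non-overlapping — a scale that resolves wild-origin
blocks in inbred genomes; the window size is not prescribed by the study
and is configurable).  `derive_het_threshold()` returns the
$(1-q)$ quantile of window values so that a fraction $q$ (default 0.9) of
wild-genome windows classify as heterozygous; the quantile is taken over
windows, not bases.  `classify_het_blocks()` merges maximal runs of
windows strictly above threshold.

`inbreeding_coefficient()` implements $F = 1 - H_{OBS}/H_{EXP}$ with
$H_{EXP} = 1-\sum_i p_i^2$ from sample allele frequencies — deliberately
without small-sample correction, matching the stated formula.  Missing
genotypes leave both numerator and denominator; monomorphic loci are
reported as undefined rather than zero.  Negative $F$ (excess
heterozygosity) is meaningful and preserved.

## Coding effects

`classify_snp()` rebuilds the affected codon from the reference
(strand- and frame-aware across multi-exon CDS), applies the substitution
and compares amino acids; classes are nonsense (sense→stop), stop-codon
(stop→sense, i.e. stop-loss; the class exists even though such changes
may be absent from a dataset), missense and synonymous.  Overlapping
transcripts resolve to the most severe class in that order.
`expected_class_fractions()` enumerates all nine single-nucleotide
substitutions of every codon and averages class indicators weighted by
codon frequency.  By default stop codons are excluded from the weighting,
because codon frequencies measured on coding sequence describe sense
codons; a flag includes them, in which case the uniform-usage expectation
equals a brute-force enumeration over all $64\times9 = 576$
substitutions (asserted in the acceptance suite).  The depletion test is
a one-sided exact binomial computed in log space, so astronomically small
tail probabilities still report a finite $\log_{10} p$.

## Linkage disequilibrium

`pair_ld()` counts gamete frequencies directly from phased haplotypes:
$D = p_{AB} - p_A p_B$, $r^2 = D^2/(p_A(1-p_A)p_B(1-p_B))$, $D'$ with the
sign-appropriate bound, and a LOD from the likelihood ratio against
independence.  `ld_scan()` is its vectorized all-pairs form with a pair
window (default 50 kb) and an $r^2$ floor (default 0.001), mirroring
common LD-scan options.  `ld_decay_summary()` bins pairs by distance and
reports the median $r^2$ per bin; the decay "plateau" is defined
explicitly as the first bin whose median is within 5% of the median over
the last ten bins — a documented stand-in for what is otherwise a visual
judgement.

`gabriel_blocks()` implements the confidence-interval block definition:
the likelihood of the four gamete counts is profiled over $|D'|$ on a
0.001 grid (allele frequencies fixed at their MLEs), the normalized
likelihood is read as a density, and the 5th/95th percentiles form the
CI.  A pair is in strong LD when the CI is within [0.70, 1] with upper
bound ≥ 0.98; strong evidence of recombination when the upper bound is
< 0.90.  Blocks are maximal spans whose bounding pair is in strong LD and
in which ≥ 95% of informative pairs are strong-LD, assigned longest-first
without overlap.  Markers below 5% MAF never enter.  Block span is
counted first-to-last marker inclusive of one bp at each marker.

## EHH, iHS and the composite filter

`ehh()` computes, at each flanking site, the probability that two random
carrier chromosomes are identical from the core to that site,
$\sum_h \binom{n_h}{2} / \binom{n_c}{2}$; the walk refactorizes haplotype
group labels at each step (no integer overflow) and skips columns that
are constant among carriers.  `ihs_unstandardized()` integrates each
allele's EHH curve by trapezoid over physical distance until the curve
crosses 0.05 (the final segment interpolated to the crossing), and takes
$\ln(iHH_A / iHH_D)$.  Curves that hit a chromosome edge before the
cutoff are flagged and excluded by default.  Physical distance is the
only map available here, so iHS is scale-invariant: doubling all
inter-site distances doubles both areas and cancels.

`standardize_ihs()` centers and scales within derived-allele-frequency
bins.  Bins are equal-count (frequency quantiles, default 20), as in the
original formulation; equal-width bins leave high-frequency bins nearly
empty at desk scale.  A `reference` scan may supply the bin moments —
this mirrors genome-wide practice, where standardization parameters come
from the overwhelmingly neutral genomic background; standardizing a
sweep-bearing region against itself inflates the bin variance with the
very signal being sought.

`composite_filter()` reproduces the published multi-condition filter: a
SNP passes when (1) its $|iHS|$ exceeds the top 0.05% quantile; within a
20-kb window centered on it (2a) the SD of iHS is below the median of
window SDs, (2b) at least 4 window SNPs reach 80% of the window maximum
$|iHS|$, and (2c) those SNPs are at least 10% of the window.  Only
negative-iHS SNPs (long derived haplotypes) are retained, and passing
SNPs within one window width merge into regions.  The source material
states the $|iHS|$ condition both as a numeric literal ("0.1") and as a
quantile ("top 0.05%"); these cannot both hold for a unit-variance
statistic, so the quantile reading is implemented (it generalizes to any
dataset) and the realized threshold is reported as an attribute.  The
merge distance for regions is likewise not stated and is set to one
window width, exposed as a parameter.

`conserved_enrichment()` compares the fraction of selected SNPs inside
conserved intervals with random equally-sized subsets of all tested SNPs
and uses the add-one permutation p-value estimator, so p is never zero.

## ABBA–BABA introgression

`site_patterns()` uses the frequency-weighted form: with derived-allele
frequencies $p_1,p_2,p_3$ and the outgroup fixed ancestral,
$ABBA = (1-p_1)p_2p_3$ and $BABA = p_1(1-p_2)p_3$; single genomes reduce
to 0/1 pattern counts.  `d_statistic()` reports
$D = (\sum ABBA - \sum BABA)/(\sum ABBA + \sum BABA)$ with a
leave-one-block-out jackknife SE over contiguous genomic blocks (default
1 Mb) and $Z = D/SE$ — the error model is this package's choice,
following standard practice for the test, since the source analysis
reports the test without one.  Fewer than five non-empty blocks withhold
the Z score.

`ghost_control()` addresses the artifact in which a population shows an
introgression signal only because a closely related sister sample truly
introgressed (or both inherited the alleles from a shared ancestor): it
restricts to sites whose test-panel frequency differs from the sister's
by more than a configurable floor (default: any difference) and
recomputes D.  Shared introgressed alleles have nearly equal frequencies
in test and sister, so they drop out; the constructed-truth test in the
suite demonstrates the naive signal and its elimination.

## Phylogenetics and mitotyping

`k2p_distance()` is the closed form
$-\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ over pairwise-complete
columns; non-positive log arguments flag the pair as saturated (the
situation with a distant outgroup) rather than producing a number.  It is
cross-checked against an independent K80 implementation.  Neighbor
joining and midpoint rooting are delegated to the standard tree packages
(ape, phangorn); negative NJ branch estimates are clamped to zero and
counted.  `majority_vote_consensus()` resolves exact ties (possible with
an even haplotype count) to the reference allele and flags them.
`gower_cluster()` encodes genotypes as alternate-dosages 0/1/2 and uses
the Gower dissimilarity with average-linkage agglomeration by default
(the distance, not the linkage, is prescribed; linkage is configurable).

`insilico_pcr()` amplifies between a forward primer and the reverse
complement of a reverse primer, honoring circular templates by searching
the doubled sequence; multiple or zero amplicons are errors.
`restriction_digest()` cuts at canonical offsets (HaeIII GG/CC, MboI
/GATC, MspI C/CGG, RsaI GT/AC, TaqI T/CGA); fragments always sum to the
amplicon length.  Mitotypes are equivalence classes of the five-enzyme
fragment patterns after binning lengths to 20 bp, emulating gel
resolution; published mitotype names belong to the typing literature and
are not reproduced — labels are pattern classes.  `dloop_typing()` trims
control-region sequences to 508 bp and collapses exact duplicates.

## Demography post-processing and heritability

`parse_psmc_output()` reads the final-round atomic intervals (scaled
times $t_k$, scaled sizes $\lambda_k$, and $\theta_0$) from PSMC text
output; the hidden-Markov inference itself is out of scope.
`scale_trajectory()` applies $N_0 = \theta_0/(4\mu s)$,
$N_e = \lambda N_0$, years $= 2N_0 t \cdot g$; the scaling is exactly
invertible.  The generation time $g$ is a *required* argument: the
organism literature supports both ~0.67 years and 1 year, and silently
preferring either would change every date by 50%.
`bin_and_combine()` samples each individual's step trajectory onto
$\log_{10}$-year bins of width 0.1 and summarizes the across-individual
distribution per bin (median and quartiles), which also answers the
pooled-versus-per-individual presentation question: both the binned
summary and the per-individual scaled series are available.

`broad_sense_heritability()` divides each measurement by its view's body
length (L1–L3 by L4, D1–D4 by D5), fits `aov(ratio ~ strain)` and
reports $H^2 = SS_{strain}/SS_{total}$ — the raw sum-of-squares ratio,
not an expected-mean-squares variance component, matching the stated
computation.  $H^2 \in [0,1]$ and is invariant to rescaling a view's
measurements.  Strains with one fish are excluded with a warning.

## Numerical choices and degenerate inputs

* Internal coordinates are the formats' native 1-based positions; BED
  boundaries convert to/from 0-based half-open at I/O only.
* Half-missing diploid genotypes are treated as fully missing
  (conservative, matches common caller semantics).
* Post-phasing filters use inclusive bounds (r² ≥ 0.6, error rate
  ≤ 0.1), applied per site; unannotated sites fail by default and can be
  configured to pass.
* Monomorphic sites: LD undefined (warned), F undefined, EHH requires
  two carriers per allele.
* The D' likelihood grid uses step 0.001; probabilities are floored at
  1e-12 before logs.
* Divisions that can be 0/0 (ancestral-consistency fold, D with zero
  total weight) are flagged or error rather than returning infinities.
* All simulators consume a single integer seed and are byte-reproducible.

## Problem sizes used by the test and acceptance suites

The suites run on desk-scale versions of the study conditions, chosen as
the smallest sizes at which the calibration properties are statistically
meaningful: Watterson and SFS checks on 10–8-haplotype, 5–20-kb
replicates (200 seeds); sweep power on 48 haplotypes over 600-kb regions
(100 seeds) standardized against a three-genome neutral background;
D-statistic calibration on 2-Mb frequency panels (200 seeds per
condition); F recovery at 105 individuals × 9 loci (200 seeds);
heritability at 6 strains × 80 fish (200 seeds).  Headline numbers from
the original deep-coverage data (genome-wide SNP counts, the 7.1e-4
heterozygosity threshold, the 712-bp mean block size, the 12.5-kb LD
plateau, the 192 selected SNPs) derive from ~125× whole-genome data and
are not reproducible at these scales; the suites instead verify the
estimators' exactness on oracles and their calibration on matched
synthetic conditions, and `scripts/acceptance.R` reports the synthetic
analogues it actually computes.

## Known limitations

* The SMC backbone approximates long-range genealogical correlations;
  quantities depending on them (e.g. exact joint distributions of
  distant trees) should not be read off these simulations.
* The admixture generator is a frequency model without linkage; it
  supports D-statistic inference but not haplotype-based admixture
  methods.
* `classify_snp()` requires the variant's reference allele to match the
  reference sequence and reports codons truncated at contig edges as
  unclassifiable rather than guessing.
* Gabriel block calling is quadratic in markers per region; it is meant
  for candidate regions, not chromosome-scale scans in one call.
* No genetic map support: iHS integrates over physical distance, as the
  available data imply.
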