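# Scenario generators layered on the neutral simulator: trios, selective
# sweeps, four-population admixture, inbred lines, microsatellite panels,
# morphometric tables and consensus call sets with planted truth.

# One meiotic gamete from a phased parent: crossovers are Poisson along the
# physical map, the starting chromatid is random.
meiosis_gamete <- function(h1, h2, pos, span, recombination_rate) {
  n_x <- rpois(1L, recombination_rate * span)
  start <- sample.int(2L, 1L)
  if (n_x == 0L) return(if (start == 1L) h1 else h2)
  brk <- sort(runif(n_x, 0, span))
  seg <- findInterval(pos, brk)          # 0..n_x, alternating chromatids
  use1 <- (seg + start) %% 2L == 1L
  out <- h2
  out[use1] <- h1[use1]
  out
}

#' Simulate mother-father-offspring trios
#'
#' Pairs up phased founders (1st with 2nd, 3rd with 4th, ...) and produces
#' one offspring per pair by simulating one recombinant gamete from each
#' parent.  Offspring are therefore Mendelian-consistent by construction,
#' which [mendel_check()] verifies.
#'
#' @param founders A phased [genotype_table()] (or [haplotype_set()]) with at
#'   least `2 * n_trios` samples.
#' @param n_trios Number of trios to form.
#' @param recombination_rate Per-bp, per-generation crossover rate.
#' @param seed Integer seed.
#' @return A list with `genotypes` (founders plus offspring, phased) and
#'   `pedigree` (tibble `child`, `father`, `mother`).
#' @export
simulate_trios <- function(founders, n_trios, recombination_rate = 2.5e-8, seed = 1L) {
  if (inherits(founders, "haplotype_set")) founders <- as_genotype_table(founders)
  stopifnot(inherits(founders, "genotype_table"))
  if (!founders$phased) abort("founders must be phased")
  nf <- length(founders$samples)
  if (nf %% 2L != 0L) abort("founder count must be even")
  if (nf < 2L * n_trios) abort("need at least 2 * n_trios founders")
  set.seed(seed)
  pos <- founders$sites$pos
  span <- max(pos) - min(pos) + 1
  kids_a1 <- matrix(NA_integer_, n_trios, nrow(founders$sites))
  kids_a2 <- kids_a1
  ped <- vector("list", n_trios)
  for (i in seq_len(n_trios)) {
    fa <- 2L * i - 1L; mo <- 2L * i
    kids_a1[i, ] <- meiosis_gamete(founders$a1[fa, ], founders$a2[fa, ], pos, span, recombination_rate)
    kids_a2[i, ] <- meiosis_gamete(founders$a1[mo, ], founders$a2[mo, ], pos, span, recombination_rate)
    ped[[i]] <- tibble(child = sprintf("O%02d", i),
                       father = founders$samples[fa],
                       mother = founders$samples[mo])
  }
  ped <- bind_rows(ped)
  gt <- genotype_table(
    founders$sites,
    a1 = rbind(founders$a1, kids_a1),
    a2 = rbind(founders$a2, kids_a2),
    samples = c(founders$samples, ped$child),
    phased = TRUE
  )
  list(genotypes = gt, pedigree = validate_pedigree(ped))
}

#' Plant a selective-sweep signature
#'
#' Marks `round(target_freq * n)` haplotypes (ties rounded towards more
#' carriers) as carriers of the derived allele at the core site, then copies
#' a template carrier haplotype onto every other carrier over a shared tract
#' whose one-sided length is exponential with mean `tract_mean_bp`.  This
#' reproduces the footprint that EHH/iHS detect -- long low-diversity
#' haplotypes around the selected allele -- without a forward simulation.
#' The default tract scale follows the classical sweep approximation
#' `s / (r * ln(2*N*s))` at `s = 0.04`, `N = 15000`, `r = 2.5e-8`
#' (about 200 kb), i.e. a strong recent sweep.
#'
#' @param haps A polarized `haplotype_set`.
#' @param position Target position in bp; the nearest segregating site is
#'   used as the core (created monomorphic-ancestral if absent).
#' @param target_freq Final derived-allele frequency in `[0, 1]`.
#' @param tract_mean_bp Mean one-sided shared-tract length (bp).
#' @param seed Integer seed.
#' @return The modified `haplotype_set`, with attributes `core_site` (site
#'   index) and `carriers` (haplotype indices).
#' @export
inject_sweep <- function(haps, position, target_freq, tract_mean_bp = 2e5, seed = 1L) {
  stopifnot(inherits(haps, "haplotype_set"))
  n <- n_haplotypes(haps)
  n_car <- as.integer(floor(target_freq * n + 0.5))   # ties toward more carriers
  if (target_freq < 0 || target_freq > 1) abort("target_freq must be in [0, 1]")
  if (n_car > n) abort("target frequency incompatible with sample size")
  set.seed(seed)
  core <- which.min(abs(haps$sites$pos - position))
  if (length(core) == 0L) abort("no sites available for the sweep core")
  dm <- haps$sites$anc[core]
  derived_val <- if (!is.na(dm) && dm == "alt") 0L else 1L
  carriers <- sort(sample.int(n, n_car))
  haps$hap[, core] <- if (derived_val == 1L) 0L else 1L
  haps$hap[carriers, core] <- derived_val
  if (n_car >= 2L) {
    template <- carriers[1L]
    pos <- haps$sites$pos
    core_pos <- pos[core]
    for (h in carriers[-1L]) {
      left <- rexp(1L, 1 / tract_mean_bp)
      right <- rexp(1L, 1 / tract_mean_bp)
      in_tract <- pos >= core_pos - left & pos <= core_pos + right
      haps$hap[h, in_tract] <- haps$hap[template, in_tract]
    }
  }
  attr(haps, "core_site") <- core
  attr(haps, "carriers") <- carriers
  haps
}

#' Simulate a four-population quartet with optional admixture
#'
#' Generates haplotypes for an (((P1,P2),P3),O) quartet from a per-site
#' allele-frequency model: the root derived-allele frequency follows the
#' neutral spectrum, drifts along the P1/P2 and P3 branches
#' (Balding-Nichols beta drift with the stated F values), and a fraction
#' `f` of P2's lineages is drawn from P3's population.  The outgroup is
#' fixed for the ancestral allele at every emitted site, so all sites are
#' polarizable.
#'
#' @param config A [sim_config()]; `n_haplotypes` haplotypes are drawn per
#'   population and the site count follows `4*Ne*mu*L`.
#' @param f Admixture fraction from P3 into P2, in `[0, 1]`.
#' @param seed Integer seed.
#' @param f_sister Drift of P1 and P2 from their common ancestor.
#' @param f_donor Drift of the P3 population from the root.
#' @return Named list of four `haplotype_set`s: `P1`, `P2`, `P3`, `O`.
#' @export
simulate_admixture <- function(config, f, seed = 1L, f_sister = 0.05, f_donor = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  if (f < 0 || f > 1) abort("admixture fraction f must be in [0, 1]")
  set.seed(seed)
  n <- config$n_haplotypes
  m <- max(50L, round(4 * config$effective_size * config$mutation_rate *
                        config$sequence_length))
  # root derived frequency ~ 1/x spectrum truncated away from the boundaries
  lo <- 0.02; hi <- 0.98
  u <- runif(m)
  p0 <- lo * (hi / lo)^u
  bn <- function(p, fst) {
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    pmin(pmax(rbeta(length(p), a, b), 0), 1)
  }
  p_anc <- bn(p0, f_sister)          # shared P1/P2 ancestor
  p1 <- bn(p_anc, f_sister)
  p2 <- bn(p_anc, f_sister)
  p3 <- bn(p0, f_donor)
  pos <- sort(sample.int(config$sequence_length, m))
  draw_pop <- function(pv) matrix(rbinom(n * m, 1L, rep(pv, each = n)), n, m)
  h1 <- draw_pop(p1)
  h3 <- draw_pop(p3)
  h2 <- draw_pop(p2)
  n_mig <- round(f * n)
  if (n_mig > 0) {
    mig <- sample.int(n, n_mig)
    h2[mig, ] <- matrix(rbinom(n_mig * m, 1L, rep(p3, each = n_mig)), n_mig, m)
  }
  ho <- matrix(0L, n, m)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "", USE.NAMES = FALSE)
  mk <- function(hm) {
    haplotype_set(tibble(chrom = config$chrom, pos = pos, ref = ref, alt = alt,
                         anc = "ref"), hm)
  }
  list(P1 = mk(h1), P2 = mk(h2), P3 = mk(h3), O = mk(ho))
}

#' Simulate an inbred line by brother-sister mating
#'
#' Starting from a founder pair, each generation mates one brother and one
#' sister (two offspring per generation), with recombinant gametes.
#' Heterozygosity decays towards the classical full-sib rate
#' `lambda = (1 + sqrt(5)) / 4` per generation, and residual heterozygosity
#' stays arranged in contiguous blocks, as seen in resequenced inbred
#' strains.
#'
#' @param founder A phased `genotype_table` with exactly two samples (the
#'   founding pair).
#' @param generations Number of brother-sister generations; `0` returns the
#'   founder unchanged.
#' @param recombination_rate Per-bp crossover rate.
#' @param seed Integer seed.
#' @return A phased `genotype_table` with the two individuals of the final
#'   generation.
#' @export
simulate_inbred_line <- function(founder, generations, recombination_rate = 2.5e-8,
                                 seed = 1L) {
  stopifnot(inherits(founder, "genotype_table"))
  if (length(founder$samples) != 2L) abort("founder must contain exactly two samples")
  if (!founder$phased) abort("founder must be phased")
  if (generations == 0L) return(founder)
  set.seed(seed)
  pos <- founder$sites$pos
  span <- if (length(pos)) max(pos) - min(pos) + 1 else 1
  a1 <- founder$a1; a2 <- founder$a2
  for (g in seq_len(generations)) {
    na1 <- a1; na2 <- a2
    for (k in 1:2) {
      na1[k, ] <- meiosis_gamete(a1[1L, ], a2[1L, ], pos, span, recombination_rate)
      na2[k, ] <- meiosis_gamete(a1[2L, ], a2[2L, ], pos, span, recombination_rate)
    }
    a1 <- na1; a2 <- na2
  }
  genotype_table(founder$sites, a1, a2,
                 samples = paste0(founder$samples, "_F", generations),
                 phased = TRUE)
}

#' Simulate a microsatellite genotype panel with a target inbreeding level
#'
#' Genotypes are a mixture of Hardy-Weinberg draws and forced homozygotes
#' with mixture weight `target_F`, which makes the expected inbreeding
#' coefficient equal to `target_F` per locus.
#'
#' @param n_loci,n_individuals Panel dimensions.
#' @param allele_counts Number of distinct alleles per locus (recycled).
#' @param target_F Expected inbreeding coefficient in `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble with columns `individual`, `locus`, `allele1`, `allele2`
#'   (allele lengths in bp).
#' @export
simulate_microsatellites <- function(n_loci = 9L, n_individuals = 105L,
                                     allele_counts = 8L, target_F = 0, seed = 1L) {
  if (target_F < 0 || target_F > 1) abort("target_F must be in [0, 1]")
  set.seed(seed)
  allele_counts <- rep_len(allele_counts, n_loci)
  out <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    k <- allele_counts[l]
    freq <- rexp(k) + 0.2
    freq <- freq / sum(freq)
    lens <- 100L + 2L * seq_len(k)     # dinucleotide ladder
    a1 <- sample(lens, n_individuals, replace = TRUE, prob = freq)
    a2 <- sample(lens, n_individuals, replace = TRUE, prob = freq)
    forced <- runif(n_individuals) < target_F
    a2[forced] <- a1[forced]
    out[[l]] <- tibble(individual = sprintf("I%03d", seq_len(n_individuals)),
                       locus = sprintf("MS%02d", l),
                       allele1 = pmin(a1, a2), allele2 = pmax(a1, a2))
  }
  bind_rows(out)
}

#' Simulate strain morphometrics with controlled heritability
#'
#' Emulates image-derived measurement tables: four lateral distances
#' (L1-L4, L4 = lateral body length) and five dorsal distances (D1-D5,
#' D5 = dorsal body length) in pixels.  Ratio traits (each measure over its
#' view's body length) get a between-strain variance fraction equal to
#' `trait_h2`.
#'
#' @param strains Strain labels (or a count).
#' @param n_per_strain Fish per strain.
#' @param trait_h2 Broad-sense heritability of the ratio traits, recycled
#'   over the seven ratio traits.
#' @param seed Integer seed.
#' @return Tibble with columns `strain`, `fish`, `L1`..`L4`, `D1`..`D5`.
#' @export
simulate_morphometrics <- function(strains = 6L, n_per_strain = 80L,
                                   trait_h2 = 0.4, seed = 1L) {
  if (is.numeric(strains) && length(strains) == 1L) {
    strains <- sprintf("strain%02d", seq_len(strains))
  }
  set.seed(seed)
  ns <- length(strains)
  n <- ns * n_per_strain
  strain <- rep(strains, each = n_per_strain)
  ratio_traits <- c("L1", "L2", "L3", "D1", "D2", "D3", "D4")
  h2 <- rep_len(trait_h2, length(ratio_traits))
  base_ratio <- c(L1 = 0.25, L2 = 0.45, L3 = 0.30, D1 = 0.15, D2 = 0.35,
                  D3 = 0.50, D4 = 0.25)
  cv <- 0.10                              # total sd of a ratio trait, relative
  body_l <- rnorm(n, 1000, 60)            # lateral body length, pixels
  body_d <- body_l * rnorm(n, 1, 0.01)    # dorsal view, near-perfect correlation
  out <- tibble(strain = strain, fish = sprintf("%s_f%03d", strain,
                                                rep(seq_len(n_per_strain), ns)),
                L4 = body_l, D5 = body_d)
  for (i in seq_along(ratio_traits)) {
    tr <- ratio_traits[i]
    sigma <- cv * base_ratio[[tr]]
    s_eff <- rnorm(ns, 0, sqrt(h2[i]) * sigma)[match(strain, strains)]
    ratio <- base_ratio[[tr]] + s_eff + rnorm(n, 0, sqrt(1 - h2[i]) * sigma)
    body <- if (startsWith(tr, "L")) body_l else body_d
    out[[tr]] <- pmax(ratio, 0.01) * body
  }
  out[, c("strain", "fish", "L1", "L2", "L3", "L4", "D1", "D2", "D3", "D4", "D5")]
}

#' Simulate deep-coverage consensus calls with planted truth
#'
#' Degrades a clean reference by planting `n_gaps` unresolved positions
#' (`N`) and `n_errors` discrepant positions (the reference base is changed
#' so that the consensus call disagrees with it), then emits the consensus
#' call set covering those positions with phred-like qualities drawn
#' uniformly from `quality_range`.  The returned truth table is the exact
#' patch set that [patch_reference()] should recover.
#'
#' @param reference Reference sequence (single character string).
#' @param n_errors,n_gaps Planted discrepant and `N` positions.
#' @param quality_range Length-2 numeric range of call qualities.
#' @param depth Constant read depth to report.
#' @param seed Integer seed.
#' @return List with `reference` (degraded sequence), `calls`
#'   (tibble `pos`, `base`, `qual`, `depth`) and `truth`
#'   (tibble `pos`, `old`, `new`, `class`).
#' @export
simulate_consensus_calls <- function(reference, n_errors, n_gaps,
                                     quality_range = c(30, 200), depth = 144L,
                                     seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  refv <- strsplit(toupper(reference), "")[[1]]
  L <- length(refv)
  if (n_errors + n_gaps > L) abort("more planted positions than bases")
  picked <- sample.int(L, n_errors + n_gaps)
  gap_pos <- sort(picked[seq_len(n_gaps)])
  err_pos <- sort(picked[seq_len(n_errors) + n_gaps])
  truth_gap <- tibble(pos = gap_pos, old = "N", new = refv[gap_pos], class = "N-fill")
  new_err <- vapply(refv[err_pos], function(b) sample(setdiff(bases, b), 1L), "",
                    USE.NAMES = FALSE)
  truth_err <- tibble(pos = err_pos, old = refv[err_pos], new = new_err,
                      class = "discrepant-revision")
  degraded <- refv
  degraded[gap_pos] <- "N"
  calls <- tibble(
    pos = c(gap_pos, err_pos),
    base = c(refv[gap_pos], new_err),
    qual = runif(n_gaps + n_errors, quality_range[1], quality_range[2]),
    depth = as.integer(depth)
  ) |> arrange(.data$pos)
  truth <- bind_rows(truth_gap, truth_err) |> arrange(.data$pos)
  list(reference = paste(degraded, collapse = ""), calls = calls, truth = truth)
}
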