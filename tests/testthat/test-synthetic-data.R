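# The simulators: trivial limits, determinism, and closed-form oracles.

test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(sequence_length = 0), "positive")
  expect_error(sim_config(n_haplotypes = 5), "even")
  expect_error(sim_config(mutation_rate = -1), "rates")
})

test_that("zero mutation rate yields zero segregating sites", {
  h <- simulate_neutral_population(sim_config(seed = 1, mutation_rate = 0,
                                              sequence_length = 1e4,
                                              n_haplotypes = 4))
  expect_equal(n_sites(h), 0L)
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(seed = 42, sequence_length = 3e4, n_haplotypes = 8)
  expect_identical(simulate_neutral_population(cfg),
                   simulate_neutral_population(cfg))
  cfg2 <- sim_config(seed = 43, sequence_length = 3e4, n_haplotypes = 8)
  expect_false(identical(simulate_neutral_population(cfg),
                         simulate_neutral_population(cfg2)))
})

test_that("segregating-site counts match the Watterson expectation", {
  cfg <- sim_config(sequence_length = 2e4, n_haplotypes = 10)
  S <- vapply(1:200, function(s) {
    cfg$seed <- s
    n_sites(simulate_neutral_population(cfg))
  }, 0L)
  expected <- expected_segregating_sites(cfg)
  se_mean <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se_mean + 1e-9)
})

test_that("folded site-frequency spectrum matches the coalescent expectation", {
  n <- 8L
  counts <- rep(0, n / 2)
  for (s in 1:200) {
    h <- simulate_neutral_population(sim_config(seed = 1000 + s,
                                                sequence_length = 5e3,
                                                n_haplotypes = n))
    if (n_sites(h) == 0) next
    sf <- folded_sfs(h)
    counts <- counts + sf$count
  }
  ef <- medapop:::expected_folded_sfs(n)
  expect_gt(chisq.test(counts, p = ef$prop)$p.value, 0.01)
})

test_that("trio offspring are legal meiotic products", {
  h <- simulate_neutral_population(sim_config(seed = 5, sequence_length = 5e4,
                                              n_haplotypes = 32))
  tr <- simulate_trios(h, n_trios = 8, seed = 6)
  mc <- mendel_check(tr$genotypes, tr$pedigree)
  expect_equal(sum(mc$per_site$n_errors), 0L)
  expect_equal(nrow(tr$pedigree), 8L)
  # forced transmission: AA x AA -> AA
  founders <- make_gt(matrix(0L, 2, 3), matrix(0L, 2, 3), phased = TRUE)
  tr2 <- simulate_trios(founders, 1, seed = 1)
  kid <- match("O01", tr2$genotypes$samples)
  expect_true(all(tr2$genotypes$a1[kid, ] == 0L & tr2$genotypes$a2[kid, ] == 0L))
})

test_that("without recombination each gamete copies one parental haplotype", {
  h <- simulate_neutral_population(sim_config(seed = 7, sequence_length = 5e4,
                                              n_haplotypes = 4))
  tr <- simulate_trios(h, 1, recombination_rate = 0, seed = 2)
  gt <- tr$genotypes
  kid <- match("O01", gt$samples)
  fa <- match(tr$pedigree$father, gt$samples)
  expect_true(identical(gt$a1[kid, ], gt$a1[fa, ]) ||
                identical(gt$a1[kid, ], gt$a2[fa, ]))
})

test_that("odd founder counts are rejected", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "T")
  gt <- genotype_table(sites, matrix(0L, 3, 2), matrix(0L, 3, 2), phased = TRUE)
  expect_error(simulate_trios(gt, 1), "even")
})

test_that("sweep injection hits the target frequency and rounding rule", {
  h <- simulate_neutral_population(sim_config(seed = 8, sequence_length = 1e5,
                                              n_haplotypes = 20))
  sw <- inject_sweep(h, 5e4, 0.5, seed = 1)
  core <- attr(sw, "core_site")
  expect_equal(sum(sw$hap[, core]), 10L)
  # ties round toward more carriers: 0.475 * 20 = 9.5 -> 10
  sw2 <- inject_sweep(h, 5e4, 0.475, seed = 1)
  expect_equal(sum(sw2$hap[, attr(sw2, "core_site")]), 10L)
  sw3 <- inject_sweep(h, 5e4, 1, seed = 1)
  expect_equal(sum(sw3$hap[, attr(sw3, "core_site")]), 20L)
})

test_that("sweep carriers show elevated EHH at 10 kb", {
  hits <- vapply(1:100, function(s) {
    h <- simulate_neutral_population(sim_config(seed = 9000 + s,
                                                sequence_length = 2e5,
                                                n_haplotypes = 24))
    sw <- inject_sweep(h, 1e5, 0.5, seed = s)
    core <- attr(sw, "core_site")
    carriers <- which(sw$hap[, core] == 1L)
    others <- which(sw$hap[, core] == 0L)
    target_pos <- sw$sites$pos[core] + 1e4
    target <- which.min(abs(sw$sites$pos - target_pos))
    if (target == core) return(NA)
    e_car <- ehh_oracle(sw$hap, carriers, core, target)
    e_non <- ehh_oracle(sw$hap, others, core, target)
    e_car > e_non
  }, NA)
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("admixture fraction drives the D statistic monotonically", {
  cfg <- sim_config(seed = 1, sequence_length = 2e6)
  mean_d <- vapply(c(0, 0.05, 0.1, 0.2), function(f) {
    mean(vapply(1:40, function(s) {
      q <- simulate_admixture(cfg, f = f, seed = s)
      fr <- quartet_freqs(q$P1, q$P2, q$P3, q$O)
      d_statistic(site_patterns(fr), block_size_bp = 5e4)$d
    }, 0))
  }, 0)
  expect_lt(abs(mean_d[1]), 0.02)          # f = 0: no asymmetry
  expect_true(all(diff(mean_d) > 0))       # monotone in f
  expect_gt(mean_d[4], 0.05)
})

test_that("f = 1 makes P2 a P3 sample with positive D", {
  cfg <- sim_config(seed = 1, sequence_length = 5e5)
  q <- simulate_admixture(cfg, f = 1, seed = 3)
  fr <- quartet_freqs(q$P1, q$P2, q$P3, q$O)
  expect_gt(d_statistic(site_patterns(fr), block_size_bp = 5e4)$d, 0.1)
  expect_error(simulate_admixture(cfg, f = 1.2), "\\[0, 1\\]")
})

test_that("inbred-line heterozygosity follows the full-sib decay rate", {
  # after g brother-sister matings (the founder cross itself, then g - 1
  # sib crosses, measured one generation later) mean IBD heterozygosity
  # is ~ lambda^g with lambda = (1 + sqrt(5)) / 4
  lambda <- (1 + sqrt(5)) / 4
  g <- 6L
  hets <- vapply(1:500, function(s) {
    line <- simulate_inbred_line(ibd_founder_pair(120), generations = g + 1L,
                                 recombination_rate = 1e-6, seed = s)
    mean_het(line)
  }, 0)
  expect_lt(abs(mean(hets) - lambda^g) / lambda^g, 0.10)
})

test_that("inbred-line edge cases: identity at zero generations, fixed founder", {
  f <- ibd_founder_pair(50)
  expect_identical(simulate_inbred_line(f, 0), f)
  hom <- make_gt(matrix(0L, 2, 30), matrix(0L, 2, 30), phased = TRUE)
  line <- simulate_inbred_line(hom, 12, seed = 2)
  expect_equal(mean_het(line), 0)
})

test_that("residual inbred heterozygosity is arranged in blocks", {
  # contiguity: heterozygous sites cluster compared with random scatter
  line <- simulate_inbred_line(ibd_founder_pair(800, spacing = 2000),
                               generations = 10, recombination_rate = 2.5e-8,
                               seed = 11)
  het <- line$a1[1, ] != line$a2[1, ]
  if (any(het) && !all(het)) {
    runs <- rle(het)
    mean_run <- mean(runs$lengths[runs$values])
    expect_gt(mean_run, 1.5)   # far above the ~1 expected for random scatter
  }
  # and the windowed profile finds those blocks
  prof <- window_heterozygosity(line, line$samples[1], window_size = 1e5)
  blocks <- classify_het_blocks(prof, 0)
  expect_true(all(blocks$n_windows >= 1))
})

test_that("microsatellite panels hit their target inbreeding coefficient", {
  f_hat <- vapply(1:200, function(s) {
    ms <- simulate_microsatellites(n_loci = 9, n_individuals = 105,
                                   target_F = 0, seed = s)
    glance(inbreeding_coefficient(ms))$mean_f
  }, 0)
  expect_lt(abs(mean(f_hat)), 0.05)
  ms1 <- simulate_microsatellites(target_F = 1, seed = 1)
  expect_true(all(ms1$allele1 == ms1$allele2))
})

test_that("morphometric heritability limits behave", {
  m0 <- simulate_morphometrics(trait_h2 = 0, seed = 1)
  expect_lt(glance(broad_sense_heritability(m0))$mean_h2, 0.1)
  m1 <- simulate_morphometrics(trait_h2 = 1, seed = 1)
  expect_gt(glance(broad_sense_heritability(m1))$mean_h2, 0.95)
})

test_that("consensus-call planting is exactly recoverable", {
  ref <- random_dna(3000)
  sim <- simulate_consensus_calls(ref, n_errors = 20, n_gaps = 15,
                                  quality_range = c(150, 250), seed = 3)
  pr <- patch_reference(sim$reference, sim$calls, mode = "thresholded")
  expect_equal(pr$records[c("pos", "old", "new", "class")],
               sim$truth[c("pos", "old", "new", "class")])
  # no planting: patching is a no-op
  sim0 <- simulate_consensus_calls(ref, 0, 0, seed = 4)
  pr0 <- patch_reference(sim0$reference, sim0$calls)
  expect_identical(pr0$sequence, ref)
  expect_equal(nrow(pr0$records), 0L)
})

test_that("low-quality calls only fill N positions in thresholded mode", {
  ref <- random_dna(2000)
  sim <- simulate_consensus_calls(ref, n_errors = 10, n_gaps = 10,
                                  quality_range = c(5, 20), seed = 5)
  pr <- patch_reference(sim$reference, sim$calls, mode = "thresholded")
  expect_true(all(pr$records$class == "N-fill"))
  expect_equal(nrow(pr$records), 10L)
})
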