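# Shared builders and independent oracles for the test suite.

# Small haplotype set from an explicit 0/1 matrix (rows = haplotypes).
make_haps <- function(hap, pos = NULL, chrom = "chr1", anc = "ref") {
  hap <- as.matrix(hap)
  m <- ncol(hap)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  haplotype_set(
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   ref = rep("A", m), alt = rep("T", m), anc = anc),
    hap
  )
}

# Unphased genotype table from allele matrices (rows = samples).
make_gt <- function(a1, a2, pos = NULL, alt = "T", phased = FALSE, ...) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  m <- ncol(a1)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_table(
    tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                   ref = rep("A", m), alt = rep(alt, m), ...),
    a1, a2, phased = phased
  )
}

# Brute-force EHH oracle: explicit haplotype-string pair counting from the
# core out to each flanking site.
ehh_oracle <- function(hap, carriers, core, target) {
  idx <- if (target >= core) core:target else target:core
  strs <- apply(hap[carriers, idx, drop = FALSE], 1, paste, collapse = "")
  n <- length(carriers)
  pairs_same <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (strs[i] == strs[j]) pairs_same <- pairs_same + 1
  }
  pairs_same / (n * (n - 1) / 2)
}

# Brute-force two-site LD oracle from explicit gamete counting.
ld_oracle <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  pa <- (n11 + n10) / n; pb <- (n11 + n01) / n
  d <- n11 / n - pa * pb
  denom <- pa * (1 - pa) * pb * (1 - pb)
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  list(d = d, r2 = d^2 / denom, dprime = if (dmax > 0) d / dmax else NA_real_)
}

# Random clean DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Founder pair with four distinguishable allele copies per site, so that
# heterozygosity tracks identity by descent exactly.
ibd_founder_pair <- function(n_sites = 400L, spacing = 5000L) {
  sites <- tibble::tibble(chrom = "chr1", pos = seq_len(n_sites) * spacing,
                          ref = "A", alt = "C,G,T")
  genotype_table(sites,
                 a1 = rbind(rep(0L, n_sites), rep(2L, n_sites)),
                 a2 = rbind(rep(1L, n_sites), rep(3L, n_sites)),
                 samples = c("F1", "F2"), phased = TRUE)
}

mean_het <- function(gt) {
  mean(gt$a1 != gt$a2, na.rm = TRUE)
}
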