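# Haplotype blocks by the confidence-interval method of Gabriel et al.:
# a pair of markers is in "strong LD" when the one-sided CI on |D'| has
# lower bound >= 0.70 and upper bound >= 0.98; it shows "strong evidence
# of recombination" when the upper bound is < 0.90.  A block is a maximal
# marker interval whose bounding pair is in strong LD and in which at
# least 95% of informative pairs are in strong LD.

# Likelihood-profile CI on |D'|: the likelihood of the four observed
# gamete counts is profiled over |D'| on a grid (allele frequencies fixed
# at their MLEs, the sign of D fixed at its point estimate); the
# normalized likelihood is treated as a density and the 5th/95th
# percentiles reported, as in Haploview.
dprime_ci <- function(n11, n10, n01, n00, grid_step = 0.001) {
  n <- n11 + n10 + n01 + n00
  pa <- (n11 + n10) / n
  pb <- (n11 + n01) / n
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(c(low = NA_real_, high = NA_real_))
  d <- n11 / n - pa * pb
  sgn <- if (d >= 0) 1 else -1
  dmax <- if (sgn > 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  dp <- seq(0, 1, by = grid_step)
  dd <- sgn * dp * dmax
  f11 <- pmax(pa * pb + dd, 1e-12)
  f10 <- pmax(pa * (1 - pb) - dd, 1e-12)
  f01 <- pmax((1 - pa) * pb - dd, 1e-12)
  f00 <- pmax((1 - pa) * (1 - pb) + dd, 1e-12)
  ll <- n11 * log(f11) + n10 * log(f10) + n01 * log(f01) + n00 * log(f00)
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  low <- dp[which(cw >= 0.05)[1]]
  high <- dp[which(cw >= 0.95)[1]]
  c(low = low, high = high)
}

#' Call haplotype blocks with the Gabriel confidence-interval method
#'
#' @param haps A phased biallelic `haplotype_set`.
#' @param maf_min Minimum minor-allele frequency for a marker to enter.
#' @param ci_lower_strong,ci_upper_strong Strong-LD bounds on the `|D'|`
#'   CI (defaults 0.70 / 0.98).
#' @param ci_upper_recomb Upper bound below which a pair counts as strong
#'   evidence of recombination (default 0.90).
#' @param informative_fraction Required fraction of informative pairs in
#'   strong LD within a block (default 0.95).
#' @param grid_step Resolution of the `D'` likelihood grid.
#' @return Tibble of blocks: `chrom`, `start`, `end`, `first_idx`,
#'   `last_idx`, `n_markers`, `markers` (list of member site indices of
#'   `haps`; sub-MAF sites are never members).
#' @export
gabriel_blocks <- function(haps, maf_min = 0.05, ci_lower_strong = 0.70,
                           ci_upper_strong = 0.98, ci_upper_recomb = 0.90,
                           informative_fraction = 0.95, grid_step = 0.001) {
  h <- haps$hap
  p <- colMeans(h)
  keep <- which(pmin(p, 1 - p) >= maf_min)
  m <- length(keep)
  if (m < 2) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  first_idx = integer(), last_idx = integer(),
                  n_markers = integer(), markers = list()))
  }
  hh <- h[, keep, drop = FALSE]
  # pair status: 1 strong LD, -1 strong recombination, 0 uninformative
  status <- matrix(0L, m, m)
  for (i in seq_len(m - 1)) {
    a <- hh[, i]
    for (j in (i + 1):m) {
      b <- hh[, j]
      ci <- dprime_ci(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b),
                      grid_step)
      if (anyNA(ci)) next
      if (ci["low"] >= ci_lower_strong && ci["high"] >= ci_upper_strong) {
        status[i, j] <- 1L
      } else if (ci["high"] < ci_upper_recomb) {
        status[i, j] <- -1L
      }
    }
  }
  # candidate spans whose end pair is strong LD, longest first
  cand <- which(status == 1L, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  first_idx = integer(), last_idx = integer(),
                  n_markers = integer(), markers = list()))
  }
  pos <- haps$sites$pos[keep]
  span <- pos[cand[, 2]] - pos[cand[, 1]]
  cand <- cand[order(-span), , drop = FALSE]
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (any(taken[i:j])) next
    sub <- status[i:j, i:j]
    informative <- sum(sub != 0L)
    if (informative == 0) next
    if (sum(sub == 1L) / informative < informative_fraction) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1]] <- tibble(
      chrom = haps$sites$chrom[keep[i]],
      start = pos[i], end = pos[j],
      first_idx = keep[i], last_idx = keep[j], n_markers = j - i + 1L,
      markers = list(keep[i:j])
    )
  }
  if (!length(blocks)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  first_idx = integer(), last_idx = integer(),
                  n_markers = integer(), markers = list()))
  }
  bind_rows(blocks) |> arrange(.data$start)
}
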