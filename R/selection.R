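# Extended haplotype homozygosity, integrated haplotype scores and the
# composite windowed filter for sweep regions.

# Homozygosity walk: starting from the carrier set at the core, extend
# haplotypes one site at a time and return EHH at each visited site.
# Group identities are re-factorized each step so integer keys never
# overflow.  Stops once EHH drops below `stop_below` (the stopping value
# is included).
ehh_walk <- function(sub, idx_seq, stop_below = 0) {
  n_c <- nrow(sub)
  denom <- n_c * (n_c - 1) / 2
  g <- rep(1L, n_c)
  out <- numeric(length(idx_seq))
  used <- 0L
  cur <- 1
  for (k in seq_along(idx_seq)) {
    a <- sub[, idx_seq[k]]
    if (any(a != a[1L])) {           # constant columns cannot split groups
      key <- g * 2L + a
      ug <- unique(key)
      g <- match(key, ug)
      tab <- tabulate(g, nbins = length(ug))
      cur <- sum(tab * (tab - 1) / 2) / denom
    }
    out[k] <- cur
    used <- k
    if (cur < stop_below || cur == 0) break
  }
  out[seq_len(used)]
}

core_carriers <- function(haps, core_site, core_allele) {
  dm_col <- haps$hap[, core_site]
  anc <- haps$sites$anc[core_site]
  if (is.na(anc)) abort("core site has unknown ancestral allele")
  derived_val <- if (anc == "ref") 1L else 0L
  val <- if (core_allele == "derived") derived_val else 1L - derived_val
  which(dm_col == val)
}

#' Extended haplotype homozygosity curve around a core allele
#'
#' EHH at flanking site `x` is the probability that two randomly chosen
#' carrier chromosomes are identical over all sites from the core to `x`:
#' `sum_h C(n_h, 2) / C(n_c, 2)` over the distinct extended haplotypes
#' `h`.  `EHH = 1` at the core and is non-increasing with distance.
#'
#' @param haps A polarized `haplotype_set`.
#' @param core_site Site index of the core SNP.
#' @param core_allele `"derived"` or `"ancestral"`.
#' @param min_ehh Stop extending once EHH falls below this (0 = walk to
#'   the ends).
#' @return An `ehh_curve` tibble: `direction` (-1 left, +1 right, 0 core),
#'   `site`, `pos`, `dist` (bp from core), `ehh`.
#' @export
ehh <- function(haps, core_site, core_allele = c("derived", "ancestral"),
                min_ehh = 0) {
  core_allele <- match.arg(core_allele)
  carriers <- core_carriers(haps, core_site, core_allele)
  if (length(carriers) < 2) abort("fewer than 2 carriers: EHH undefined")
  pos <- haps$sites$pos
  m <- length(pos)
  right_idx <- if (core_site < m) (core_site + 1L):m else integer(0)
  left_idx <- if (core_site > 1L) (core_site - 1L):1L else integer(0)
  sub <- haps$hap[carriers, , drop = FALSE]
  e_r <- ehh_walk(sub, right_idx, min_ehh)
  e_l <- ehh_walk(sub, left_idx, min_ehh)
  rows <- list(
    tibble(direction = 0L, site = core_site, pos = pos[core_site], dist = 0,
           ehh = 1)
  )
  if (length(e_l)) {
    s <- left_idx[seq_along(e_l)]
    rows <- c(rows, list(tibble(direction = -1L, site = s, pos = pos[s],
                                dist = pos[core_site] - pos[s], ehh = e_l)))
  }
  if (length(e_r)) {
    s <- right_idx[seq_along(e_r)]
    rows <- c(rows, list(tibble(direction = 1L, site = s, pos = pos[s],
                                dist = pos[s] - pos[core_site], ehh = e_r)))
  }
  structure(bind_rows(rows) |> arrange(.data$pos),
            class = c("ehh_curve", class(tibble())),
            core_site = core_site, core_allele = core_allele,
            n_carriers = length(carriers))
}

# Trapezoidal area under one side of an EHH curve, integrated from the
# core (EHH 1) out to the interpolated crossing of `cutoff`.  Returns the
# area and whether the curve was truncated by the chromosome edge before
# reaching the cutoff.
ihh_one_side <- function(dists, ehhs, cutoff) {
  d <- c(0, dists); e <- c(1, ehhs)
  area <- 0
  for (k in seq_along(dists)) {
    if (e[k + 1] < cutoff) {
      # interpolate the crossing
      f <- (e[k] - cutoff) / (e[k] - e[k + 1])
      dc <- d[k] + f * (d[k + 1] - d[k])
      area <- area + (e[k] + cutoff) / 2 * (dc - d[k])
      return(list(area = area, truncated = FALSE))
    }
    area <- area + (e[k] + e[k + 1]) / 2 * (d[k + 1] - d[k])
  }
  list(area = area, truncated = TRUE)   # ran off the ends above cutoff
}

#' Unstandardized integrated haplotype score at one site
#'
#' Integrates the EHH curve of each core allele (trapezoid over physical
#' distance) from the core until EHH drops below `ehh_cutoff` in each
#' direction; `iHS = ln(iHH_ancestral / iHH_derived)`.  Curves truncated
#' by the chromosome edge before reaching the cutoff are flagged.
#'
#' @param haps A polarized `haplotype_set`.
#' @param site Site index.
#' @param ehh_cutoff EHH level at which integration stops (default 0.05).
#' @param min_carriers Minimum carriers required for each allele.
#' @return One-row tibble: `site`, `pos`, `daf`, `ihh_a`, `ihh_d`,
#'   `ihs_unstd`, `edge_truncated`.
#' @export
ihs_unstandardized <- function(haps, site, ehh_cutoff = 0.05, min_carriers = 2L) {
  anc <- haps$sites$anc[site]
  if (is.na(anc)) abort("site has unknown ancestral allele")
  pos <- haps$sites$pos
  m <- length(pos)
  n <- n_haplotypes(haps)
  derived_val <- if (anc == "ref") 1L else 0L
  daf <- mean(haps$hap[, site] == derived_val)
  res <- list()
  trunc <- FALSE
  for (allele in c("ancestral", "derived")) {
    carriers <- core_carriers(haps, site, allele)
    if (length(carriers) < min_carriers) {
      return(tibble(site = site, pos = pos[site], daf = daf, ihh_a = NA_real_,
                    ihh_d = NA_real_, ihs_unstd = NA_real_,
                    edge_truncated = NA))
    }
    sub <- haps$hap[carriers, , drop = FALSE]
    area <- 0
    for (dir in c(-1L, 1L)) {
      idx <- if (dir == 1L) {
        if (site < m) (site + 1L):m else integer(0)
      } else {
        if (site > 1L) (site - 1L):1L else integer(0)
      }
      e <- ehh_walk(sub, idx, ehh_cutoff)
      d <- abs(pos[idx[seq_along(e)]] - pos[site])
      side <- ihh_one_side(d, e, ehh_cutoff)
      if (!length(e)) side$truncated <- TRUE   # core at the chromosome edge
      area <- area + side$area
      trunc <- trunc || side$truncated
    }
    res[[allele]] <- area
  }
  ihs <- if (res$ancestral > 0 && res$derived > 0) {
    log(res$ancestral / res$derived)
  } else NA_real_
  tibble(site = site, pos = pos[site], daf = daf, ihh_a = res$ancestral,
         ihh_d = res$derived, ihs_unstd = ihs, edge_truncated = trunc)
}

#' Genome-wide unstandardized iHS scan
#'
#' @param haps A polarized `haplotype_set`.
#' @param min_maf Minimum derived/ancestral allele frequency for a site to
#'   be scored.
#' @param ehh_cutoff EHH integration cutoff.
#' @param drop_truncated Drop records whose EHH curve hit a chromosome
#'   edge before the cutoff (default TRUE).
#' @param sites Optional site indices to score (default: all sites
#'   passing the frequency filter); thinning keeps large scans cheap
#'   while leaving the frequency-bin standardization unbiased.
#' @return An `ihs_scan` tibble, one record per scored site.
#' @export
ihs_scan <- function(haps, min_maf = 0.05, ehh_cutoff = 0.05,
                     drop_truncated = TRUE, sites = NULL) {
  dm <- derived_matrix(haps)
  daf <- colMeans(dm)
  ok <- which(!is.na(daf) & daf >= min_maf & daf <= 1 - min_maf)
  if (!is.null(sites)) ok <- intersect(sites, ok)
  recs <- map(ok, function(s) ihs_unstandardized(haps, s, ehh_cutoff)) |>
    bind_rows()
  if (nrow(recs)) {
    recs$chrom <- haps$sites$chrom[recs$site]
    if (drop_truncated) recs <- filter(recs, !.data$edge_truncated %in% TRUE)
    recs <- filter(recs, !is.na(.data$ihs_unstd))
  }
  structure(recs, class = c("ihs_scan", class(tibble())))
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Subtracts the bin mean and divides by the bin standard deviation within
#' each derived-allele-frequency bin, giving a statistic centered on zero
#' with unit variance; bins are equal-count (frequency quantiles), as in
#' the original formulation, and bins with fewer than two records are
#' dropped with a flag.
#'
#' @param records An `ihs_scan` tibble (needs `daf`, `ihs_unstd`).
#' @param n_bins Number of equal-count frequency bins.
#' @param reference Optional `ihs_scan` tibble supplying the bin means
#'   and standard deviations (e.g. a genome-wide background scan); by
#'   default the records standardize against themselves.  Candidate
#'   sweep regions should be standardized against a neutral background,
#'   since the empirical moments are otherwise inflated by the signal
#'   itself.
#' @return The records with `bin` and `std_ihs` columns; records in bins
#'   the reference cannot parameterize are removed (count in attribute
#'   `n_dropped`).
#' @export
standardize_ihs <- function(records, n_bins = 20L, reference = NULL) {
  ref <- reference %||% records
  brk <- unique(quantile(ref$daf, seq(0, 1, length.out = n_bins + 1)))
  brk[1] <- 0; brk[length(brk)] <- 1
  if (length(brk) < 2) brk <- c(0, 1)
  bin_of <- function(x) cut(x, brk, include.lowest = TRUE, labels = FALSE)
  stats <- ref |>
    mutate(bin = bin_of(.data$daf)) |>
    group_by(.data$bin) |>
    summarise(bin_mean = mean(.data$ihs_unstd), bin_sd = sd(.data$ihs_unstd),
              n_in_bin = n(), .groups = "drop")
  std <- records |>
    mutate(bin = bin_of(.data$daf)) |>
    left_join(stats, by = "bin") |>
    mutate(std_ihs = (.data$ihs_unstd - .data$bin_mean) / .data$bin_sd)
  dropped <- sum(is.na(std$std_ihs) | std$n_in_bin < 2)
  std <- std |>
    filter(!is.na(.data$std_ihs), .data$n_in_bin >= 2) |>
    select(-"n_in_bin", -"bin_mean", -"bin_sd")
  structure(std, class = c("ihs_scan", class(tibble())), n_dropped = dropped)
}

#' Composite windowed filter for sweep regions
#'
#' A SNP passes when (1) its `|iHS|` exceeds the `top_fraction` upper
#' quantile of all `|iHS|`; and, within a window of `window_bp` centered
#' on it: (2a) the standard deviation of iHS is below the `sd_quantile`
#' quantile of all window SDs, (2b) at least `min_peak_snps` window SNPs
#' have `|iHS|` at or above `peak_ratio` times the window maximum, and
#' (2c) those SNPs make up at least `min_peak_fraction` of the window.
#' Only SNPs with negative iHS (long derived haplotypes) are retained;
#' passing SNPs within one window width are merged into regions.
#'
#' @param records Standardized records from [standardize_ihs()].
#' @param window_bp Window size centered on each SNP (bp).
#' @param top_fraction Tail fraction defining the `|iHS|` threshold.
#' @param sd_quantile Quantile of window SDs used as the SD ceiling.
#' @param peak_ratio Fraction of the window maximum defining peak SNPs.
#' @param min_peak_snps,min_peak_fraction Minimum count and fraction of
#'   peak SNPs per window.
#' @param merge_bp Merge distance for passing SNPs (defaults to
#'   `window_bp`).
#' @return A `selected_regions` tibble: `chrom`, `start`, `end`,
#'   `n_snps`, `snps` (list of member positions), with attribute
#'   `ihs_threshold` (the realized quantile threshold).
#' @export
composite_filter <- function(records, window_bp = 20000, top_fraction = 5e-4,
                             sd_quantile = 0.5, peak_ratio = 0.8,
                             min_peak_snps = 4L, min_peak_fraction = 0.1,
                             merge_bp = window_bp) {
  if (!nrow(records)) abort("empty record set")
  half <- window_bp / 2
  thr <- quantile(abs(records$std_ihs), 1 - top_fraction, names = FALSE)
  out <- list()
  for (ch in unique(records$chrom)) {
    r <- arrange(records[records$chrom == ch, ], .data$pos)
    pos <- r$pos; v <- r$std_ihs; av <- abs(v)
    lo <- findInterval(pos - half, pos) + 1L
    hi <- findInterval(pos + half, pos)
    wsd <- vapply(seq_along(pos), function(k) {
      if (hi[k] - lo[k] < 1) return(NA_real_)
      sd(v[lo[k]:hi[k]])
    }, 0)
    sd_thr <- quantile(wsd, sd_quantile, na.rm = TRUE, names = FALSE)
    pass <- vapply(seq_along(pos), function(k) {
      if (av[k] < thr || v[k] >= 0) return(FALSE)
      if (is.na(wsd[k]) || wsd[k] > sd_thr) return(FALSE)
      w <- lo[k]:hi[k]
      peak <- sum(av[w] >= peak_ratio * max(av[w]))
      peak >= min_peak_snps && peak >= min_peak_fraction * length(w)
    }, NA)
    pp <- pos[pass]
    if (!length(pp)) next
    grp <- cumsum(c(1, diff(pp) > merge_bp))
    out <- c(out, map(split(pp, grp), function(g) {
      tibble(chrom = ch, start = min(g), end = max(g), n_snps = length(g),
             snps = list(g))
    }))
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           n_snps = integer(), snps = list())
  structure(arrange(res, .data$chrom, .data$start),
            class = c("selected_regions", class(tibble())),
            ihs_threshold = thr)
}

#' Enrichment of selected SNPs in conserved intervals
#'
#' Compares the fraction of selected SNPs falling in the intervals to a
#' permutation null of equally sized random subsets of all tested SNPs.
#' `fold = observed / mean(null)`; the p-value uses the add-one
#' estimator.
#'
#' @param selected Tibble of selected SNPs (`chrom`, `pos`).
#' @param intervals Tibble of intervals (`chrom`, `start`, `end`,
#'   1-based closed).
#' @param tested Tibble of all tested SNPs (`chrom`, `pos`).
#' @param n_permutations Number of random subsets.
#' @param seed Integer seed.
#' @return Tibble with `observed_fraction`, `null_fraction`, `fold`,
#'   `p_value`, `n_selected`.
#' @export
conserved_enrichment <- function(selected, intervals, tested,
                                 n_permutations = 999, seed = 1L) {
  set.seed(seed)
  in_iv <- function(df) {
    vapply(seq_len(nrow(df)), function(k) {
      any(intervals$chrom == df$chrom[k] & intervals$start <= df$pos[k] &
            intervals$end >= df$pos[k])
    }, NA)
  }
  tested$in_iv <- in_iv(tested)
  key <- paste(selected$chrom, selected$pos)
  tkey <- paste(tested$chrom, tested$pos)
  obs <- mean(tested$in_iv[match(key, tkey)])
  k <- nrow(selected)
  null <- vapply(seq_len(n_permutations), function(b) {
    mean(tested$in_iv[sample.int(nrow(tested), k)])
  }, 0)
  tibble(
    observed_fraction = obs,
    null_fraction = mean(null),
    fold = obs / mean(null),
    p_value = (1 + sum(null >= obs)) / (1 + n_permutations),
    n_selected = k
  )
}
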