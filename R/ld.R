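# Pairwise LD (r2, D', LOD), windowed decay summaries and gene/exon
# co-localization of high-LD pairs.

ld_from_freqs <- function(p11, pa, pb) {
  d <- p11 - pa * pb
  denom <- pa * (1 - pa) * pb * (1 - pb)
  r2 <- if (denom > 0) d^2 / denom else NA_real_
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  dprime <- if (dmax > 0) d / dmax else NA_real_
  list(d = d, r2 = r2, dprime = dprime)
}

ld_lod <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  obs <- c(n11, n10, n01, n00)
  f_obs <- obs / n
  pa <- (n11 + n10) / n
  pb <- (n11 + n01) / n
  f_ind <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  ll <- function(f) sum(obs[obs > 0] * log(f[obs > 0]))
  (ll(f_obs) - ll(f_ind)) / log(10)
}

#' Pairwise linkage disequilibrium between two sites
#'
#' Haplotype frequencies are counted directly from the phased data;
#' `D = p_AB - p_A p_B`, `r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`, `D'` is `D`
#' over its sign-appropriate bound, and the LOD is the log10 likelihood
#' ratio of the observed haplotype frequencies against independence.
#'
#' @param haps A `haplotype_set`.
#' @param i,j Site indices.
#' @return One-row tibble with `i`, `j`, `pos_i`, `pos_j`, `dist`, `d`,
#'   `r2`, `dprime`, `lod`, `n`; statistics are `NA` (with a warning) when
#'   either site is monomorphic.
#' @export
pair_ld <- function(haps, i, j) {
  a <- haps$hap[, i]; b <- haps$hap[, j]
  n <- length(a)
  pa <- mean(a); pb <- mean(b)
  base <- tibble(i = i, j = j, pos_i = haps$sites$pos[i], pos_j = haps$sites$pos[j],
                 dist = abs(haps$sites$pos[j] - haps$sites$pos[i]), n = n)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    warn("monomorphic site: LD undefined")
    return(mutate(base, d = NA_real_, r2 = NA_real_, dprime = NA_real_,
                  lod = NA_real_))
  }
  p11 <- mean(a == 1L & b == 1L)
  s <- ld_from_freqs(p11, pa, pb)
  lod <- ld_lod(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  mutate(base, d = s$d, r2 = s$r2, dprime = s$dprime, lod = lod)
}

#' Scan all site pairs within a window for LD
#'
#' Emits every pair within `pair_window_bp` whose `r2` reaches `min_r2`.
#'
#' @param haps A `haplotype_set` (biallelic phased sites).
#' @param pair_window_bp Maximum pair distance in bp.
#' @param min_r2 Minimum `r2` for a pair to be reported.
#' @return Tibble of pairs (`i`, `j`, `pos_i`, `pos_j`, `dist`, `r2`,
#'   `d`, `dprime`).
#' @export
ld_scan <- function(haps, pair_window_bp = 50000, min_r2 = 0.001) {
  h <- haps$hap
  pos <- haps$sites$pos
  m <- ncol(h); n <- nrow(h)
  p <- colMeans(h)
  poly <- which(p > 0 & p < 1)
  out <- vector("list", length(poly))
  for (k in seq_along(poly)) {
    i <- poly[k]
    js <- poly[poly > i]
    js <- js[pos[js] - pos[i] <= pair_window_bp]
    if (!length(js)) next
    p11 <- as.numeric(crossprod(h[, i], h[, js, drop = FALSE])) / n
    d <- p11 - p[i] * p[js]
    denom <- p[i] * (1 - p[i]) * p[js] * (1 - p[js])
    r2 <- d^2 / denom
    dmax <- if_else(d >= 0, pmin(p[i] * (1 - p[js]), (1 - p[i]) * p[js]),
                    pmin(p[i] * p[js], (1 - p[i]) * (1 - p[js])))
    keep <- r2 >= min_r2
    if (!any(keep)) next
    out[[k]] <- tibble(i = i, j = js[keep], pos_i = pos[i], pos_j = pos[js[keep]],
                       dist = pos[js[keep]] - pos[i], r2 = r2[keep],
                       d = d[keep], dprime = d[keep] / dmax[keep])
  }
  bind_rows(out)
}

#' Median r2 per distance bin and decay plateau
#'
#' Summarizes an [ld_scan()] result into per-distance-bin medians; the
#' plateau is the first bin whose median is within 5% of the median over
#' the final ten bins.
#'
#' @param pairs Pair tibble from [ld_scan()].
#' @param bin_width Distance bin width in bp.
#' @return An `ld_decay` tibble (`bin_start`, `bin_mid`, `n_pairs`,
#'   `median_r2`) with attribute `plateau_bp`.
#' @export
ld_decay_summary <- function(pairs, bin_width = 500) {
  if (!nrow(pairs)) abort("no pairs to summarize")
  b <- floor(pairs$dist / bin_width)
  sm <- pairs |>
    mutate(bin = b) |>
    group_by(.data$bin) |>
    summarise(n_pairs = n(), median_r2 = median(.data$r2), .groups = "drop") |>
    mutate(bin_start = .data$bin * bin_width,
           bin_mid = .data$bin_start + bin_width / 2) |>
    select("bin_start", "bin_mid", "n_pairs", "median_r2") |>
    arrange(.data$bin_start)
  tail_med <- median(tail(sm$median_r2, 10))
  at <- which(abs(sm$median_r2 - tail_med) <= 0.05 * tail_med)
  plateau <- if (length(at)) sm$bin_mid[at[1]] else NA_real_
  structure(sm, class = c("ld_decay", class(sm)), plateau_bp = plateau)
}

#' Summary of haplotype-block spans
#'
#' Span is last-to-first marker distance inclusive of one bp at each
#' marker (`end - start + 1`).
#'
#' @param blocks Block tibble from [gabriel_blocks()].
#' @return Tibble with `n_blocks`, `mean_bp`, `median_bp`, `max_bp`;
#'   all-`NA` (flagged by `n_blocks = 0`) when no blocks exist.
#' @export
block_size_summary <- function(blocks) {
  if (!nrow(blocks)) {
    return(tibble(n_blocks = 0L, mean_bp = NA_real_, median_bp = NA_real_,
                  max_bp = NA_real_))
  }
  span <- blocks$end - blocks$start + 1
  tibble(n_blocks = nrow(blocks), mean_bp = mean(span),
         median_bp = median(span), max_bp = max(span))
}

#' Gene and exon co-localization of high-LD pairs
#'
#' Among pairs with `r2 > r2_min`, the fraction whose two sites fall
#' within the span of one gene, and within one exon interval.
#'
#' @param pairs Pair tibble from [ld_scan()] (needs `pos_i`, `pos_j`,
#'   `r2`) with an implicit single chromosome, or a `chrom` column.
#' @param model An [exon_model()].
#' @param r2_min High-LD threshold (default 0.8).
#' @param chrom Chromosome of the pairs when not carried as a column.
#' @return Tibble with `n_pairs`, `frac_same_gene`, `frac_same_exon`.
#' @export
high_ld_colocalization <- function(pairs, model, r2_min = 0.8, chrom = NULL) {
  hi <- pairs[pairs$r2 > r2_min, ]
  if (!"chrom" %in% names(hi)) {
    hi$chrom <- chrom %||% model$chrom[1]
  }
  if (!nrow(hi)) {
    return(tibble(n_pairs = 0L, frac_same_gene = NA_real_,
                  frac_same_exon = NA_real_))
  }
  genes <- model |>
    group_by(.data$gene, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  in_span <- function(chroms, pos, spans) {
    lapply(seq_along(pos), function(k) {
      which(spans$chrom == chroms[k] & spans$start <= pos[k] & spans$end >= pos[k])
    })
  }
  gi <- in_span(hi$chrom, hi$pos_i, genes)
  gj <- in_span(hi$chrom, hi$pos_j, genes)
  same_gene <- vapply(seq_len(nrow(hi)), function(k) {
    length(intersect(gi[[k]], gj[[k]])) > 0
  }, NA)
  ei <- in_span(hi$chrom, hi$pos_i, model)
  ej <- in_span(hi$chrom, hi$pos_j, model)
  same_exon <- vapply(seq_len(nrow(hi)), function(k) {
    length(intersect(ei[[k]], ej[[k]])) > 0
  }, NA)
  tibble(n_pairs = nrow(hi), frac_same_gene = mean(same_gene),
         frac_same_exon = mean(same_exon))
}
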