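# ABBA-BABA introgression test: frequency-weighted site patterns, block
# jackknife uncertainty, and the ghost-population control.

#' Derived-allele frequencies of a haplotype set
#'
#' @param haps A polarized `haplotype_set`.
#' @return Tibble `chrom`, `pos`, `p` (derived-allele frequency; `NA`
#'   where the ancestral allele is unknown).
#' @export
derived_freqs <- function(haps) {
  dm <- derived_matrix(haps)
  tibble(chrom = haps$sites$chrom, pos = haps$sites$pos, p = colMeans(dm))
}

#' Per-site ABBA/BABA weights for a population quartet
#'
#' With derived-allele frequencies `p1`, `p2`, `p3` in the three ingroup
#' panels (outgroup fixed ancestral), the weights are
#' `ABBA = (1 - p1) * p2 * p3` and `BABA = p1 * (1 - p2) * p3`; for
#' single genomes these reduce to 0/1 pattern counts.  Sites with unknown
#' ancestral state (`NA` frequency) are excluded.
#'
#' @param freqs Tibble with `chrom`, `pos`, `p1`, `p2`, `p3` — derived
#'   frequencies for P1 (sister), P2 (test), P3 (candidate introgressor).
#'   Build it with [quartet_freqs()] or by joining [derived_freqs()]
#'   outputs.
#' @return `freqs` with `abba` and `baba` columns, polarizable sites only.
#' @export
site_patterns <- function(freqs) {
  ok <- complete.cases(freqs[c("p1", "p2", "p3")])
  f <- freqs[ok, ]
  mutate(f,
         abba = (1 - .data$p1) * .data$p2 * .data$p3,
         baba = .data$p1 * (1 - .data$p2) * .data$p3)
}

#' Assemble quartet derived-allele frequencies
#'
#' @param p1,p2,p3 `haplotype_set`s for the sister, test and candidate
#'   introgressor panels (shared site tables).
#' @param outgroup Optional `haplotype_set` for the outgroup; sites where
#'   it is not fixed for the ancestral allele are dropped.
#' @return Frequency tibble for [site_patterns()].
#' @export
quartet_freqs <- function(p1, p2, p3, outgroup = NULL) {
  stopifnot(identical(p1$sites$pos, p2$sites$pos),
            identical(p1$sites$pos, p3$sites$pos))
  f <- tibble(chrom = p1$sites$chrom, pos = p1$sites$pos,
              p1 = colMeans(derived_matrix(p1)),
              p2 = colMeans(derived_matrix(p2)),
              p3 = colMeans(derived_matrix(p3)))
  if (!is.null(outgroup)) {
    po <- colMeans(derived_matrix(outgroup))
    f <- f[!is.na(po) & po == 0, ]
  }
  f
}

#' D statistic with block-jackknife uncertainty
#'
#' `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)`.  The standard
#' error comes from a leave-one-out jackknife over contiguous genomic
#' blocks of `block_size_bp`; `Z = D / SE`.  With fewer than
#' `n_blocks_min` non-empty blocks the Z score is withheld.
#'
#' @param patterns Tibble from [site_patterns()].
#' @param block_size_bp Jackknife block length (default 1 Mb).
#' @param n_blocks_min Minimum non-empty blocks for a Z score.
#' @param subset Label describing the site subset tested.
#' @return A `dstat_result`; see [tidy.dstat_result()].
#' @export
d_statistic <- function(patterns, block_size_bp = 1e6, n_blocks_min = 5L,
                        subset = "all sites") {
  if (!nrow(patterns)) abort("no usable sites")
  sa <- sum(patterns$abba); sb <- sum(patterns$baba)
  if (sa + sb == 0) abort("ABBA + BABA weights sum to zero")
  d <- (sa - sb) / (sa + sb)
  blk <- paste(patterns$chrom, floor((patterns$pos - 1) / block_size_bp))
  ub <- unique(blk)
  se <- NA_real_; z <- NA_real_
  if (length(ub) >= n_blocks_min) {
    d_loo <- vapply(ub, function(b) {
      keep <- blk != b
      (sum(patterns$abba[keep]) - sum(patterns$baba[keep])) /
        (sum(patterns$abba[keep]) + sum(patterns$baba[keep]))
    }, 0)
    nb <- length(ub)
    se <- sqrt((nb - 1) / nb * sum((d_loo - mean(d_loo))^2))
    z <- d / se
  }
  structure(list(d = d, se = se, z = z, abba = sa, baba = sb,
                 n_sites = nrow(patterns), n_blocks = length(ub),
                 subset = subset),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("<dstat_result> D = %.4f (SE %.4f, Z %.2f), %d sites, %s\n",
              x$d, x$se, x$z, x$n_sites, x$subset))
  invisible(x)
}

#' Tidy a D-statistic result
#'
#' @param x A `dstat_result`.
#' @param ... Unused.
#' @return One-row tibble `d`, `se`, `z`, `abba`, `baba`, `subset`.
#' @export
tidy.dstat_result <- function(x, ...) {
  tibble(d = x$d, se = x$se, z = x$z, abba = x$abba, baba = x$baba,
         subset = x$subset)
}

#' @export
glance.dstat_result <- function(x, ...) {
  tibble(n_sites = x$n_sites, n_blocks = x$n_blocks)
}

#' Ghost-population control for a D-statistic
#'
#' A spurious signal can arise when the test population is closely
#' related to a sister sample that truly introgressed.  The control
#' restricts the test to sites that differentiate the test panel from the
#' sister (absolute frequency difference above `min_diff`) and recomputes
#' D on the subset; alleles shared with the sister -- including any
#' inherited introgressed ones -- then no longer contribute.
#'
#' @param freqs Quartet frequency tibble with an additional `p_sister`
#'   column (the sister panel's derived frequency; 0/1 for a single
#'   genome).
#' @param min_diff Differentiation floor; the default keeps any
#'   difference, `1` demands complete differentiation.
#' @param ... Passed to [d_statistic()].
#' @return List with `subset` (the retained frequency rows, flagged empty
#'   via a warning) and `result` (`dstat_result` or `NULL`).
#' @export
ghost_control <- function(freqs, min_diff = 0, ...) {
  if (!"p_sister" %in% names(freqs)) abort("freqs needs a p_sister column")
  keep <- !is.na(freqs$p_sister) &
    abs(freqs$p2 - freqs$p_sister) > min_diff - 1e-12
  keep <- keep & abs(freqs$p2 - freqs$p_sister) > 0
  sub <- freqs[keep, ]
  if (!nrow(sub)) {
    warn("no sites differentiate the test population from the sister")
    return(list(subset = sub, result = NULL))
  }
  list(subset = sub,
       result = d_statistic(site_patterns(sub), ...,
                            subset = "sister-differentiating sites"))
}
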