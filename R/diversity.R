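# Windowed heterozygosity profiles, block classification, inbreeding
# coefficients and population summary fractions.

#' Windowed heterozygosity profile for one sample
#'
#' Counts heterozygous genotypes per window and divides by window length
#' (heterozygous sites per bp).  If a reference sequence is supplied, the
#' per-window overlap with assembly gaps (`N` runs) is reported separately.
#'
#' @param table A `genotype_table`.
#' @param sample Sample label.
#' @param window_size Window size in bp (default 50 kb).
#' @param step Step between window starts; defaults to non-overlapping.
#' @param seq_length Profiled length per chromosome (named vector); defaults
#'   to the last site position.
#' @param reference Optional named character vector of reference sequences
#'   used to report gap overlap.
#' @return A `het_profile`: tibble with `chrom`, `start`, `end`, `n_het`,
#'   `het` (per bp) and optionally `gap_bp`.
#' @export
window_heterozygosity <- function(table, sample, window_size = 50000,
                                  step = window_size, seq_length = NULL,
                                  reference = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (window_size <= 0) abort("window_size must be positive")
  i <- match(sample, table$samples)
  if (is.na(i)) abort(sprintf("sample '%s' not found", sample))
  het <- table$a1[i, ] != table$a2[i, ]
  out <- vector("list", 0)
  for (ch in unique(table$sites$chrom)) {
    rows <- which(table$sites$chrom == ch)
    L <- if (!is.null(seq_length)) seq_length[[ch]] else max(table$sites$pos[rows])
    starts <- seq(1, max(1, L - 1), by = step)
    ends <- pmin(starts + window_size - 1, L)
    hp <- table$sites$pos[rows][which(het[rows])]
    n_het <- vapply(seq_along(starts), function(w) {
      sum(hp >= starts[w] & hp <= ends[w])
    }, 0L)
    win <- tibble(chrom = ch, start = starts, end = ends, n_het = n_het,
                  het = n_het / (ends - starts + 1))
    if (!is.null(reference) && ch %in% names(reference)) {
      isn <- strsplit(toupper(reference[[ch]]), "")[[1]] == "N"
      cn <- cumsum(isn)
      win$gap_bp <- cn[pmin(ends, length(cn))] -
        c(0, cn)[pmax(pmin(starts, length(cn) + 1), 1)]
    }
    out <- c(out, list(win))
  }
  structure(bind_rows(out), class = c("het_profile", "tbl_df", "tbl", "data.frame"))
}

#' Heterozygosity threshold classifying a stated fraction of the genome
#'
#' Returns the `(1 - classified_fraction)` quantile of the per-window
#' heterozygosity values, so that `classified_fraction` of windows lie at
#' or above it.  Degenerate profiles (all windows equal) are flagged with a
#' warning.
#'
#' @param wild_profile A `het_profile` from a wild (outbred) sample.
#' @param classified_fraction Fraction of windows to classify as
#'   heterozygous (default 0.9).
#' @return The threshold (heterozygous sites per bp).
#' @export
derive_het_threshold <- function(wild_profile, classified_fraction = 0.9) {
  v <- wild_profile$het
  if (!length(v)) abort("empty profile")
  if (length(unique(v)) == 1L) {
    warn("degenerate profile: all windows have identical heterozygosity")
  }
  unname(quantile(v, 1 - classified_fraction, type = 7))
}

#' Classify windows above a heterozygosity threshold into blocks
#'
#' Maximal runs of consecutive windows strictly above the threshold are
#' merged into blocks.
#'
#' @param profile A `het_profile`.
#' @param threshold Heterozygosity threshold (per bp).
#' @return Tibble with `chrom`, `start`, `end`, `n_windows`.
#' @export
classify_het_blocks <- function(profile, threshold) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, ]
    above <- p$het > threshold
    if (!any(above)) next
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    hit <- which(r$values)
    out <- c(out, list(tibble(
      chrom = ch,
      start = p$start[starts_i[hit]],
      end = p$end[ends_i[hit]],
      n_windows = r$lengths[hit]
    )))
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer()))
  }
  bind_rows(out)
}

het_fraction_pair <- function(a1, a2) {
  ok <- !is.na(a1)
  c(h = sum(a1[ok] != a2[ok]), n = sum(ok))
}

#' Inbreeding coefficient from genotype data
#'
#' `F = 1 - HOBS / HEXP`, with `HOBS` the observed heterozygote fraction
#' and `HEXP = 1 - sum(p_i^2)` from the sample allele frequencies (no
#' small-sample correction).  Missing genotypes are excluded from both
#' numerator and denominator; monomorphic loci have undefined `F`.
#'
#' @param x A microsatellite tibble (`individual`, `locus`, `allele1`,
#'   `allele2`) as from [simulate_microsatellites()], or a
#'   `genotype_table` (each site is a locus).
#' @return An `fstat` object; [tidy()] gives per-locus rows
#'   (`locus`, `n`, `hobs`, `hexp`, `f`), [glance()] the mean and range.
#' @export
inbreeding_coefficient <- function(x) {
  if (inherits(x, "genotype_table")) {
    per <- map(seq_len(n_sites(x)), function(j) {
      f_one_locus(x$a1[, j], x$a2[, j],
                  paste0(x$sites$chrom[j], ":", x$sites$pos[j]))
    }) |> bind_rows()
  } else {
    x <- as_tibble(x)
    per <- x |>
      group_by(.data$locus) |>
      dplyr::group_map(~ f_one_locus(.x$allele1, .x$allele2, .y$locus)) |>
      bind_rows()
  }
  structure(list(per_locus = per), class = "fstat")
}

f_one_locus <- function(a1, a2, label) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) {
    return(tibble(locus = label, n = n, hobs = NA_real_, hexp = NA_real_,
                  f = NA_real_))
  }
  p <- table(c(a1, a2)) / (2 * n)
  hexp <- 1 - sum(p^2)
  hobs <- mean(a1 != a2)
  tibble(locus = as.character(label), n = n, hobs = hobs, hexp = hexp,
         f = if (hexp == 0) NA_real_ else 1 - hobs / hexp)
}

#' @export
tidy.fstat <- function(x, ...) x$per_locus

#' @export
glance.fstat <- function(x, ...) {
  f <- x$per_locus$f
  tibble(mean_f = mean(f, na.rm = TRUE),
         min_f = suppressWarnings(min(f, na.rm = TRUE)),
         max_f = suppressWarnings(max(f, na.rm = TRUE)),
         n_loci = sum(!is.na(f)),
         n_positive = sum(f > 0, na.rm = TRUE),
         n_negative = sum(f < 0, na.rm = TRUE))
}

#' @export
print.fstat <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fstat> %d loci, mean F = %.3f (range %.3f to %.3f)\n",
              g$n_loci, g$mean_f, g$min_f, g$max_f))
  invisible(x)
}

#' Fraction of divergent sites that are heterozygous in a sample
#'
#' Among sites where the sample carries at least one non-reference allele,
#' the fraction called heterozygous.
#'
#' @param table A `genotype_table`.
#' @param sample Sample label.
#' @return A single fraction (0 when the sample has no divergent sites).
#' @export
divergent_site_het_fraction <- function(table, sample) {
  i <- match(sample, table$samples)
  if (is.na(i)) abort(sprintf("sample '%s' not found", sample))
  a1 <- table$a1[i, ]; a2 <- table$a2[i, ]
  ok <- !is.na(a1)
  div <- ok & (a1 > 0 | a2 > 0)
  if (!sum(div)) return(0)
  mean(a1[div] != a2[div])
}

#' Fraction of variant sites monoallelic across a population
#'
#' A site is monoallelic when every non-missing genotype in the population
#' is homozygous for the same non-reference allele.
#'
#' @param table A `genotype_table` of the population.
#' @return Fraction over sites with at least one non-missing genotype.
#' @export
monoallelic_fraction <- function(table) {
  mono <- vapply(seq_len(n_sites(table)), function(j) {
    a1 <- table$a1[, j]; a2 <- table$a2[, j]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA)
    a <- c(a1[ok], a2[ok])
    length(unique(a)) == 1L && a[1] > 0L
  }, NA)
  mean(mono, na.rm = TRUE)
}
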