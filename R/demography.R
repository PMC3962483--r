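# Post-processing of PSMC output: parsing, scaling to years / diploid Ne,
# and combining individuals on log10 time bins.

#' Parse PSMC text output
#'
#' Extracts the atomic-interval table (`RS` records: scaled time `t_k`,
#' scaled size `lambda_k`) and `theta0` from the final round (last `RD`
#' block) of a PSMC output file.
#'
#' @param path PSMC `.psmc` output file.
#' @return A `psmc_trajectory` tibble (`k`, `t`, `lambda`) with
#'   attributes `theta0` and `round`.
#' @export
parse_psmc_output <- function(path) {
  lines <- readLines(path)
  rd <- grep("^RD\t", lines)
  if (!length(rd)) abort("malformed PSMC file: no RD records")
  last <- rd[length(rd)]
  block <- lines[last:length(lines)]
  stop_at <- grep("^//", block)
  if (length(stop_at)) block <- block[seq_len(stop_at[1] - 1)]
  rs <- block[grepl("^RS\t", block)]
  tr <- block[grepl("^TR\t", block)]
  if (!length(rs) || !length(tr)) abort("malformed PSMC file: missing RS/TR records")
  theta0 <- as.numeric(strsplit(tr[1], "\t")[[1]][2])
  f <- do.call(rbind, lapply(strsplit(rs, "\t"), function(x) as.numeric(x[2:4])))
  structure(tibble(k = as.integer(f[, 1]), t = f[, 2], lambda = f[, 3]),
            class = c("psmc_trajectory", class(tibble())),
            theta0 = theta0,
            round = as.integer(strsplit(lines[last], "\t")[[1]][2]))
}

#' Write a PSMC-style output fixture
#'
#' Emits a minimal file (one RD block with RS/TR records) that
#' [parse_psmc_output()] reads back; used for round-trip tests and
#' examples.
#'
#' @param traj Tibble `k`, `t`, `lambda`.
#' @param theta0 Scaled mutation rate for the TR record.
#' @param path Output file.
#' @export
write_psmc_fixture <- function(traj, theta0, path) {
  lines <- c("RD\t25",
             sprintf("TR\t%g\t%g", theta0, theta0 / 5),
             sprintf("RS\t%d\t%g\t%g\t0\t0\t0", traj$k, traj$t, traj$lambda),
             "//")
  writeLines(lines, path)
  invisible(path)
}

#' Scale a PSMC trajectory to years and diploid Ne
#'
#' `N0 = theta0 / (4 * mu * s)`; `Ne = lambda * N0`;
#' `years = 2 * N0 * t * generation_years`.  The generation time is a
#' required explicit argument (the organism literature supports several
#' values, so no silent default is appropriate).
#'
#' @param traj A `psmc_trajectory` (or tibble `t`, `lambda`).
#' @param generation_years Generation time in years.
#' @param mutation_rate Per-bp, per-generation mutation rate.
#' @param bin_size PSMC bin size `s` (bp per bin, default 100).
#' @param theta0 Scaled theta; defaults to the parsed attribute.
#' @return Tibble `years`, `ne` (plus the scaled inputs), invertible
#'   given the same parameters.
#' @export
scale_trajectory <- function(traj, generation_years, mutation_rate = 2.5e-8,
                             bin_size = 100, theta0 = attr(traj, "theta0")) {
  if (is.null(theta0)) abort("theta0 required (attribute or argument)")
  n0 <- theta0 / (4 * mutation_rate * bin_size)
  tibble(t = traj$t, lambda = traj$lambda,
         years = 2 * n0 * traj$t * generation_years,
         ne = traj$lambda * n0)
}

#' Combine scaled trajectories across individuals on log10 time bins
#'
#' Each individual's step trajectory is sampled onto a common grid of
#' log10(years) bins of width `log10_bin_width`; the across-individual
#' distribution is summarized per bin.
#'
#' @param trajectories List of scaled tibbles (`years`, `ne`) from
#'   [scale_trajectory()].
#' @param log10_bin_width Bin width on log10(years) (default 0.1).
#' @return Tibble `log10_years`, `years`, `n`, `median_ne`, `q25`, `q75`.
#' @export
bin_and_combine <- function(trajectories, log10_bin_width = 0.1) {
  pos_years <- unlist(map(trajectories, function(tr) tr$years[tr$years > 0]))
  rng <- range(log10(pos_years))
  brks <- seq(floor(rng[1] / log10_bin_width) * log10_bin_width,
              ceiling(rng[2] / log10_bin_width) * log10_bin_width,
              by = log10_bin_width)
  mids <- brks[-length(brks)] + log10_bin_width / 2
  # step-function lookup: Ne at time y is the lambda of the interval
  # containing y (intervals start at each years value)
  sampled <- map(trajectories, function(tr) {
    tr <- arrange(tr, .data$years)
    idx <- findInterval(10^mids, tr$years)
    ne <- tr$ne[pmax(idx, 1L)]
    ne[idx == 0] <- tr$ne[1]
    ne
  })
  mat <- do.call(rbind, sampled)
  tibble(log10_years = mids, years = 10^mids, n = nrow(mat),
         median_ne = apply(mat, 2, median),
         q25 = apply(mat, 2, quantile, 0.25),
         q75 = apply(mat, 2, quantile, 0.75))
}

#' Broad-sense heritability of morphometric traits
#'
#' Divides each measurement by its view's body length (lateral L1-L3 by
#' L4, dorsal D1-D4 by D5), fits a one-way analysis of variance on strain
#' and reports `H2 = SS_strain / SS_total` per ratio trait.  Strains with
#' fewer than two fish are excluded with a warning.
#'
#' @param table Morphometric tibble (`strain`, `L1`..`L4`, `D1`..`D5`),
#'   e.g. from [simulate_morphometrics()].
#' @return An `h2_fit`; [tidy()] gives per-trait `H2`, [glance()] the
#'   design summary.
#' @export
broad_sense_heritability <- function(table) {
  table <- as_tibble(table)
  counts <- table(table$strain)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warn(sprintf("excluding strain(s) with a single fish: %s",
                 paste(small, collapse = ", ")))
    table <- table[!table$strain %in% small, ]
  }
  if (length(unique(table$strain)) < 2) abort("need at least two strains")
  traits <- list(L1 = "L4", L2 = "L4", L3 = "L4",
                 D1 = "D5", D2 = "D5", D3 = "D5", D4 = "D5")
  traits <- traits[names(traits) %in% names(table)]
  per <- imap(traits, function(body, tr) {
    ratio <- table[[tr]] / table[[body]]
    fit <- aov(ratio ~ strain, data = tibble(ratio = ratio, strain = table$strain))
    ss <- summary(fit)[[1]][["Sum Sq"]]
    tibble(trait = paste0(tr, "/", body), h2 = ss[1] / sum(ss))
  }) |> bind_rows()
  structure(list(per_trait = per,
                 n_strains = length(unique(table$strain)),
                 n_fish = nrow(table)),
            class = "h2_fit")
}

#' @export
tidy.h2_fit <- function(x, ...) x$per_trait

#' @export
glance.h2_fit <- function(x, ...) {
  tibble(n_strains = x$n_strains, n_fish = x$n_fish,
         mean_h2 = mean(x$per_trait$h2),
         n_traits = nrow(x$per_trait))
}

#' @export
print.h2_fit <- function(x, ...) {
  cat(sprintf("<h2_fit> %d traits, %d strains, %d fish; mean H2 = %.2f\n",
              nrow(x$per_trait), x$n_strains, x$n_fish, mean(x$per_trait$h2)))
  invisible(x)
}
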