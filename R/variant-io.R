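# Standard-format I/O (VCF via vcfR, FASTA via Biostrings, BED/pedigree as
# delimited text) plus the pedigree-aware checks and post-phasing filters.

#' Read a VCF file into a genotype table or haplotype set
#'
#' Coordinates stay 1-based; multiallelic sites keep all alleles.
#' Haplotype extraction demands fully phased ("|"-separated), fully called,
#' biallelic genotypes.  Half-missing calls are treated as missing.  The
#' INFO keys `AA` (ancestral allele), `EMPR2` and `ERATE` populate the
#' `anc`, `emp_r2` and `erate` site columns when present.
#'
#' @param path VCF 4.x file (optionally gzipped).
#' @param as `"genotypes"` or `"haplotypes"`.
#' @param region Optional `"chrom:start-end"` filter.
#' @return A [genotype_table()] or [haplotype_set()].
#' @export
read_vcf <- function(path, as = c("genotypes", "haplotypes"), region = NULL) {
  as <- match.arg(as)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1] %||% character(0)
    ns <- length(samples)
    gt <- genotype_table(
      tibble(chrom = character(), pos = integer(),
             ref = character(), alt = character()),
      matrix(integer(), ns, 0), matrix(integer(), ns, 0),
      samples = samples, phased = TRUE
    )
    return(if (as == "haplotypes") as_haplotype_set(gt) else gt)
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    abort(sprintf("malformed VCF record (non-numeric POS) at data line %s",
                  paste(which(is.na(pos)), collapse = ",")))
  }
  info <- fix[, "INFO"]
  info_val <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- sub(paste0(".*", key, "="), "", regmatches(info, regexpr(
      paste0("(^|;)", key, "=[^;]*"), info)))
    out
  }
  aa <- info_val("AA")
  sites <- tibble(
    chrom = fix[, "CHROM"], pos = pos,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    anc = dplyr::case_when(
      is.na(aa) ~ NA_character_,
      aa == fix[, "REF"] ~ "ref",
      vapply(seq_along(aa), function(i) {
        !is.na(aa[i]) && aa[i] %in% strsplit(fix[i, "ALT"], ",")[[1]]
      }, logical(1)) ~ "alt",
      TRUE ~ NA_character_
    ),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    emp_r2 = suppressWarnings(as.numeric(info_val("EMPR2"))),
    erate = suppressWarnings(as.numeric(info_val("ERATE")))
  )
  gtm <- v@gt
  fmt <- strsplit(gtm[, 1], ":")
  gt_idx <- vapply(fmt, function(f) match("GT", f), 0L)
  samples <- colnames(gtm)[-1]
  ns <- length(samples); m <- nrow(fix)
  a1 <- matrix(NA_integer_, ns, m); a2 <- matrix(NA_integer_, ns, m)
  phased_all <- TRUE
  for (j in seq_len(m)) {
    cells <- gtm[j, -1]
    g <- vapply(strsplit(cells, ":"), function(x) x[gt_idx[j]], "")
    ph <- grepl("|", g, fixed = TRUE)
    if (!all(ph | g %in% c(".", "./.", ".|."))) phased_all <- FALSE
    parts <- strsplit(g, "[/|]")
    p1 <- vapply(parts, function(p) p[1] %||% ".", "")
    p2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else ".", "")
    a1[, j] <- suppressWarnings(as.integer(p1))
    a2[, j] <- suppressWarnings(as.integer(p2))
  }
  gt <- genotype_table(sites, a1, a2, samples, phased = phased_all)
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- gt$sites$chrom == r$chrom & gt$sites$pos >= r$start & gt$sites$pos <= r$end
    gt <- subset_sites(gt, keep)
  }
  if (as == "haplotypes") {
    if (!phased_all) abort("unphased genotypes: haplotype extraction needs '|' GT")
    return(as_haplotype_set(gt))
  }
  gt
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) abort("region must look like 'chrom:start-end'")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Write a genotype table or haplotype set as VCF 4.2
#'
#' Phased data are written with `"|"` separators.  Ancestral alleles and
#' phasing-quality annotations present on the site table are emitted as the
#' INFO keys `AA`, `EMPR2` and `ERATE`.  A `.gz` suffix triggers gzip
#' compression.
#'
#' @param x A `genotype_table` or `haplotype_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "haplotype_set")) x <- as_genotype_table(x)
  stopifnot(inherits(x, "genotype_table"))
  s <- x$sites
  sep <- if (x$phased) "|" else "/"
  fmt_allele <- function(a) if_else(is.na(a), ".", as.character(a))
  body <- vapply(seq_len(nrow(s)), function(j) {
    info <- character(0)
    if (!is.na(s$anc[j])) {
      aa <- if (s$anc[j] == "ref") s$ref[j] else strsplit(s$alt[j], ",")[[1]][1]
      info <- c(info, paste0("AA=", aa))
    }
    if ("emp_r2" %in% names(s) && !is.na(s$emp_r2[j])) {
      info <- c(info, paste0("EMPR2=", format(s$emp_r2[j])))
    }
    if ("erate" %in% names(s) && !is.na(s$erate[j])) {
      info <- c(info, paste0("ERATE=", format(s$erate[j])))
    }
    qual <- if ("qual" %in% names(s) && !is.na(s$qual[j])) format(s$qual[j]) else "."
    gts <- paste(fmt_allele(x$a1[, j]), fmt_allele(x$a2[, j]), sep = sep)
    paste(c(s$chrom[j], s$pos[j], ".", s$ref[j], s$alt[j], qual, "PASS",
            if (length(info)) paste(info, collapse = ";") else ".", "GT", gts),
          collapse = "\t")
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=EMPR2,Number=1,Type=Float,Description=\"Empirical r2 between inferred and expected genotypes\">",
    "##INFO=<ID=ERATE,Number=1,Type=Float,Description=\"Observed Mendelian error rate\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting named character
#' vectors of sequences.
#'
#' @param path FASTA file.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write a tab-delimited pedigree (sample, father, mother)
#'
#' @param path TSV file with columns `sample`, `father`, `mother`.
#' @return Pedigree tibble with columns `child`, `father`, `mother`.
#' @export
read_pedigree <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  names(p)[1] <- "child"
  validate_pedigree(p)
}

#' @rdname read_pedigree
#' @param ped Pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  ped <- validate_pedigree(ped)
  readr::write_tsv(rename(ped, sample = "child"), path)
  invisible(path)
}

#' Read and write BED intervals
#'
#' On disk BED is 0-based half-open; in memory intervals are 1-based
#' closed (`start`, `end`).
#'
#' @param path BED file.
#' @return Tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
read_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = FALSE,
                       col_types = readr::cols(.default = "c"), comment = "#")
  tibble(chrom = b[[1]], start = as.integer(b[[2]]) + 1L, end = as.integer(b[[3]]))
}

#' @rdname read_bed
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(tibble(intervals$chrom, intervals$start - 1L, intervals$end),
                   path, col_names = FALSE)
  invisible(path)
}

#' Filter to well-genotyped biallelic sites
#'
#' Keeps biallelic sites whose missing-call fraction and minor-allele
#' frequency pass the thresholds, preserving site order.  Idempotent.
#'
#' @param table A `genotype_table`.
#' @param min_alleles,max_alleles Allowed allele counts (default biallelic
#'   only).
#' @param max_missing_fraction Maximum fraction of missing genotypes per
#'   site (a call-rate threshold of 0.8 corresponds to 0.2 here).
#' @param min_maf Minimum minor-allele frequency.
#' @return The filtered `genotype_table`.
#' @export
filter_biallelic_maf_missing <- function(table, min_alleles = 2L, max_alleles = 2L,
                                         max_missing_fraction = 0.2, min_maf = 0) {
  stopifnot(inherits(table, "genotype_table"))
  if (max_missing_fraction < 0 || max_missing_fraction > 1 ||
      min_maf < 0 || min_maf > 1) {
    abort("thresholds must lie in [0, 1]")
  }
  n_alleles <- 1L + vapply(strsplit(table$sites$alt, ","), length, 0L)
  miss <- colMeans(is.na(table$a1))
  maf <- vapply(seq_len(n_sites(table)), function(j) {
    a <- c(table$a1[, j], table$a2[, j])
    a <- a[!is.na(a)]
    if (!length(a)) return(0)
    f <- tabulate(a + 1L, nbins = max(a) + 1L) / length(a)
    f <- f[f > 0]
    if (length(f) < 2) 0 else min(f)
  }, 0)
  keep <- n_alleles >= min_alleles & n_alleles <= max_alleles &
    miss <= max_missing_fraction & maf >= min_maf
  subset_sites(table, keep)
}

#' Count Mendelian errors per site and per trio
#'
#' An error is a child genotype impossible under Mendelian transmission
#' from its parents' genotypes; any missing genotype in the trio makes the
#' site uninformative for that trio, never an error.
#'
#' @param table A `genotype_table`.
#' @param pedigree Tibble with `child`, `father`, `mother`.
#' @return List of tibbles `per_site` (`chrom`, `pos`, `n_errors`,
#'   `n_informative`) and `per_trio` (`child`, `n_errors`,
#'   `n_informative`).
#' @export
mendel_check <- function(table, pedigree) {
  stopifnot(inherits(table, "genotype_table"))
  pedigree <- validate_pedigree(pedigree)
  idx <- function(s) match(s, table$samples)
  trios <- pedigree |>
    mutate(ci = idx(.data$child), fi = idx(.data$father), mi = idx(.data$mother)) |>
    filter(!is.na(.data$ci), !is.na(.data$fi), !is.na(.data$mi))
  m <- n_sites(table)
  site_err <- integer(m); site_inf <- integer(m)
  trio_err <- integer(nrow(trios)); trio_inf <- integer(nrow(trios))
  for (t in seq_len(nrow(trios))) {
    c1 <- table$a1[trios$ci[t], ]; c2 <- table$a2[trios$ci[t], ]
    f1 <- table$a1[trios$fi[t], ]; f2 <- table$a2[trios$fi[t], ]
    m1 <- table$a1[trios$mi[t], ]; m2 <- table$a2[trios$mi[t], ]
    inf <- !(is.na(c1) | is.na(f1) | is.na(m1))
    ok <- ((c1 == f1 | c1 == f2) & (c2 == m1 | c2 == m2)) |
      ((c1 == m1 | c1 == m2) & (c2 == f1 | c2 == f2))
    err <- inf & !ok
    site_err <- site_err + as.integer(err)
    site_inf <- site_inf + as.integer(inf)
    trio_err[t] <- sum(err)
    trio_inf[t] <- sum(inf)
  }
  list(
    per_site = tibble(chrom = table$sites$chrom, pos = table$sites$pos,
                      n_errors = site_err, n_informative = site_inf),
    per_trio = tibble(child = trios$child, n_errors = trio_err,
                      n_informative = trio_inf)
  )
}

#' Filter sites on trio-phasing quality annotations
#'
#' Keeps sites with empirical r-squared at or above `min_empirical_r2` and
#' Mendelian error rate at or below `max_erate` (both bounds inclusive, as
#' published).  Sites lacking the annotations pass or fail according to
#' `missing`.
#'
#' @param table A `genotype_table` whose site table carries `emp_r2` and
#'   `erate` columns.
#' @param min_empirical_r2 Inclusive lower bound on empirical r-squared.
#' @param max_erate Inclusive upper bound on the Mendelian error rate.
#' @param missing `"fail"` (default) or `"pass"` for unannotated sites.
#' @return The filtered `genotype_table`.
#' @export
filter_phasing_quality <- function(table, min_empirical_r2 = 0.6, max_erate = 0.1,
                                   missing = c("fail", "pass")) {
  stopifnot(inherits(table, "genotype_table"))
  missing <- match.arg(missing)
  s <- table$sites
  r2 <- if ("emp_r2" %in% names(s)) s$emp_r2 else rep(NA_real_, nrow(s))
  er <- if ("erate" %in% names(s)) s$erate else rep(NA_real_, nrow(s))
  default <- missing == "pass"
  ok_r2 <- if_else(is.na(r2), default, r2 >= min_empirical_r2)
  ok_er <- if_else(is.na(er), default, er <= max_erate)
  subset_sites(table, ok_r2 & ok_er)
}

#' Polarize alleles against an outgroup sequence
#'
#' Sets the ancestral allele of every site to the outgroup base at that
#' reference coordinate when it matches the site's ref or one of its alt
#' alleles; otherwise (mismatch, `N`, or gap) the site stays unpolarized.
#'
#' @param x A `genotype_table` or `haplotype_set`.
#' @param outgroup Named character vector of outgroup sequences on
#'   reference coordinates (names = chromosomes), e.g. from [read_fasta()].
#' @return `x` with the site `anc` column filled in.
#' @export
polarize_by_outgroup <- function(x, outgroup) {
  s <- x$sites
  anc <- rep(NA_character_, nrow(s))
  for (ch in unique(s$chrom)) {
    if (!ch %in% names(outgroup)) abort(sprintf("outgroup lacks sequence for %s", ch))
    seq_ch <- outgroup[[ch]]
    rows <- which(s$chrom == ch)
    if (length(rows) && max(s$pos[rows]) > nchar(seq_ch)) {
      abort("outgroup sequence shorter than needed")
    }
    ob <- toupper(substring(seq_ch, s$pos[rows], s$pos[rows]))
    for (k in seq_along(rows)) {
      i <- rows[k]
      if (ob[k] == s$ref[i]) {
        anc[i] <- "ref"
      } else if (ob[k] %in% strsplit(s$alt[i], ",")[[1]]) {
        anc[i] <- "alt"
      }
    }
  }
  x$sites$anc <- anc
  x
}
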