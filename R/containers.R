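# Core containers: a site table shared by both, plus allele matrices.
# Haplotypes are rows (chromosomes), sites are columns; genotype matrices are
# individuals x sites.  Site tables are tibbles with 1-based positions as in
# VCF; conversion to 0-based half-open happens only at BED boundaries.

site_cols <- c("chrom", "pos", "ref", "alt")

validate_sites <- function(sites) {
  if (!all(site_cols %in% names(sites))) {
    abort(paste0("site table needs columns: ", paste(site_cols, collapse = ", ")))
  }
  if (any(sites$pos < 1)) abort("positions must be >= 1 (1-based)")
  if (nrow(sites) > 1) {
    same <- sites$chrom[-1] == sites$chrom[-nrow(sites)]
    if (any(same & diff(sites$pos) <= 0)) {
      abort("site positions must be strictly increasing within a chromosome")
    }
  }
  if (!"anc" %in% names(sites)) sites$anc <- NA_character_
  bad <- !is.na(sites$anc) & !sites$anc %in% c("ref", "alt")
  if (any(bad)) abort("ancestral annotation must be 'ref', 'alt' or NA")
  sites
}

#' Phased haplotype set
#'
#' Bundles an ordered site table with a binary haplotype matrix
#' (rows = chromosomes, columns = sites; 0 = reference allele, 1 = alternate).
#' Two consecutive rows belong to one diploid sample.  The optional `anc`
#' column of the site table records which allele is ancestral (`"ref"`,
#' `"alt"`, or `NA` when unpolarized), as set by [polarize_by_outgroup()].
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   and optionally `anc`.
#' @param hap Integer 0/1 matrix, `2 * n_samples` rows by `nrow(sites)`
#'   columns.
#' @param samples Character vector of diploid sample labels
#'   (`nrow(hap) / 2` of them).
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(sites, hap, samples = NULL) {
  sites <- validate_sites(as_tibble(sites))
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (ncol(hap) != nrow(sites)) abort("hap must have one column per site")
  if (nrow(hap) %% 2L != 0L) abort("haplotype count must be even (diploids)")
  if (nrow(hap) > 0 && !all(hap %in% c(0L, 1L))) abort("hap entries must be 0/1")
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(hap) / 2L))
  if (length(samples) != nrow(hap) / 2L) abort("need one sample label per haplotype pair")
  structure(
    list(sites = sites, hap = hap, samples = as.character(samples)),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf(
    "<haplotype_set> %d haplotypes (%d samples) x %d sites on %s\n",
    nrow(x$hap), length(x$samples), nrow(x$sites),
    paste(unique(x$sites$chrom), collapse = ",")
  ))
  invisible(x)
}

#' @rdname haplotype_set
#' @param x A `haplotype_set`.
#' @export
n_haplotypes <- function(x) nrow(x$hap)

#' @rdname haplotype_set
#' @export
n_sites <- function(x) UseMethod("n_sites")

#' @export
n_sites.haplotype_set <- function(x) nrow(x$sites)

#' @export
n_sites.genotype_table <- function(x) nrow(x$sites)

#' Diploid genotype table
#'
#' Site table plus two allele-index matrices (`a1`, `a2`; individuals x
#' sites; 0 = ref, 1.. = alternate alleles, `NA` = missing).  `phased = TRUE`
#' asserts that `a1`/`a2` are the two chromosome-resolved haplotypes.
#' Half-missing diploid calls are stored fully missing.
#'
#' @param sites Site tibble as in [haplotype_set()]; `alt` may hold several
#'   comma-separated alleles.
#' @param a1,a2 Integer allele matrices, samples x sites.
#' @param samples Sample labels.
#' @param phased Logical scalar.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(sites, a1, a2, samples = NULL, phased = FALSE) {
  sites <- validate_sites(as_tibble(sites))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) abort("a1 and a2 must have identical shape")
  if (ncol(a1) != nrow(sites)) abort("allele matrices need one column per site")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(a1)))
  if (length(samples) != nrow(a1)) abort("need one sample label per row")
  structure(
    list(sites = sites, a1 = a1, a2 = a2,
         samples = as.character(samples), phased = isTRUE(phased)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "<genotype_table> %d samples x %d sites (%s)\n",
    length(x$samples), nrow(x$sites), if (x$phased) "phased" else "unphased"
  ))
  invisible(x)
}

#' Convert between haplotype sets and genotype tables
#'
#' @param x A `haplotype_set` or phased `genotype_table`.
#' @return The other representation.
#' @export
as_genotype_table <- function(x) {
  stopifnot(inherits(x, "haplotype_set"))
  odd <- seq(1L, nrow(x$hap), by = 2L)
  genotype_table(x$sites,
                 a1 = x$hap[odd, , drop = FALSE],
                 a2 = x$hap[odd + 1L, , drop = FALSE],
                 samples = x$samples, phased = TRUE)
}

#' @rdname as_genotype_table
#' @export
as_haplotype_set <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  if (!x$phased) abort("genotypes are unphased; haplotype extraction needs phased data")
  n <- length(x$samples)
  hap <- matrix(0L, 2L * n, nrow(x$sites))
  hap[seq(1L, 2L * n, 2L), ] <- x$a1
  hap[seq(2L, 2L * n, 2L), ] <- x$a2
  if (anyNA(hap)) abort("missing genotypes cannot be turned into haplotypes")
  if (nrow(x$sites) > 0 && any(hap > 1L)) abort("haplotype extraction requires biallelic sites")
  haplotype_set(x$sites, hap, x$samples)
}

#' @exportS3Method tibble::as_tibble
as_tibble.haplotype_set <- function(x, ...) {
  hap_id <- seq_len(nrow(x$hap))
  tibble(
    haplotype = rep(hap_id, times = nrow(x$sites)),
    sample = rep(rep(x$samples, each = 2L), times = nrow(x$sites)),
    chrom = rep(x$sites$chrom, each = nrow(x$hap)),
    pos = rep(x$sites$pos, each = nrow(x$hap)),
    allele = as.integer(x$hap)
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.genotype_table <- function(x, ...) {
  ns <- length(x$samples)
  tibble(
    sample = rep(x$samples, times = nrow(x$sites)),
    chrom = rep(x$sites$chrom, each = ns),
    pos = rep(x$sites$pos, each = ns),
    a1 = as.integer(x$a1),
    a2 = as.integer(x$a2)
  )
}

#' @exportS3Method generics::tidy
tidy.haplotype_set <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::tidy
tidy.genotype_table <- function(x, ...) as_tibble(x)

#' Subset sites of a container
#'
#' @param x Container.
#' @param keep Logical or integer index over sites.
#' @export
subset_sites <- function(x, keep) UseMethod("subset_sites")

#' @export
subset_sites.haplotype_set <- function(x, keep) {
  haplotype_set(x$sites[keep, , drop = FALSE], x$hap[, keep, drop = FALSE], x$samples)
}

#' @export
subset_sites.genotype_table <- function(x, keep) {
  genotype_table(x$sites[keep, , drop = FALSE],
                 x$a1[, keep, drop = FALSE], x$a2[, keep, drop = FALSE],
                 x$samples, phased = x$phased)
}

#' Validate a pedigree table
#'
#' A pedigree is a tibble with columns `child`, `father`, `mother` over
#' sample labels.  Parents absent from `samples` are treated as external
#' founders.  Cycles are rejected.
#'
#' @param ped Tibble with columns `child`, `father`, `mother`.
#' @param samples Optional sample universe for membership checks.
#' @return The validated pedigree tibble (invisibly usable downstream).
#' @export
validate_pedigree <- function(ped, samples = NULL) {
  ped <- as_tibble(ped)
  if (!all(c("child", "father", "mother") %in% names(ped))) {
    abort("pedigree needs columns child, father, mother")
  }
  if (anyDuplicated(ped$child)) abort("each child may appear once")
  # cycle check: walk up from every child
  up <- function(s) {
    seen <- character()
    while (s %in% ped$child) {
      if (s %in% seen) abort("pedigree contains a cycle")
      seen <- c(seen, s)
      s <- ped$father[match(s, ped$child)]
    }
    invisible(NULL)
  }
  for (ch in ped$child) up(ch)
  ped
}

# Derived-allele coding helper: column of 0/1 where 1 = derived.
# Requires the site's anc annotation; NA anc -> NA result.
derived_matrix <- function(hs) {
  m <- hs$hap
  flip <- which(hs$sites$anc == "alt")
  if (length(flip)) m[, flip] <- 1L - m[, flip]
  unknown <- which(is.na(hs$sites$anc))
  if (length(unknown)) m[, unknown] <- NA_integer_
  m
}
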