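# Format round-trips, filters and pedigree-aware checks.

test_that("VCF write/read round-trips genotypes bit-exactly", {
  h <- simulate_neutral_population(sim_config(seed = 2, sequence_length = 2e4,
                                              n_haplotypes = 8))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(h, path)
  back <- read_vcf(path, as = "haplotypes")
  expect_identical(back$hap, h$hap)
  expect_equal(back$sites$pos, h$sites$pos)
  expect_equal(back$sites$anc, h$sites$anc)
  # and through the genotype view, gzipped
  gz <- withr::local_tempfile(fileext = ".vcf.gz")
  gt <- as_genotype_table(h)
  write_vcf(gt, gz)
  gt2 <- read_vcf(gz)
  expect_identical(gt2$a1, gt$a1)
  expect_identical(gt2$a2, gt$a2)
})

test_that("an empty VCF body reads as an empty table", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", sep = "\t")), path)
  gt <- suppressWarnings(read_vcf(path))
  expect_equal(n_sites(gt), 0L)
})

test_that("a 3-site 2-sample phased fixture gives 4 haplotypes x 3 sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t0|0\t0|1",
    "chr1\t30\t.\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|0"
  ), path)
  h <- read_vcf(path, as = "haplotypes")
  expect_equal(dim(h$hap), c(4L, 3L))
  expect_equal(h$hap[, 1], c(0L, 1L, 1L, 1L))
})

test_that("haplotype extraction refuses unphased genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"
  ), path)
  expect_error(read_vcf(path, as = "haplotypes"), "unphased")
})

test_that("half-missing genotypes are treated as fully missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t./1"
  ), path)
  gt <- read_vcf(path)
  expect_true(is.na(gt$a1[1, 1]) && is.na(gt$a2[1, 1]))
})

test_that("biallelic/missing/MAF filter selects the exact survivor set", {
  # 10 sites: 1-2 fine, 3 triallelic, 4 50% missing, 5 zero MAF,
  # 6 low MAF, 7-10 fine
  alt <- c("T", "T", "T,G", "T", "T", "T", "T", "T", "T", "T")
  a1 <- matrix(0L, 10, 10); a2 <- matrix(1L, 10, 10)
  a2[, 3] <- 2L
  a1[1:5, 4] <- NA_integer_; a2[1:5, 4] <- NA_integer_
  a1[, 5] <- 1L                     # monomorphic alt
  a2[, 6] <- 0L; a2[1, 6] <- 1L     # maf 0.05
  sites <- tibble::tibble(chrom = "chr1", pos = 1:10 * 10L, ref = "A", alt = alt)
  gt <- genotype_table(sites, a1, a2)
  out <- filter_biallelic_maf_missing(gt, max_missing_fraction = 0.2,
                                      min_maf = 0.1)
  expect_equal(out$sites$pos, c(1, 2, 7, 8, 9, 10) * 10)
  # idempotence
  out2 <- filter_biallelic_maf_missing(out, max_missing_fraction = 0.2,
                                       min_maf = 0.1)
  expect_identical(out2$sites, out$sites)
  expect_error(filter_biallelic_maf_missing(gt, min_maf = 2), "\\[0, 1\\]")
})

test_that("Mendelian checks count impossible child genotypes only", {
  # sites: 1 AAxAA -> Aa (error); 2 AAxaa -> Aa (fine); 3 missing child
  ped <- tibble::tibble(child = "S03", father = "S01", mother = "S02")
  a1 <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, NA))
  a2 <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, NA))
  gt <- make_gt(a1, a2)
  mc <- mendel_check(gt, ped)
  expect_equal(mc$per_site$n_errors, c(1L, 0L, 0L))
  expect_equal(mc$per_site$n_informative, c(1L, 1L, 0L))
  expect_equal(mc$per_trio$n_errors, 1L)
})

test_that("phasing-quality filter applies inclusive published bounds", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:6 * 10L, ref = "A", alt = "T",
    emp_r2 = c(0.60, 0.59, 0.95, 0.80, NA, 0.70),
    erate = c(0.10, 0.05, 0.11, 0.10, 0.01, NA)
  )
  gt <- genotype_table(sites, matrix(0L, 2, 6), matrix(1L, 2, 6))
  kept <- filter_phasing_quality(gt)$sites$pos
  expect_equal(kept, c(10, 40))           # boundary site retained, NA fails
  kept_pass <- filter_phasing_quality(gt, missing = "pass")$sites$pos
  expect_equal(kept_pass, c(10, 40, 50, 60))
})

test_that("outgroup polarization assigns ancestral alleles case by case", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(1L, 3L, 5L, 7L, 9L),
                          ref = c("A", "C", "G", "T", "A"),
                          alt = c("T", "G", "A", "C", "G"))
  gt <- genotype_table(sites, matrix(0L, 2, 5), matrix(1L, 2, 5))
  #            pos:  1    3    5    7    9
  # outgroup base:  A    G    N    A    C   (ref, alt, unknown, neither, neither)
  outg <- c(chr1 = "AXGXNXAXC")
  out <- polarize_by_outgroup(gt, outg)
  expect_equal(out$sites$anc, c("ref", "alt", NA, NA, NA))
  expect_error(polarize_by_outgroup(gt, c(chr1 = "ACGT")), "shorter")
})

test_that("FASTA, BED and pedigree files round-trip", {
  seqs <- c(chr1 = random_dna(200), chr2 = random_dna(100))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)

  iv <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(11L, 1L),
                       end = c(50L, 100L))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, bed)
  expect_equal(read_bed(bed), iv)
  # 0-based half-open on disk
  raw <- readr::read_tsv(bed, col_names = FALSE, show_col_types = FALSE)
  expect_equal(raw$X2, c(10, 0))

  ped <- tibble::tibble(child = "kid", father = "dad", mother = "mum")
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, pf)
  expect_equal(read_pedigree(pf), ped)
})

test_that("GFF3 exon models round-trip through rtracklayer", {
  skip_if_not_installed("rtracklayer")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tCDS\t11\t19\t.\t+\t0\tID=cds1;Parent=tx1;gene_id=g1",
    "chr1\ttest\tCDS\t31\t36\t.\t+\t0\tID=cds2;Parent=tx1;gene_id=g1"
  ), gff)
  em <- read_exon_model(gff)
  expect_s3_class(em, "exon_model")
  expect_equal(nrow(em), 2L)
  expect_equal(sum(em$end - em$start + 1), 15)
  expect_equal(unique(em$gene), "g1")
})

test_that("pedigree validation rejects cycles", {
  bad <- tibble::tibble(child = c("a", "b"), father = c("b", "a"),
                        mother = c("x", "y"))
  expect_error(validate_pedigree(bad), "cycle")
})
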