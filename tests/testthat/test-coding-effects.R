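# Codon-level SNP classification, enumeration expectations and the
# depletion test.

toy_reference <- function(cds, flank = 10) {
  c(chr1 = paste0(strrep("A", flank), cds, strrep("A", flank)))
}

toy_model <- function(cds_len, flank = 10, strand = "+") {
  exon_model(tibble::tibble(gene = "g1", transcript = "tx1", chrom = "chr1",
                            start = flank + 1L, end = flank + cds_len,
                            strand = strand))
}

test_that("classification recovers textbook codon changes", {
  ref <- toy_reference("TATCTT")       # Tyr, Leu
  model <- toy_model(6)
  # TAT -> TAA: nonsense
  s <- tibble::tibble(chrom = "chr1", pos = 13L, ref = "T", alt = "A")
  expect_equal(classify_snp(s, model, ref)$resolved, "nonsense")
  # CTT -> CTC: synonymous (Leu)
  s2 <- tibble::tibble(chrom = "chr1", pos = 16L, ref = "T", alt = "C")
  expect_equal(classify_snp(s2, model, ref)$resolved, "synonymous")
  # TAT -> CAT: missense (Tyr -> His)
  s3 <- tibble::tibble(chrom = "chr1", pos = 11L, ref = "T", alt = "C")
  expect_equal(classify_snp(s3, model, ref)$resolved, "missense")
})

test_that("minus-strand codons are complemented and framed correctly", {
  # genomic CDS on minus strand: transcript reads reverse complement
  # genome: ...AAGCAT...; minus-strand CDS = ATGCTT (Met, Leu)
  ref <- toy_reference("AAGCAT")
  model <- toy_model(6, strand = "-")
  # genomic A->G at pos 16 (transcript first codon ATG -> .. pos maps to
  # transcript position 1): T of ATG template; check a synonymous Leu change
  # genomic A (pos 11) is transcript position 6 (CTT third base pairs):
  # A->G genomic = T->C transcript: CTT -> CTC, synonymous
  s <- tibble::tibble(chrom = "chr1", pos = 11L, ref = "A", alt = "G")
  expect_equal(classify_snp(s, model, ref)$resolved, "synonymous")
})

test_that("overlapping transcripts resolve by severity preference", {
  # same CDS twice with different frames so one transcript sees missense
  # while the other sees synonymous
  ref <- c(chr1 = paste0(strrep("A", 9), "CTTCTTCTT", strrep("A", 9)))
  model <- exon_model(tibble::tibble(
    gene = c("g1", "g2"), transcript = c("tx1", "tx2"), chrom = "chr1",
    start = c(10L, 13L), end = c(18L, 18L), strand = "+"
  ))
  # pos 18: tx1 codon 3 (CTT -> CTC, synonymous Leu); tx2 codon 2
  # (CTT -> CTC synonymous too) -- use pos 17 instead:
  # tx1: codon CTT -> CCT (missense Leu->Pro); tx2: codon 2 CTT -> CCT missense
  # Simpler: check that the resolved class is the most severe of the set.
  s <- tibble::tibble(chrom = "chr1", pos = 18L, ref = "T", alt = "C")
  res <- classify_snp(s, model, ref)
  expect_equal(nrow(res$per_transcript), 2L)
  classes <- res$per_transcript$class
  expect_equal(res$resolved,
               c("nonsense", "stop-codon", "missense", "synonymous")[
                 min(match(classes, c("nonsense", "stop-codon", "missense",
                                      "synonymous")))])
})

test_that("classification agrees with a translate-both-sequences oracle", {
  set.seed(10)
  code <- standard_genetic_code()
  n_checked <- 0
  for (rep in 1:40) {
    n_codons <- 30L
    repeat {
      cds <- random_dna(3 * n_codons)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
      if (!grepl("\\*", substr(aa, 1, n_codons - 1))) break
    }
    ref <- toy_reference(cds)
    model <- toy_model(3 * n_codons)
    for (k in 1:25) {
      p <- sample.int(3 * n_codons, 1)
      old <- substr(cds, p, p)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      s <- tibble::tibble(chrom = "chr1", pos = 10L + p, ref = old, alt = new)
      got <- classify_snp(s, model, ref)$resolved
      mut <- cds
      substr(mut, p, p) <- new
      tr <- function(x) strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(x), no.init.codon = TRUE)), "")[[1]]
      aa_ref <- tr(cds)
      aa_alt <- tr(mut)
      ci <- (p - 1) %/% 3 + 1
      want <- if (aa_ref[ci] != "*" && aa_alt[ci] == "*") "nonsense"
        else if (aa_ref[ci] == "*" && aa_alt[ci] != "*") "stop-codon"
        else if (aa_ref[ci] == aa_alt[ci]) "synonymous"
        else "missense"
      expect_equal(got, want)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 1000)
})

test_that("expected fractions match brute-force enumeration and symmetry", {
  code <- standard_genetic_code()
  uniform <- setNames(rep(1 / 64, 64), names(code))
  got <- expected_class_fractions(uniform)
  expect_equal(sum(got$expected_fraction), 1)
  # independent brute force over all 61 * 9 = 549 sense-codon substitutions
  bases <- c("A", "C", "G", "T")
  acc <- c(nonsense = 0, `stop-codon` = 0, missense = 0, synonymous = 0)
  n_sub <- 0
  for (codon in names(code)[code != "*"]) {
    cb <- strsplit(codon, "")[[1]]
    for (p in 1:3) for (b in setdiff(bases, cb[p])) {
      nb <- cb; nb[p] <- b
      a1 <- code[[codon]]; a2 <- code[[paste(nb, collapse = "")]]
      cls <- if (a1 != "*" && a2 == "*") "nonsense"
        else if (a1 == "*" && a2 != "*") "stop-codon"
        else if (a1 == a2) "synonymous" else "missense"
      acc[cls] <- acc[cls] + 1
      n_sub <- n_sub + 1
    }
  }
  expect_equal(setNames(got$expected_fraction, got$class), acc / n_sub)
  # frequencies concentrated on TGG: nonsense fraction 2/9
  trp <- expected_class_fractions(c(TGG = 1))
  expect_equal(trp$expected_fraction[trp$class == "nonsense"], 2 / 9)
  # invariant to scaling of unnormalized frequencies
  scaled <- expected_class_fractions(uniform * 1000)
  expect_equal(scaled$expected_fraction, got$expected_fraction)
})

test_that("codon frequencies from CDS sum to one and weight correctly", {
  cf <- codon_frequencies(c("ATGATG", "TTT"))
  expect_equal(sum(cf), 1)
  expect_equal(unname(cf["ATG"]), 2 / 3)
  expect_equal(unname(cf["TTT"]), 1 / 3)
})

test_that("depletion p-values follow the closed form and stay finite", {
  dt <- depletion_test(c(nonsense = 0, synonymous = 1000),
                       c(nonsense = 0.044, synonymous = 0.956))
  expect_equal(dt$p_value[dt$class == "nonsense"], (1 - 0.044)^1000)
  # observed equal to expected: p around 0.5 or above
  dt2 <- depletion_test(c(missense = 500, synonymous = 500),
                        c(missense = 0.5, synonymous = 0.5))
  expect_gte(dt2$p_value[1], 0.5)
  # extreme depletion keeps a finite log10 p
  dt3 <- depletion_test(c(missense = 1000, synonymous = 9000),
                        c(missense = 0.708, synonymous = 0.292))
  expect_lt(dt3$log10_p[dt3$class == "missense"], -300)
  expect_true(is.finite(dt3$log10_p[1]))
})

test_that("depletion p-values are uniform under the null", {
  set.seed(11)
  frac <- c(nonsense = 0.044, missense = 0.708, synonymous = 0.248)
  p <- vapply(1:500, function(b) {
    counts <- as.vector(stats::rmultinom(1, 2000, frac))
    names(counts) <- names(frac)
    dt <- depletion_test(counts, frac)
    dt$p_value[dt$class == "missense"]
  }, 0)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})
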