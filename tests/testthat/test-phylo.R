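# K2P distances, neighbor joining, consensus, Gower clustering,
# in-silico PCR/digest mitotyping and D-loop typing.

test_that("K2P distance matches its closed form", {
  expect_equal(k2p_distance("ACGT", "ACGT"), 0, ignore_attr = TRUE)
  # one transversion among 4 sites: -1/2 ln(0.75) - 1/4 ln(0.5)
  v <- k2p_distance("ACGT", "ACGA")
  expect_equal(as.numeric(v), -0.5 * log(0.75) - 0.25 * log(0.5))
  expect_equal(attr(v, "P"), 0)
  expect_equal(attr(v, "Q"), 0.25)
  # saturation: P = 0.5, Q = 0 makes the log argument zero
  sat <- k2p_distance("ACAC", "GCGC")
  expect_true(is.na(sat))
  expect_true(attr(sat, "saturated"))
  # gaps and N dropped pairwise
  g <- k2p_distance("ACGTN", "ACG-A")
  expect_equal(as.numeric(g), 0)
})

test_that("K2P matches independent arithmetic on 1000 random pairs", {
  set.seed(50)
  for (rep in 1:1000) {
    L <- 60L
    a <- sample(c("A", "C", "G", "T"), L, TRUE)
    b <- a
    mut <- runif(L) < 0.12
    b[mut] <- vapply(b[mut], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    p <- mean(b == ts_map[a] & b != a)
    q <- mean(b != a & b != ts_map[a])
    got <- k2p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0) {
      expect_true(attr(got, "saturated"))
    } else {
      expect_equal(as.numeric(got), -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q),
                   tolerance = 1e-10)
    }
  }
})

test_that("K2P agrees with the ape K80 implementation", {
  set.seed(51)
  mk <- function() paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  seqs <- c(a = mk(), b = mk())
  mat <- k2p_matrix(seqs)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  want <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(mat$matrix["a", "b"], want["a", "b"], tolerance = 1e-10)
})

test_that("neighbor joining reconstructs additive distances exactly", {
  # known 4-taxon additive matrix: ((A:2,B:3):1,(C:4,D:4):1)
  dm <- matrix(c(0, 5, 7, 7,
                 5, 0, 8, 8,
                 7, 8, 0, 8,
                 7, 8, 8, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm, midpoint = FALSE)
  # tree distances reproduce the matrix exactly (additivity)
  got <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(got, dm, tolerance = 1e-10)
  # topology: A and B are sisters
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ topology matches an independent implementation on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(52)
  agree <- vapply(1:100, function(s) {
    n <- 6
    x <- matrix(runif(n * 4), n, 4)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    t1 <- nj_tree(d, midpoint = FALSE)
    t2 <- phangorn::NJ(as.dist(d))
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
  }, NA)
  expect_gte(mean(agree), 0.99)
})

test_that("midpoint rooting balances the longest leaf-to-leaf path", {
  dm <- matrix(c(0, 2, 10, 2, 0, 10, 10, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm, midpoint = TRUE)
  expect_true(ape::is.rooted(tr))
  dep <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(max(dep[c(1, 2)]), dep[3], tolerance = 1e-9)
})

test_that("majority-vote consensus applies the tie rule", {
  hap <- rbind(matrix(1L, 30, 1), matrix(0L, 18, 1))
  hap <- cbind(hap, c(rep(1L, 24), rep(0L, 24)), rep(0L, 48))
  h <- make_haps(hap)
  cons <- majority_vote_consensus(h)
  expect_equal(cons$allele, c(1L, 0L, 0L))      # 30/18; 24/24 tie -> ref; 0/48
  expect_equal(cons$tie, c(FALSE, TRUE, FALSE))
  expect_equal(cons$base, c("T", "A", "A"))
})

test_that("Gower clustering matches hand-computed dosages", {
  # 4 samples, 2 sites; dosages: s1 = (0,0), s2 = (2,2), s3 = (0,2), s4 = (1,1)
  a1 <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 1L), c(0L, 0L))
  a2 <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 1L), c(1L, 1L))
  gt <- make_gt(a1, a2)
  gc <- gower_cluster(gt)
  d <- as.matrix(gc$dist)
  expect_equal(d["S01", "S02"], 1)              # opposite homozygotes
  expect_equal(d["S01", "S03"], 0.5)            # one site differs fully
  expect_equal(d["S01", "S04"], 0.5)            # half-range at both sites
  expect_equal(d["S01", "S01"], 0)
  expect_s3_class(gc$hclust, "hclust")
})

test_that("in-silico PCR finds unique amplicons and honors circularity", {
  set.seed(53)
  tmpl <- random_dna(2000)
  fwd <- substr(tmpl, 301, 320)
  rev_site <- substr(tmpl, 1520, 1541)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_site)))
  amp <- insilico_pcr(tmpl, fwd, rev)
  expect_equal(amp$length, 1541 - 301 + 1)
  expect_equal(amp$sequence, substr(tmpl, 301, 1541))
  # absent reverse primer: error
  expect_error(insilico_pcr(tmpl, fwd, "ACGTACGTACGTACGTACGT"), "no amplicon")
  # amplicon spanning the origin of a circular template
  fwd2 <- substr(tmpl, 1801, 1820)
  rev2_site <- substr(tmpl, 101, 120)
  rev2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev2_site)))
  expect_error(insilico_pcr(tmpl, fwd2, rev2, circular = FALSE), "no amplicon")
  amp2 <- insilico_pcr(tmpl, fwd2, rev2, circular = TRUE)
  expect_equal(amp2$length, 2000 - 1801 + 1 + 120)
})

test_that("restriction digestion respects cut offsets and conserves length", {
  # MboI cuts before the G of GATC
  dg <- restriction_digest("AAGATCAA",
                           enzymes = mitotyping_enzymes()[2, ])   # MboI
  expect_equal(dg$fragments[[1]], sort(c(2L, 6L)))
  # no recognition site: single full-length fragment
  dg0 <- restriction_digest("AAAAAAAA")
  expect_true(all(vapply(dg0$fragments, length, 0L) == 1L))
  # fragments always sum to amplicon length
  set.seed(54)
  for (rep in 1:20) {
    amp <- random_dna(500)
    dg2 <- restriction_digest(amp)
    expect_true(all(vapply(dg2$fragments, sum, 0L) == 500L))
  }
})

test_that("mitotypes are equivalence classes of binned fragment patterns", {
  set.seed(55)
  base <- random_dna(1241)
  # a variant differing only outside all recognition sites keeps its type:
  # substitute an A<->T at a position not inside any site occurrence
  enz <- mitotyping_enzymes()
  v <- base
  for (p in sample(nchar(base), 200)) {
    window <- substr(base, max(1, p - 3), min(nchar(base), p + 3))
    cand <- strsplit(v, "")[[1]]
    old <- cand[p]
    new <- chartr("ACGT", "TGCA", old)
    cand[p] <- new
    cand_s <- paste(cand, collapse = "")
    same_sites <- all(vapply(seq_len(nrow(enz)), function(i) {
      identical(medapop:::match_starts(enz$site[i], cand_s),
                medapop:::match_starts(enz$site[i], base))
    }, NA))
    if (same_sites) { v <- cand_s; break }
  }
  other <- random_dna(1241)
  mt <- assign_mitotype(list(a = restriction_digest(base),
                             b = restriction_digest(v),
                             c = restriction_digest(other)))
  expect_equal(mt$mitotype[1], mt$mitotype[2])
  expect_false(mt$mitotype[1] == mt$mitotype[3])
})

test_that("D-loop typing trims, collapses and counts variants", {
  set.seed(56)
  variants <- vapply(1:8, function(i) random_dna(520), "")
  seqs <- sample(variants, 105, replace = TRUE)
  # guarantee every variant appears
  seqs[1:8] <- variants
  names(seqs) <- sprintf("ind%03d", seq_along(seqs))
  dt <- dloop_typing(seqs, trim_to = 508)
  expect_equal(nrow(dt$variants), 8L)
  expect_equal(sum(dt$variants$count), 105L)
  expect_equal(nrow(dt$membership), 105L)
  # identical input collapses to one variant
  one <- dloop_typing(rep(variants[1], 10))
  expect_equal(nrow(one$variants), 1L)
  # short sequences are excluded with a warning
  expect_warning(sh <- dloop_typing(c(variants[1], substr(variants[2], 1, 100))),
                 "excluded")
  expect_equal(nrow(sh$membership), 1L)
})
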