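# Distance-based phylogenetics: Kimura two-parameter distances,
# neighbor-joining with midpoint rooting, majority-vote consensus and
# Gower clustering of genotypes.

transitions <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` the transition and
#' `Q` the transversion fraction over pairwise-complete columns (gaps and
#' `N` dropped).  When a log argument is non-positive the distance is
#' saturated: `NA` with attribute `saturated = TRUE`.
#'
#' @param seq_a,seq_b Equal-length aligned sequences (character strings).
#' @return Numeric distance, with attributes `P`, `Q` and `saturated`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) abort("sequences must be aligned to equal length")
  ok <- a %in% names(transitions) & b %in% names(transitions)
  a <- a[ok]; b <- b[ok]
  if (!length(a)) abort("no comparable columns")
  diff <- a != b
  ts <- diff & (transitions[a] == b)
  p <- mean(ts)
  q <- mean(diff & !ts)
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0) {
    return(structure(NA_real_, P = p, Q = q, saturated = TRUE))
  }
  structure(-0.5 * log(w1) - 0.25 * log(w2), P = p, Q = q, saturated = FALSE)
}

#' Pairwise K2P distance matrix
#'
#' @param seqs Named character vector of aligned sequences.
#' @return List with `matrix` (saturated pairs `NA`) and `saturated`
#'   (logical matrix flagging them).
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- k2p_distance(seqs[[i]], seqs[[j]])
    d[i, j] <- d[j, i] <- as.numeric(v)
    sat[i, j] <- sat[j, i] <- attr(v, "saturated")
  }
  list(matrix = d, saturated = sat)
}

#' Neighbor-joining tree with optional midpoint rooting
#'
#' Standard NJ agglomeration (via ape) on a symmetric distance matrix;
#' negative branch-length estimates are clamped to zero and flagged.
#'
#' @param d Symmetric distance matrix with labels, or `dist`.
#' @param midpoint Root at the midpoint of the longest leaf-to-leaf path?
#' @return An `ape::phylo` tree with attribute `clamped` (number of
#'   negative branch estimates set to zero).
#' @export
nj_tree <- function(d, midpoint = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (midpoint) tr <- phangorn::midpoint(tr)
  attr(tr, "clamped") <- neg
  tr
}

#' Midpoint-root a tree
#'
#' @param tree An `ape::phylo` tree.
#' @return The midpoint-rooted tree.
#' @export
midpoint_root <- function(tree) phangorn::midpoint(tree)

#' Majority-vote consensus across haplotypes
#'
#' Per site, the allele carried by the strict majority of haplotypes;
#' exact ties resolve to the reference allele and are flagged.
#'
#' @param haps A `haplotype_set`.
#' @return Tibble `chrom`, `pos`, `allele` (0/1), `base`, `tie`.
#' @export
majority_vote_consensus <- function(haps) {
  n <- n_haplotypes(haps)
  cnt1 <- colSums(haps$hap)
  tie <- cnt1 * 2L == n
  allele <- if_else(cnt1 * 2L > n, 1L, 0L)   # ties -> reference
  tibble(chrom = haps$sites$chrom, pos = haps$sites$pos, allele = allele,
         base = if_else(allele == 1L,
                        vapply(strsplit(haps$sites$alt, ","), `[`, "", 1),
                        haps$sites$ref),
         tie = tie)
}

#' Hierarchical clustering of genotypes with Gower distances
#'
#' Genotypes are encoded as alternate-allele dosages (0/1/2); the Gower
#' dissimilarity averages `|x - y| / range` over non-missing sites
#' (equivalently via `cluster::daisy`), followed by agglomerative
#' clustering.
#'
#' @param table A `genotype_table`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return List with `dist` (a `dist`), `hclust` (the dendrogram) and
#'   `dosage` (the samples x sites dosage matrix).
#' @export
gower_cluster <- function(table, linkage = "average") {
  stopifnot(inherits(table, "genotype_table"))
  dos <- table$a1 + table$a2
  rownames(dos) <- table$samples
  dd <- cluster::daisy(as.data.frame(dos), metric = "gower")
  list(dist = dd, hclust = stats::hclust(dd, method = linkage), dosage = dos)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Symmetric labelled matrix.
#' @param path Output file.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
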