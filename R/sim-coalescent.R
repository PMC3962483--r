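# Sequentially Markov coalescent simulator.
#
# The genealogy at the left end of the chromosome is a Kingman coalescent
# tree; moving rightwards, recombination breakpoints arrive at rate
# 2 * Ne * r * T_total per bp (T_total = total branch length in units of
# 2*Ne generations).  At a breakpoint a uniformly chosen branch point is
# detached and the floating lineage re-coalesces with the remaining tree
# (SMC of McVean & Cardin).  Marginal trees are exactly Kingman-distributed,
# so single-site expectations (Watterson's theta, the site-frequency
# spectrum) hold exactly; correlations between nearby trees generate
# realistic LD decay.  Mutations follow the infinite-sites model.

#' Simulation configuration
#'
#' Defaults describe the wild medaka study conditions: per-generation,
#' per-bp mutation rate `2.5e-8` and a diploid effective size of 15,000 so
#' that expected nucleotide heterozygosity `4*Ne*mu` is `1.5e-3`, the level
#' observed in a wild catch.  Recombination defaults to the mutation rate.
#'
#' @param seed Integer seed; fully determines the output.
#' @param sequence_length Sequence length in bp.
#' @param n_haplotypes Even number of haplotypes to sample.
#' @param mutation_rate Per-bp, per-generation mutation rate.
#' @param recombination_rate Per-bp, per-generation recombination rate.
#' @param effective_size Diploid effective population size.
#' @param chrom Chromosome label for emitted sites.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, sequence_length = 1e5, n_haplotypes = 48L,
                       mutation_rate = 2.5e-8, recombination_rate = 2.5e-8,
                       effective_size = 15000, chrom = "chr1") {
  if (sequence_length < 1) abort("sequence_length must be positive")
  if (n_haplotypes < 2 || n_haplotypes %% 2 != 0) abort("n_haplotypes must be even and >= 2")
  if (mutation_rate < 0 || recombination_rate < 0 || effective_size <= 0) {
    abort("rates must be >= 0 and effective_size > 0")
  }
  structure(list(seed = as.integer(seed), sequence_length = sequence_length,
                 n_haplotypes = as.integer(n_haplotypes),
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 effective_size = effective_size, chrom = chrom),
            class = "sim_config")
}

# A tree over n leaves: parent/time arrays over node ids 1..2n-1, root id.
sim_kingman_tree <- function(n) {
  parent <- rep(NA_integer_, 2L * n - 1L)
  time <- numeric(2L * n - 1L)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1L, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    parent[active[pick]] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, root = nxt - 1L, n = n)
}

tree_branch_lengths <- function(tr) {
  bl <- rep(0, length(tr$parent))
  has_p <- !is.na(tr$parent)
  bl[has_p] <- tr$time[tr$parent[has_p]] - tr$time[which(has_p)]
  bl
}

# Leaves below each node (list of integer vectors), by increasing time order.
tree_descendants <- function(tr) {
  n <- tr$n
  desc <- vector("list", length(tr$parent))
  for (i in seq_len(n)) desc[[i]] <- i
  ord <- order(tr$time[(n + 1L):length(tr$time)]) + n
  for (v in ord) {
    ch <- which(tr$parent == v)
    desc[[v]] <- unlist(desc[ch], use.names = FALSE)
  }
  desc
}

# One SMC transition: prune a uniform branch point, re-coalesce.
smc_step <- function(tr) {
  bl <- tree_branch_lengths(tr)
  b <- sample.int(length(bl), 1L, prob = bl)
  u <- tr$time[b] + runif(1L) * bl[b]
  pb <- tr$parent[b]
  ch <- which(tr$parent == pb)
  sib <- ch[ch != b]
  ppb <- tr$parent[pb]
  # excise pb, splice sib through
  if (is.na(ppb)) {
    tr$parent[sib] <- NA_integer_
    root0 <- sib
  } else {
    tr$parent[sib] <- ppb
    root0 <- tr$root
  }
  tr$parent[b] <- NA_integer_
  # nodes of the floating subtree rooted at b
  in_float <- rep(FALSE, length(tr$parent))
  stack <- b
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    in_float[v] <- TRUE
    stack <- c(stack, which(tr$parent == v & !in_float))
  }
  # remaining edges: nodes (not root0, not pb, not floating) with a parent
  rem <- which(!in_float & seq_along(tr$parent) != pb &
                 (!is.na(tr$parent) | seq_along(tr$parent) == root0))
  rem_nonroot <- setdiff(rem, root0)
  t_lo <- tr$time[rem_nonroot]
  t_hi <- tr$time[tr$parent[rem_nonroot]]
  troot <- tr$time[root0]
  # piecewise-constant lineage count above u
  brks <- sort(unique(c(u, t_lo[t_lo > u], t_hi[t_hi > u], max(troot, u))))
  draw <- rexp(1L)
  tc <- NA_real_
  for (i in seq_along(brks)) {
    lo <- brks[i]
    hi <- if (i < length(brks)) brks[i + 1L] else Inf
    k <- sum(t_lo <= lo & t_hi > lo) + (lo >= troot)
    if (k <= 0) next
    if (is.finite(hi) && draw > k * (hi - lo)) {
      draw <- draw - k * (hi - lo)
    } else {
      tc <- lo + draw / k
      break
    }
  }
  # choose target edge among those crossing tc (root lineage included)
  cand <- rem_nonroot[t_lo <= tc & t_hi > tc]
  if (tc >= troot) cand <- c(cand, root0)
  target <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  tr$time[pb] <- tc
  if (target == root0 && tc >= troot) {
    tr$parent[root0] <- pb
    tr$parent[pb] <- NA_integer_
    tr$parent[b] <- pb
    tr$root <- pb
  } else {
    tr$parent[pb] <- tr$parent[target]
    tr$parent[target] <- pb
    tr$parent[b] <- pb
    tr$root <- root0
  }
  tr
}

#' Simulate a neutral, recombining population sample
#'
#' Generates phased haplotypes for a panmictic constant-size population
#' under the sequentially Markov coalescent with infinite-sites mutation.
#' Every site is polarized: allele 0 is ancestral and recorded as the
#' reference allele (`anc = "ref"`).
#'
#' @param config A [sim_config()].
#' @return A [haplotype_set()].
#' @examples
#' haps <- simulate_neutral_population(sim_config(seed = 1, sequence_length = 2e4))
#' haps
#' @export
simulate_neutral_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_haplotypes
  L <- config$sequence_length
  two_n_e <- 2 * config$effective_size
  mut_per_bp <- config$mutation_rate * two_n_e   # per unit coalescent time
  rec_per_bp <- config$recombination_rate * two_n_e
  tr <- sim_kingman_tree(n)
  pos <- 0
  mut_pos <- numeric(0)
  mut_carriers <- list()
  while (pos < L) {
    bl <- tree_branch_lengths(tr)
    ttot <- sum(bl)
    seg_end <- if (rec_per_bp * ttot > 0) {
      min(L, pos + rexp(1L, rec_per_bp * ttot))
    } else L
    seg_len <- seg_end - pos
    n_mut <- rpois(1L, mut_per_bp * ttot * seg_len)
    if (n_mut > 0) {
      desc <- tree_descendants(tr)
      branches <- sample.int(length(bl), n_mut, replace = TRUE, prob = bl)
      mut_pos <- c(mut_pos, pos + runif(n_mut) * seg_len)
      mut_carriers <- c(mut_carriers, desc[branches])
    }
    if (seg_end >= L) break
    tr <- smc_step(tr)
    pos <- seg_end
  }
  build_haplotype_set_from_mutations(mut_pos, mut_carriers, n, L, config$chrom)
}

build_haplotype_set_from_mutations <- function(mut_pos, mut_carriers, n, L, chrom) {
  keep <- lengths(mut_carriers) > 0 & lengths(mut_carriers) < n
  mut_pos <- mut_pos[keep]; mut_carriers <- mut_carriers[keep]
  ipos <- pmin(floor(mut_pos) + 1L, L)
  ord <- order(ipos)
  ipos <- ipos[ord]; mut_carriers <- mut_carriers[ord]
  dup <- duplicated(ipos)
  ipos <- ipos[!dup]; mut_carriers <- mut_carriers[!dup]
  m <- length(ipos)
  hap <- matrix(0L, n, m)
  for (j in seq_len(m)) hap[mut_carriers[[j]], j] <- 1L
  bases <- c("A", "C", "G", "T")
  ref <- if (m) sample(bases, m, replace = TRUE) else character(0)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "", USE.NAMES = FALSE)
  sites <- tibble(chrom = rep(chrom, m), pos = as.integer(ipos),
                  ref = ref, alt = alt, anc = rep("ref", m))
  haplotype_set(sites, hap)
}

#' Watterson expectation for the number of segregating sites
#'
#' `E[S] = 4 * Ne * mu * L * sum_{i=1}^{n-1} 1/i` under the neutral
#' coalescent; used as the closed-form oracle for the simulator.
#'
#' @param config A [sim_config()].
#' @return Expected segregating-site count.
#' @export
expected_segregating_sites <- function(config) {
  theta <- 4 * config$effective_size * config$mutation_rate * config$sequence_length
  theta * sum(1 / seq_len(config$n_haplotypes - 1L))
}

#' Folded site-frequency spectrum
#'
#' @param haps A `haplotype_set` (allele 0 taken as ancestral unless `anc`
#'   says otherwise).
#' @return Tibble with minor/derived-allele count classes and site counts.
#' @export
folded_sfs <- function(haps) {
  n <- n_haplotypes(haps)
  dc <- colSums(haps$hap)
  fold <- pmin(dc, n - dc)
  tibble(k = seq_len(floor(n / 2)),
         count = vapply(seq_len(floor(n / 2)), function(k) sum(fold == k), 0L))
}

# Neutral expectation of the folded SFS (proportions over classes 1..n/2).
expected_folded_sfs <- function(n) {
  k <- seq_len(floor(n / 2))
  eta <- (1 / k + 1 / (n - k)) / (1 + (k == n - k))
  tibble(k = k, prop = eta / sum(eta))
}
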