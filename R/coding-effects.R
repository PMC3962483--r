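# SNP effect classification on coding exons, codon-enumeration expected
# class fractions and binomial depletion tests.
#
# Effect classes: "nonsense" (sense codon -> stop), "stop-codon"
# (stop codon -> sense, i.e. stop-loss), "missense", "synonymous".
# Ambiguities across overlapping transcripts resolve in that order of
# preference.

effect_classes <- c("nonsense", "stop-codon", "missense", "synonymous")

#' Build an exon model table
#'
#' An exon model is a tibble of coding-exon intervals: one row per CDS
#' exon with `gene`, `transcript`, `chrom`, `start`, `end` (1-based
#' inclusive) and `strand` (`"+"`/`"-"`).  Exon order along the transcript
#' follows genomic order on `+` transcripts and reverse order on `-`.
#' CDS lengths must be multiples of three.
#'
#' @param df Data frame with the columns above.
#' @return Validated `exon_model` tibble.
#' @export
exon_model <- function(df) {
  df <- as_tibble(df)
  need <- c("gene", "transcript", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    abort(paste("exon model needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  len <- df |>
    group_by(.data$transcript) |>
    summarise(l = sum(.data$end - .data$start + 1))
  if (any(len$l %% 3 != 0)) {
    abort(sprintf("CDS length not a multiple of 3 for: %s",
                  paste(len$transcript[len$l %% 3 != 0], collapse = ", ")))
  }
  structure(arrange(df, .data$transcript, .data$start),
            class = c("exon_model", class(tibble())))
}

#' Read an exon model from GFF3
#'
#' Extracts `CDS` features; `gene` and `transcript` come from the `Parent`
#' and `gene_id`/`ID` attributes as available.
#'
#' @param path GFF3 file.
#' @return An [exon_model()] tibble.
#' @export
read_exon_model <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  g <- rtracklayer::import(path)
  g <- g[g$type == "CDS"]
  parent <- vapply(as.list(g$Parent), function(p) if (length(p)) p[[1]] else NA_character_, "")
  gene <- if (!is.null(g$gene_id)) g$gene_id else sub("\\..*", "", parent)
  exon_model(tibble(
    gene = gene, transcript = parent,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g))
  ))
}

# CDS genomic coordinates of one transcript, 5'->3'.
transcript_cds_positions <- function(model, tx) {
  ex <- model[model$transcript == tx, ]
  ex <- ex[order(ex$start), ]
  pos <- unlist(map2(ex$start, ex$end, seq), use.names = FALSE)
  if (ex$strand[1] == "-") rev(pos) else pos
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

translate_codon <- function(codon, code) {
  unname(code[codon])
}

#' Classify the coding effect of a SNP
#'
#' For every transcript whose CDS covers the site, rebuilds the affected
#' codon from the reference sequence (strand- and frame-aware), applies
#' the substitution and compares amino acids.  The resolved class is the
#' most severe across transcripts (nonsense > stop-codon > missense >
#' synonymous).
#'
#' @param site One-row tibble (or list) with `chrom`, `pos`, `ref`, `alt`
#'   (single alternate base).
#' @param model An [exon_model()].
#' @param reference Named character vector of chromosome sequences.
#' @param code Genetic code (named character vector over 64 codons);
#'   defaults to the standard code.
#' @return List with `per_transcript` (tibble `transcript`, `codon_ref`,
#'   `codon_alt`, `aa_ref`, `aa_alt`, `class`) and `resolved` (character,
#'   `NA` when no transcript covers the site or the codon is incomplete).
#' @export
classify_snp <- function(site, model, reference, code = standard_genetic_code()) {
  cover <- model[model$chrom == site$chrom & model$start <= site$pos &
                   model$end >= site$pos, ]
  txs <- unique(cover$transcript)
  rows <- list()
  for (tx in txs) {
    pos5 <- transcript_cds_positions(model, tx)
    cds_idx <- match(site$pos, pos5)
    if (is.na(cds_idx)) next
    strand <- model$strand[model$transcript == tx][1]
    codon_i <- (cds_idx - 1L) %/% 3L
    cpos <- pos5[codon_i * 3L + 1:3]
    if (anyNA(cpos)) {
      rows[[tx]] <- tibble(transcript = tx, codon_ref = NA, codon_alt = NA,
                           aa_ref = NA, aa_alt = NA, class = NA_character_)
      next
    }
    chrseq <- reference[[site$chrom]]
    gbase <- toupper(substring(chrseq, cpos, cpos))
    ref_b <- toupper(site$ref); alt_b <- toupper(site$alt)
    if (strand == "-") gbase <- comp_base[gbase]
    codon_ref <- paste(gbase, collapse = "")
    within <- which(cpos == site$pos)
    sub_ref <- if (strand == "-") comp_base[[ref_b]] else ref_b
    sub_alt <- if (strand == "-") comp_base[[alt_b]] else alt_b
    if (gbase[within] != sub_ref) {
      abort(sprintf("reference mismatch for %s at %s:%d", tx, site$chrom, site$pos))
    }
    calt <- gbase
    calt[within] <- sub_alt
    codon_alt <- paste(calt, collapse = "")
    aa_ref <- translate_codon(codon_ref, code)
    aa_alt <- translate_codon(codon_alt, code)
    cls <- if (aa_ref != "*" && aa_alt == "*") "nonsense"
      else if (aa_ref == "*" && aa_alt != "*") "stop-codon"
      else if (aa_ref == aa_alt) "synonymous"
      else "missense"
    rows[[tx]] <- tibble(transcript = tx, codon_ref = codon_ref,
                         codon_alt = codon_alt, aa_ref = aa_ref,
                         aa_alt = aa_alt, class = cls)
  }
  per <- if (length(rows)) bind_rows(rows) else
    tibble(transcript = character(), codon_ref = character(),
           codon_alt = character(), aa_ref = character(),
           aa_alt = character(), class = character())
  cls <- per$class[!is.na(per$class)]
  resolved <- if (!length(cls)) NA_character_ else
    effect_classes[min(match(cls, effect_classes))]
  list(per_transcript = per, resolved = resolved)
}

#' Classify many SNPs at once
#'
#' @param sites Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @inheritParams classify_snp
#' @return `sites` with a `class` column (resolved class, `NA` outside
#'   CDS or for incomplete codons).
#' @export
classify_variant_effects <- function(sites, model, reference,
                                     code = standard_genetic_code()) {
  sites$class <- vapply(seq_len(nrow(sites)), function(i) {
    classify_snp(sites[i, ], model, reference, code)$resolved
  }, "")
  sites
}

#' The standard genetic code
#'
#' @return Named character vector mapping the 64 codons to one-letter
#'   amino acids (`*` = stop), from Biostrings.
#' @export
standard_genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

#' Codon usage frequencies from coding sequences
#'
#' @param cds Character vector of in-frame CDS sequences.
#' @return Named numeric vector of codon frequencies summing to 1.
#' @export
codon_frequencies <- function(cds) {
  counts <- table(unlist(lapply(toupper(cds), function(s) {
    n <- nchar(s) - nchar(s) %% 3
    substring(s, seq(1, n, 3), seq(3, n, 3))
  })))
  all_codons <- names(standard_genetic_code())
  out <- setNames(rep(0, 64), all_codons)
  out[names(counts)] <- as.numeric(counts)
  out / sum(out)
}

#' Expected effect-class fractions from codon enumeration
#'
#' Enumerates all nine single-nucleotide substitutions of every codon,
#' classifies each, and averages the class indicators weighted by codon
#' frequency.  By default stop codons are dropped from the weighting
#' (substitutions are evaluated within sense codons, as appropriate for
#' frequencies measured on coding sequence); set
#' `include_stop_codons = TRUE` to weight them too.  Unnormalized
#' frequencies are rescaled.
#'
#' @param codon_freq Named numeric vector of codon frequencies (any
#'   subset of the 64 codons).
#' @param code Genetic code.
#' @param include_stop_codons Keep stop codons in the weighting?
#' @return Tibble with `class` and `expected_fraction` (summing to 1).
#' @export
expected_class_fractions <- function(codon_freq, code = standard_genetic_code(),
                                     include_stop_codons = FALSE) {
  if (any(codon_freq < 0)) abort("codon frequencies must be non-negative")
  codon_freq <- codon_freq[codon_freq > 0]
  if (!include_stop_codons) {
    codon_freq <- codon_freq[code[names(codon_freq)] != "*"]
  }
  codon_freq <- codon_freq / sum(codon_freq)
  bases <- c("A", "C", "G", "T")
  acc <- setNames(rep(0, length(effect_classes)), effect_classes)
  for (codon in names(codon_freq)) {
    cb <- strsplit(codon, "")[[1]]
    aa_ref <- code[[codon]]
    for (p in 1:3) for (b in setdiff(bases, cb[p])) {
      nb <- cb; nb[p] <- b
      aa_alt <- code[[paste(nb, collapse = "")]]
      cls <- if (aa_ref != "*" && aa_alt == "*") "nonsense"
        else if (aa_ref == "*" && aa_alt != "*") "stop-codon"
        else if (aa_ref == aa_alt) "synonymous"
        else "missense"
      acc[cls] <- acc[cls] + codon_freq[[codon]] / 9
    }
  }
  tibble(class = effect_classes, expected_fraction = unname(acc))
}

#' One-sided binomial depletion test per effect class
#'
#' Tests whether each observed class count falls below its codon-
#' enumeration expectation (`n_total * expected_fraction`), one-sided.
#' The exact binomial tail is computed in log space, so extreme depletion
#' reports a finite `log10_p` even when `p_value` underflows to zero.
#'
#' @param observed Named integer vector of observed counts per class (any
#'   subset of the four classes).
#' @param expected Tibble from [expected_class_fractions()] or named
#'   vector of fractions.
#' @return Tibble with `class`, `observed`, `n_total`,
#'   `expected_fraction`, `ratio` (obs/exp), `p_value`, `log10_p`.
#' @export
depletion_test <- function(observed, expected) {
  if (is.data.frame(expected)) {
    expected <- setNames(expected$expected_fraction, expected$class)
  }
  n_total <- sum(observed)
  out <- map(names(observed), function(cl) {
    p <- expected[[cl]]
    k <- observed[[cl]]
    lp <- pbinom(k, n_total, p, lower.tail = TRUE, log.p = TRUE)
    tibble(class = cl, observed = as.integer(k), n_total = n_total,
           expected_fraction = p,
           ratio = (k / n_total) / p,
           p_value = exp(lp),
           log10_p = lp / log(10))
  })
  bind_rows(out)
}
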