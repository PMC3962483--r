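# In-silico mitotyping: PCR amplification, restriction digestion,
# fragment-pattern equivalence classes, and D-loop sequence typing.

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# All start positions of `pattern` in `subject` (exact match).
match_starts <- function(pattern, subject) {
  Biostrings::start(Biostrings::matchPattern(pattern, Biostrings::DNAString(subject)))
}

#' In-silico PCR amplification
#'
#' The amplicon runs from the forward-primer start to the end of the
#' reverse complement of the reverse primer.  Circular templates are
#' handled by searching the doubled sequence, so amplicons may span the
#' origin.  Zero or multiple possible amplicons are errors.
#'
#' @param template Template sequence (character string).
#' @param forward,reverse Primer sequences, 5'->3' (the reverse primer on
#'   the opposite strand, as supplied to a PCR).
#' @param circular Is the template circular?
#' @return List with `sequence`, `start`, `end` (1-based on the
#'   template; `end` may exceed the template length for origin-spanning
#'   amplicons on circular templates) and `length`.
#' @export
insilico_pcr <- function(template, forward, reverse, circular = FALSE) {
  template <- toupper(template)
  L <- nchar(template)
  subject <- if (circular) paste0(template, template) else template
  f_hits <- match_starts(toupper(forward), subject)
  r_site <- revcomp(toupper(reverse))
  r_hits <- match_starts(r_site, subject)
  if (circular) {
    f_hits <- f_hits[f_hits <= L]
  }
  amps <- list()
  for (f in f_hits) {
    ends <- r_hits[r_hits >= f] + nchar(r_site) - 1L
    ends <- ends[ends - f + 1L <= L]   # at most one template length
    if (length(ends)) {
      amps[[length(amps) + 1]] <- c(start = f, end = min(ends))
    }
  }
  if (!length(amps)) abort("no amplicon: primer pair does not anneal in order")
  if (length(amps) > 1) abort("ambiguous amplification: multiple amplicons")
  a <- amps[[1]]
  list(sequence = substring(subject, a["start"], a["end"]),
       start = unname(a["start"]), end = unname(a["end"]),
       length = unname(a["end"] - a["start"] + 1L))
}

#' Restriction enzymes used for cytochrome-B mitotyping
#'
#' Recognition sites with canonical cut offsets (bases 5' of the cut
#' within the site): HaeIII GG/CC, MboI /GATC, MspI C/CGG, RsaI GT/AC,
#' TaqI T/CGA.
#'
#' @return Tibble with `enzyme`, `site`, `cut_offset`.
#' @export
mitotyping_enzymes <- function() {
  tibble(enzyme = c("HaeIII", "MboI", "MspI", "RsaI", "TaqI"),
         site = c("GGCC", "GATC", "CCGG", "GTAC", "TCGA"),
         cut_offset = c(2L, 0L, 1L, 2L, 1L))
}

#' Restriction digest of an amplicon
#'
#' Cuts at every occurrence of each enzyme's recognition site (offset
#' within the site per [mitotyping_enzymes()]) and returns sorted
#' fragment lengths per enzyme; fragments always sum to the amplicon
#' length.
#'
#' @param amplicon Sequence to digest (character string).
#' @param enzymes Tibble like [mitotyping_enzymes()].
#' @return Tibble `enzyme`, `fragments` (list column of sorted integer
#'   lengths), `n_fragments`.
#' @export
restriction_digest <- function(amplicon, enzymes = mitotyping_enzymes()) {
  amplicon <- toupper(amplicon)
  L <- nchar(amplicon)
  out <- map(seq_len(nrow(enzymes)), function(i) {
    cuts <- match_starts(enzymes$site[i], amplicon) + enzymes$cut_offset[i] - 1L
    cuts <- sort(cuts[cuts >= 1 & cuts < L])   # cut after this base
    frag <- diff(c(0L, cuts, L))
    tibble(enzyme = enzymes$enzyme[i], fragments = list(sort(frag)),
           n_fragments = length(frag))
  })
  bind_rows(out)
}

#' Assign mitotypes from multi-enzyme fragment patterns
#'
#' Fragment lengths are binned to `resolution` bp (emulating gel
#' resolution); samples with identical binned five-enzyme patterns share
#' a mitotype label (`M1`, `M2`, ... in order of first appearance).
#'
#' @param digests Named list of digest tibbles (one per sample, from
#'   [restriction_digest()]).
#' @param resolution Gel resolution in bp (default 20).
#' @return Tibble `sample`, `mitotype`, `pattern` (the binned signature).
#' @export
assign_mitotype <- function(digests, resolution = 20) {
  sig <- vapply(digests, function(d) {
    paste(vapply(seq_len(nrow(d)), function(i) {
      paste0(d$enzyme[i], ":",
             paste(round(d$fragments[[i]] / resolution), collapse = ","))
    }, ""), collapse = ";")
  }, "")
  labels <- paste0("M", match(sig, unique(sig)))
  tibble(sample = names(digests) %||% as.character(seq_along(digests)),
         mitotype = labels, pattern = sig)
}

#' D-loop sequence typing
#'
#' Trims each sequence to `trim_to` bp, drops (with a warning) sequences
#' shorter than that, collapses exact duplicates and reports the variant
#' classes.
#'
#' @param sequences Named character vector of D-loop sequences.
#' @param trim_to Comparison length in bp (default 508).
#' @return List with `variants` (tibble `variant`, `sequence`, `count`)
#'   and `membership` (tibble `sample`, `variant`).
#' @export
dloop_typing <- function(sequences, trim_to = 508) {
  keep <- nchar(sequences) >= trim_to
  if (any(!keep)) {
    warn(sprintf("%d sequence(s) shorter than %d bp excluded", sum(!keep), trim_to))
  }
  s <- toupper(substr(sequences[keep], 1, trim_to))
  uniq <- unique(s)
  vid <- paste0("V", match(s, uniq))
  list(
    variants = tibble(variant = paste0("V", seq_along(uniq)), sequence = uniq,
                      count = as.integer(table(vid)[paste0("V", seq_along(uniq))])),
    membership = tibble(sample = names(s) %||% as.character(seq_along(s)),
                        variant = vid)
  )
}
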