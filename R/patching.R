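# Reference "patching": single-base revision of an assembly from
# deep-coverage consensus calls, plus its validation metrics.

#' Patch a reference sequence with consensus calls
#'
#' Unresolved reference positions (`N`) with a defined consensus base are
#' always filled.  Positions where a defined reference base disagrees with
#' the call are revised only when the call quality reaches
#' `quality_threshold` in `"thresholded"` mode, and unconditionally in
#' `"unthresholded"` mode.  Ambiguous (non-ACGT) consensus calls never
#' revise anything.  Every change is emitted as a patch record.
#'
#' @param reference Reference sequence (single character string; may
#'   contain `N`).
#' @param calls Tibble with columns `pos` (1-based), `base`, `qual` and
#'   optionally `depth`; one call per position.
#' @param quality_threshold Minimum quality for a discrepant revision.
#' @param mode `"thresholded"` or `"unthresholded"`.
#' @return List with `sequence` (patched string) and `records` (tibble
#'   `pos`, `old`, `new`, `qual`, `class`).
#' @export
patch_reference <- function(reference, calls, quality_threshold = 100,
                            mode = c("thresholded", "unthresholded")) {
  mode <- match.arg(mode)
  refv <- strsplit(toupper(reference), "")[[1]]
  if (nrow(calls) == 0) {
    return(list(sequence = paste(refv, collapse = ""), records = empty_patch_records()))
  }
  if (anyDuplicated(calls$pos)) abort("conflicting calls: duplicated positions")
  if (any(calls$pos < 1 | calls$pos > length(refv))) {
    abort("calls fall outside the reference")
  }
  base <- toupper(calls$base)
  defined <- base %in% c("A", "C", "G", "T")
  old <- refv[calls$pos]
  is_n <- old == "N"
  fill <- is_n & defined
  revise <- !is_n & defined & base != old &
    (mode == "unthresholded" | calls$qual >= quality_threshold)
  change <- fill | revise
  refv[calls$pos[change]] <- base[change]
  records <- tibble(
    pos = as.integer(calls$pos[change]),
    old = old[change],
    new = base[change],
    qual = calls$qual[change],
    class = if_else(is_n[change], "N-fill", "discrepant-revision")
  ) |> arrange(.data$pos)
  list(sequence = paste(refv, collapse = ""), records = records)
}

empty_patch_records <- function() {
  tibble(pos = integer(), old = character(), new = character(),
         qual = numeric(), class = character())
}

#' Concordance of patch records with an independent genotype panel
#'
#' A record "matches" a sample when its new base occurs among that
#' sample's alleles at the record position; the strict fraction requires a
#' match in every non-missing sample, the lenient one in at least one.
#' Records at positions the panel does not cover are excluded from both
#' denominators and counted.
#'
#' @param records Patch-record tibble from [patch_reference()].
#' @param panel A `genotype_table` on the same coordinates (single
#'   chromosome assumed when `chrom` is omitted from the records).
#' @return Tibble with `frac_all`, `frac_any`, `n_used`, `n_uncovered`.
#' @export
panel_concordance <- function(records, panel) {
  stopifnot(inherits(panel, "genotype_table"))
  hit <- match(records$pos, panel$sites$pos)
  used <- which(!is.na(hit))
  all_m <- logical(0); any_m <- logical(0)
  for (k in used) {
    j <- hit[k]
    alleles <- c(panel$sites$ref[j], strsplit(panel$sites$alt[j], ",")[[1]])
    a1 <- panel$a1[, j]; a2 <- panel$a2[, j]
    ok <- !is.na(a1)
    if (!any(ok)) { hit[k] <- NA; next }
    has_new <- alleles[a1[ok] + 1L] == records$new[k] |
      alleles[a2[ok] + 1L] == records$new[k]
    all_m <- c(all_m, all(has_new))
    any_m <- c(any_m, any(has_new))
  }
  n_used <- length(all_m)
  tibble(
    frac_all = if (n_used) mean(all_m) else NA_real_,
    frac_any = if (n_used) mean(any_m) else NA_real_,
    n_used = n_used,
    n_uncovered = nrow(records) - n_used
  )
}

#' Ancestral-consistency fold change of revised positions
#'
#' Among records with a defined outgroup base, computes the fraction of
#' positions whose new base equals the outgroup base over the fraction
#' whose old base does.  A zero denominator yields an undefined
#' (`NA`) fold, flagged rather than infinite.
#'
#' @param records Patch records (typically class `discrepant-revision`).
#' @param outgroup Outgroup sequence on reference coordinates (character
#'   string).
#' @return Tibble `fold`, `frac_new`, `frac_old`, `n_used`, `undefined`.
#' @export
ancestral_consistency_fold <- function(records, outgroup) {
  ob <- toupper(substring(outgroup, records$pos, records$pos))
  use <- ob %in% c("A", "C", "G", "T")
  frac_new <- mean(records$new[use] == ob[use])
  frac_old <- mean(records$old[use] == ob[use])
  undefined <- !sum(use) || frac_old == 0
  tibble(
    fold = if (undefined) NA_real_ else frac_new / frac_old,
    frac_new = if (sum(use)) frac_new else NA_real_,
    frac_old = if (sum(use)) frac_old else NA_real_,
    n_used = sum(use),
    undefined = undefined
  )
}

#' Supplement remaining undefined positions from other strains
#'
#' Positions still `N` after patching are supplemented when at least
#' `min_strains_agreeing` strain consensus call sets agree on one defined
#' base at that position.
#'
#' @param patched Patched sequence (character string).
#' @param strain_calls List of call tibbles (`pos`, `base`, ...), one per
#'   strain.
#' @param min_strains_agreeing Required number of agreeing strains;
#'   defaults to all strains supplied.
#' @return Patch-record tibble with class `strain-supplement`.
#' @export
supplement_from_strains <- function(patched, strain_calls,
                                    min_strains_agreeing = length(strain_calls)) {
  refv <- strsplit(toupper(patched), "")[[1]]
  n_pos <- which(refv == "N")
  if (!length(n_pos)) return(empty_patch_records())
  calls <- bind_rows(lapply(seq_along(strain_calls), function(i) {
    mutate(strain_calls[[i]][c("pos", "base")], strain = i)
  })) |>
    filter(.data$pos %in% n_pos, toupper(.data$base) %in% c("A", "C", "G", "T"))
  if (!nrow(calls)) return(empty_patch_records())
  agg <- calls |>
    mutate(base = toupper(.data$base)) |>
    distinct(.data$pos, .data$base, .data$strain) |>
    dplyr::count(.data$pos, .data$base) |>
    group_by(.data$pos) |>
    slice(which.max(.data$n)) |>
    ungroup() |>
    filter(.data$n >= min_strains_agreeing)
  tibble(pos = as.integer(agg$pos), old = "N", new = agg$base,
         qual = NA_real_, class = "strain-supplement") |> arrange(.data$pos)
}

#' Apply patch records to a sequence
#'
#' @param sequence Character string.
#' @param records Patch-record tibble.
#' @return The revised sequence.
#' @export
apply_patch_records <- function(sequence, records) {
  refv <- strsplit(sequence, "")[[1]]
  refv[records$pos] <- records$new
  paste(refv, collapse = "")
}
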