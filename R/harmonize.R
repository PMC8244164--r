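COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize outcome associations to the exposure's effect allele
#'
#' Re-expresses each outcome association on the exposure's effect allele so
#' that the Wald ratio (SNP-on-outcome divided by SNP-on-exposure) refers to
#' the same allele in numerator and denominator. Handles three situations:
#'
#' * alleles already aligned — outcome kept unchanged;
#' * alleles swapped (directly or after strand complement) — outcome beta is
#'   negated and `eaf` replaced by `1 - eaf`;
#' * palindromic variants (A/T or C/G), where strand cannot be resolved from
#'   the alleles — kept, unchanged, only when both effect-allele frequencies
#'   are outside `0.5 +/- palindrome_eaf_window` *and* on the same side of
#'   0.5; otherwise dropped as ambiguous.
#'
#' Variants whose allele sets cannot be reconciled even after strand
#' complementing are excluded with reason `"allele_mismatch"`; variants
#' present in only one table are excluded with reason `"not_in_outcome"` /
#' `"not_in_exposure"`. Harmonization is idempotent: harmonized output passes
#' through unchanged.
#'
#' @param exposure,outcome `sumstats` tables sharing `variant_id`s.
#' @param palindrome_eaf_window Half-width `w` of the ambiguity window around
#'   0.5 for palindromic variants (default 0.08).
#'
#' @return A list with elements `exposure` and `outcome` (row-aligned
#'   `sumstats` tables for the retained variants, outcome alleles rewritten
#'   to the exposure's) and `dropped` (data.frame of `variant_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  w <- palindrome_eaf_window
  stopifnot(is.numeric(w), w >= 0, w < 0.5)

  dropped <- list()
  drop <- function(id, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(
      variant_id = id, reason = reason, stringsAsFactors = FALSE)
  }
  only_exp <- setdiff(exposure$variant_id, outcome$variant_id)
  for (id in only_exp) drop(id, "not_in_outcome")
  only_out <- setdiff(outcome$variant_id, exposure$variant_id)
  for (id in only_out) drop(id, "not_in_exposure")

  shared <- intersect(exposure$variant_id, outcome$variant_id)
  e <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  o <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  keep <- logical(length(shared))

  for (i in seq_along(shared)) {
    e_ea <- e$effect_allele[i]; e_oa <- e$other_allele[i]
    o_ea <- o$effect_allele[i]; o_oa <- o$other_allele[i]
    if (is_palindromic(e_ea, e_oa)) {
      # strand is unresolvable from alleles; use allele frequencies
      if (!setequal(c(o_ea, o_oa), c(e_ea, e_oa))) {
        drop(shared[i], "allele_mismatch"); next
      }
      f_e <- e$eaf[i]; f_o <- o$eaf[i]
      if (is.na(f_e) || is.na(f_o)) {
        drop(shared[i], "palindromic_no_eaf"); next
      }
      outside <- abs(f_e - 0.5) > w && abs(f_o - 0.5) > w
      same_side <- sign(f_e - 0.5) == sign(f_o - 0.5)
      if (!(outside && same_side)) {
        drop(shared[i], "palindromic_ambiguous"); next
      }
      # frequencies agree in orientation: treat as aligned
      o$effect_allele[i] <- e_ea; o$other_allele[i] <- e_oa
      keep[i] <- TRUE
    } else {
      o_ea_c <- unname(COMPLEMENT[o_ea]); o_oa_c <- unname(COMPLEMENT[o_oa])
      if (o_ea == e_ea && o_oa == e_oa) {
        action <- "none"
      } else if (o_ea == e_oa && o_oa == e_ea) {
        action <- "swap"
      } else if (o_ea_c == e_ea && o_oa_c == e_oa) {
        action <- "none"   # strand complement only
      } else if (o_ea_c == e_oa && o_oa_c == e_ea) {
        action <- "swap"   # complement then swap
      } else {
        drop(shared[i], "allele_mismatch"); next
      }
      if (action == "swap") {
        o$beta[i] <- -o$beta[i]
        if (!is.na(o$eaf[i])) o$eaf[i] <- 1 - o$eaf[i]
      }
      o$effect_allele[i] <- e_ea; o$other_allele[i] <- e_oa
      keep[i] <- TRUE
    }
  }

  dropped_df <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(variant_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  e <- e[keep, , drop = FALSE]; o <- o[keep, , drop = FALSE]
  rownames(e) <- rownames(o) <- NULL
  list(exposure = e, outcome = o, dropped = dropped_df)
}
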