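is_palindromic <- function(ea, oa) !is.na(oa) & oa == unname(COMPLEMENT[ea])

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each exposure index SNP with the outcome dataset onto a common
#' effect allele (the exposure's), resolving allele-order swaps, strand
#' differences, and palindromic ambiguity, substituting LD proxies for
#' variants absent from the outcome, and dropping what cannot be resolved.
#'
#' For each exposure SNP:
#' \itemize{
#'   \item same allele pair in both datasets: kept; if the outcome's effect
#'     allele is the exposure's other allele, the outcome beta sign is
#'     flipped and its frequency replaced by its complement (`flipped`);
#'   \item reverse-complementary allele pair (strand difference,
#'     non-palindromic): complemented, then as above (`strand_swapped`);
#'   \item palindromic pair (A/T or C/G): allele labels cannot distinguish a
#'     strand flip from an allele swap, so orientation is decided by which
#'     side of 0.5 the effect-allele frequency falls on in each dataset —
#'     same side keeps the reported orientation, opposite sides flip
#'     (`palindromic_aligned`); if the folded frequency is within
#'     `palindrome_eaf_window` of 0.5 in either dataset the comparison is
#'     unsafe and the SNP is dropped (`palindromic_dropped`);
#'   \item absent from the outcome: the LD table is searched for the
#'     highest-r2 variant with `r2 > proxy_r2` present in both datasets; the
#'     proxy's own statistics are harmonized in its place (`proxied`), else
#'     the SNP is dropped (`dropped_unmatched`).
#' }
#'
#' @param exposure An `instrument_set` or `summary_stat_set` of exposure
#'   index SNPs. Every record must have both alleles known.
#' @param outcome A `summary_stat_set` for the outcome trait.
#' @param ld Optional `ld_table` used for proxy search.
#' @param proxy_r2 Minimum (strict) r-squared for a proxy; default 0.8.
#' @param palindrome_eaf_window Half-width of the frequency ambiguity zone
#'   around 0.5 for palindromic SNPs; default 0.08. `0` trusts any frequency
#'   difference, however small.
#' @param exposure_full Optional `summary_stat_set` of all exposure
#'   candidates, searched for proxy exposure statistics; defaults to the
#'   index SNPs themselves (a proxy absent from it drops the original).
#' @return A `harmonized_set`: `biomarker`, `instruments` (tibble of aligned
#'   beta/se/eaf pairs with per-SNP decision provenance), `dropped`
#'   (tibble of `variant_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome, ld = NULL, proxy_r2 = 0.8,
                      palindrome_eaf_window = 0.08, exposure_full = NULL) {
  stopifnot(proxy_r2 > 0, proxy_r2 <= 1,
            palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  exp_df <- if (inherits(exposure, "instrument_set")) exposure$records
            else if (inherits(exposure, "summary_stat_set")) exposure$records
            else rlang::abort("exposure must be an instrument_set or summary_stat_set")
  biomarker <- if (inherits(exposure, "instrument_set")) exposure$biomarker
               else exposure$trait_name
  stopifnot(inherits(outcome, "summary_stat_set"))
  if (any(is.na(exp_df$effect_allele) | is.na(exp_df$other_allele) |
          !(exp_df$effect_allele %in% BASES) |
          !(exp_df$other_allele %in% BASES))) {
    rlang::abort("exposure SNP(s) with missing allele information",
                 class = "mr_input_error")
  }
  out_df <- outcome$records
  pool_df <- if (!is.null(exposure_full)) exposure_full$records else exp_df

  kept <- list()
  dropped <- list()
  for (i in seq_len(nrow(exp_df))) {
    ex <- exp_df[i, ]
    target_id <- ex$variant_id
    proxy_of <- NA_character_
    prefix <- character()
    if (!target_id %in% out_df$variant_id) {
      cand <- ld_partners(ld, target_id)
      cand <- cand[!is.na(cand$r2) & cand$r2 > proxy_r2 &
                     cand$variant_id %in% out_df$variant_id &
                     cand$variant_id %in% pool_df$variant_id, ]
      if (nrow(cand) == 0) {
        dropped[[length(dropped) + 1]] <- tibble::tibble(
          variant_id = target_id, reason = "dropped_unmatched",
          detail = sprintf("absent from outcome; no proxy with r2 > %g", proxy_r2))
        next
      }
      proxy_of <- target_id
      target_id <- cand$variant_id[1]
      prefix <- sprintf("proxied via %s (r2 = %g)", target_id, cand$r2[1])
      ex <- pool_df[pool_df$variant_id == target_id, ][1, ]
    }
    ou <- out_df[out_df$variant_id == target_id, ][1, ]
    res <- align_alleles(ex, ou, palindrome_eaf_window)
    detail <- paste(c(prefix, res$detail), collapse = "; ")
    if (res$status == "dropped") {
      dropped[[length(dropped) + 1]] <- tibble::tibble(
        variant_id = proxy_of %|na|% target_id, reason = res$decision,
        detail = detail)
    } else {
      kept[[length(kept) + 1]] <- tibble::tibble(
        variant_id = target_id, proxy_of = proxy_of,
        effect_allele = ex$effect_allele, other_allele = ex$other_allele,
        beta_exposure = ex$beta, se_exposure = ex$se, eaf_exposure = ex$eaf,
        beta_outcome = res$beta_outcome, se_outcome = ou$se,
        eaf_outcome = res$eaf_outcome,
        decision = if (!is.na(proxy_of)) "proxied" else res$decision,
        detail = detail)
    }
  }
  empty_kept <- tibble::tibble(
    variant_id = character(), proxy_of = character(),
    effect_allele = character(), other_allele = character(),
    beta_exposure = numeric(), se_exposure = numeric(),
    eaf_exposure = numeric(), beta_outcome = numeric(),
    se_outcome = numeric(), eaf_outcome = numeric(),
    decision = character(), detail = character())
  structure(list(
    biomarker = biomarker,
    instruments = dplyr::bind_rows(empty_kept, kept),
    dropped = dplyr::bind_rows(
      tibble::tibble(variant_id = character(), reason = character(),
                     detail = character()), dropped)),
    class = "harmonized_set")
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

# Align one outcome record onto the exposure record's allele orientation.
align_alleles <- function(ex, ou, window) {
  flip <- function(detail) list(status = "kept", decision = "flipped",
                                beta_outcome = -ou$beta,
                                eaf_outcome = 1 - ou$eaf, detail = detail)
  keep <- function(decision, detail) list(status = "kept", decision = decision,
                                          beta_outcome = ou$beta,
                                          eaf_outcome = ou$eaf, detail = detail)
  drop <- function(decision, detail) list(status = "dropped",
                                          decision = decision, detail = detail)
  e1 <- ex$effect_allele; e2 <- ex$other_allele
  o1 <- ou$effect_allele; o2 <- ou$other_allele

  if (is_palindromic(e1, e2)) {
    # Strand flips are invisible for A/T and C/G variants; orient by
    # effect-allele frequency instead of allele labels.
    pal_ok <- !is.na(o1) && o1 %in% c(e1, e2) &&
      (is.na(o2) || o2 %in% c(e1, e2))
    if (!pal_ok) return(drop("dropped_unmatched", "incompatible allele pair"))
    f_ex <- min(ex$eaf, 1 - ex$eaf); f_ou <- min(ou$eaf, 1 - ou$eaf)
    if (0.5 - f_ex <= window || 0.5 - f_ou <= window) {
      return(drop("palindromic_dropped",
                  sprintf("folded eaf within %g of 0.5 (exposure %.3g, outcome %.3g)",
                          window, ex$eaf, ou$eaf)))
    }
    same_side <- (ex$eaf > 0.5) == (ou$eaf > 0.5)
    if (same_side) {
      return(keep("palindromic_aligned", "eaf on same side of 0.5; orientation kept"))
    }
    res <- flip("eaf on opposite sides of 0.5; orientation flipped")
    res$decision <- "palindromic_aligned"
    return(res)
  }

  if (is.na(o2) || !(o2 %in% BASES)) {
    return(drop("dropped_unmatched",
                "outcome other allele unknown; strand unresolvable"))
  }
  if (o1 == e1 && o2 == e2) return(keep("kept", "same alleles, same orientation"))
  if (o1 == e2 && o2 == e1) return(flip("effect allele is exposure's other allele"))
  c1 <- unname(COMPLEMENT[o1]); c2 <- unname(COMPLEMENT[o2])
  if (c1 == e1 && c2 == e2) {
    res <- keep("strand_swapped", "alleles complemented to exposure strand")
    return(res)
  }
  if (c1 == e2 && c2 == e1) {
    res <- flip("alleles complemented to exposure strand, then flipped")
    res$decision <- "strand_swapped"
    return(res)
  }
  drop("dropped_unmatched", "incompatible allele pair")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s: %d instrument(s), %d dropped\n",
              x$biomarker, nrow(x$instruments), nrow(x$dropped)))
  print(x$instruments, ...)
  invisible(x)
}

#' Harmonization audit report
#'
#' One row per input SNP, lossless with respect to the per-SNP decisions:
#' kept instruments (with any proxy substitution and the allele action
#' taken) and dropped SNPs with the drop reason.
#'
#' @param h A `harmonized_set`.
#' @return A tibble with `variant_id`, `proxy_of`, `kept`, `decision`,
#'   `detail`.
#' @export
audit_report <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  kept <- tibble::tibble(variant_id = dplyr::coalesce(h$instruments$proxy_of,
                                                      h$instruments$variant_id),
                         proxy_of = h$instruments$proxy_of,
                         kept = rep(TRUE, nrow(h$instruments)),
                         decision = h$instruments$decision,
                         detail = h$instruments$detail)
  dropped <- tibble::tibble(variant_id = h$dropped$variant_id,
                            proxy_of = rep(NA_character_, nrow(h$dropped)),
                            kept = rep(FALSE, nrow(h$dropped)),
                            decision = h$dropped$reason,
                            detail = h$dropped$detail)
  dplyr::bind_rows(kept, dropped)
}
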