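#' Variance in a standardized trait explained by a biallelic SNP
#'
#' R-squared = 2 beta^2 f (1 - f), with f the folded minor-allele frequency
#' `min(eaf, 1 - eaf)` and beta the per-allele effect in trait SD units.
#' Symmetric in `eaf` vs `1 - eaf`, maximal at `eaf = 0.5`, and bounded by
#' `beta^2 / 2`.
#'
#' @param beta Per-allele effect(s) in SD units.
#' @param eaf Effect-allele frequency in `[0, 1]` (vectorised with `beta`).
#' @return Fraction(s) of trait variance explained.
#' @export
variance_explained <- function(beta, eaf) {
  stopifnot(all(eaf >= 0 & eaf <= 1, na.rm = TRUE))
  f <- pmin(eaf, 1 - eaf)
  2 * beta^2 * f * (1 - f)
}

new_instrument_set <- function(biomarker, records, per_snp_variance = NULL,
                               selection_log = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(per_snp_variance)) {
    per_snp_variance <- stats::setNames(
      variance_explained(records$beta, records$eaf), records$variant_id)
  }
  stopifnot(setequal(names(per_snp_variance), records$variant_id))
  per_snp_variance <- per_snp_variance[records$variant_id]
  if (is.null(selection_log)) {
    selection_log <- tibble::tibble(variant_id = character(),
                                    action = character(), reason = character())
  }
  structure(list(biomarker = biomarker, records = records,
                 per_snp_variance = per_snp_variance,
                 total_variance = sum(per_snp_variance),
                 selection_log = selection_log),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d index SNP(s), total variance explained %.4g%%\n",
              x$biomarker, nrow(x$records), 100 * x$total_variance))
  print(x$records, ...)
  invisible(x)
}

#' Filter candidate instruments by association p-value and folded MAF
#'
#' Retains records with `pvalue <= p_threshold` and folded minor-allele
#' frequency `min(eaf, 1 - eaf)` strictly greater than `maf_threshold`.
#' Every exclusion is logged with its reason in the `selection_log`
#' attribute of the returned set.
#'
#' The defaults are the genome-wide Bonferroni threshold 5e-8 and a MAF
#' floor of 0.3. The MAF floor is configurable: published instrument tables
#' for these biomarkers include index SNPs with folded MAF well below 0.3
#' (e.g. 0.066), so a run reproducing them must relax it.
#'
#' @param candidates A `summary_stat_set`.
#' @param p_threshold Keep `pvalue <= p_threshold`; in `(0, 1)`.
#' @param maf_threshold Keep folded MAF `> maf_threshold`; in `[0, 0.5]`.
#' @return A filtered `summary_stat_set` with attribute `selection_log`.
#' @export
filter_candidates <- function(candidates, p_threshold = 5e-8,
                              maf_threshold = 0.3) {
  stopifnot(inherits(candidates, "summary_stat_set"),
            p_threshold > 0, p_threshold < 1,
            maf_threshold >= 0, maf_threshold <= 0.5)
  df <- candidates$records
  fmaf <- pmin(df$eaf, 1 - df$eaf)
  keep_p <- df$pvalue <= p_threshold
  keep_maf <- fmaf > maf_threshold
  reason <- dplyr::case_when(
    !keep_p & !keep_maf ~ sprintf("p = %.3g > %.3g and folded MAF %.3g <= %.3g",
                                  df$pvalue, p_threshold, fmaf, maf_threshold),
    !keep_p ~ sprintf("p = %.3g > %.3g", df$pvalue, p_threshold),
    !keep_maf ~ sprintf("folded MAF %.3g <= %.3g", fmaf, maf_threshold),
    TRUE ~ "passed p and MAF filters")
  keep <- keep_p & keep_maf
  out <- new_summary_stat_set(candidates$trait_name, candidates$trait_type,
                              df[keep, ])
  attr(out, "selection_log") <- tibble::tibble(
    variant_id = df$variant_id,
    action = ifelse(keep, "retained", "excluded"),
    reason = reason)
  out
}

#' LD-clump candidate instruments to an independent index-SNP set
#'
#' Partitions candidates into clusters connected by known pairwise
#' `r2 > r2_threshold` (transitive closure over the LD graph) and keeps, from
#' each cluster, the record with the greatest `|beta|` as the index SNP.
#' Ties on `|beta|` break to the smaller p-value, then to the
#' lexicographically smaller variant ID, so the result is deterministic and
#' independent of input order. A pair with no entry in the LD table is
#' treated as independent (with a logged note): clumping only acts on known
#' linkage.
#'
#' @param candidates A `summary_stat_set` of candidates for one biomarker.
#' @param ld An `ld_table`, or `NULL` for no known LD.
#' @param r2_threshold Link variants when known r-squared exceeds this;
#'   default 0.2.
#' @return An `instrument_set` with per-SNP and total variance explained and
#'   a selection log recording every clumping decision.
#' @export
clump <- function(candidates, ld = NULL, r2_threshold = 0.2) {
  stopifnot(inherits(candidates, "summary_stat_set"),
            r2_threshold >= 0, r2_threshold <= 1)
  df <- candidates$records
  df <- df[order(df$variant_id), ]
  n <- nrow(df)
  log <- tibble::tibble(variant_id = character(), action = character(),
                        reason = character())
  if (n == 0) {
    return(new_instrument_set(candidates$trait_name, df, selection_log = log))
  }
  # LD graph over candidates; edges where known r2 exceeds the threshold
  edges <- NULL
  n_unknown <- 0L
  if (n > 1) {
    pairs <- utils::combn(df$variant_id, 2)
    r2 <- ld_r2(ld, pairs[1, ], pairs[2, ])
    n_unknown <- sum(is.na(r2))
    linked <- !is.na(r2) & r2 > r2_threshold
    edges <- cbind(pairs[1, linked], pairs[2, linked])
  }
  if (n_unknown > 0) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      variant_id = NA_character_, action = "note",
      reason = sprintf("%d candidate pair(s) with unknown r2 treated as independent",
                       n_unknown)))
  }
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges %||% matrix(character(), ncol = 2),
                      stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = df$variant_id, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[df$variant_id]

  keep <- logical(n)
  for (cl in unique(comp)) {
    idx <- which(comp == cl)
    sub <- df[idx, ]
    ord <- order(-abs(sub$beta), sub$pvalue, sub$variant_id)
    index_row <- idx[ord[1]]
    keep[index_row] <- TRUE
    log <- dplyr::bind_rows(log,
      tibble::tibble(variant_id = df$variant_id[index_row], action = "index",
                     reason = sprintf("greatest |beta| of %d-SNP cluster",
                                      length(idx))),
      if (length(idx) > 1) tibble::tibble(
        variant_id = df$variant_id[setdiff(idx, index_row)],
        action = "clumped",
        reason = paste0("in LD cluster of index ", df$variant_id[index_row])))
  }
  new_instrument_set(candidates$trait_name, df[keep, ], selection_log = log)
}

#' Summarize instrument strength
#'
#' Total variance explained (the exact sum of per-SNP values) and a per-SNP
#' report ordered by descending variance explained.
#'
#' @param instruments An `instrument_set`.
#' @return List with `biomarker`, `n_snps`, `total_variance` (fraction),
#'   and `report` (tibble of `variant_id`, `variance_explained`, descending).
#' @export
summarize_strength <- function(instruments) {
  stopifnot(inherits(instruments, "instrument_set"))
  v <- instruments$per_snp_variance
  report <- tibble::tibble(variant_id = names(v), variance_explained = unname(v))
  report <- report[order(-report$variance_explained, report$variant_id), ]
  list(biomarker = instruments$biomarker,
       n_snps = length(v),
       total_variance = sum(v),
       report = report)
}
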