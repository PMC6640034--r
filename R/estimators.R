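new_mr_estimate <- function(method, beta, se, n_snps, ci_level = 0.95,
                            df = NULL) {
  stopifnot(se > 0 || beta == 0)
  q <- if (is.null(df)) stats::qnorm(1 - (1 - ci_level) / 2)
       else stats::qt(1 - (1 - ci_level) / 2, df)
  z <- beta / se
  pvalue <- if (is.null(df)) 2 * stats::pnorm(-abs(z))
            else 2 * stats::pt(-abs(z), df)
  tibble::tibble(method = method, n_snps = as.integer(n_snps),
                 beta = beta, se = se,
                 ci_low = beta - q * se, ci_high = beta + q * se,
                 or = exp(beta), or_ci_low = exp(beta - q * se),
                 or_ci_high = exp(beta + q * se),
                 pvalue = pvalue, ci_level = ci_level)
}

harmonized_frame <- function(h) {
  df <- if (inherits(h, "harmonized_set")) h$instruments else tibble::as_tibble(h)
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(df)))
  df
}

#' Wald-ratio causal estimate from a single variant
#'
#' The per-SNP causal estimate is the SNP-outcome effect divided by the
#' SNP-exposure effect; its standard error is the first-order delta-method
#' approximation `se_outcome / |beta_exposure|` (the contribution of the
#' exposure-side sampling error is ignored, as is standard in two-sample
#' practice; it enters only at second order). Confidence interval and
#' two-tailed p-value use the normal reference distribution.
#'
#' @param beta_exposure,se_exposure SNP-exposure effect (SD units) and SE.
#' @param beta_outcome,se_outcome SNP-outcome effect (log-odds) and SE.
#' @param ci_level Confidence level; default 0.95.
#' @return One-row tibble: `method`, `n_snps`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `or`, `or_ci_low`, `or_ci_high`, `pvalue`, `ci_level`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                       ci_level = 0.95) {
  if (beta_exposure == 0) {
    rlang::abort("Wald ratio undefined: beta_exposure is 0",
                 class = "mr_stat_error")
  }
  new_mr_estimate("wald", beta_outcome / beta_exposure,
                  se_outcome / abs(beta_exposure), 1L, ci_level)
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect weighted regression of outcome effects on exposure effects
#' through the origin, with weights `1 / se_outcome^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, `se = 1 / sqrt(sum(w bx^2))` —
#' algebraically the inverse-variance-weighted mean of the per-SNP Wald
#' ratios. With a single instrument it reduces exactly to the Wald ratio.
#' Two-tailed p-value from the normal reference distribution.
#'
#' An optional multiplicative random-effects variant inflates the SE by the
#' square root of the residual overdispersion when it exceeds 1; with the
#' 2-4 instruments typical of cytokine MR this estimate of overdispersion is
#' degenerate, so it is off by default.
#'
#' @param h A `harmonized_set`, or a data frame with columns
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param ci_level Confidence level; default 0.95.
#' @param random_effects Apply multiplicative random-effects SE scaling.
#' @return One-row tibble as in [wald_ratio()], `method = "ivw"`.
#' @export
ivw <- function(h, ci_level = 0.95, random_effects = FALSE) {
  df <- harmonized_frame(h)
  if (nrow(df) == 0) {
    rlang::abort("IVW requires at least one harmonized instrument",
                 class = "mr_stat_error")
  }
  if (nrow(df) == 1) {
    # single-instrument degeneracy: exactly the Wald ratio
    beta <- df$beta_outcome / df$beta_exposure
    se <- df$se_outcome / abs(df$beta_exposure)
  } else {
    w <- 1 / df$se_outcome^2
    denom <- sum(w * df$beta_exposure^2)
    beta <- sum(w * df$beta_exposure * df$beta_outcome) / denom
    se <- 1 / sqrt(denom)
  }
  if (random_effects && nrow(df) > 1) {
    sigma2 <- sum(w * (df$beta_outcome - beta * df$beta_exposure)^2) /
      (nrow(df) - 1)
    se <- se * sqrt(max(1, sigma2))
  }
  new_mr_estimate("ivw", beta, se, nrow(df), ci_level)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with a free intercept, weights `1 / se_outcome^2`. The slope estimates
#' the causal effect; the intercept estimates the average directional
#' (horizontal) pleiotropy, valid when instrument strength is independent of
#' the direct effects (the InSIDE assumption). Before fitting, all exposure
#' effects are oriented non-negative (flipping the paired outcome effect
#' signs); orientation changes the intercept's sign but not its magnitude
#' and is noted in the result's `orientation` attribute. Inference on both
#' coefficients uses the t distribution with `n_snps - 2` degrees of
#' freedom, two-tailed.
#'
#' Requires at least three instruments; with fewer, the extra pleiotropy
#' parameter is not identifiable alongside a residual scale and the fit is
#' refused.
#'
#' @inheritParams ivw
#' @return Two-row tibble: `method = "egger_slope"` and
#'   `method = "egger_intercept"`.
#' @export
mr_egger <- function(h, ci_level = 0.95) {
  df <- harmonized_frame(h)
  if (nrow(df) < 3) {
    rlang::abort(paste0("MR-Egger requires three or more index SNPs (got ",
                        nrow(df), ")"),
                 class = "mr_insufficient_instruments")
  }
  s <- ifelse(df$beta_exposure < 0, -1, 1)
  bx <- s * df$beta_exposure
  by <- s * df$beta_outcome
  w <- 1 / df$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  co <- stats::coef(summary(fit))
  n <- nrow(df)
  out <- dplyr::bind_rows(
    new_mr_estimate("egger_slope", co["bx", "Estimate"],
                    co["bx", "Std. Error"], n, ci_level, df = n - 2),
    new_mr_estimate("egger_intercept", co["(Intercept)", "Estimate"],
                    co["(Intercept)", "Std. Error"], n, ci_level, df = n - 2))
  attr(out, "orientation") <- s
  out
}

#' Re-derive the odds-ratio-scale fields of an estimate table
#'
#' Populates `or`, `or_ci_low`, `or_ci_high` as the exponential of the
#' log-odds-scale `beta`, `ci_low`, `ci_high`. The transformation is
#' monotone, so interval ordering is preserved.
#'
#' @param e A tibble of MR estimates (as returned by the estimators).
#' @return The same tibble with the OR fields recomputed.
#' @export
to_or_scale <- function(e) {
  e$or <- exp(e$beta)
  e$or_ci_low <- exp(e$ci_low)
  e$or_ci_high <- exp(e$ci_high)
  e
}

#' Run the requested causal estimators on a harmonized set
#'
#' IVW is always attempted; MR-Egger only when three or more instruments are
#' available — with fewer it is skipped with a logged reason rather than an
#' error, and the IVW result is still returned.
#'
#' @param h A `harmonized_set` (or compatible data frame).
#' @param methods Subset of `c("ivw", "egger", "wald")`; `"wald"` adds
#'   per-SNP Wald ratios.
#' @param ci_level Confidence level; default 0.95.
#' @param random_effects Passed to [ivw()].
#' @return Tibble of estimates with attributes `egger_performed` (logical)
#'   and `egger_skip_reason` (character or `NA`).
#' @export
mr_estimate_all <- function(h, methods = c("ivw", "egger"), ci_level = 0.95,
                            random_effects = FALSE) {
  methods <- match.arg(methods, c("ivw", "egger", "wald"), several.ok = TRUE)
  df <- harmonized_frame(h)
  out <- list()
  if ("ivw" %in% methods) {
    out$ivw <- ivw(df, ci_level = ci_level, random_effects = random_effects)
  }
  egger_performed <- FALSE
  egger_skip_reason <- NA_character_
  if ("egger" %in% methods) {
    if (nrow(df) >= 3) {
      out$egger <- mr_egger(df, ci_level = ci_level)
      egger_performed <- TRUE
    } else {
      egger_skip_reason <- sprintf(
        "MR-Egger skipped: %d instrument(s), three or more required", nrow(df))
      rlang::inform(egger_skip_reason)
    }
  }
  if ("wald" %in% methods) {
    out$wald <- dplyr::bind_rows(lapply(seq_len(nrow(df)), function(i) {
      e <- wald_ratio(df$beta_exposure[i], df$se_exposure[i],
                      df$beta_outcome[i], df$se_outcome[i], ci_level)
      e$variant_id <- df$variant_id[i] %||% NA_character_
      e
    }))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "egger_performed") <- egger_performed
  attr(res, "egger_skip_reason") <- egger_skip_reason
  res
}
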