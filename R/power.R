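#' Case fraction of the IGAP stage-1 Alzheimer's disease meta-analysis
#'
#' 17008 cases out of 17008 + 37154 participants, the default outcome-study
#' composition for power calculations.
#'
#' @return A fraction (about 0.314).
#' @export
igap_case_fraction <- function() 17008 / (17008 + 37154)

check_power_query <- function(r2_xz, or_per_sd, n_outcome, case_fraction,
                              alpha) {
  if (!(r2_xz > 0 && r2_xz < 1)) {
    rlang::abort("r2_xz must be in (0,1)", class = "mr_input_error")
  }
  if (!(or_per_sd > 0)) {
    rlang::abort("or_per_sd must be > 0", class = "mr_input_error")
  }
  if (!(case_fraction > 0 && case_fraction < 1)) {
    rlang::abort("case_fraction must be in (0,1)", class = "mr_input_error")
  }
  if (!(alpha > 0 && alpha < 1)) {
    rlang::abort("alpha must be in (0,1)", class = "mr_input_error")
  }
  if (any(n_outcome < 0)) {
    rlang::abort("n_outcome must be nonnegative", class = "mr_input_error")
  }
}

#' Power of a two-sample MR test with a binary outcome
#'
#' Two-sided normal approximation: the Wald statistic for the causal
#' log-odds ratio has noncentrality `sqrt(lambda)` with
#' `lambda = n_outcome * r2_xz * log(or_per_sd)^2 * K * (1 - K)`,
#' where `r2_xz` is the exposure variance explained by the instruments and
#' `K` the outcome-study case fraction; power at two-sided level `alpha` is
#' `pnorm(-z + sqrt(lambda)) + pnorm(-z - sqrt(lambda))` with
#' `z = qnorm(1 - alpha/2)`. At the null OR of 1 this equals `alpha`, and
#' it is nondecreasing in `n_outcome`, `r2_xz`, and `|log(or_per_sd)|`.
#'
#' @param r2_xz Fraction of exposure variance explained by the instruments,
#'   in `(0, 1)`.
#' @param or_per_sd Hypothesized causal odds ratio per SD of exposure.
#' @param n_outcome Outcome-study sample size (vectorised).
#' @param case_fraction Outcome-study case fraction `K`; defaults to the
#'   IGAP stage-1 ratio ([igap_case_fraction()]).
#' @param alpha Two-sided type-I error rate; default 0.05.
#' @return Power, in `(0, 1)` (vectorised over `n_outcome`).
#' @export
mr_power <- function(r2_xz, or_per_sd, n_outcome,
                     case_fraction = igap_case_fraction(), alpha = 0.05) {
  check_power_query(r2_xz, or_per_sd, n_outcome, case_fraction, alpha)
  k <- case_fraction
  lambda <- n_outcome * r2_xz * log(or_per_sd)^2 * k * (1 - k)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-z + sqrt(lambda)) + stats::pnorm(-z - sqrt(lambda))
}

#' Minimum outcome sample size for a target MR power
#'
#' Smallest integer `n_outcome` for which [mr_power()] reaches
#' `target_power`. Undefined at the null OR of 1 (power never exceeds
#' `alpha` there), which raises an error; a `target_power <= alpha` is
#' reached by any sample size, so 1 is returned.
#'
#' @inheritParams mr_power
#' @param target_power Power to reach; default 0.8.
#' @return Integer sample size.
#' @export
min_sample_size <- function(r2_xz, or_per_sd,
                            case_fraction = igap_case_fraction(),
                            alpha = 0.05, target_power = 0.8) {
  check_power_query(r2_xz, or_per_sd, 1, case_fraction, alpha)
  stopifnot(target_power > 0, target_power < 1)
  if (or_per_sd == 1) {
    rlang::abort("minimum sample size undefined at the null OR of 1",
                 class = "mr_input_error")
  }
  if (target_power <= alpha) return(1L)
  k <- case_fraction
  unit <- r2_xz * log(or_per_sd)^2 * k * (1 - k)  # lambda per sample
  power_of_lambda <- function(lambda) {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(-z + sqrt(lambda)) + stats::pnorm(-z - sqrt(lambda))
  }
  lam <- stats::uniroot(function(l) power_of_lambda(l) - target_power,
                        lower = 0, upper = 1e6, tol = 1e-12)$root
  n <- max(1L, ceiling(lam / unit - 1e-9))
  while (mr_power(r2_xz, or_per_sd, n, k, alpha) < target_power) n <- n + 1L
  while (n > 1L && mr_power(r2_xz, or_per_sd, n - 1L, k, alpha) >=
         target_power) n <- n - 1L
  as.integer(n)
}
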