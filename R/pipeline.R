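#' Assemble a run configuration
#'
#' Collects input locations (or a simulation block), all analysis thresholds,
#' the estimator list, and the seed for one reproducible end-to-end run.
#' Thresholds default to the motivating analysis: genome-wide p-value 5e-8,
#' folded-MAF floor 0.3, clumping r-squared 0.2, proxy r-squared 0.8,
#' palindrome frequency window 0.08, 95% confidence level, alpha 0.05.
#'
#' @param exposure,outcome,ld File paths of exposure/outcome summary
#'   statistics and an LD table, or pre-built objects
#'   (`summary_stat_set` / `ld_table`). Ignored when `simulate` or
#'   `fixture_table1` is given.
#' @param simulate Optional [sim_config()] (or plain list of its arguments):
#'   generate the inputs instead of reading them.
#' @param fixture_table1 If `TRUE`, run in published-table reproduction
#'   mode: load the packaged 12-SNP instrument table, group by biomarker,
#'   and report instrument counts and strength totals (no outcome data are
#'   packaged, so no causal estimates are produced in this mode).
#' @param exposure_name,outcome_name Trait labels used when reading files.
#' @param p_threshold,maf_threshold,r2_threshold,proxy_r2,palindrome_eaf_window
#'   Stage thresholds; see [filter_candidates()], [clump()], [harmonize()].
#' @param methods Estimators to run; see [mr_estimate_all()].
#' @param ci_level,alpha Confidence level and test size.
#' @param power_or Optional odds ratio per SD at which to compute power and
#'   minimum sample size for the realized instrument strength.
#' @param out_dir Optional directory; when given, every stage's output is
#'   persisted there as TSV/JSON together with a run manifest.
#' @param seed Seed for any simulation and for the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(exposure = NULL, outcome = NULL, ld = NULL,
                       simulate = NULL, fixture_table1 = FALSE,
                       exposure_name = "exposure", outcome_name = "outcome",
                       p_threshold = 5e-8, maf_threshold = 0.3,
                       r2_threshold = 0.2, proxy_r2 = 0.8,
                       palindrome_eaf_window = 0.08,
                       methods = c("ivw", "egger"), ci_level = 0.95,
                       alpha = 0.05, power_or = NULL, out_dir = NULL,
                       seed = 1) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            maf_threshold >= 0, maf_threshold <= 0.5,
            r2_threshold >= 0, r2_threshold <= 1,
            proxy_r2 > 0, proxy_r2 <= 1,
            palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5,
            ci_level > 0, ci_level < 1, alpha > 0, alpha < 1)
  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 simulate = simulate, fixture_table1 = fixture_table1,
                 exposure_name = exposure_name, outcome_name = outcome_name,
                 p_threshold = p_threshold, maf_threshold = maf_threshold,
                 r2_threshold = r2_threshold, proxy_r2 = proxy_r2,
                 palindrome_eaf_window = palindrome_eaf_window,
                 methods = methods, ci_level = ci_level, alpha = alpha,
                 power_or = power_or, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys are the arguments of [run_config()]; a `simulate` block
#' holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "mr_config_error")
  }
  do.call(run_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 class = "mr_stage_error", parent = e)
  })
}

resolve_input <- function(x, reader, ...) {
  if (is.null(x) || !is.character(x)) x else reader(x, ...)
}

#' Run the full two-sample MR pipeline
#'
#' Executes select (p/MAF filter + LD clump), harmonize, estimate, strength
#' summary, and optional power calculation in order, from files, in-memory
#' objects, a simulation block, or the packaged published-table fixture.
#' Every stage's output is returned (and persisted when `out_dir` is set,
#' together with a manifest recording the configuration, its hash, package
#' version, and seed). Re-running with an identical configuration reproduces
#' identical outputs. A failing stage aborts with the stage name and the
#' causal diagnostic.
#'
#' @param config A `run_config`, or a path to a YAML file for
#'   [read_run_config()].
#' @return List of class `mr_run`: `instruments`, `harmonized`, `estimates`
#'   (with `egger_performed` flag), `strength`, `power`, `audit`, `config`;
#'   in fixture mode, per-biomarker `strength` and `counts` instead.
#' @export
mr_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  if (isTRUE(config$fixture_table1)) {
    sets <- stage("fixture", fixture_instrument_sets())
    strength <- lapply(sets, summarize_strength)
    counts <- vapply(strength, `[[`, integer(1), "n_snps")
    totals <- vapply(strength, `[[`, numeric(1), "total_variance")
    res <- structure(list(mode = "fixture", instruments = sets,
                          strength = strength, counts = counts,
                          total_variance_pct = 100 * totals,
                          config = config),
                     class = "mr_run")
    persist_run(res, config)
    return(res)
  }

  if (!is.null(config$simulate)) {
    simcfg <- config$simulate
    if (!inherits(simcfg, "sim_config")) {
      simcfg <- do.call(sim_config,
                        utils::modifyList(list(seed = config$seed),
                                          as.list(simcfg)))
    }
    sim <- stage("simulate", simulate_mr(simcfg))
    exposure <- sim$exposure; outcome <- sim$outcome; ld <- sim$ld
  } else {
    sim <- NULL
    exposure <- stage("read_exposure",
                      resolve_input(config$exposure, read_summary_stats,
                                    trait_name = config$exposure_name,
                                    trait_type = "continuous"))
    outcome <- stage("read_outcome",
                     resolve_input(config$outcome, read_summary_stats,
                                   trait_name = config$outcome_name,
                                   trait_type = "binary"))
    ld <- stage("read_ld", resolve_input(config$ld, read_ld_table))
  }

  filtered <- stage("filter",
                    filter_candidates(exposure, config$p_threshold,
                                      config$maf_threshold))
  instruments <- stage("clump", clump(filtered, ld, config$r2_threshold))
  harmonized <- stage("harmonize",
                      harmonize(instruments, outcome, ld, config$proxy_r2,
                                config$palindrome_eaf_window,
                                exposure_full = exposure))
  estimates <- stage("estimate",
                     mr_estimate_all(harmonized, config$methods,
                                     config$ci_level))
  strength <- stage("strength", summarize_strength(instruments))
  power <- NULL
  if (!is.null(config$power_or) && strength$total_variance > 0) {
    n_out <- outcome$records$n[1] %|na|% (17008 + 37154)
    power <- stage("power", list(
      r2_xz = strength$total_variance, or_per_sd = config$power_or,
      n_outcome = n_out,
      power = mr_power(strength$total_variance, config$power_or, n_out,
                       alpha = config$alpha),
      min_n_for_target = if (config$power_or != 1) {
        min_sample_size(strength$total_variance, config$power_or,
                        alpha = config$alpha)
      }))
  }
  res <- structure(list(mode = "analysis", simulation = sim,
                        instruments = instruments, harmonized = harmonized,
                        estimates = estimates, strength = strength,
                        power = power, audit = audit_report(harmonized),
                        config = config),
                   class = "mr_run")
  persist_run(res, config)
  res
}

persist_run <- function(res, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- lapply(unclass(config), function(x) {
    if (inherits(x, "summary_stat_set") || inherits(x, "ld_table")) {
      "<in-memory object>"
    } else if (inherits(x, "sim_config")) unclass(x) else x
  })
  manifest <- list(package = "mrinflame",
                   version = as.character(utils::packageVersion("mrinflame")),
                   r_version = as.character(getRversion()),
                   seed = config$seed,
                   config = cfg_plain,
                   config_hash = rlang::hash(cfg_plain))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (identical(res$mode, "fixture")) {
    jsonlite::write_json(
      list(counts = as.list(res$counts),
           total_variance_pct = as.list(res$total_variance_pct)),
      file.path(dir, "strength.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(dir))
  }
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(res$instruments$records, "instruments.tsv")
  tsv(res$harmonized$instruments, "harmonized.tsv")
  tsv(res$estimates, "estimates.tsv")
  tsv(res$audit, "audit.tsv")
  jsonlite::write_json(
    list(biomarker = res$strength$biomarker, n_snps = res$strength$n_snps,
         total_variance = res$strength$total_variance,
         report = res$strength$report,
         power = res$power),
    file.path(dir, "strength.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @export
print.mr_run <- function(x, ...) {
  if (identical(x$mode, "fixture")) {
    cat("<mr_run> published-table reproduction mode\n")
    for (bm in names(x$strength)) {
      cat(sprintf("  %-7s %d index SNP(s), total variance explained %.2f%%\n",
                  bm, x$counts[[bm]], x$total_variance_pct[[bm]]))
    }
    return(invisible(x))
  }
  cat(sprintf("<mr_run> %s: %d instrument(s) harmonized, %d dropped\n",
              x$harmonized$biomarker, nrow(x$harmonized$instruments),
              nrow(x$harmonized$dropped)))
  print(report_table(x$estimates), ...)
  invisible(x)
}

#' Estimate table in the published layout
#'
#' Method, number of SNPs, odds ratio with 95% CI bounds and p-value —
#' mirroring the layout of published two-sample MR result tables — with the
#' log-odds-scale columns appended.
#'
#' @param estimates An estimate tibble from [mr_estimate_all()].
#' @return A tibble.
#' @export
report_table <- function(estimates) {
  tibble::tibble(method = estimates$method, n_snps = estimates$n_snps,
                 or = estimates$or, or_ci_low = estimates$or_ci_low,
                 or_ci_high = estimates$or_ci_high,
                 pvalue = estimates$pvalue, beta = estimates$beta,
                 se = estimates$se, ci_low = estimates$ci_low,
                 ci_high = estimates$ci_high)
}

#' Scatter plot of harmonized effects with fitted causal slopes
#'
#' SNP-outcome effects against SNP-exposure effects (error bars at one SE),
#' with the IVW line through the origin and, when at least three instruments
#' are available, the MR-Egger line with its pleiotropy intercept.
#'
#' @param h A `harmonized_set`.
#' @param ci_level Confidence level passed to the estimators.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, ci_level = 0.95) {
  df <- harmonized_frame(h)
  s <- ifelse(df$beta_exposure < 0, -1, 1)
  df$bx <- s * df$beta_exposure
  df$by <- s * df$beta_outcome
  est_ivw <- ivw(df, ci_level = ci_level)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_outcome,
                                        ymax = .data$by + .data$se_outcome),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = est_ivw$beta,
                         colour = "#1b6ca8") +
    ggplot2::labs(x = "SNP effect on exposure (SD units, oriented positive)",
                  y = "SNP effect on outcome (log-odds)",
                  subtitle = sprintf("IVW slope %.3f", est_ivw$beta)) +
    ggplot2::theme_minimal()
  if (nrow(df) >= 3) {
    est_egger <- mr_egger(df, ci_level = ci_level)
    p <- p + ggplot2::geom_abline(
      intercept = est_egger$beta[est_egger$method == "egger_intercept"],
      slope = est_egger$beta[est_egger$method == "egger_slope"],
      colour = "#b3473b", linetype = "dashed")
  }
  p
}
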