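#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Default column mapping for GWAS summary-statistic files
#'
#' Maps the canonical internal field names to the column headers expected in
#' an input file. The source GWAS publications for cytokine and ESR summary
#' statistics use heterogeneous headers, so every entry can be overridden.
#'
#' @return Named character vector; names are internal fields
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n`), values are file column names.
#' @export
default_column_map <- function() {
  c(variant_id = "variant_id", chromosome = "chr", position = "pos",
    effect_allele = "ea", other_allele = "oa", eaf = "eaf",
    beta = "beta", se = "se", pvalue = "p", n = "n")
}

MANDATORY_FIELDS <- c("variant_id", "chromosome", "position", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pvalue")

new_summary_stat_set <- function(trait_name, trait_type, records) {
  stopifnot(is.character(trait_name), length(trait_name) == 1)
  trait_type <- match.arg(trait_type, c("continuous", "binary"))
  records <- as_tibble(records)
  if (anyDuplicated(records$variant_id)) {
    dup <- unique(records$variant_id[duplicated(records$variant_id)])
    abort(paste0("duplicate variant_id in '", trait_name, "': ",
                 paste(dup, collapse = ", ")), class = "mr_input_error")
  }
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 records = records),
            class = "summary_stat_set")
}

#' @export
print.summary_stat_set <- function(x, ...) {
  cat(sprintf("<summary_stat_set> %s (%s), %d variants\n",
              x$trait_name, x$trait_type, nrow(x$records)))
  print(x$records, ...)
  invisible(x)
}

# Row-level validation. Returns character reason or NA if valid.
validate_record_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, msg, reason)
  }
  reason <- bad(is.na(df$variant_id) | df$variant_id == "", "empty variant_id")
  reason <- bad(!(df$effect_allele %in% BASES), "effect_allele not one of A/C/G/T")
  oa_known <- !is.na(df$other_allele) & df$other_allele != ""
  reason <- ifelse(is.na(reason) & oa_known & !(df$other_allele %in% BASES),
                   "other_allele not one of A/C/G/T", reason)
  reason <- ifelse(is.na(reason) & oa_known & df$other_allele == df$effect_allele,
                   "effect_allele equals other_allele", reason)
  reason <- bad(!(df$eaf >= 0 & df$eaf <= 1), "eaf outside [0,1]")
  reason <- bad(!(df$se > 0), "se not > 0")
  reason <- bad(!(df$pvalue > 0 & df$pvalue <= 1), "pvalue outside (0,1]")
  reason <- bad(!is.finite(df$beta), "non-finite beta")
  reason
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header row, maps its columns to
#' the canonical summary-statistic fields, validates every row, and returns a
#' summary-statistic set. Rows failing validation are rejected with a
#' row-numbered diagnostic (collected in the `rejected` attribute of the
#' returned object and reported via a warning); alleles are upper-cased.
#'
#' @param path Path to the file.
#' @param trait_name Label for the trait (e.g. `"IL-6"`).
#' @param trait_type `"continuous"` (effects in trait SD units) or `"binary"`
#'   (effects in log-odds).
#' @param column_map Named character vector mapping internal field names to
#'   file headers; see [default_column_map()]. `n` is optional.
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `summary_stat_set`: list with `trait_name`, `trait_type`, and
#'   `records` (a tibble keyed by `variant_id`).
#' @export
read_summary_stats <- function(path, trait_name,
                               trait_type = c("continuous", "binary"),
                               column_map = default_column_map(),
                               delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                class = "mr_config_error")
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(column_map[MANDATORY_FIELDS]), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mr_config_error")
  }
  fields <- intersect(names(column_map), c(MANDATORY_FIELDS, "n"))
  fields <- fields[unname(column_map[fields]) %in% names(raw)]
  df <- tibble(.rows = nrow(raw))
  for (f in fields) df[[f]] <- raw[[column_map[[f]]]]
  if (!"n" %in% names(df)) df$n <- NA_character_

  df$variant_id <- as.character(df$variant_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- suppressWarnings(as.integer(df$position))
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  for (f in c("eaf", "beta", "se", "pvalue", "n")) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  }

  reason <- validate_record_rows(df)
  rejected <- tibble(row = which(!is.na(reason)) + 1L,  # +1 for header line
                     variant_id = df$variant_id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  if (nrow(rejected) > 0) {
    warn(paste0("rejected ", nrow(rejected), " row(s) of ", path, ":\n",
                paste(sprintf("  line %d (%s): %s", rejected$row,
                              rejected$variant_id, rejected$reason),
                      collapse = "\n")))
  }
  set <- new_summary_stat_set(trait_name, trait_type, df[is.na(reason), ])
  attr(set, "rejected") <- rejected
  set
}

#' Write a summary-statistic set to a TSV file
#'
#' Numeric fields are written with 17 significant digits so that a
#' write-then-read round trip reproduces every field to full double precision.
#'
#' @param set A `summary_stat_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(set, path) {
  stopifnot(inherits(set, "summary_stat_set"))
  df <- set$records
  out <- df
  for (f in names(out)) {
    if (is.double(out[[f]])) {
      out[[f]] <- vapply(out[[f]], function(v) {
        if (is.na(v)) "" else format(v, digits = 17, scientific = TRUE)
      }, character(1))
    }
  }
  names(out) <- unname(default_column_map()[names(df)])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pairwise linkage-disequilibrium table
#'
#' Expects three columns `variant_a`, `variant_b`, `r2`. The table is stored
#' with a canonical (sorted) pair key so lookups are symmetric; a later
#' duplicate of a pair overwrites the earlier entry with a warning.
#'
#' @param path Path to a tab-delimited LD file.
#' @return An `ld_table` object.
#' @export
read_ld_table <- function(path) {
  df <- readr::read_delim(path, delim = "\t", show_col_types = FALSE,
                          progress = FALSE)
  need <- c("variant_a", "variant_b", "r2")
  if (!all(need %in% names(df))) {
    abort(paste0("LD table must have columns: ", paste(need, collapse = ", ")),
          class = "mr_config_error")
  }
  new_ld_table(df$variant_a, df$variant_b, df$r2)
}

#' Construct an LD table from vectors of variant pairs and r-squared values
#'
#' @param variant_a,variant_b Character vectors of variant IDs.
#' @param r2 Numeric vector of pairwise r-squared values in `[0, 1]`.
#' @return An `ld_table` object supporting symmetric lookup via [ld_r2()].
#' @export
new_ld_table <- function(variant_a = character(), variant_b = character(),
                         r2 = numeric()) {
  stopifnot(length(variant_a) == length(variant_b),
            length(variant_a) == length(r2))
  if (any(!is.na(r2) & (r2 < 0 | r2 > 1))) {
    abort("r2 outside [0,1] in LD table", class = "mr_input_error")
  }
  a <- pmin(as.character(variant_a), as.character(variant_b))
  b <- pmax(as.character(variant_a), as.character(variant_b))
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    warn(paste0("duplicate LD pair(s); later entries overwrite earlier: ",
                paste(gsub("\r", "/", dups), collapse = ", ")))
    keep <- !duplicated(key, fromLast = TRUE)
    a <- a[keep]; b <- b[keep]; r2 <- r2[keep]
  }
  structure(list(entries = tibble(variant_a = a, variant_b = b, r2 = r2)),
            class = "ld_table")
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("<ld_table> %d pairs\n", nrow(x$entries)))
  print(x$entries, ...)
  invisible(x)
}

#' Look up pairwise r-squared in an LD table
#'
#' Lookup is symmetric in the two variants; `r2(x, x)` is 1 by definition.
#' An absent pair returns `NA` ("unknown"), never 0: absence of evidence of
#' linkage is not evidence of independence.
#'
#' @param ld An `ld_table` (or `NULL`, treated as an empty table).
#' @param a,b Variant IDs (vectorised, recycled).
#' @return Numeric vector of r-squared values, `NA` where the pair is unknown.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, NA_real_)
  if (is.null(ld) || nrow(ld$entries) == 0) return(out)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab_key <- paste(ld$entries$variant_a, ld$entries$variant_b, sep = "\r")
  hit <- match(key, tab_key)
  out[a != b] <- ld$entries$r2[hit][a != b]
  out
}

# All LD partners of `id` recorded in the table, sorted by descending r2.
ld_partners <- function(ld, id) {
  if (is.null(ld)) return(tibble(variant_id = character(), r2 = numeric()))
  e <- ld$entries
  hit <- e$variant_a == id | e$variant_b == id
  partner <- ifelse(e$variant_a[hit] == id, e$variant_b[hit], e$variant_a[hit])
  out <- tibble(variant_id = partner, r2 = e$r2[hit])
  out[order(-out$r2, out$variant_id), ]
}

#' Load the packaged instrument table for the four inflammatory biomarkers
#'
#' Returns the 12 index SNPs for IL-18, IL-1ra, IL-6, and ESR as published:
#' biomarker label, chromosome, position (1-based, build as provided),
#' effect allele in the AD outcome GWAS (IGAP), effect allele in the
#' biomarker GWAS, allele frequency, and per-SNP variance explained (%).
#' The source table labels the frequency column "minor allele frequency" but
#' contains values above 0.5 (up to 0.934); it is therefore stored as
#' effect-allele frequency.
#'
#' @return A tibble with 12 rows, one per index SNP.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_instruments.tsv",
                      package = "mrinflame", mustWork = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df
}

# Non-palindromic companion allele used when a source table reports only the
# effect allele: any base that is neither the effect allele nor its complement.
synthetic_other_allele <- function(ea) {
  vapply(ea, function(x) setdiff(BASES, c(x, COMPLEMENT[[x]]))[1], character(1))
}

#' Build instrument sets from the packaged biomarker instrument table
#'
#' One `instrument_set` per biomarker, with per-SNP variance explained taken
#' verbatim from the published table (converted from percent to fractions).
#' SNP effect sizes are back-computed from variance explained and allele
#' frequency via R-squared = 2 beta^2 f (1-f); standard errors and p-values
#' are not published per SNP and are left `NA`.
#'
#' @return Named list of `instrument_set` objects
#'   (IL-18, IL-1ra, IL-6, ESR, in published order).
#' @export
fixture_instrument_sets <- function() {
  df <- load_table1_fixture()
  out <- list()
  for (bm in unique(df$biomarker)) {
    rows <- df[df$biomarker == bm, ]
    f <- pmin(rows$eaf, 1 - rows$eaf)
    records <- tibble(
      variant_id = rows$variant_id,
      chromosome = rows$chromosome,
      position = rows$position,
      effect_allele = rows$biomarker_effect_allele,
      other_allele = synthetic_other_allele(rows$biomarker_effect_allele),
      eaf = rows$eaf,
      beta = sqrt((rows$variance_explained_pct / 100) / (2 * f * (1 - f))),
      se = NA_real_, pvalue = NA_real_, n = NA_real_)
    out[[bm]] <- new_instrument_set(
      biomarker = bm, records = records,
      per_snp_variance = stats::setNames(rows$variance_explained_pct / 100,
                                         rows$variant_id),
      selection_log = tibble(variant_id = rows$variant_id, action = "kept",
                             reason = "published index SNP"))
  }
  out
}

#' Exposure and outcome summary-statistic stubs from the packaged table
#'
#' Builds a pair of `summary_stat_set` stubs from the published instrument
#' table, mainly for exercising harmonization: the exposure stub carries the
#' back-computed biomarker effect sizes; the outcome stub carries null effects
#' on the same variants. Alleles are synthesized to be non-palindromic
#' (the published table reports effect alleles only); with
#' `identical_alleles = TRUE` (default) the outcome uses the exposure's
#' allele coding so that harmonization is the identity.
#'
#' @param identical_alleles Use the exposure allele coding for the outcome.
#' @return List with elements `exposure` and `outcome`.
#' @export
fixture_stub_sets <- function(identical_alleles = TRUE) {
  df <- load_table1_fixture()
  ea <- df$biomarker_effect_allele
  oa <- synthetic_other_allele(ea)
  f <- pmin(df$eaf, 1 - df$eaf)
  beta <- sqrt((df$variance_explained_pct / 100) / (2 * f * (1 - f)))
  exposure <- new_summary_stat_set("inflammatory biomarkers", "continuous",
    tibble(variant_id = df$variant_id, chromosome = df$chromosome,
           position = df$position, effect_allele = ea, other_allele = oa,
           eaf = df$eaf, beta = beta, se = 0.05, pvalue = 1e-9, n = NA_real_))
  out_ea <- if (identical_alleles) ea else df$igap_effect_allele
  outcome <- new_summary_stat_set("Alzheimer's disease", "binary",
    tibble(variant_id = df$variant_id, chromosome = df$chromosome,
           position = df$position, effect_allele = out_ea,
           other_allele = if (identical_alleles) oa else synthetic_other_allele(out_ea),
           eaf = df$eaf, beta = 0, se = 0.1, pvalue = 1, n = NA_real_))
  list(exposure = exposure, outcome = outcome)
}
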