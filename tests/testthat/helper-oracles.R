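# Independent oracles and fixture builders used across the suite.

# Generic weighted least squares by explicit normal equations.
# Returns coefficients, fixed-effect SEs (no residual scaling), and
# residual-scaled SEs (sigma-hat, df = n - p).
wls_oracle <- function(X, y, w) {
  X <- as.matrix(X)
  XtWX <- crossprod(X, w * X)
  inv <- solve(XtWX)
  coef <- drop(inv %*% crossprod(X, w * y))
  resid <- y - drop(X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sum(w * resid^2) / df else NA_real_
  list(coef = coef, se_fixed = sqrt(diag(inv)),
       se_scaled = sqrt(sigma2 * diag(inv)))
}

# Exhaustive connected-component enumeration on a small LD graph:
# boolean transitive closure by repeated squaring of the adjacency matrix.
cluster_oracle <- function(ids, linked_pairs) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  rownames(adj) <- colnames(adj) <- ids
  if (nrow(linked_pairs) > 0) {
    for (k in seq_len(nrow(linked_pairs))) {
      a <- linked_pairs[[1]][k]; b <- linked_pairs[[2]][k]
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  unname(split(ids, apply(adj, 1, function(r) paste(which(r), collapse = ","))))
}

# Quick summary_stat_set from vectors; synthesizes what is not supplied.
make_sss <- function(variant_id, beta, se = 0.05, pvalue = 1e-9, eaf = 0.3,
                     effect_allele = "A", other_allele = "G",
                     trait_name = "test trait", trait_type = "continuous",
                     n = NA_real_, chromosome = "1") {
  m <- length(variant_id)
  mrinflame:::new_summary_stat_set(
    trait_name, trait_type,
    tibble::tibble(
      variant_id = variant_id, chromosome = rep_len(chromosome, m),
      position = seq_len(m) * 100L,
      effect_allele = rep_len(effect_allele, m),
      other_allele = rep_len(other_allele, m),
      eaf = rep_len(eaf, m), beta = rep_len(beta, m), se = rep_len(se, m),
      pvalue = rep_len(pvalue, m), n = rep_len(n, m)))
}

# Harmonized-style frame straight from a clean simulation (identical allele
# coding on both sides), bypassing harmonize() for speed in replicate loops.
sim_frame <- function(sim) {
  ex <- sim$exposure$records
  ou <- sim$outcome$records[match(ex$variant_id, sim$outcome$records$variant_id), ]
  tibble::tibble(variant_id = ex$variant_id,
                 beta_exposure = ex$beta, se_exposure = ex$se,
                 beta_outcome = ou$beta, se_outcome = ou$se)
}
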