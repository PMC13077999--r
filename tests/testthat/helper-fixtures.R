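# Fixtures and independent oracles used across the suite.

# Build a HarmonisedSet directly from effect vectors.
make_pairs <- function(gamma, Gamma, se_gamma = rep(0.01, length(gamma)),
                       se_Gamma = rep(0.01, length(gamma)),
                       ids = sprintf("rs%03d", seq_along(gamma)),
                       exposure_id = "exp", outcome_id = "out") {
  HarmonisedSet(exposure_id, outcome_id, data.frame(
    variant_id = ids, gamma = gamma, se_gamma = se_gamma,
    p_gamma = 2 * pnorm(-abs(gamma / se_gamma)),
    Gamma = Gamma, se_Gamma = se_Gamma,
    p_Gamma = 2 * pnorm(-abs(Gamma / se_Gamma)),
    eaf = rep(0.3, length(gamma)), flags = "", stringsAsFactors = FALSE))
}

# One-row summary-statistic record.
make_record <- function(id = "rs1", ea = "A", oa = "G", beta = 0.1,
                        se = 0.02, eaf = 0.3, chrom = "1", pos = 1e6,
                        pvalue = NULL, n = 10000) {
  data.frame(variant_id = id, chromosome = chrom, position = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta,
             se = se,
             pvalue = if (is.null(pvalue)) 2 * pnorm(-abs(beta / se)) else pvalue,
             n = n, stringsAsFactors = FALSE)
}

make_sumstats <- function(records, trait_id = "trait",
                          trait_type = "continuous") {
  SummaryStats(trait_id, trait_type, do.call(rbind, records))
}

# Independent brute-force greedy clumping oracle: repeatedly take the best
# remaining variant by p (ties by chromosome, position, id) and eliminate
# every correlated in-window variant, using only the raw pair table.
oracle_clump_ids <- function(df, ld_table, r2, window) {
  lookup_r <- function(a, b) {
    hit <- (ld_table$id_a == a & ld_table$id_b == b) |
      (ld_table$id_a == b & ld_table$id_b == a)
    if (any(hit)) ld_table$r[which(hit)[1]] else 0
  }
  remaining <- df[order(df$pvalue, df$chromosome, df$position,
                        df$variant_id), , drop = FALSE]
  kept <- character()
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    kept <- c(kept, top$variant_id)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- vapply(seq_len(nrow(remaining)), function(j) {
      v <- remaining[j, ]
      if (is.na(v$chromosome) || is.na(top$chromosome) ||
          v$chromosome != top$chromosome) return(FALSE)
      if (!is.na(v$position) && !is.na(top$position) &&
          abs(v$position - top$position) > window) return(FALSE)
      lookup_r(top$variant_id, v$variant_id)^2 >= r2
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# Weighted-least-squares oracle via lm(): slope/intercept, unscaled SEs and
# the weighted residual sum of squares.
oracle_wls <- function(g, G, w, intercept = FALSE) {
  fit <- if (intercept) lm(G ~ g, weights = w) else lm(G ~ 0 + g, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  coefs <- sm$coefficients
  list(slope = coefs[if (intercept) "g" else "g", "Estimate"],
       intercept = if (intercept) coefs["(Intercept)", "Estimate"] else NA,
       se_slope_unscaled = coefs[if (intercept) "g" else "g", "Std. Error"] / sigma,
       se_int_unscaled = if (intercept) coefs["(Intercept)", "Std. Error"] / sigma else NA,
       sigma2 = sigma^2,
       q = sum(w * residuals(fit)^2))
}

# Convenience: a simulation whose harmonisation stressors are disabled.
clean_config <- function(...) {
  simConfig(palindromic_fraction = 0, strand_flip_fraction = 0,
            swap_fraction = 0, missing_outcome_fraction = 0, ...)
}
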