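# Screen orchestration: the per-exposure pipeline, multiple-testing
# control, and the screen-level outputs.

not_analysable <- function(exposure_id, outcome_id, reason, n_initial = 0L,
                           provenance = list()) {
  new("MRBattery", exposureId = exposure_id, outcomeId = outcome_id,
      status = "not_analysable", reason = reason, results = list(),
      diagnostics = list(), nSnpInitial = as.integer(n_initial),
      nSnpFinal = 0L, nPleiotropyFiltered = 0L, removed = list(),
      provenance = provenance)
}

#' Run the full MR pipeline for one exposure
#'
#' Fixed stage order: instrument selection over the p-value ladder,
#' harmonisation (with proxy substitution), the outcome-vs-exposure
#' p-value pleiotropy filter, radial MR outlier removal, then the
#' estimator battery and diagnostics on the final pair set. With a single
#' surviving instrument only the Wald ratio is computed; with two, both
#' IVW modes; with three or more, the full five-estimator battery. All
#' removals are logged with reasons.
#'
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param ld an [LDReference-class] object.
#' @param config an `mr_config` list from [mrConfig()].
#' @return An [MRBattery-class] object (status `"not_analysable"` with a
#'   reason when selection rejects the exposure or filtering empties it).
#' @export
runSingle <- function(exposure, outcome, ld, config = mrConfig()) {
  exposure_id <- traitId(exposure)
  outcome_id <- traitId(outcome)
  sel <- selectInstruments(exposure, ld, ladder = config$ladder,
                           min_instruments = config$min_instruments,
                           r2_threshold = config$clump_r2,
                           window_bp = config$clump_window_bp)
  if (is(sel, "InstrumentRejection")) {
    return(not_analysable(exposure_id, outcome_id,
                          sprintf("fewer than %d independent instruments (best %d)",
                                  config$min_instruments, sel@bestCount)))
  }
  n_initial <- nVariants(sel)
  hs <- harmoniseSet(sel, exposure, outcome, ld,
                     maf_limit = config$maf_limit,
                     proxy_r2 = config$proxy_r2)
  pf <- pleiotropyFilter(hs)
  if (nVariants(pf$set) >= 3) {
    rad <- radialOutliers(pf$set, alpha = config$radial_alpha,
                          iterate = config$radial_iterate,
                          bonferroni = config$radial_bonferroni)
  } else {
    rad <- list(outliers = character(), iterations = 0L, pairs = pf$set)
  }
  final <- rad$pairs
  J <- nVariants(final)
  removed <- list(exclusions = names(exclusions(hs)),
                  pleiotropy = pf$removed, radial = rad$outliers)
  provenance <- list(threshold_used = sel@thresholdUsed,
                     clump_r2 = sel@clumpR2,
                     clump_window_bp = sel@clumpWindowBp,
                     config_digest = config_digest(config))
  if (J == 0) {
    b <- not_analysable(exposure_id, outcome_id,
                        "no instruments survive harmonisation and filtering",
                        n_initial, provenance)
    b@removed <- removed
    return(b)
  }

  seed_e <- derive_seed(config$seed, exposure_id)
  fp <- pairs_df(final)
  results <- list()
  if (J == 1) {
    results$wald <- waldRatio(final)
  } else {
    results$ivw_fe <- ivw(final, "fixed")
    results$ivw_mre <- ivw(final, "multiplicative_random",
                           phi_truncate = config$phi_truncate)
    if (J >= 3) {
      results$egger <- mrEgger(final)
      results$weighted_median <- weightedMedian(final, n_boot = config$n_boot,
                                                seed = seed_e)
      results$weighted_mode <- weightedMode(
        final, bandwidth_factor = config$bandwidth_factor,
        n_boot = config$n_boot, seed = seed_e + 1L)
    } else {
      results$egger <- mr_unavailable("egger", J, "requires at least 3 instruments")
      results$weighted_median <- mr_unavailable("weighted_median", J,
                                                "requires at least 3 instruments")
      results$weighted_mode <- mr_unavailable("weighted_mode", J,
                                              "requires at least 3 instruments")
    }
  }

  diag <- list(mean_f = fStatistics(data.frame(variant_id = fp$variant_id,
                                               beta = fp$gamma,
                                               se = fp$se_gamma))$mean_f,
               radial_outliers = rad$outliers,
               radial_iterations = rad$iterations)
  if (J >= 2) {
    beta_fe <- results$ivw_fe@beta
    qres <- cochranQ(final, beta_fe)
    diag$q <- qres$q; diag$q_df <- qres$df; diag$q_p <- qres$p
    diag$i2_gx <- i2GX(final)
  }
  if (J >= 3) {
    loo <- leaveOneOut(final)
    diag$loo <- loo$loo
    diag$n_loo_nonsig <- loo$n_nonsig
    diag$egger_intercept_p <- results$egger@extras$intercept_p %||% NA_real_
  }

  new("MRBattery", exposureId = exposure_id, outcomeId = outcome_id,
      status = "ok", reason = "", results = results, diagnostics = diag,
      nSnpInitial = as.integer(n_initial), nSnpFinal = as.integer(J),
      nPleiotropyFiltered = length(pf$removed), removed = removed,
      provenance = provenance)
}

#' Bonferroni significance threshold
#'
#' @param alpha_family family-wise alpha (e.g. 0.05).
#' @param n_tests number of tests attempted (the full panel size, not only
#'   the analysable exposures).
#' @return alpha_family / n_tests.
#' @export
bonferroniThreshold <- function(alpha_family, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive integer", call. = FALSE)
  alpha_family / n_tests
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; the
#' input order is preserved in the output.
#'
#' @param pvalues numeric vector of p-values in (0, 1] (`NA` allowed).
#' @return numeric vector of adjusted p-values.
#' @export
bhFDR <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

primary_result <- function(battery) {
  if (battery@status != "ok") return(NULL)
  battery@results$ivw_mre %||% battery@results$wald
}

#' Run the metabolome-wide screen
#'
#' Runs [runSingle()] for every exposure in the panel against a shared
#' outcome, applies multiple-testing control over the number of exposures
#' attempted, and computes the q-q inflation of the primary
#' (multiplicative random-effects IVW) p-values. Per-exposure failures are
#' recorded as not-analysable batteries, never fatal. Results are ordered
#' by exposure id and all bootstrap seeds derive from the configuration
#' seed and the exposure id, so the result is independent of panel order.
#'
#' @param exposures list of [SummaryStats-class] exposure panels.
#' @param outcome a [SummaryStats-class] object.
#' @param ld an [LDReference-class] object.
#' @param config an `mr_config` list from [mrConfig()].
#' @return A [ScreenResult-class] object.
#' @export
runScreen <- function(exposures, outcome, ld, config = mrConfig()) {
  if (length(exposures) == 0) stop("empty exposure panel", call. = FALSE)
  ids <- vapply(exposures, traitId, character(1))
  if (anyDuplicated(ids)) stop("duplicate exposure ids", call. = FALSE)
  exposures <- exposures[order(ids)]
  ids <- sort(ids)
  bats <- lapply(exposures, function(e) runSingle(e, outcome, ld, config))
  names(bats) <- ids

  n_tests <- length(exposures)
  pvec <- vapply(bats, function(b) {
    pr <- primary_result(b)
    if (is.null(pr)) NA_real_ else pr@pvalue
  }, numeric(1))
  bvec <- vapply(bats, function(b) {
    pr <- primary_result(b)
    if (is.null(pr)) NA_real_ else pr@beta
  }, numeric(1))
  svec <- vapply(bats, function(b) {
    pr <- primary_result(b)
    if (is.null(pr)) NA_real_ else pr@se
  }, numeric(1))
  mvec <- vapply(bats, function(b) {
    pr <- primary_result(b)
    if (is.null(pr)) NA_character_ else pr@method
  }, character(1))

  threshold <- bonferroniThreshold(config$alpha_family, n_tests)
  adjusted <- bhFDR(pvec)
  significant <- if (config$correction == "bonferroni") {
    !is.na(pvec) & pvec <= threshold
  } else {
    !is.na(adjusted) & adjusted <= config$alpha_family
  }

  ok_p <- pvec[!is.na(pvec)]
  if (length(ok_p) >= 10) {
    qi <- qqInflation(ok_p)
    lambda <- qi$lambda_median
    qq <- qi$qq
  } else {
    lambda <- NA_real_
    qq <- data.frame(expected = numeric(), observed = numeric())
  }

  tab <- data.frame(exposure_id = ids,
                    status = vapply(bats, function(b) b@status, character(1)),
                    n_snp_final = vapply(bats, function(b) b@nSnpFinal,
                                         integer(1)),
                    primary_method = mvec, beta = bvec, se = svec,
                    pvalue = pvec, p_adjusted = adjusted,
                    significant = significant, stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  new("ScreenResult", batteries = bats, table = tab,
      correction = config$correction, alphaFamily = config$alpha_family,
      threshold = threshold, significantIds = ids[significant],
      lambdaMedian = lambda, qq = qq)
}

#' Write screen outputs
#'
#' Writes `PREFIX.batteries.tsv` (one row per exposure battery),
#' `PREFIX.screen.tsv` (primary p-values and adjustment), `PREFIX.qq.tsv`
#' (quantile pairs) and `PREFIX.log` (a run summary).
#'
#' @param screen a [ScreenResult-class] object.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeScreenResult <- function(screen, prefix) {
  paths <- paste0(prefix, c(".batteries.tsv", ".screen.tsv", ".qq.tsv",
                            ".log"))
  writeBatteries(screen@batteries, paths[1])
  data.table::fwrite(screen@table, paths[2], sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(screen@qq, paths[3], sep = "\t", quote = FALSE)
  writeLines(c(sprintf("exposures tested: %d", nrow(screen@table)),
               sprintf("correction: %s (family alpha %g)", screen@correction,
                       screen@alphaFamily),
               sprintf("threshold: %g", screen@threshold),
               sprintf("lambda_median: %g", screen@lambdaMedian),
               sprintf("significant: %s",
                       paste(screen@significantIds, collapse = ", "))),
             paths[4])
  invisible(paths)
}
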