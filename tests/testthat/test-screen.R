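# Screen orchestration, multiple-testing control and outputs.

test_that("the Bonferroni threshold reproduces the screen cutoff", {
  expect_equal(signif(bonferroniThreshold(0.05, 575), 2), 8.7e-5)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 20), 2.5e-3)
  expect_error(bonferroniThreshold(0.05, 0), "positive")
})

test_that("Benjamini-Hochberg adjustment is the standard step-up", {
  expect_equal(bhFDR(0.01), 0.01)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  # order of input preserved
  expect_equal(bhFDR(c(0.04, 0.01, 0.02, 0.03)), rep(0.04, 4))
})

test_that("a clean simulated exposure yields an accurate, fully-diagnosed battery", {
  cfg <- clean_config(n_snps = 9, true_beta = 0.2, seed = 15,
                      gamma_sd = 0.2)  # strong candidates so all 9 are selected
  sim <- simulatePair(cfg)
  b <- runSingle(sim$exposure, sim$outcome, sim$ld, mrConfig(seed = 4))
  expect_equal(b@status, "ok")
  pr <- b@results$ivw_mre
  expect_lt(abs(pr@beta - 0.2), 3 * pr@se)
  expect_equal(b@nPleiotropyFiltered, 0L)
  # a homogeneous set loses at most the occasional per-SNP alpha = 0.05
  # radial false positive
  expect_lte(length(b@removed$radial), 1L)
  expect_equal(b@nSnpFinal,
               b@nSnpInitial - length(b@removed$exclusions) -
                 b@nPleiotropyFiltered - length(b@removed$radial))
  expect_true(all(c("ivw_fe", "ivw_mre", "egger", "weighted_median",
                    "weighted_mode") %in% names(b@results)))
})

test_that("exposures with too few independent instruments are not analysable", {
  recs <- lapply(1:4, function(i)
    make_record(sprintf("rs%d", i), chrom = as.character(i), pos = 1e6,
                beta = 0.15, se = 0.02))
  exposure <- make_sumstats(recs, "weak_met")
  outcome <- make_sumstats(recs, "out", "binary")
  b <- runSingle(exposure, outcome, LDReference(), mrConfig())
  expect_equal(b@status, "not_analysable")
  expect_match(b@reason, "best 4")
})

test_that("a planted gross outlier is removed before final estimation", {
  cfg <- clean_config(n_snps = 9, true_beta = 0.2, seed = 28, gamma_sd = 0.2)
  sim <- simulatePair(cfg)
  rec <- records(sim$outcome)
  worst <- which.max(records(sim$exposure)$beta)
  rec$beta[worst] <- rec$beta[worst] + 12 * rec$se[worst]
  outcome <- SummaryStats("outcome", "binary", rec)
  b <- runSingle(sim$exposure, outcome, sim$ld, mrConfig(seed = 4))
  planted <- rec$variant_id[worst]
  expect_true(planted %in% b@removed$radial)
  expect_equal(b@nSnpFinal, b@nSnpInitial - length(b@removed$exclusions) -
                 b@nPleiotropyFiltered - length(b@removed$radial))
})

test_that("screen results are order-independent and deterministic on disk", {
  cfg <- clean_config(seed = 33, n_exposure = 8000, n_cases = 25000,
                      n_controls = 100000)
  panel <- simulateScreenPanel(cfg, n_exposures = 12, n_causal = 2,
                               n_candidates = 15)
  mc <- mrConfig(seed = 33)
  s1 <- runScreen(panel$exposures, panel$outcome, panel$ld, mc)
  s2 <- runScreen(rev(panel$exposures), panel$outcome, panel$ld, mc)
  expect_equal(s1@table, s2@table)
  expect_identical(s1@significantIds, s2@significantIds)
  p1 <- file.path(tempdir(), "scr1"); p2 <- file.path(tempdir(), "scr2")
  writeScreenResult(s1, p1); writeScreenResult(s2, p2)
  for (suffix in c(".batteries.tsv", ".screen.tsv", ".qq.tsv"))
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
})

test_that("every Bonferroni-significant exposure is also BH-significant", {
  cfg <- clean_config(seed = 61, n_exposure = 8000, n_cases = 25000,
                      n_controls = 100000)
  panel <- simulateScreenPanel(cfg, n_exposures = 15, n_causal = 3,
                               n_candidates = 15)
  bonf <- runScreen(panel$exposures, panel$outcome, panel$ld,
                    mrConfig(seed = 61, correction = "bonferroni"))
  bh <- runScreen(panel$exposures, panel$outcome, panel$ld,
                  mrConfig(seed = 61, correction = "benjamini_hochberg"))
  expect_true(all(significantIds(bonf) %in% significantIds(bh)))
})

test_that("a single-exposure screen uses the family alpha unchanged", {
  cfg <- clean_config(seed = 44, gamma_sd = 0.2, true_beta = 0.3)
  sim <- simulatePair(cfg, exposure_id = "solo")
  s <- runScreen(list(sim$exposure), sim$outcome, sim$ld, mrConfig(seed = 2))
  expect_equal(s@threshold, 0.05)
  expect_equal(nrow(s@table), 1L)
})

test_that("the battery equals estimators called directly on the final pair set", {
  cfg <- clean_config(n_snps = 10, true_beta = 0.25, seed = 52,
                      gamma_sd = 0.2)
  sim <- simulatePair(cfg)
  mc <- mrConfig(seed = 9)
  b <- runSingle(sim$exposure, sim$outcome, sim$ld, mc)
  # rebuild the final set from the battery's own accounting
  hs <- simulateHarmonised(sim)
  keep <- setdiff(pairs_df(hs)$variant_id,
                  c(b@removed$pleiotropy, b@removed$radial))
  sel_ids <- keep[keep %in% pairs_df(hs)$variant_id]
  p <- pairs_df(hs)
  final <- p[p$variant_id %in% sel_ids & p$variant_id %in%
               records(sim$exposure)$variant_id[records(sim$exposure)$pvalue <=
                                                  b@provenance$threshold_used], ]
  direct <- ivw(final, "multiplicative_random")
  expect_equal(b@results$ivw_mre@beta, direct@beta, tolerance = 1e-12)
  expect_equal(b@results$ivw_mre@se, direct@se, tolerance = 1e-12)
})

test_that("configuration files round-trip through YAML with strict keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("alpha_family: 0.05", "min_instruments: 3",
               "correction: benjamini_hochberg", "seed: 12"), path)
  cfg <- readConfig(path)
  expect_equal(cfg$min_instruments, 3L)
  expect_equal(cfg$correction, "benjamini_hochberg")
  expect_equal(cfg$clump_r2, 0.001)  # default preserved
  writeLines("not_a_key: 1", path)
  expect_error(readConfig(path), "unknown configuration key")
})
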