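# Instrument selection: clumping, the adaptive ladder, proxies, F
# statistics and the pleiotropy p-filter.

test_that("clumping keeps the most significant of a correlated pair", {
  cand <- rbind(make_record("rs1", pos = 1e6, pvalue = 1e-9),
                make_record("rs2", pos = 2e6, pvalue = 1e-8))
  ld <- LDReference(data.frame(id_a = "rs1", id_b = "rs2", r = sqrt(0.5)))
  out <- clumpVariants(cand, ld, r2_threshold = 0.1, window_bp = 1e7)
  expect_equal(out$variant_id, "rs1")
})

test_that("variants on different chromosomes are independent", {
  cand <- rbind(make_record("rs1", chrom = "1", pvalue = 1e-9),
                make_record("rs2", chrom = "2", pvalue = 1e-8))
  ld <- LDReference()  # no entries at all
  out <- clumpVariants(cand, ld, 0.001, 1e7)
  expect_setequal(out$variant_id, c("rs1", "rs2"))
})

test_that("greedy clumping matches the brute-force oracle on block LD", {
  set.seed(41)
  for (rep in 1:5) {
    sim <- simulateLDReference(simConfig(n_snps = 10, ld_block_size = 5,
                                         ld_rho = 0.7, seed = 100 + rep))
    cand <- records(sim$sumstats)
    got <- clumpVariants(cand, sim$ld, r2_threshold = 0.1, window_bp = 1e7)
    want <- oracle_clump_ids(cand, sim$ld@table, 0.1, 1e7)
    expect_equal(got$variant_id, want)
    # certification: every retained in-window pair is below the threshold
    if (nrow(got) > 1) {
      cmb <- combn(got$variant_id, 2)
      r <- ldLookup(sim$ld, cmb[1, ], cmb[2, ])
      expect_true(all(r^2 < 0.1))
    }
  }
})

test_that("clumping output is invariant to input order", {
  sim <- simulateLDReference(simConfig(n_snps = 12, ld_block_size = 4,
                                       ld_rho = 0.8, seed = 9))
  cand <- records(sim$sumstats)
  a <- clumpVariants(cand, sim$ld, 0.05, 1e7)
  b <- clumpVariants(cand[rev(seq_len(nrow(cand))), ], sim$ld, 0.05, 1e7)
  expect_equal(a, b)
})

make_independent_exposure <- function(pvals, trait_id = "met") {
  recs <- lapply(seq_along(pvals), function(i) {
    z <- qnorm(pvals[i] / 2, lower.tail = FALSE)
    make_record(sprintf("rs%03d", i), chrom = as.character(i %% 22 + 1),
                pos = 1e6 + i * 3e7, beta = z * 0.02, se = 0.02,
                pvalue = pvals[i])
  })
  make_sumstats(recs, trait_id = trait_id)
}

test_that("the ladder stops at the most stringent rung with enough instruments", {
  ld <- LDReference()
  # six independent SNPs below 5e-8: the first rung suffices
  e1 <- make_independent_exposure(rep(1e-9, 6))
  s1 <- selectInstruments(e1, ld)
  expect_s4_class(s1, "InstrumentSet")
  expect_equal(s1@thresholdUsed, 5e-8)
  expect_equal(nVariants(s1), 6L)
  # only three below 5e-8 but five below 5e-6: relaxes to the last rung
  e2 <- make_independent_exposure(c(1e-9, 1e-9, 1e-9, 2e-6, 2e-6))
  s2 <- selectInstruments(e2, ld)
  expect_equal(s2@thresholdUsed, 5e-6)
  expect_equal(nVariants(s2), 5L)
  # at most four anywhere on the ladder: rejection carrying the best count
  e3 <- make_independent_exposure(c(1e-9, 1e-9, 2e-6, 2e-6))
  s3 <- selectInstruments(e3, ld)
  expect_s4_class(s3, "InstrumentRejection")
  expect_equal(s3@bestCount, 4L)
  # empty exposure: rejection with count 0
  e4 <- make_independent_exposure(0.5)
  s4 <- selectInstruments(e4, ld)
  expect_s4_class(s4, "InstrumentRejection")
  expect_equal(s4@bestCount, 0L)
})

test_that("relaxing the ladder never reduces the instrument count", {
  for (seed in 1:5) {
    sim <- simulateLDReference(simConfig(n_snps = 15, ld_block_size = 3,
                                         ld_rho = 0.6, seed = seed),
                               lead_z = 6)
    cand <- records(sim$sumstats)
    counts <- vapply(c(5e-8, 1e-7, 5e-7, 1e-6, 5e-6), function(thr) {
      nrow(clumpVariants(cand[cand$pvalue <= thr, , drop = FALSE], sim$ld,
                         0.001, 1e7))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("proxy search returns the best candidate above the r2 floor, with sign", {
  outcome <- make_sumstats(list(make_record("p1"), make_record("p2"),
                                make_record("p3")), "out", "binary")
  ld <- LDReference(data.frame(id_a = c("m", "m", "m"),
                               id_b = c("p1", "p2", "p3"),
                               r = c(sqrt(0.95), -sqrt(0.92), 0.5)))
  px <- findProxy("m", outcome, ld, r2_min = 0.9)
  expect_equal(px$record$variant_id, "p1")
  expect_gt(px$r, 0)
  # negative-sign proxies propagate their sign
  ld2 <- LDReference(data.frame(id_a = "m", id_b = "p2", r = -0.97))
  px2 <- findProxy("m", outcome, ld2, r2_min = 0.9)
  expect_equal(px2$record$variant_id, "p2")
  expect_lt(px2$r, 0)
  # best candidate below the floor: no proxy
  ld3 <- LDReference(data.frame(id_a = "m", id_b = "p1", r = sqrt(0.89)))
  expect_null(findProxy("m", outcome, ld3, r2_min = 0.9))
  # unsigned dialect refuses
  ld4 <- LDReference(data.frame(id_a = "m", id_b = "p1", r = 0.98),
                     signed = FALSE)
  expect_error(findProxy("m", outcome, ld4), "unsigned")
})

test_that("F statistics are squared z-scores with a weak-instrument flag", {
  inst <- data.frame(variant_id = c("a", "b"), beta = c(0.1, 0.06),
                     se = c(0.02, 0.02))
  f <- fStatistics(inst)
  expect_equal(unname(f$f["a"]), 25)
  expect_equal(f$mean_f, mean(c(25, 9)))
  expect_false(f$weak)
  weak <- fStatistics(data.frame(variant_id = "a", beta = 0.02, se = 0.02))
  expect_true(weak$weak)
  # all F equal: the mean equals the common value
  eq <- fStatistics(data.frame(variant_id = c("a", "b"),
                               beta = c(0.1, -0.1), se = c(0.02, 0.02)))
  expect_equal(eq$mean_f, 25)
})

test_that("the pleiotropy filter removes pairs with stronger outcome association", {
  hs <- make_pairs(gamma = c(0.1, 0.1, 0.1), Gamma = c(0.02, 0.02, 0.02))
  p <- pairs_df(hs)
  p$p_gamma <- c(1e-6, 1e-8, 1e-8)
  p$p_Gamma <- c(1e-10, 0.3, 1e-8)   # stronger, weaker, exactly equal
  hs@pairs <- p
  out <- pleiotropyFilter(hs)
  expect_equal(out$removed, "rs001")
  expect_equal(pairs_df(out$set)$variant_id, c("rs002", "rs003"))
})
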