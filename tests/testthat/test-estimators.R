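# The five estimators against closed forms, an independent WLS oracle,
# and their equivariance properties.

test_that("ratio estimates follow the first-order delta method", {
  hs <- make_pairs(gamma = c(0.04, 0.1), Gamma = c(0.04, 0),
                   se_Gamma = c(0.0092, 0.01))
  r <- ratioEstimates(hs)
  expect_equal(r$ratio, c(1, 0))
  expect_equal(r$se, c(0.0092 / 0.04, 0.1))
  # zero exposure effect is a hard error naming the variant
  bad <- make_pairs(gamma = c(0.1, 0), Gamma = c(0.1, 0.1))
  expect_error(ratioEstimates(bad), "rs002")
})

test_that("second-order delta SEs agree with first-order for strong instruments", {
  # strong instruments (exposure z = 25) with modest outcome associations
  # (outcome z <= 3), the regime where the first-order formula is used
  grid <- expand.grid(gamma = c(0.05, 0.1, 0.2), z_out = c(0.5, 1.5, 3))
  for (i in seq_len(nrow(grid))) {
    g <- grid$gamma[i]
    G <- 0.3 * g
    hs <- make_pairs(gamma = g, Gamma = G, se_gamma = g / 25,
                     se_Gamma = abs(G) / grid$z_out[i])
    s1 <- ratioEstimates(hs)$se
    s2 <- ratioEstimates(hs, second_order = TRUE)$se
    expect_lt(abs(s2 - s1) / s1, 0.01)
  }
})

test_that("the Wald ratio is the single-instrument estimator", {
  hs <- make_pairs(gamma = 0.04, Gamma = 0.04, se_Gamma = 0.0092)
  w <- waldRatio(hs)
  expect_equal(w@beta, 1)
  expect_equal(w@nSnp, 1L)
  # linearity in the outcome effect
  w2 <- waldRatio(make_pairs(gamma = 0.04, Gamma = 0.08, se_Gamma = 0.0092))
  expect_equal(w2@beta, 2 * w@beta)
  # beta/se = 1.96 gives p ~= 0.05
  w3 <- waldRatio(make_pairs(gamma = 1, Gamma = 1.96, se_Gamma = 1))
  expect_equal(w3@pvalue, 2 * pnorm(-1.96))
  expect_error(waldRatio(make_pairs(c(1, 1), c(1, 1))), "exactly one")
})

test_that("IVW recovers a perfect proportional fit with no heterogeneity", {
  g <- c(0.05, 0.1, 0.15, 0.2)
  hs <- make_pairs(gamma = g, Gamma = 0.2 * g)
  fit <- ivw(hs)
  expect_equal(fit@beta, 0.2)
  expect_equal(fit@extras$Q, 0, tolerance = 1e-20)
  expect_equal(fit@extras$phi, 1)
})

test_that("IVW with one pair delegates to the Wald ratio exactly", {
  set.seed(8)
  for (i in 1:20) {
    hs <- make_pairs(gamma = rnorm(1, 0.1, 0.05), Gamma = rnorm(1, 0, 0.05),
                     se_gamma = runif(1, 0.005, 0.02),
                     se_Gamma = runif(1, 0.005, 0.02))
    w <- waldRatio(hs)
    for (mode in c("fixed", "multiplicative_random")) {
      v <- ivw(hs, mode)
      expect_identical(v@beta, w@beta)
      expect_identical(v@se, w@se)
      expect_identical(v@pvalue, w@pvalue)
    }
  }
})

test_that("IVW and Egger match the weighted-least-squares oracle to 1e-10", {
  set.seed(19)
  for (i in 1:20) {
    J <- sample(3:30, 1)
    g <- abs(rnorm(J, 0.1, 0.05)) + 0.01
    G <- 0.3 * g + rnorm(J, 0, 0.02)
    seG <- runif(J, 0.005, 0.03)
    hs <- make_pairs(g, G, se_Gamma = seG)
    w <- seG^-2

    o <- oracle_wls(g, G, w, intercept = FALSE)
    fe <- ivw(hs, "fixed")
    mre <- ivw(hs, "multiplicative_random", phi_truncate = FALSE)
    expect_equal(fe@beta, o$slope, tolerance = 1e-10)
    expect_equal(fe@se, o$se_slope_unscaled, tolerance = 1e-10)
    expect_equal(mre@se, o$se_slope_unscaled * sqrt(o$sigma2),
                 tolerance = 1e-10)
    expect_equal(mre@extras$Q, o$q, tolerance = 1e-10)

    oi <- oracle_wls(g, G, w, intercept = TRUE)
    eg <- mrEgger(hs)
    expect_equal(eg@beta, oi$slope, tolerance = 1e-10)
    expect_equal(eg@extras$intercept, oi$intercept, tolerance = 1e-10)
    phi <- max(1, oi$sigma2)
    expect_equal(eg@se, oi$se_slope_unscaled * sqrt(phi), tolerance = 1e-10)
    expect_equal(eg@extras$intercept_se, oi$se_int_unscaled * sqrt(phi),
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact affine relationship", {
  g <- c(0.05, 0.1, 0.15, 0.22, 0.3)
  # no pleiotropy: zero intercept, slope recovered
  e0 <- mrEgger(make_pairs(g, 0.4 * g))
  expect_equal(e0@beta, 0.4, tolerance = 1e-12)
  expect_equal(e0@extras$intercept, 0, tolerance = 1e-12)
  # constant directional pleiotropy: intercept c, slope unchanged
  e1 <- mrEgger(make_pairs(g, 0.4 * g + 0.03))
  expect_equal(e1@beta, 0.4, tolerance = 1e-12)
  expect_equal(e1@extras$intercept, 0.03, tolerance = 1e-12)
  # orientation: flipping the coding of some SNPs changes nothing
  flip <- c(1, -1, 1, -1, 1)
  e2 <- mrEgger(make_pairs(g * flip, (0.4 * g + 0.03) * flip))
  expect_equal(e2@beta, e1@beta, tolerance = 1e-12)
  expect_equal(e2@extras$intercept, e1@extras$intercept, tolerance = 1e-12)
  # too few instruments: typed unavailability, not an error
  short <- mrEgger(make_pairs(g[1:2], g[1:2]))
  expect_true(short@extras$unavailable)
  expect_true(is.na(short@beta))
})

test_that("the weighted median interpolates the weighted quantile function", {
  hs <- make_pairs(gamma = c(1, 1, 1), Gamma = c(0.1, 0.5, 0.9))
  wm <- weightedMedian(hs, n_boot = 200, seed = 1)
  expect_equal(wm@beta, 0.5)
  # all ratios equal: the estimate is that value
  hs2 <- make_pairs(gamma = c(0.5, 1, 2), Gamma = 0.3 * c(0.5, 1, 2))
  wm2 <- weightedMedian(hs2, n_boot = 200, seed = 1)
  expect_equal(wm2@beta, 0.3)
  expect_true(is.finite(wm2@se))
  expect_true(weightedMedian(make_pairs(1, 1))@extras$unavailable)
})

test_that("the weighted mode tracks the dominant ratio cluster", {
  hs <- make_pairs(gamma = rep(1, 4), Gamma = c(0.2, 0.2, 0.2, 0.9))
  wm <- weightedMode(hs, n_boot = 200, seed = 2)
  expect_lt(abs(wm@beta - 0.2), 0.05)
  # tight cluster: estimate within one bandwidth of the centre
  r <- c(0.50, 0.51, 0.49, 0.505)
  hs2 <- make_pairs(gamma = rep(1, 4), Gamma = r)
  wm2 <- weightedMode(hs2, n_boot = 200, seed = 2)
  expect_lt(abs(wm2@beta - 0.5), wm2@extras$bandwidth + 0.02)
})

test_that("the weighted mode follows the majority component of a bimodal set", {
  hits <- 0L
  for (rep in 1:200) {
    set.seed(3000 + rep)
    J <- 10
    comp <- rep(c(0.2, 0.8), times = c(6, 4))   # 60/40 mass split
    r <- rnorm(J, comp, 0.03)
    hs <- make_pairs(gamma = rep(1, J), Gamma = r)
    est <- weightedMode(hs, n_boot = 2, seed = rep)@beta
    if (abs(est - 0.2) < abs(est - 0.8)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("bootstrap standard errors are bit-identical under the same seed", {
  hs <- make_pairs(gamma = c(0.1, 0.12, 0.2, 0.08), Gamma = c(0.02, 0.03, 0.05, 0.01))
  a <- weightedMedian(hs, n_boot = 300, seed = 99)
  b <- weightedMedian(hs, n_boot = 300, seed = 99)
  expect_identical(a@se, b@se)
  c1 <- weightedMode(hs, n_boot = 300, seed = 99)
  c2 <- weightedMode(hs, n_boot = 300, seed = 99)
  expect_identical(c1@se, c2@se)
  # and the bootstrap does not disturb the global RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(weightedMedian(hs, n_boot = 10, seed = 5))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(55)
  g <- abs(rnorm(8, 0.1, 0.04)) + 0.02
  G <- 0.25 * g + rnorm(8, 0, 0.01)
  seg <- runif(8, 0.005, 0.02)
  seG <- runif(8, 0.005, 0.02)
  hs <- make_pairs(g, G, seg, seG)
  neg <- make_pairs(g, -G, seg, seG)
  sc <- 3.7
  scl <- make_pairs(sc * g, G, sc * seg, seG)
  fits <- function(x, seed = 7) list(
    ivw(x), mrEgger(x),
    weightedMedian(x, n_boot = 100, seed = seed),
    weightedMode(x, n_boot = 100, seed = seed))
  f0 <- fits(hs); fn <- fits(neg); fs <- fits(scl)
  for (k in seq_along(f0)) {
    expect_equal(fn[[k]]@beta, -f0[[k]]@beta, tolerance = 1e-12)
    expect_equal(fs[[k]]@beta, f0[[k]]@beta / sc, tolerance = 1e-12)
    expect_equal(fs[[k]]@se, f0[[k]]@se / sc, tolerance = 1e-12)
  }
  # analytic standard errors are exactly invariant under sign flips
  expect_identical(fn[[1]]@se, f0[[1]]@se)
  expect_equal(fn[[2]]@se, f0[[2]]@se, tolerance = 1e-12)
})
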