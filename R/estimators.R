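# The five causal-effect estimators: Wald ratio, IVW (fixed and
# multiplicative random effects), MR-Egger with intercept test, weighted
# median and weighted mode. All operate on a HarmonisedSet.

as_pairs <- function(x) {
  if (is(x, "HarmonisedSet")) pairs_df(x) else as.data.frame(x)
}

#' Per-SNP ratio (Wald) estimates
#'
#' r_j = Gamma_j / gamma_j with first-order delta-method standard error
#' se(r_j) = se(Gamma_j) / |gamma_j|. The shared kernel of the Wald,
#' weighted-median and weighted-mode estimators.
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame.
#' @param second_order use the second-order delta expansion
#'   (adds the gamma uncertainty term); default first-order.
#' @return data.frame (`variant_id`, `ratio`, `se`), input order preserved.
#' @export
ratioEstimates <- function(x, second_order = FALSE) {
  p <- as_pairs(x)
  if (any(p$gamma == 0))
    stop("ratio estimate undefined for variant(s) with zero exposure effect: ",
         paste(p$variant_id[p$gamma == 0], collapse = ", "), call. = FALSE)
  se <- p$se_Gamma / abs(p$gamma)
  if (second_order)
    se <- sqrt(p$se_Gamma^2 / p$gamma^2 +
                 p$Gamma^2 * p$se_gamma^2 / p$gamma^4)
  data.frame(variant_id = p$variant_id, ratio = p$Gamma / p$gamma, se = se,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimator (single instrument)
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame with exactly one
#'   pair.
#' @return An [MRResult-class] (`method = "wald"`, two-sided normal p).
#' @export
waldRatio <- function(x) {
  p <- as_pairs(x)
  if (nrow(p) != 1L)
    stop("waldRatio requires exactly one pair; use ivw() for several",
         call. = FALSE)
  r <- ratioEstimates(p)
  MRResult("wald", r$ratio, r$se, p_from_z(r$ratio / r$se), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of the outcome effects on the exposure effects
#' through the origin with weights se(Gamma)^-2. The fixed-effect standard
#' error is (sum w gamma^2)^(-1/2); the multiplicative random-effects mode
#' scales it by sqrt(phi) with phi = Q / (J - 1) from Cochran's Q,
#' truncated below at 1 so underdispersion never shrinks the error
#' (`phi_truncate = FALSE` lifts the truncation). A single pair delegates
#' to [waldRatio()].
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame.
#' @param mode `"multiplicative_random"` (the screen's primary test) or
#'   `"fixed"`.
#' @param phi_truncate truncate the overdispersion scale at 1 (default).
#' @return An [MRResult-class]; `extras` carries `phi` and `Q`.
#' @export
ivw <- function(x, mode = c("multiplicative_random", "fixed"),
                phi_truncate = TRUE) {
  mode <- match.arg(mode)
  p <- as_pairs(x)
  method <- if (mode == "fixed") "ivw_fe" else "ivw_mre"
  if (nrow(p) == 0) stop("no pairs", call. = FALSE)
  if (all(p$gamma == 0)) stop("all exposure effects are zero", call. = FALSE)
  if (nrow(p) == 1L) {
    w <- waldRatio(p)
    return(MRResult(method, w@beta, w@se, w@pvalue, 1L,
                    extras = list(phi = 1, Q = 0, delegated = "wald")))
  }
  w <- p$se_Gamma^-2
  s_xx <- sum(w * p$gamma^2)
  beta <- sum(w * p$gamma * p$Gamma) / s_xx
  se_fe <- sqrt(1 / s_xx)
  Q <- sum(w * (p$Gamma - beta * p$gamma)^2)
  phi <- Q / (nrow(p) - 1)
  if (phi_truncate) phi <- max(1, phi)
  se <- if (mode == "fixed") se_fe else se_fe * sqrt(phi)
  MRResult(method, beta, se, p_from_z(beta / se), nrow(p),
           extras = list(phi = phi, Q = Q))
}

#' MR-Egger regression with intercept test
#'
#' Pairs are first oriented so that all exposure effects are non-negative
#' (both signs flipped where needed; the intercept is otherwise not
#' identified). Weighted regression of Gamma on gamma with an
#' unconstrained intercept, weights se(Gamma)^-2; the slope is the causal
#' estimate and a nonzero intercept indicates directional horizontal
#' pleiotropy. Standard errors are scaled by sqrt(max(1, Q_egger/(J-2)))
#' and inference uses the t distribution with J - 2 df.
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame with at least 3
#'   pairs (fewer returns a typed-unavailable result).
#' @return An [MRResult-class]; `extras` carries `intercept`,
#'   `intercept_se`, `intercept_p`, `phi` and `Q`.
#' @export
mrEgger <- function(x) {
  p <- as_pairs(x)
  J <- nrow(p)
  if (J < 3) return(mr_unavailable("egger", J, "requires at least 3 instruments"))
  s <- ifelse(p$gamma < 0, -1, 1)
  g <- s * p$gamma
  G <- s * p$Gamma
  w <- p$se_Gamma^-2
  sw <- sum(w); swx <- sum(w * g); swxx <- sum(w * g^2)
  swy <- sum(w * G); swxy <- sum(w * g * G)
  det <- sw * swxx - swx^2
  if (det <= 0) return(mr_unavailable("egger", J, "degenerate design"))
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  Q <- sum(w * (G - intercept - slope * g)^2)
  phi <- max(1, Q / (J - 2))
  se_slope <- sqrt(sw / det * phi)
  se_int <- sqrt(swxx / det * phi)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = J - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = J - 2)
  MRResult("egger", slope, se_slope, p_slope, J,
           extras = list(intercept = intercept, intercept_se = se_int,
                         intercept_p = p_int, phi = phi, Q = Q))
}

# Parametric bootstrap over the summary statistics: redraw gamma and Gamma
# from normals centred on the observed values with their standard errors,
# recompute the estimator, and report the SD of the replicates.
boot_se <- function(p, n_boot, seed, estimator) {
  J <- nrow(p)
  withr::with_seed(seed, {
    est <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      g_b <- stats::rnorm(J, p$gamma, p$se_gamma)
      G_b <- stats::rnorm(J, p$Gamma, p$se_Gamma)
      est[b] <- estimator(g_b, G_b, p$se_Gamma)
    }
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' The weighted 50 percent quantile of the per-SNP ratio estimates with
#' weights se(r_j)^-2, linearly interpolated through midpoint cumulative
#' weights. Consistent when at least half the weight comes from valid
#' instruments. The standard error comes from a seeded parametric
#' bootstrap of the summary statistics.
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame with at least 3
#'   pairs (fewer returns a typed-unavailable result).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap (mandatory).
#' @return An [MRResult-class] with two-sided normal p.
#' @export
weightedMedian <- function(x, n_boot = 1000L, seed) {
  p <- as_pairs(x)
  J <- nrow(p)
  if (J < 3)
    return(mr_unavailable("weighted_median", J, "requires at least 3 instruments"))
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  kernel <- function(g, G, seG) {
    r <- G / g
    weighted_median_est(r, (seG / abs(g))^-2)
  }
  est <- kernel(p$gamma, p$Gamma, p$se_Gamma)
  se <- boot_se(p, n_boot, seed, kernel)
  MRResult("weighted_median", est, se, p_from_z(est / se), J,
           extras = list(n_boot = n_boot, seed = seed))
}

#' Weighted mode estimator
#'
#' The argmax of a Gaussian-kernel-smoothed weighted density of the
#' per-SNP ratio estimates (weights se(r_j)^-2, NOME assumption),
#' bandwidth `bandwidth_factor` times the modified Silverman rule.
#' Consistent when the largest cluster of instruments is valid. Standard
#' error by the same seeded parametric bootstrap as [weightedMedian()].
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame with at least 3
#'   pairs (fewer returns a typed-unavailable result).
#' @param bandwidth_factor multiplier on the Silverman bandwidth
#'   (default 1).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap (mandatory).
#' @return An [MRResult-class] with two-sided normal p; `extras` carries
#'   the bandwidth used.
#' @export
weightedMode <- function(x, bandwidth_factor = 1, n_boot = 1000L, seed) {
  p <- as_pairs(x)
  J <- nrow(p)
  if (J < 3)
    return(mr_unavailable("weighted_mode", J, "requires at least 3 instruments"))
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  kernel <- function(g, G, seG) {
    r <- G / g
    weighted_mode_est(r, (seG / abs(g))^-2, mode_bandwidth(r, bandwidth_factor))
  }
  est <- kernel(p$gamma, p$Gamma, p$se_Gamma)
  se <- boot_se(p, n_boot, seed, kernel)
  h <- mode_bandwidth(p$Gamma / p$gamma, bandwidth_factor)
  MRResult("weighted_mode", est, se, p_from_z(est / se), J,
           extras = list(bandwidth = h, n_boot = n_boot, seed = seed))
}
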