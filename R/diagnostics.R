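# Heterogeneity, pleiotropy and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Q = sum w_j (Gamma_j - beta gamma_j)^2 with w_j = se(Gamma_j)^-2,
#' evaluated at the IVW slope (or a supplied one); df = J - 1 with an
#' upper-tail chi-square p-value. Excess heterogeneity across per-SNP
#' causal estimates signals pleiotropy.
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame (>= 2 pairs).
#' @param beta_ivw slope at which to evaluate Q; defaults to the IVW
#'   (fixed-effect) slope of `x`.
#' @return list (`q`, `df`, `p`).
#' @export
cochranQ <- function(x, beta_ivw = NULL) {
  p <- as_pairs(x)
  if (nrow(p) < 2) stop("Cochran's Q requires at least 2 pairs", call. = FALSE)
  w <- p$se_Gamma^-2
  if (is.null(beta_ivw))
    beta_ivw <- sum(w * p$gamma * p$Gamma) / sum(w * p$gamma^2)
  q <- sum(w * (p$Gamma - beta_ivw * p$gamma)^2)
  df <- nrow(p) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' I-squared of the instrument-exposure association
#'
#' Measures how precisely the instrument effects on the exposure are
#' estimated relative to their spread; values near 1 mean regression
#' dilution of the MR-Egger slope is negligible, while low values indicate
#' bias towards the null.
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame (>= 2 pairs).
#' @return numeric in [0, 1].
#' @export
i2GX <- function(x) {
  p <- as_pairs(x)
  if (nrow(p) < 2) stop("I2_GX requires at least 2 pairs", call. = FALSE)
  w <- p$se_gamma^-2
  gbar <- sum(w * p$gamma) / sum(w)
  q_gx <- sum((p$gamma - gbar)^2 / p$se_gamma^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (nrow(p) - 1)) / q_gx)
}

#' Radial MR outlier detection and removal
#'
#' Radial reformulation of IVW: regress Gamma_j/se(Gamma_j) on
#' gamma_j/se(Gamma_j) through the origin; each SNP's contribution
#' Q_j = (Gamma_j/se - beta_radial gamma_j/se)^2 is referred to the
#' chi-square(1) upper tail, and SNPs with p below `alpha` are flagged.
#' The sum of the Q_j equals Cochran's Q under these weights. With
#' `iterate`, the fit is repeated after removal until no outlier remains
#' or fewer than 3 SNPs would survive.
#'
#' @param x a [HarmonisedSet-class] object (>= 3 pairs; fewer returns no
#'   outliers).
#' @param alpha per-SNP outlier significance level (default 0.05).
#' @param iterate refit after removal (default TRUE).
#' @param bonferroni divide alpha by the current number of SNPs.
#' @return list (`outliers` character ids, `iterations`, `pairs` the
#'   surviving [HarmonisedSet-class]).
#' @export
radialOutliers <- function(x, alpha = 0.05, iterate = TRUE,
                           bonferroni = FALSE) {
  stopifnot(is(x, "HarmonisedSet"))
  current <- pairs_df(x)
  outliers <- character()
  iterations <- 0L
  repeat {
    if (nrow(current) < 3) break
    w <- current$se_Gamma^-2
    beta <- sum(w * current$gamma * current$Gamma) / sum(w * current$gamma^2)
    q_j <- w * (current$Gamma - beta * current$gamma)^2
    thr <- if (bonferroni) alpha / nrow(current) else alpha
    flag <- stats::pchisq(q_j, 1, lower.tail = FALSE) < thr
    iterations <- iterations + 1L
    if (!any(flag)) break
    outliers <- c(outliers, current$variant_id[flag])
    current <- current[!flag, , drop = FALSE]
    if (!iterate || nrow(current) < 3) break
  }
  list(outliers = outliers, iterations = iterations,
       pairs = HarmonisedSet(x@exposureId, x@outcomeId, current,
                             x@exclusions))
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the multiplicative random-effects IVW with each instrument
#' removed in turn; a refit whose p-value rises above 0.05 marks an
#' instrument with disproportionate influence.
#'
#' @param x a [HarmonisedSet-class] or pairs data.frame (>= 3 pairs).
#' @return list (`loo` data.frame of per-leave-out beta/se/p,
#'   `n_nonsig` count of refits with p > 0.05).
#' @export
leaveOneOut <- function(x) {
  p <- as_pairs(x)
  if (nrow(p) < 3) stop("leave-one-out requires at least 3 pairs", call. = FALSE)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    fit <- ivw(p[-i, , drop = FALSE], "multiplicative_random")
    data.frame(left_out = p$variant_id[i], beta = fit@beta, se = fit@se,
               pvalue = fit@pvalue, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  list(loo = loo, n_nonsig = sum(loo$pvalue > 0.05))
}

#' Q-Q inflation of a screen's p-values
#'
#' The median chi-square statistic implied by the p-values divided by the
#' null median (0.4549...), the genomic-inflation-style lambda. A lambda
#' above `bound` raises the inflation flag. Also returns the
#' (expected, observed) -log10 quantile pairs for plotting.
#'
#' @param pvalues numeric vector of at least 10 p-values in (0, 1].
#' @param bound inflation flag threshold (default 1.1).
#' @return list (`lambda_median`, `flag`, `qq` data.frame).
#' @export
qqInflation <- function(pvalues, bound = 1.1) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 10)
    stop("q-q inflation needs at least 10 p-values", call. = FALSE)
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1,
                                                 lower.tail = FALSE)
  n <- length(pvalues)
  qq <- data.frame(expected = -log10(stats::ppoints(n)),
                   observed = -log10(sort(pvalues)))
  list(lambda_median = lambda, flag = lambda > bound, qq = qq)
}
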