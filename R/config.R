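# Screen configuration: one flat list of tunables with the screen's
# published settings as defaults, optionally loaded from YAML.

#' Screen configuration
#'
#' Builds the configuration list driving [runSingle()] and [runScreen()].
#' Defaults are the metabolome-screen settings: a 5e-8..5e-6 p-value
#' ladder, clumping at r-squared 0.001 within 10,000 kb, proxies at
#' r-squared above 0.9, palindrome exclusion at MAF above 0.42, at least 5
#' LD-independent instruments, per-SNP radial outlier alpha 0.05 with
#' iteration, and Bonferroni control at family alpha 0.05.
#'
#' @param ladder strictly increasing p-value thresholds.
#' @param clump_r2,clump_window_bp greedy clumping parameters.
#' @param proxy_r2 minimum proxy r-squared (strict).
#' @param maf_limit palindrome ambiguity bound on MAF.
#' @param min_instruments minimum post-clump instrument count.
#' @param radial_alpha,radial_iterate,radial_bonferroni radial MR settings.
#' @param n_boot bootstrap draws for median/mode standard errors.
#' @param seed master seed; per-exposure bootstrap seeds are derived from
#'   it and the exposure id, so screen results do not depend on panel
#'   order.
#' @param correction `"bonferroni"` or `"benjamini_hochberg"`.
#' @param alpha_family family-wise (or FDR) alpha.
#' @param bandwidth_factor weighted-mode bandwidth multiplier.
#' @param phi_truncate truncate the IVW overdispersion scale at 1.
#' @return named list of class `mr_config`.
#' @export
mrConfig <- function(ladder = c(5e-8, 1e-7, 5e-7, 1e-6, 5e-6),
                     clump_r2 = 0.001, clump_window_bp = 1e7,
                     proxy_r2 = 0.9, maf_limit = 0.42,
                     min_instruments = 5L, radial_alpha = 0.05,
                     radial_iterate = TRUE, radial_bonferroni = FALSE,
                     n_boot = 1000L, seed = 1L,
                     correction = c("bonferroni", "benjamini_hochberg"),
                     alpha_family = 0.05, bandwidth_factor = 1,
                     phi_truncate = TRUE) {
  correction <- match.arg(correction)
  cfg <- list(ladder = ladder, clump_r2 = clump_r2,
              clump_window_bp = clump_window_bp, proxy_r2 = proxy_r2,
              maf_limit = maf_limit,
              min_instruments = as.integer(min_instruments),
              radial_alpha = radial_alpha, radial_iterate = radial_iterate,
              radial_bonferroni = radial_bonferroni,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              correction = correction, alpha_family = alpha_family,
              bandwidth_factor = bandwidth_factor,
              phi_truncate = phi_truncate)
  class(cfg) <- "mr_config"
  cfg
}

#' Read a screen configuration from YAML
#'
#' Unknown keys are an error; omitted keys take the [mrConfig()] defaults.
#'
#' @param path YAML file path.
#' @return named list of class `mr_config`.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mrConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(mrConfig, vals)
}

config_digest <- function(config) {
  paste(vapply(config, function(v) paste(format(v), collapse = ","),
               character(1)), collapse = "|")
}
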