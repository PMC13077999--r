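# Closed-form generator of two-sample GWAS summary statistics with known
# ground truth: a linear instrumental-variable model with configurable
# causal effect, pleiotropy (balanced or directional, with optional
# correlation to instrument strength), binary-outcome log-odds scaling via
# the effective sample size, LD block structure, and harmonisation
# stressors (allele swaps, strand flips, palindromes, missing outcome
# records with planted proxies).

#' Build a simulation configuration
#'
#' Defaults mirror the observed regime of a metabolome-versus-disease
#' screen: 9 candidate instruments, exposure GWAS of 8000, a case-control
#' outcome of 29,612/122,656, and instrument effects calibrated so the
#' mean F-statistic is about 40 (inside the 22-51 band such screens
#' report). Effects are drawn on the trait-increasing allele coding
#' (gamma_j = |N(0, gamma_sd^2)|), the convention under which directional
#' pleiotropy is directional.
#'
#' @param n_snps number of candidate instruments J.
#' @param true_beta causal effect (log-odds of outcome per SD exposure).
#' @param maf_range allele-frequency range, within (0, 0.5].
#' @param gamma_sd spread of true instrument effects (SD units).
#' @param n_exposure exposure GWAS sample size.
#' @param n_cases,n_controls outcome GWAS case/control counts.
#' @param pleiotropy_mean,pleiotropy_sd direct-effect moments (mu_alpha,
#'   sigma_alpha).
#' @param prop_invalid fraction of SNPs with nonzero direct effects.
#' @param inside_correlation correlation rho between direct effects and
#'   instrument strength; 0 means InSIDE holds.
#' @param ld_block_size,ld_rho LD structure for [simulateLDReference()]
#'   (AR-1 within block).
#' @param palindromic_fraction fraction of SNPs assigned A/T or C/G
#'   alleles.
#' @param strand_flip_fraction fraction of outcome records reported on the
#'   opposite strand.
#' @param swap_fraction fraction of outcome records with effect/other
#'   alleles swapped (sign and frequency recoded accordingly).
#' @param missing_outcome_fraction fraction of SNPs deleted from the
#'   outcome, each with a planted LD proxy.
#' @param proxy_r absolute LD correlation of planted proxies (sign is
#'   drawn at random).
#' @param seed master seed; `effects`, `noise` and `stressors` use named
#'   substreams derived from it, so stressors can be toggled without
#'   changing the latent truth.
#' @return A [SimulationConfig-class] object.
#' @export
simConfig <- function(n_snps = 9L, true_beta = 0, maf_range = c(0.05, 0.5),
                      gamma_sd = 0.115, n_exposure = 8000,
                      n_cases = 29612, n_controls = 122656,
                      pleiotropy_mean = 0, pleiotropy_sd = 0,
                      prop_invalid = 0, inside_correlation = 0,
                      ld_block_size = 1L, ld_rho = 0,
                      palindromic_fraction = 0.1,
                      strand_flip_fraction = 0.1, swap_fraction = 0.25,
                      missing_outcome_fraction = 0.05, proxy_r = 0.95,
                      seed = 1L) {
  new("SimulationConfig", nSnps = as.integer(n_snps),
      trueBeta = true_beta, mafRange = maf_range, gammaSd = gamma_sd,
      nExposure = n_exposure, nOutcomeCases = n_cases,
      nOutcomeControls = n_controls, pleiotropyMean = pleiotropy_mean,
      pleiotropySd = pleiotropy_sd, propInvalid = prop_invalid,
      insideCorrelation = inside_correlation,
      ldBlockSize = as.integer(ld_block_size), ldRho = ld_rho,
      palindromicFraction = palindromic_fraction,
      strandFlipFraction = strand_flip_fraction,
      swapFraction = swap_fraction,
      missingOutcomeFraction = missing_outcome_fraction,
      proxyR = proxy_r, seed = as.integer(seed))
}

#' Effective sample size of a case-control GWAS
#' @param cases,controls case and control counts.
#' @return 4 / (1/cases + 1/controls).
#' @export
effectiveSampleSize <- function(cases, controls) {
  4 / (1 / cases + 1 / controls)
}

# Standard errors of per-allele effects under the generator's regime:
# standardised continuous trait (small per-SNP variance explained) and
# log-odds binary trait via the effective sample size.
se_continuous <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)
se_binary <- function(maf, n_eff) sqrt(4 / (2 * maf * (1 - maf) * n_eff))

sub_seeds <- function(seed) {
  withr::with_seed(seed, stats::setNames(sample.int(2147483646L, 4L),
                                         c("effects", "noise", "stressors",
                                           "extra")))
}

NON_PALINDROMIC_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("G", "A"),
                               c("C", "A"), c("T", "G"), c("T", "C"),
                               c("G", "T"), c("C", "T"))
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"),
                           c("G", "C"))

#' Simulate one two-sample exposure/outcome GWAS pair
#'
#' Per SNP j: maf_j ~ U(maf range); instrument effect
#' gamma_j = |N(0, gamma_sd^2)|; a direct (pleiotropic) effect alpha_j is
#' nonzero with probability `prop_invalid`, with mean `pleiotropy_mean`,
#' SD `pleiotropy_sd` and correlation `inside_correlation` with
#' instrument strength; the outcome effect is
#' Gamma_j = true_beta * gamma_j + alpha_j on the log-odds scale.
#' Observed effects are drawn around the truth with the standardised-trait
#' and effective-sample-size standard errors. Harmonisation stressors
#' (allele swaps, strand flips, palindromic assignment, outcome deletion
#' with a planted LD proxy) are then applied to the outcome records; the
#' truth record retains every latent quantity and stressor decision.
#'
#' @param config a [SimulationConfig-class] object.
#' @param exposure_id,outcome_id trait identifiers.
#' @return list with `exposure` and `outcome` ([SummaryStats-class]),
#'   `ld` ([LDReference-class] carrying planted proxy entries), and
#'   `truth` (data.frame of latent quantities).
#' @export
simulatePair <- function(config, exposure_id = "exposure",
                         outcome_id = "outcome") {
  stopifnot(is(config, "SimulationConfig"))
  J <- config@nSnps
  seeds <- sub_seeds(config@seed)
  n_eff <- effectiveSampleSize(config@nOutcomeCases, config@nOutcomeControls)

  eff <- withr::with_seed(seeds[["effects"]], {
    maf <- stats::runif(J, config@mafRange[1], config@mafRange[2])
    gamma <- abs(stats::rnorm(J, 0, config@gammaSd))
    invalid <- stats::runif(J) < config@propInvalid
    # standardise |gamma| (half-normal) to build the InSIDE-violating part
    hn_mean <- config@gammaSd * sqrt(2 / pi)
    hn_sd <- config@gammaSd * sqrt(1 - 2 / pi)
    z_gamma <- (gamma - hn_mean) / hn_sd
    rho <- config@insideCorrelation
    alpha <- ifelse(invalid,
                    config@pleiotropyMean + config@pleiotropySd *
                      (rho * z_gamma +
                         sqrt(1 - rho^2) * stats::rnorm(J)),
                    0)
    list(maf = maf, gamma = gamma, alpha = alpha, invalid = invalid)
  })
  Gamma_true <- config@trueBeta * eff$gamma + eff$alpha
  se_g <- se_continuous(eff$maf, config@nExposure)
  se_G <- se_binary(eff$maf, n_eff)

  noise <- withr::with_seed(seeds[["noise"]], {
    list(gamma_hat = stats::rnorm(J, eff$gamma, se_g),
         Gamma_hat = stats::rnorm(J, Gamma_true, se_G))
  })

  ids <- sprintf("%s_rs%04d", exposure_id, seq_len(J))
  chrom <- as.character(((seq_len(J) - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((seq_len(J) - 1L) %/% 22L) * 2.5e7

  st <- withr::with_seed(seeds[["stressors"]], {
    palin <- stats::runif(J) < config@palindromicFraction
    allele_idx <- ifelse(palin,
                         sample.int(nrow(PALINDROMIC_PAIRS), J, replace = TRUE),
                         sample.int(nrow(NON_PALINDROMIC_PAIRS), J,
                                    replace = TRUE))
    swap <- stats::runif(J) < config@swapFraction
    strand <- stats::runif(J) < config@strandFlipFraction
    missing <- stats::runif(J) < config@missingOutcomeFraction
    proxy_sign <- sample(c(1, -1), J, replace = TRUE)
    proxy_noise <- stats::rnorm(J)
    list(palin = palin, allele_idx = allele_idx, swap = swap,
         strand = strand, missing = missing, proxy_sign = proxy_sign,
         proxy_noise = proxy_noise)
  })

  ea <- oa <- character(J)
  ea[st$palin] <- PALINDROMIC_PAIRS[st$allele_idx[st$palin], 1]
  oa[st$palin] <- PALINDROMIC_PAIRS[st$allele_idx[st$palin], 2]
  ea[!st$palin] <- NON_PALINDROMIC_PAIRS[st$allele_idx[!st$palin], 1]
  oa[!st$palin] <- NON_PALINDROMIC_PAIRS[st$allele_idx[!st$palin], 2]

  exposure_rec <- data.frame(
    variant_id = ids, chromosome = chrom, position = pos,
    effect_allele = ea, other_allele = oa, eaf = eff$maf,
    beta = noise$gamma_hat, se = se_g,
    pvalue = p_from_z(noise$gamma_hat / se_g), n = config@nExposure,
    stringsAsFactors = FALSE)

  # outcome records start aligned, then stressors recode them
  out_ea <- ea; out_oa <- oa
  out_beta <- noise$Gamma_hat
  out_eaf <- eff$maf
  sw <- st$swap
  out_ea[sw] <- oa[sw]; out_oa[sw] <- ea[sw]
  out_beta[sw] <- -out_beta[sw]
  out_eaf[sw] <- 1 - out_eaf[sw]
  fl <- st$strand
  out_ea[fl] <- complement_alleles(out_ea[fl])
  out_oa[fl] <- complement_alleles(out_oa[fl])

  outcome_rec <- data.frame(
    variant_id = ids, chromosome = chrom, position = pos,
    effect_allele = out_ea, other_allele = out_oa, eaf = out_eaf,
    beta = out_beta, se = se_G, pvalue = p_from_z(noise$Gamma_hat / se_G),
    n = config@nOutcomeCases + config@nOutcomeControls,
    stringsAsFactors = FALSE)

  # delete a fraction of outcome records, planting a nearby LD proxy whose
  # stated effect satisfies sign(r) * beta_proxy ~ |r| * Gamma
  miss <- which(st$missing)
  ld_tab <- data.frame(id_a = character(), id_b = character(), r = numeric(),
                       stringsAsFactors = FALSE)
  proxy_id <- rep(NA_character_, J)
  proxy_r <- rep(NA_real_, J)
  if (length(miss)) {
    pid <- paste0(ids[miss], "p")
    r_signed <- st$proxy_sign[miss] * config@proxyR
    proxy_beta <- sign(r_signed) * config@proxyR * Gamma_true[miss] +
      se_G[miss] * st$proxy_noise[miss]
    proxy_rec <- data.frame(
      variant_id = pid, chromosome = chrom[miss], position = pos[miss] + 5e4,
      effect_allele = "A", other_allele = "G", eaf = eff$maf[miss],
      beta = proxy_beta, se = se_G[miss],
      pvalue = p_from_z(proxy_beta / se_G[miss]),
      n = config@nOutcomeCases + config@nOutcomeControls,
      stringsAsFactors = FALSE)
    outcome_rec <- rbind(outcome_rec[-miss, , drop = FALSE], proxy_rec)
    ld_tab <- data.frame(id_a = ids[miss], id_b = pid, r = r_signed,
                         stringsAsFactors = FALSE)
    proxy_id[miss] <- pid
    proxy_r[miss] <- r_signed
  }

  positions <- rbind(
    data.frame(variant_id = ids, chromosome = chrom, position = pos,
               stringsAsFactors = FALSE),
    if (length(miss))
      data.frame(variant_id = paste0(ids[miss], "p"),
                 chromosome = chrom[miss], position = pos[miss] + 5e4,
                 stringsAsFactors = FALSE))

  truth <- data.frame(
    variant_id = ids, maf = eff$maf, gamma = eff$gamma, alpha = eff$alpha,
    Gamma = Gamma_true, invalid = eff$invalid, se_gamma = se_g,
    se_Gamma = se_G, palindromic = st$palin, swapped = st$swap,
    strand_flipped = st$strand, missing_outcome = st$missing,
    proxy_id = proxy_id, proxy_r = proxy_r, true_beta = config@trueBeta,
    stringsAsFactors = FALSE)

  list(exposure = SummaryStats(exposure_id, "continuous", exposure_rec),
       outcome = SummaryStats(outcome_id, "binary", outcome_rec),
       ld = LDReference(ld_tab, signed = TRUE, window_bp = 1e7,
                        positions = positions),
       truth = truth)
}

#' Harmonise a simulated pair through the real pipeline
#'
#' Convenience wrapper: treats every simulated exposure SNP as an
#' instrument (no p-value selection) and runs [harmoniseSet()], so
#' estimator-level simulations exercise the production harmonisation code.
#'
#' @param sim output of [simulatePair()].
#' @param maf_limit,proxy_r2 see [harmoniseSet()].
#' @return A [HarmonisedSet-class] object.
#' @export
simulateHarmonised <- function(sim, maf_limit = 0.42, proxy_r2 = 0.9) {
  inst <- new("InstrumentSet", exposureId = traitId(sim$exposure),
              variants = records(sim$exposure), thresholdUsed = 1,
              proxiesUsed = character(), clumpR2 = 1, clumpWindowBp = 1e7)
  harmoniseSet(inst, sim$exposure, sim$outcome, sim$ld,
               maf_limit = maf_limit, proxy_r2 = proxy_r2)
}

#' Simulate an LD reference with block structure
#'
#' Builds blocks of `ld_block_size` adjacent SNPs with AR-1 correlation
#' (r = ld_rho^|i-j| within a block, independent across blocks) and draws
#' exposure summary statistics whose z-scores are consistent with that LD:
#' each block has one causal lead SNP and the other members' expected
#' z-scores are attenuated by their correlation with the lead. Blocks are
#' spaced to fall inside a single clump window.
#'
#' @param config a [SimulationConfig-class] object (`n_snps`,
#'   `ld_block_size`, `ld_rho`, `maf_range`, `gamma_sd`, `n_exposure`,
#'   `seed`).
#' @param lead_z expected z-score of each block's lead SNP (default 8).
#' @return list with `ld` ([LDReference-class]), `sumstats`
#'   ([SummaryStats-class]) and `blocks` (data.frame variant -> block,
#'   lead flag).
#' @export
simulateLDReference <- function(config, lead_z = 8) {
  stopifnot(is(config, "SimulationConfig"))
  J <- config@nSnps
  bs <- config@ldBlockSize
  rho <- config@ldRho
  block <- ((seq_len(J) - 1L) %/% bs) + 1L
  within <- ((seq_len(J) - 1L) %% bs) + 1L
  ids <- sprintf("ld_rs%04d", seq_len(J))
  chrom <- rep("1", J)
  pos <- (block - 1L) * 5e7 + within * 1e4 + 1e6

  pairs <- list()
  for (b in unique(block)) {
    idx <- which(block == b)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    pairs[[length(pairs) + 1L]] <- data.frame(
      id_a = ids[cmb[1, ]], id_b = ids[cmb[2, ]],
      r = rho^abs(within[cmb[1, ]] - within[cmb[2, ]]),
      stringsAsFactors = FALSE)
  }
  ld_tab <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id_a = character(), id_b = character(), r = numeric())

  rec <- withr::with_seed(config@seed, {
    maf <- stats::runif(J, config@mafRange[1], config@mafRange[2])
    se <- se_continuous(maf, config@nExposure)
    z <- numeric(J)
    for (b in unique(block)) {
      idx <- which(block == b)
      k <- length(idx)
      R <- rho^abs(outer(within[idx], within[idx], "-"))
      mu <- R[, 1] * lead_z   # lead SNP is the first in the block
      z[idx] <- if (k == 1) stats::rnorm(1, mu, 1) else
        as.vector(mu + t(chol(R)) %*% stats::rnorm(k))
    }
    data.frame(variant_id = ids, chromosome = chrom, position = pos,
               effect_allele = "A", other_allele = "G", eaf = maf,
               beta = z * se, se = se, pvalue = p_from_z(z),
               n = config@nExposure, stringsAsFactors = FALSE)
  })

  list(ld = LDReference(ld_tab, signed = TRUE, window_bp = 1e7,
                        positions = rec[, c("variant_id", "chromosome",
                                            "position")]),
       sumstats = SummaryStats("ld_panel", "continuous", rec),
       blocks = data.frame(variant_id = ids, block = block,
                           lead = within == 1L, stringsAsFactors = FALSE))
}

#' Simulate a screen-shaped exposure panel with known truth
#'
#' Generates `n_exposures` exposure GWAS sharing one outcome GWAS;
#' `n_causal` of them receive a latent causal effect drawn from the
#' effect band seen in metabolome screens (|beta| in `beta_range`, signs
#' mixed) and the rest are null. Each exposure contributes
#' `n_candidates` candidate SNPs so that the post-ladder instrument count
#' lands in the 5-9 range such screens report.
#'
#' @param config a [SimulationConfig-class] object (sample sizes,
#'   stressors and seed; `true_beta` is overridden per exposure).
#' @param n_exposures panel size (default 40).
#' @param n_causal number of causal exposures (default 4).
#' @param beta_range absolute causal-effect band (default c(0.2, 0.7)).
#' @param n_candidates candidate SNPs per exposure (default 25).
#' @return list with `exposures` (list of [SummaryStats-class]), `outcome`
#'   ([SummaryStats-class]), `ld` ([LDReference-class]) and `truth`
#'   (data.frame exposure_id, true_beta, causal).
#' @export
simulateScreenPanel <- function(config, n_exposures = 40L, n_causal = 4L,
                                beta_range = c(0.2, 0.7),
                                n_candidates = 25L) {
  stopifnot(is(config, "SimulationConfig"), n_causal <= n_exposures)
  ids <- sprintf("met%03d", seq_len(n_exposures))
  betas <- withr::with_seed(derive_seed(config@seed, "panel_truth"), {
    b <- numeric(n_exposures)
    causal <- sample.int(n_exposures, n_causal)
    b[causal] <- sample(c(-1, 1), n_causal, replace = TRUE) *
      stats::runif(n_causal, beta_range[1], beta_range[2])
    b
  })

  exposures <- vector("list", n_exposures)
  outcome_recs <- vector("list", n_exposures)
  ld_tabs <- vector("list", n_exposures)
  pos_tabs <- vector("list", n_exposures)
  for (k in seq_len(n_exposures)) {
    cfg_k <- config
    cfg_k@trueBeta <- betas[k]
    cfg_k@nSnps <- as.integer(n_candidates)
    cfg_k@seed <- derive_seed(config@seed, ids[k])
    sim <- simulatePair(cfg_k, exposure_id = ids[k], outcome_id = "outcome")
    exposures[[k]] <- sim$exposure
    outcome_recs[[k]] <- records(sim$outcome)
    ld_tabs[[k]] <- sim$ld@table
    pos_tabs[[k]] <- sim$ld@positions
  }
  outcome <- SummaryStats("outcome", "binary", do.call(rbind, outcome_recs))
  ld <- LDReference(do.call(rbind, ld_tabs), signed = TRUE, window_bp = 1e7,
                    positions = do.call(rbind, pos_tabs))
  list(exposures = exposures, outcome = outcome, ld = ld,
       truth = data.frame(exposure_id = ids, true_beta = betas,
                          causal = betas != 0, stringsAsFactors = FALSE))
}

#' Write a simulated dataset to disk
#'
#' Emits exposure/outcome summary statistics and the LD pair table in the
#' exact formats [readSumstats()] and [readLDTable()] read, plus
#' `truth.tsv`.
#'
#' @param sim output of [simulatePair()] or [simulateScreenPanel()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$exposures)) {
    for (e in sim$exposures)
      writeSumstats(e, file.path(dir, paste0(traitId(e), ".tsv")))
  } else {
    writeSumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  }
  writeSumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  writeLDTable(sim$ld, file.path(dir, "ld.tsv"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     na = "NA", quote = FALSE)
  invisible(dir)
}
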