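#' @import methods
NULL

SUMSTAT_COLUMNS <- c("variant_id", "chromosome", "position", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pvalue", "n")

empty_records <- function() {
  data.frame(variant_id = character(), chromosome = character(),
             position = numeric(), effect_allele = character(),
             other_allele = character(), eaf = numeric(), beta = numeric(),
             se = numeric(), pvalue = numeric(), n = numeric(),
             stringsAsFactors = FALSE)
}

#' GWAS summary statistics for one trait
#'
#' Container for per-variant association records of a single exposure or
#' outcome GWAS. Each record carries the variant identifier, coordinates,
#' effect/other allele (single nucleotides, uppercase), effect-allele
#' frequency, the per-allele effect size (log-odds for binary traits, SD
#' units for continuous traits), its standard error, p-value and sample
#' size. Validity enforces unique variant identifiers, positive standard
#' errors, p-values in (0, 1] and frequencies in (0, 1).
#'
#' @slot traitId character, trait identifier.
#' @slot traitType `"continuous"` or `"binary"`.
#' @slot records data.frame with one row per variant.
#' @export
setClass("SummaryStats",
         representation(traitId = "character", traitType = "character",
                        records = "data.frame"))

setValidity("SummaryStats", function(object) {
  rec <- object@records
  msgs <- character()
  if (length(object@traitId) != 1L) msgs <- c(msgs, "traitId must be length 1")
  if (!object@traitType %in% c("continuous", "binary"))
    msgs <- c(msgs, "traitType must be 'continuous' or 'binary'")
  if (!all(SUMSTAT_COLUMNS %in% names(rec)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(SUMSTAT_COLUMNS, collapse = ", ")))
  else {
    if (anyDuplicated(rec$variant_id))
      msgs <- c(msgs, "variant_id must be unique within a trait")
    if (nrow(rec) > 0) {
      if (any(rec$se <= 0 | is.na(rec$se))) msgs <- c(msgs, "all se must be > 0")
      if (any(is.na(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1))
        msgs <- c(msgs, "all pvalue must be in (0, 1]")
      eaf <- rec$eaf[!is.na(rec$eaf)]
      if (any(eaf <= 0 | eaf >= 1)) msgs <- c(msgs, "eaf must be in (0, 1)")
      if (any(rec$effect_allele == rec$other_allele))
        msgs <- c(msgs, "effect_allele must differ from other_allele")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SummaryStats object
#'
#' @param trait_id character trait identifier.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param records data.frame of per-variant records; missing optional
#'   columns (`chromosome`, `position`, `eaf`, `n`) are filled with `NA`,
#'   and a missing `pvalue` column is derived from the two-sided normal
#'   test of `beta / se`.
#' @return A [SummaryStats-class] object.
#' @export
SummaryStats <- function(trait_id, trait_type = c("continuous", "binary"),
                         records) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("chromosome")) if (is.null(records[[col]]))
    records[[col]] <- NA_character_
  for (col in c("position", "eaf", "n")) if (is.null(records[[col]]))
    records[[col]] <- NA_real_
  if (is.null(records$pvalue))
    records$pvalue <- p_from_z(records$beta / records$se)
  records <- records[, SUMSTAT_COLUMNS, drop = FALSE]
  records$chromosome <- as.character(records$chromosome)
  rownames(records) <- NULL
  new("SummaryStats", traitId = trait_id, traitType = trait_type,
      records = records)
}

#' Linkage-disequilibrium reference
#'
#' Signed (or unsigned, see `signed`) pairwise correlations between
#' variants. Pairs absent from the table are treated as r = 0; the
#' self-correlation is always 1. The stored window (base pairs) documents
#' the panel's range; distance handling itself uses the variant positions
#' carried by the summary statistics being clumped.
#'
#' @slot table data.frame with columns `id_a`, `id_b`, `r`.
#' @slot entries named numeric lookup (canonical pair key -> r).
#' @slot signed logical; `FALSE` when the source reported unsigned r².
#'   Unsigned references cannot support proxy allele alignment.
#' @slot windowBp numeric window in base pairs.
#' @slot positions data.frame (`variant_id`, `chromosome`, `position`),
#'   possibly empty.
#' @export
setClass("LDReference",
         representation(table = "data.frame", entries = "numeric",
                        signed = "logical", windowBp = "numeric",
                        positions = "data.frame"))

setValidity("LDReference", function(object) {
  msgs <- character()
  if (nrow(object@table) > 0 && any(abs(object@table$r) > 1))
    msgs <- c(msgs, "|r| must be <= 1")
  if (length(object@windowBp) != 1L || object@windowBp <= 0)
    msgs <- c(msgs, "windowBp must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

ld_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Construct an LDReference from a pair table
#'
#' @param table data.frame with columns `id_a`, `id_b`, `r` (signed).
#' @param signed logical, whether `r` carries sign information.
#' @param window_bp LD window in base pairs (default 1e7, i.e. 10,000 kb).
#' @param positions optional data.frame (`variant_id`, `chromosome`,
#'   `position`).
#' @return An [LDReference-class] object with symmetric closure applied.
#' @export
LDReference <- function(table = data.frame(id_a = character(),
                                           id_b = character(), r = numeric()),
                        signed = TRUE, window_bp = 1e7,
                        positions = data.frame(variant_id = character(),
                                               chromosome = character(),
                                               position = numeric())) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (nrow(table) > 0 && any(abs(table$r) > 1))
    stop("LD table contains |r| > 1", call. = FALSE)
  table <- table[table$id_a != table$id_b, , drop = FALSE]
  entries <- stats::setNames(table$r, ld_key(table$id_a, table$id_b))
  entries <- entries[!duplicated(names(entries))]
  new("LDReference", table = table, entries = entries, signed = signed,
      windowBp = window_bp, positions = as.data.frame(positions))
}

#' Selected genetic instruments for one exposure
#'
#' @slot exposureId character.
#' @slot variants data.frame of exposure association records (one per
#'   retained instrument).
#' @slot thresholdUsed numeric, the p-value ladder rung that yielded the set.
#' @slot proxiesUsed named character (original id -> proxy id), filled during
#'   harmonisation.
#' @slot clumpR2 numeric r-squared clumping threshold.
#' @slot clumpWindowBp numeric clumping window in base pairs.
#' @export
setClass("InstrumentSet",
         representation(exposureId = "character", variants = "data.frame",
                        thresholdUsed = "numeric", proxiesUsed = "character",
                        clumpR2 = "numeric", clumpWindowBp = "numeric"))

#' Rejection of an exposure at instrument selection
#'
#' Returned by [selectInstruments()] when no ladder rung yields the minimum
#' number of independent instruments.
#'
#' @slot exposureId character.
#' @slot bestCount integer, the largest post-clump instrument count achieved.
#' @slot thresholds numeric, the ladder that was tried.
#' @export
setClass("InstrumentRejection",
         representation(exposureId = "character", bestCount = "integer",
                        thresholds = "numeric"))

PAIR_COLUMNS <- c("variant_id", "gamma", "se_gamma", "p_gamma",
                  "Gamma", "se_Gamma", "p_Gamma", "eaf", "flags")

empty_pairs <- function() {
  data.frame(variant_id = character(), gamma = numeric(),
             se_gamma = numeric(), p_gamma = numeric(), Gamma = numeric(),
             se_Gamma = numeric(), p_Gamma = numeric(), eaf = numeric(),
             flags = character(), stringsAsFactors = FALSE)
}

#' Harmonised exposure-outcome variant pairs
#'
#' Analysis-ready pairs with exposure (`gamma`) and outcome (`Gamma`)
#' effects aligned to a shared effect allele, plus the fully enumerated
#' exclusions (variant id -> reason).
#'
#' @slot exposureId,outcomeId character.
#' @slot pairs data.frame with columns `variant_id`, `gamma`, `se_gamma`,
#'   `p_gamma`, `Gamma`, `se_Gamma`, `p_Gamma`, `eaf`, `flags` (semicolon
#'   separated provenance flags).
#' @slot exclusions named character; reasons are one of
#'   `palindromic_ambiguous`, `allele_mismatch`,
#'   `missing_in_outcome_no_proxy`.
#' @export
setClass("HarmonisedSet",
         representation(exposureId = "character", outcomeId = "character",
                        pairs = "data.frame", exclusions = "character"))

setValidity("HarmonisedSet", function(object) {
  msgs <- character()
  p <- object@pairs
  if (!all(PAIR_COLUMNS %in% names(p)))
    msgs <- c(msgs, paste("pairs must have columns:",
                          paste(PAIR_COLUMNS, collapse = ", ")))
  else if (nrow(p) > 0) {
    if (anyDuplicated(p$variant_id)) msgs <- c(msgs, "variant_id must be unique")
    if (any(p$se_gamma <= 0) || any(p$se_Gamma <= 0))
      msgs <- c(msgs, "standard errors must be > 0")
  }
  bad <- setdiff(unique(object@exclusions),
                 c("palindromic_ambiguous", "allele_mismatch",
                   "missing_in_outcome_no_proxy"))
  if (length(bad))
    msgs <- c(msgs, paste("unknown exclusion reason:", paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

HarmonisedSet <- function(exposure_id, outcome_id, pairs,
                          exclusions = character()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) pairs <- empty_pairs()
  rownames(pairs) <- NULL
  new("HarmonisedSet", exposureId = exposure_id, outcomeId = outcome_id,
      pairs = pairs[, PAIR_COLUMNS, drop = FALSE], exclusions = exclusions)
}

#' Result of a single causal-effect estimator
#'
#' @slot method one of `wald`, `ivw_fe`, `ivw_mre`, `egger`,
#'   `weighted_median`, `weighted_mode`.
#' @slot beta,se,pvalue numeric estimate, standard error and two-sided
#'   p-value (`NA` when the method is unavailable for the pair set).
#' @slot nSnp integer number of instruments used.
#' @slot extras list of method-specific quantities (Egger intercept and its
#'   test, overdispersion scale `phi`, bootstrap settings, ...).
#' @export
setClass("MRResult",
         representation(method = "character", beta = "numeric", se = "numeric",
                        pvalue = "numeric", nSnp = "integer", extras = "list"))

MRResult <- function(method, beta, se, pvalue, n_snp, extras = list()) {
  new("MRResult", method = method, beta = as.numeric(beta),
      se = as.numeric(se), pvalue = as.numeric(pvalue),
      nSnp = as.integer(n_snp), extras = extras)
}

mr_unavailable <- function(method, n_snp, reason) {
  MRResult(method, NA_real_, NA_real_, NA_real_, n_snp,
           extras = list(unavailable = TRUE, reason = reason))
}

#' Per-exposure result battery
#'
#' The full per-exposure output of the screen: the five-estimator battery,
#' sensitivity diagnostics, instrument accounting and provenance. Mirrors
#' the per-metabolite result table of a metabolome-wide MR screen.
#'
#' @slot exposureId,outcomeId character.
#' @slot status `"ok"` or `"not_analysable"`.
#' @slot reason character, why the exposure was not analysable (or "").
#' @slot results named list of [MRResult-class].
#' @slot diagnostics list (Cochran's Q with df and p, I2 of the
#'   instrument-exposure association, mean F, radial outliers and iteration
#'   count, leave-one-out table and its non-significant count, Egger
#'   intercept p).
#' @slot nSnpInitial,nSnpFinal,nPleiotropyFiltered integers.
#' @slot removed list of removal records (exclusions, pleiotropy filter,
#'   radial outliers).
#' @slot provenance list (threshold used, clump settings, proxies, seeds).
#' @export
setClass("MRBattery",
         representation(exposureId = "character", outcomeId = "character",
                        status = "character", reason = "character",
                        results = "list", diagnostics = "list",
                        nSnpInitial = "integer", nSnpFinal = "integer",
                        nPleiotropyFiltered = "integer", removed = "list",
                        provenance = "list"))

setValidity("MRBattery", function(object) {
  if (object@status == "ok") {
    n_excl <- length(object@removed$exclusions %||% character())
    n_radial <- length(object@removed$radial %||% character())
    expect <- object@nSnpInitial - n_excl - object@nPleiotropyFiltered - n_radial
    if (object@nSnpFinal != expect)
      return(sprintf("instrument accounting broken: final %d != initial %d - %d - %d - %d",
                     object@nSnpFinal, object@nSnpInitial, n_excl,
                     object@nPleiotropyFiltered, n_radial))
  }
  TRUE
})

#' Screen-level result
#'
#' @slot batteries named list of [MRBattery-class], ordered by exposure id.
#' @slot table data.frame with one row per exposure (primary estimate,
#'   raw and adjusted p, significance call).
#' @slot correction `"bonferroni"` or `"benjamini_hochberg"`.
#' @slot alphaFamily numeric family-wise alpha.
#' @slot threshold numeric per-test significance cutoff (Bonferroni).
#' @slot significantIds character.
#' @slot lambdaMedian numeric q-q inflation factor of the primary p-values.
#' @slot qq data.frame of (expected, observed) -log10 p quantile pairs.
#' @export
setClass("ScreenResult",
         representation(batteries = "list", table = "data.frame",
                        correction = "character", alphaFamily = "numeric",
                        threshold = "numeric", significantIds = "character",
                        lambdaMedian = "numeric", qq = "data.frame"))

#' Generative model settings for two-sample summary statistics
#'
#' Parameters of the linear instrumental-variable generative model: per-SNP
#' instrument effects gamma_j (trait-increasing allele coding), optional
#' direct (pleiotropic) effects alpha_j with configurable mean, spread,
#' prevalence and correlation with instrument strength, a causal effect
#' beta on the log-odds scale of a binary outcome, GWAS sample sizes, LD
#' block structure and harmonisation stressor fractions.
#'
#' @slot nSnps integer number of candidate instruments.
#' @slot trueBeta causal effect (log-odds of outcome per SD exposure).
#' @slot mafRange numeric length 2, allele-frequency range in (0, 0.5].
#' @slot gammaSd spread of true instrument effects (SD units).
#' @slot nExposure exposure GWAS sample size.
#' @slot nOutcomeCases,nOutcomeControls outcome case-control sizes.
#' @slot pleiotropyMean,pleiotropySd moments of direct effects.
#' @slot propInvalid fraction of SNPs with nonzero direct effects.
#' @slot insideCorrelation correlation between direct effects and
#'   instrument strength (0 = InSIDE holds).
#' @slot ldBlockSize,ldRho LD block structure (AR-1 within block).
#' @slot palindromicFraction,strandFlipFraction,swapFraction,missingOutcomeFraction
#'   harmonisation stressor fractions.
#' @slot proxyR absolute LD correlation of planted proxies.
#' @slot seed integer master seed; all randomness flows from it through
#'   named substreams.
#' @export
setClass("SimulationConfig",
         representation(nSnps = "integer", trueBeta = "numeric",
                        mafRange = "numeric", gammaSd = "numeric",
                        nExposure = "numeric", nOutcomeCases = "numeric",
                        nOutcomeControls = "numeric",
                        pleiotropyMean = "numeric", pleiotropySd = "numeric",
                        propInvalid = "numeric", insideCorrelation = "numeric",
                        ldBlockSize = "integer", ldRho = "numeric",
                        palindromicFraction = "numeric",
                        strandFlipFraction = "numeric",
                        swapFraction = "numeric",
                        missingOutcomeFraction = "numeric",
                        proxyR = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@propInvalid < 0 || object@propInvalid > 1)
    msgs <- c(msgs, "propInvalid must be in [0, 1]")
  if (abs(object@insideCorrelation) >= 1)
    msgs <- c(msgs, "|insideCorrelation| must be < 1")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must lie within (0, 0.5]")
  if (object@ldBlockSize < 1L) msgs <- c(msgs, "ldBlockSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})
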