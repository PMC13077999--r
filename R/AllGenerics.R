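# Generics, accessors and show methods.

#' Trait identifier of a summary-statistics set
#' @param x a [SummaryStats-class] object.
#' @return character scalar.
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname traitId
#' @export
setMethod("traitId", "SummaryStats", function(x) x@traitId)

#' Trait type of a summary-statistics set
#' @param x a [SummaryStats-class] object.
#' @return `"continuous"` or `"binary"`.
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname traitType
#' @export
setMethod("traitType", "SummaryStats", function(x) x@traitType)

#' Per-variant records
#' @param x a [SummaryStats-class] or [InstrumentSet-class] object.
#' @return data.frame of per-variant association records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "SummaryStats", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "InstrumentSet", function(x) x@variants)

#' Number of variants
#' @param x a [SummaryStats-class], [InstrumentSet-class] or
#'   [HarmonisedSet-class] object.
#' @return integer.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname nVariants
#' @export
setMethod("nVariants", "SummaryStats", function(x) nrow(x@records))

#' @rdname nVariants
#' @export
setMethod("nVariants", "InstrumentSet", function(x) nrow(x@variants))

#' @rdname nVariants
#' @export
setMethod("nVariants", "HarmonisedSet", function(x) nrow(x@pairs))

#' Harmonised variant pairs
#' @param x a [HarmonisedSet-class] object.
#' @return data.frame of aligned exposure/outcome effects.
#' @export
setGeneric("pairs_df", function(x) standardGeneric("pairs_df"))

#' @rdname pairs_df
#' @export
setMethod("pairs_df", "HarmonisedSet", function(x) x@pairs)

#' Harmonisation exclusions
#' @param x a [HarmonisedSet-class] object.
#' @return named character vector (variant id -> reason).
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname exclusions
#' @export
setMethod("exclusions", "HarmonisedSet", function(x) x@exclusions)

#' Look up a pairwise LD correlation
#'
#' Self-pairs return 1; pairs absent from the table return 0 (variants on
#' different chromosomes or beyond the panel window are never stored).
#'
#' @param x an [LDReference-class] object.
#' @param a,b character vectors of variant ids (recycled to equal length).
#' @return numeric vector of signed correlations.
#' @export
setGeneric("ldLookup", function(x, a, b) standardGeneric("ldLookup"))

#' @rdname ldLookup
#' @export
setMethod("ldLookup", "LDReference", function(x, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  r <- unname(x@entries[ld_key(a, b)])
  r[is.na(r)] <- 0
  r[a == b] <- 1
  r
})

#' Batteries of a screen result
#' @param x a [ScreenResult-class] object.
#' @return named list of [MRBattery-class] objects.
#' @export
setGeneric("batteries", function(x) standardGeneric("batteries"))

#' @rdname batteries
#' @export
setMethod("batteries", "ScreenResult", function(x) x@batteries)

#' Significant exposures of a screen
#' @param x a [ScreenResult-class] object.
#' @return character vector of exposure ids.
#' @export
setGeneric("significantIds", function(x) standardGeneric("significantIds"))

#' @rdname significantIds
#' @export
setMethod("significantIds", "ScreenResult", function(x) x@significantIds)

#' Extract one estimator result from a battery
#' @param x an [MRBattery-class] object.
#' @param method estimator name (e.g. `"ivw_mre"`).
#' @return an [MRResult-class] or `NULL`.
#' @export
setGeneric("estimate", function(x, method) standardGeneric("estimate"))

#' @rdname estimate
#' @export
setMethod("estimate", "MRBattery", function(x, method) x@results[[method]])

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats '%s' (%s): %d variants\n", object@traitId,
              object@traitType, nrow(object@records)))
})

setMethod("show", "LDReference", function(object) {
  cat(sprintf("LDReference: %d pairs, %s, window %.0f bp\n",
              nrow(object@table),
              if (object@signed) "signed r" else "unsigned r2",
              object@windowBp))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet '%s': %d instruments at p <= %.3g (clump r2 < %g, window %.0f bp)\n",
              object@exposureId, nrow(object@variants), object@thresholdUsed,
              object@clumpR2, object@clumpWindowBp))
})

setMethod("show", "InstrumentRejection", function(object) {
  cat(sprintf("InstrumentRejection '%s': best post-clump count %d across ladder {%s}\n",
              object@exposureId, object@bestCount,
              paste(signif(object@thresholds, 2), collapse = ", ")))
})

setMethod("show", "HarmonisedSet", function(object) {
  cat(sprintf("HarmonisedSet %s -> %s: %d pairs, %d exclusions\n",
              object@exposureId, object@outcomeId, nrow(object@pairs),
              length(object@exclusions)))
})

setMethod("show", "MRResult", function(object) {
  if (isTRUE(object@extras$unavailable)) {
    cat(sprintf("MRResult [%s]: unavailable (%s)\n", object@method,
                object@extras$reason))
  } else {
    cat(sprintf("MRResult [%s]: beta = %.4g (se %.4g), p = %.3g, %d SNPs\n",
                object@method, object@beta, object@se, object@pvalue,
                object@nSnp))
  }
})

setMethod("show", "MRBattery", function(object) {
  cat(sprintf("MRBattery %s -> %s [%s]\n", object@exposureId,
              object@outcomeId, object@status))
  if (object@status != "ok") {
    cat("  reason:", object@reason, "\n")
    return(invisible(NULL))
  }
  cat(sprintf("  SNPs: %d selected, %d final (%d excluded, %d p-filtered, %d radial outliers)\n",
              object@nSnpInitial, object@nSnpFinal,
              length(object@removed$exclusions %||% character()),
              object@nPleiotropyFiltered,
              length(object@removed$radial %||% character())))
  for (res in object@results) {
    if (isTRUE(res@extras$unavailable)) next
    cat(sprintf("  %-15s beta % .4f  se %.4f  p %.3g\n", res@method,
                res@beta, res@se, res@pvalue))
  }
  d <- object@diagnostics
  if (!is.null(d$mean_f))
    cat(sprintf("  mean F %.1f | Q %.2f (p %.3g) | I2_GX %.3f | LOO>0.05: %d\n",
                d$mean_f, d$q %||% NA, d$q_p %||% NA, d$i2_gx %||% NA,
                d$n_loo_nonsig %||% NA))
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult: %d exposures, correction %s (alpha %.3g)\n",
              nrow(object@table), object@correction, object@alphaFamily))
  cat(sprintf("  threshold %.3g | lambda_median %.3f | %d significant: %s\n",
              object@threshold, object@lambdaMedian,
              length(object@significantIds),
              paste(object@significantIds, collapse = ", ")))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: J = %d, beta = %g, gamma sd %g, n_exp %g, cases/controls %g/%g, seed %d\n",
              object@nSnps, object@trueBeta, object@gammaSd, object@nExposure,
              object@nOutcomeCases, object@nOutcomeControls, object@seed))
})
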