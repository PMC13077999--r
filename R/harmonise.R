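# Allele harmonisation: align exposure and outcome effects to a shared
# effect allele, resolving allele order, strand flips and palindromes.

#' Harmonise one exposure/outcome record pair
#'
#' Aligns the outcome effect to the exposure's effect allele. Matching
#' allele order passes through unchanged; swapped alleles flip the outcome
#' sign and frequency; complementary (strand-flipped) non-palindromic
#' alleles are complemented first. Palindromic variants (A/T or C/G) carry
#' no strand information in their letters, so they are aligned by matching
#' the minor allele across the two traits; they are excluded as ambiguous
#' when the minor-allele frequency exceeds `maf_limit` on either trait or
#' when either frequency is missing. Any other allele configuration is an
#' `allele_mismatch` exclusion.
#'
#' @param exp,out one-row data.frames (standard summary-statistic columns)
#'   for the same variant.
#' @param maf_limit palindrome ambiguity bound on the minor-allele
#'   frequency (default 0.42).
#' @return list with either `pair` (one-row harmonised data.frame) or
#'   `reason` (typed exclusion).
#' @export
harmonisePair <- function(exp, out, maf_limit = 0.42) {
  ea_x <- exp$effect_allele; oa_x <- exp$other_allele
  ea_y <- out$effect_allele; oa_y <- out$other_allele
  G <- out$beta
  eaf_y <- out$eaf
  flags <- character()

  if (is_palindromic(ea_x, oa_x)) {
    same_set <- setequal(c(ea_y, oa_y), c(ea_x, oa_x))
    if (!same_set) return(list(reason = "allele_mismatch"))
    eaf_x <- exp$eaf
    if (is.na(eaf_x) || is.na(eaf_y))
      return(list(reason = "palindromic_ambiguous"))
    if (min(eaf_x, 1 - eaf_x) > maf_limit ||
        min(eaf_y, 1 - eaf_y) > maf_limit)
      return(list(reason = "palindromic_ambiguous"))
    # frequencies are strand-invariant: align minor allele to minor allele
    if ((eaf_x < 0.5) != (eaf_y < 0.5)) {
      G <- -G
      eaf_y <- 1 - eaf_y
      flags <- c(flags, "flipped")
    }
    flags <- c(flags, "palindromic_kept")
  } else {
    flip_freq <- function(f) if (is.na(f)) NA_real_ else 1 - f
    if (identical(c(ea_y, oa_y), c(ea_x, oa_x))) {
      # aligned as stated
    } else if (identical(c(ea_y, oa_y), c(oa_x, ea_x))) {
      G <- -G; eaf_y <- flip_freq(eaf_y); flags <- c(flags, "flipped")
    } else {
      cea <- complement_alleles(ea_y); coa <- complement_alleles(oa_y)
      if (identical(c(cea, coa), c(ea_x, oa_x))) {
        # pure strand difference, numerically unchanged
      } else if (identical(c(cea, coa), c(oa_x, ea_x))) {
        G <- -G; eaf_y <- flip_freq(eaf_y); flags <- c(flags, "flipped")
      } else {
        return(list(reason = "allele_mismatch"))
      }
    }
  }

  eaf <- if (!is.na(exp$eaf)) exp$eaf else eaf_y
  list(pair = data.frame(
    variant_id = exp$variant_id, gamma = exp$beta, se_gamma = exp$se,
    p_gamma = exp$pvalue, Gamma = G, se_Gamma = out$se,
    p_Gamma = out$pvalue, eaf = eaf,
    flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE))
}

#' Harmonise an instrument set against an outcome GWAS
#'
#' For each instrument: a direct match in the outcome is harmonised with
#' [harmonisePair()]; an instrument missing from the outcome is replaced
#' by its best LD proxy (r-squared above `proxy_r2`), taking the proxy's
#' outcome effect multiplied by the sign of the LD correlation; with no
#' qualifying proxy the instrument is excluded. Exclusions are fully
#' enumerated so that instruments = pairs + exclusions.
#'
#' @param instruments an [InstrumentSet-class] object.
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param ld an [LDReference-class] object.
#' @param maf_limit palindrome ambiguity bound, see [harmonisePair()].
#' @param proxy_r2 minimum proxy r-squared (strict, default 0.9).
#' @return A [HarmonisedSet-class] object. The instrument-to-proxy mapping
#'   is recorded in the `proxy` flags of the affected pairs.
#' @export
harmoniseSet <- function(instruments, exposure, outcome, ld,
                         maf_limit = 0.42, proxy_r2 = 0.9) {
  inst <- records(instruments)
  out_rec <- records(outcome)
  out_idx <- match(inst$variant_id, out_rec$variant_id)
  pair_rows <- vector("list", nrow(inst))
  exclusions <- character()
  for (i in seq_len(nrow(inst))) {
    exp_i <- inst[i, , drop = FALSE]
    if (!is.na(out_idx[i])) {
      h <- harmonisePair(exp_i, out_rec[out_idx[i], , drop = FALSE], maf_limit)
      if (is.null(h$pair)) {
        exclusions[exp_i$variant_id] <- h$reason
      } else {
        pair_rows[[i]] <- h$pair
      }
    } else {
      px <- findProxy(exp_i$variant_id, outcome, ld, r2_min = proxy_r2)
      if (is.null(px)) {
        exclusions[exp_i$variant_id] <- "missing_in_outcome_no_proxy"
      } else {
        flags <- c("proxy", if (px$r < 0) "proxy_sign_flipped")
        pair_rows[[i]] <- data.frame(
          variant_id = exp_i$variant_id, gamma = exp_i$beta,
          se_gamma = exp_i$se, p_gamma = exp_i$pvalue,
          Gamma = sign(px$r) * px$record$beta, se_Gamma = px$record$se,
          p_Gamma = px$record$pvalue, eaf = exp_i$eaf,
          flags = paste(c(flags, paste0("proxy_id=", px$record$variant_id)),
                        collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, pair_rows[!vapply(pair_rows, is.null, logical(1))])
  if (is.null(pairs)) pairs <- empty_pairs()
  HarmonisedSet(instruments@exposureId, traitId(outcome), pairs, exclusions)
}

#' Export a harmonised set as TSV for audit
#' @param hset a [HarmonisedSet-class] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeHarmonised <- function(hset, path) {
  data.table::fwrite(pairs_df(hset), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
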