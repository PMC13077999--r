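# Instrument selection: adaptive p-value thresholding over a ladder,
# greedy LD clumping, proxy lookup, instrument strength, and the
# outcome-vs-exposure p-value pleiotropy filter.

#' Greedy LD clumping
#'
#' Reduces a set of candidate variants to a quasi-independent set: the
#' variant with the lowest p-value is retained and all variants with
#' r-squared at or above the threshold within the window around it are
#' discarded; the procedure repeats on the remainder. Ties in p are broken
#' by (chromosome, position, variant id) so the output is invariant to
#' input order. Pairs on different chromosomes, or with unknown LD, are
#' treated as independent (r = 0).
#'
#' @param candidates data.frame of summary-statistic records (needs
#'   `variant_id`, `chromosome`, `position`, `pvalue`).
#' @param ld an [LDReference-class] object.
#' @param r2_threshold clumping r-squared cutoff in (0, 1] (default 0.001,
#'   the stringent screen setting).
#' @param window_bp window in base pairs (default 1e7 = 10,000 kb).
#' @return The retained subset of `candidates`, ordered by ascending p.
#' @export
clumpVariants <- function(candidates, ld, r2_threshold = 0.001,
                          window_bp = 1e7) {
  assert_scalar_number(r2_threshold, "r2_threshold", lower = 1e-12, upper = 1)
  assert_scalar_number(window_bp, "window_bp", lower = 1)
  if (nrow(candidates) == 0) return(candidates[0, , drop = FALSE])
  ord <- order(candidates$pvalue, candidates$chromosome,
               candidates$position, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  pos <- cand$position
  chr <- cand$chromosome
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    idx <- which(alive)
    if (!length(idx)) break
    same_chr <- !is.na(chr[idx]) & !is.na(chr[i]) & chr[idx] == chr[i]
    near <- same_chr &
      (is.na(pos[idx]) | is.na(pos[i]) | abs(pos[idx] - pos[i]) <= window_bp)
    if (any(near)) {
      j <- idx[near]
      r <- ldLookup(ld, cand$variant_id[i], cand$variant_id[j])
      alive[j[r^2 >= r2_threshold]] <- FALSE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Certify pairwise independence of a clumped set (asserted on every run).
certify_clump <- function(retained, ld, r2_threshold, window_bp) {
  n <- nrow(retained)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    same_chr <- !is.na(retained$chromosome[j]) &
      retained$chromosome[j] == retained$chromosome[i]
    near <- same_chr & (is.na(retained$position[j]) |
                          abs(retained$position[j] - retained$position[i]) <= window_bp)
    if (any(near)) {
      r <- ldLookup(ld, retained$variant_id[i], retained$variant_id[j][near])
      if (any(r^2 >= r2_threshold))
        stop("clump certification failed: retained pair with r2 >= threshold",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Select instruments over an adaptive p-value ladder
#'
#' Walks a strictly increasing ladder of p-value thresholds (default
#' 5e-8 to 5e-6) and returns the instrument set at the most stringent rung
#' whose post-clump count reaches `min_instruments`. If no rung qualifies,
#' an [InstrumentRejection-class] carrying the best count achieved is
#' returned, and the exposure is reported as not analysable downstream.
#'
#' @param exposure a [SummaryStats-class] object for the exposure.
#' @param ld an [LDReference-class] object.
#' @param ladder strictly increasing p-value thresholds.
#' @param min_instruments minimum post-clump instrument count (default 5).
#' @param r2_threshold,window_bp clumping parameters, see [clumpVariants()].
#' @return An [InstrumentSet-class] or [InstrumentRejection-class].
#' @export
selectInstruments <- function(exposure, ld,
                              ladder = c(5e-8, 1e-7, 5e-7, 1e-6, 5e-6),
                              min_instruments = 5L, r2_threshold = 0.001,
                              window_bp = 1e7) {
  if (is.unsorted(ladder, strictly = TRUE))
    stop("ladder must be strictly increasing", call. = FALSE)
  if (min_instruments < 1L) stop("min_instruments must be >= 1", call. = FALSE)
  rec <- records(exposure)
  best <- 0L
  for (thr in ladder) {
    cand <- rec[rec$pvalue <= thr, , drop = FALSE]
    if (nrow(cand) < min_instruments) {
      best <- max(best, nrow(clumpVariants(cand, ld, r2_threshold, window_bp)))
      next
    }
    retained <- clumpVariants(cand, ld, r2_threshold, window_bp)
    certify_clump(retained, ld, r2_threshold, window_bp)
    best <- max(best, nrow(retained))
    if (nrow(retained) >= min_instruments) {
      return(new("InstrumentSet", exposureId = traitId(exposure),
                 variants = retained, thresholdUsed = thr,
                 proxiesUsed = character(), clumpR2 = r2_threshold,
                 clumpWindowBp = window_bp))
    }
  }
  new("InstrumentRejection", exposureId = traitId(exposure),
      bestCount = as.integer(best), thresholds = ladder)
}

#' Find an LD proxy for an instrument missing from the outcome GWAS
#'
#' Among outcome variants in LD with the missing instrument above
#' `r2_min`, returns the one with the highest r-squared together with the
#' signed correlation (needed to map the proxy's effect allele back to the
#' instrument). Requires a signed LD reference.
#'
#' @param missing_id variant id absent from the outcome set.
#' @param outcome a [SummaryStats-class] object for the outcome.
#' @param ld an [LDReference-class] object (signed dialect).
#' @param r2_min minimum r-squared, strict (default 0.9).
#' @return list with elements `record` (one-row data.frame of the proxy's
#'   outcome association) and `r` (signed correlation), or `NULL` if no
#'   candidate qualifies.
#' @export
findProxy <- function(missing_id, outcome, ld, r2_min = 0.9) {
  if (!ld@signed)
    stop("proxy search requires a signed LD reference; the loaded table is unsigned r2",
         call. = FALSE)
  tab <- ld@table
  hit <- tab$id_a == missing_id | tab$id_b == missing_id
  if (!any(hit)) return(NULL)
  tab <- tab[hit, , drop = FALSE]
  partner <- ifelse(tab$id_a == missing_id, tab$id_b, tab$id_a)
  out_rec <- records(outcome)
  ok <- partner %in% out_rec$variant_id & tab$r^2 > r2_min &
    partner != missing_id
  if (!any(ok)) return(NULL)
  best <- which.max(tab$r[ok]^2)
  id <- partner[ok][best]
  list(record = out_rec[out_rec$variant_id == id, , drop = FALSE],
       r = tab$r[ok][best])
}

#' Per-SNP F-statistics and instrument strength
#'
#' F_j = (beta_j / se_j)^2, the squared z-score, a small-effect
#' approximation of the first-stage F. A mean F above 10 indicates
#' acceptable instrument strength (bias below 10 percent).
#'
#' @param x an [InstrumentSet-class], [SummaryStats-class] or data.frame
#'   with `beta` and `se` columns.
#' @return list with `f` (named per-SNP values), `mean_f`, and
#'   `weak` (TRUE when mean F <= 10).
#' @export
fStatistics <- function(x) {
  rec <- if (is.data.frame(x)) x else records(x)
  f <- (rec$beta / rec$se)^2
  names(f) <- rec$variant_id
  list(f = f, mean_f = mean(f), weak = mean(f) <= 10)
}

#' Outcome-vs-exposure p-value pleiotropy filter
#'
#' Removes harmonised pairs whose outcome association is stronger than the
#' exposure association (p_outcome strictly below p_exposure), the screen's
#' guard against instruments acting on the outcome through another
#' pathway. Order is otherwise preserved.
#'
#' @param hset a [HarmonisedSet-class] object.
#' @return list with `set` (filtered [HarmonisedSet-class]) and `removed`
#'   (character vector of removed variant ids).
#' @export
pleiotropyFilter <- function(hset) {
  p <- pairs_df(hset)
  drop <- p$p_Gamma < p$p_gamma
  removed <- p$variant_id[drop]
  list(set = HarmonisedSet(hset@exposureId, hset@outcomeId,
                           p[!drop, , drop = FALSE], hset@exclusions),
       removed = removed)
}
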