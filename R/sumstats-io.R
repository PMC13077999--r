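# Reading, validation and writing of GWAS summary statistics, LD pair
# tables and result batteries. All files are delimited text; gzip input is
# handled transparently by data.table.

#' Default column mapping (GWAS-SSF-like names)
#'
#' Maps the package's standard field names to the column names expected in
#' input files. Override individual entries via the `column_map` argument
#' of [readSumstats()].
#' @return named character vector.
#' @export
defaultColumnMap <- function() {
  c(variant_id = "rsid", chromosome = "chromosome",
    position = "base_pair_location", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "effect_allele_frequency",
    beta = "beta", se = "standard_error", pvalue = "p_value", n = "n")
}

MANDATORY_FIELDS <- c("variant_id", "effect_allele", "other_allele",
                      "beta", "se")

#' Read GWAS summary statistics
#'
#' Reads a delimited text file (optionally gzipped) of per-variant
#' associations, maps columns to the standard field set, uppercases
#' alleles, and validates every record. Records violating the data model
#' (non-SNP or identical alleles, `se <= 0`, p outside (0, 1], frequency
#' outside (0, 1)) are dropped and counted in the read report attached as
#' `attr(x, "read_report")`. Records whose p-value disagrees with
#' `|beta| / se` by more than 10 percent on the z scale are kept but
#' counted as warnings (published GWAS round their p-values).
#'
#' @param path file path.
#' @param column_map named character vector mapping standard fields to file
#'   column names; merged over [defaultColumnMap()].
#' @param trait_type `"continuous"` or `"binary"`.
#' @param trait_id trait identifier (defaults to the file base name).
#' @return A [SummaryStats-class] object with a `read_report` attribute
#'   (list: `n_read`, `n_kept`, `n_dropped`, `n_pz_warnings`).
#' @export
readSumstats <- function(path, column_map = NULL,
                         trait_type = c("continuous", "binary"),
                         trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  map <- defaultColumnMap()
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0) stop("empty summary-statistics file: ", path, call. = FALSE)
  missing <- MANDATORY_FIELDS[!map[MANDATORY_FIELDS] %in% names(dt)]
  if (length(missing))
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (expected '%s')", missing, map[missing]),
               collapse = ", "), call. = FALSE)

  get_col <- function(field, default = NA_real_) {
    if (map[[field]] %in% names(dt)) dt[[map[[field]]]] else
      rep(default, nrow(dt))
  }
  rec <- data.frame(
    variant_id = as.character(get_col("variant_id")),
    chromosome = as.character(get_col("chromosome", NA_character_)),
    position = suppressWarnings(as.numeric(get_col("position"))),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE)
  if (all(is.na(rec$pvalue))) rec$pvalue <- p_from_z(rec$beta / rec$se)

  n_read <- nrow(rec)
  nucl <- c("A", "C", "G", "T")
  valid <- !is.na(rec$variant_id) & !duplicated(rec$variant_id) &
    rec$effect_allele %in% nucl & rec$other_allele %in% nucl &
    rec$effect_allele != rec$other_allele &
    !is.na(rec$beta) & !is.na(rec$se) & rec$se > 0 &
    !is.na(rec$pvalue) & rec$pvalue > 0 & rec$pvalue <= 1 &
    (is.na(rec$eaf) | (rec$eaf > 0 & rec$eaf < 1))
  kept <- rec[valid, , drop = FALSE]

  # p/z consistency: warn, never drop or mutate
  z_obs <- abs(kept$beta) / kept$se
  z_p <- stats::qnorm(pmin(kept$pvalue, 1) / 2, lower.tail = FALSE)
  comparable <- is.finite(z_obs) & is.finite(z_p) & z_p > 0
  n_warn <- sum(comparable & abs(z_obs - z_p) / pmax(z_p, 1e-12) > 0.1)
  if (n_warn > 0)
    warning(sprintf("%d record(s) with p-value inconsistent with beta/se beyond 10%% on the z scale (kept)",
                    n_warn), call. = FALSE)

  out <- SummaryStats(trait_id %||% sub("\\.(tsv|txt|csv)(\\.gz)?$", "",
                                        basename(path)),
                      trait_type, kept)
  attr(out, "read_report") <- list(n_read = n_read, n_kept = nrow(kept),
                                   n_dropped = n_read - nrow(kept),
                                   n_pz_warnings = n_warn)
  out
}

#' Read an LD pair table
#'
#' Reads a delimited table of pairwise LD between variants. The first three
#' columns (or columns named `id_a`, `id_b` and `r`/`r2`) give the two
#' variant ids and their correlation. Signed r is the native dialect;
#' unsigned r-squared input is accepted (`dialect = "r2"`, stored as the
#' positive square root) but forbids proxy allele alignment downstream.
#'
#' @param path file path.
#' @param dialect `"r"` (signed correlation) or `"r2"` (unsigned).
#' @param window_bp panel window in base pairs (default 1e7 = 10,000 kb).
#' @return An [LDReference-class] object.
#' @export
readLDTable <- function(path, dialect = c("r", "r2"), window_bp = 1e7) {
  dialect <- match.arg(dialect)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  nm <- names(dt)
  ia <- if ("id_a" %in% nm) "id_a" else nm[1]
  ib <- if ("id_b" %in% nm) "id_b" else nm[2]
  rc <- if (dialect == "r" && "r" %in% nm) "r" else
    if (dialect == "r2" && "r2" %in% nm) "r2" else nm[3]
  r <- as.numeric(dt[[rc]])
  if (dialect == "r2") {
    if (any(r < 0 | r > 1)) stop("r2 values must lie in [0, 1]", call. = FALSE)
    r <- sqrt(r)
  }
  if (any(abs(r) > 1)) stop("LD table contains |r| > 1", call. = FALSE)
  LDReference(data.frame(id_a = as.character(dt[[ia]]),
                         id_b = as.character(dt[[ib]]), r = r,
                         stringsAsFactors = FALSE),
              signed = dialect == "r", window_bp = window_bp)
}

#' Write an LD reference back to a pair table
#' @param ld an [LDReference-class] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeLDTable <- function(ld, path) {
  data.table::fwrite(ld@table, path, sep = "\t")
  invisible(path)
}

#' Write a summary-statistics set
#'
#' Writes the records as tab-delimited text with GWAS-SSF-like column
#' names, the format [readSumstats()] reads back losslessly.
#'
#' @param x a [SummaryStats-class] object.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSumstats <- function(x, path) {
  rec <- records(x)
  names(rec) <- defaultColumnMap()[names(rec)]
  data.table::fwrite(rec, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

battery_row <- function(b) {
  res_cols <- list()
  for (m in c("wald", "ivw_fe", "ivw_mre", "egger", "weighted_median",
              "weighted_mode")) {
    r <- b@results[[m]]
    res_cols[[paste0(m, "_beta")]] <- if (is.null(r)) NA_real_ else r@beta
    res_cols[[paste0(m, "_se")]] <- if (is.null(r)) NA_real_ else r@se
    res_cols[[paste0(m, "_p")]] <- if (is.null(r)) NA_real_ else r@pvalue
  }
  eg <- b@results[["egger"]]
  d <- b@diagnostics
  data.frame(
    exposure_id = b@exposureId, outcome_id = b@outcomeId, status = b@status,
    reason = b@reason,
    n_snp_initial = b@nSnpInitial, n_snp_final = b@nSnpFinal,
    n_excluded = length(b@removed$exclusions %||% character()),
    n_pleiotropy_filtered = b@nPleiotropyFiltered,
    n_radial_outliers = length(b@removed$radial %||% character()),
    as.data.frame(res_cols),
    egger_intercept = if (!is.null(eg)) eg@extras$intercept %||% NA_real_ else NA_real_,
    egger_intercept_se = if (!is.null(eg)) eg@extras$intercept_se %||% NA_real_ else NA_real_,
    egger_intercept_p = if (!is.null(eg)) eg@extras$intercept_p %||% NA_real_ else NA_real_,
    mean_f = d$mean_f %||% NA_real_,
    cochran_q = d$q %||% NA_real_,
    cochran_q_df = d$q_df %||% NA_real_,
    cochran_q_p = d$q_p %||% NA_real_,
    i2_gx = d$i2_gx %||% NA_real_,
    radial_outlier_ids = paste(b@removed$radial %||% character(),
                               collapse = ","),
    radial_iterations = d$radial_iterations %||% NA_real_,
    n_loo_nonsig = d$n_loo_nonsig %||% NA_real_,
    threshold_used = b@provenance$threshold_used %||% NA_real_,
    stringsAsFactors = FALSE)
}

#' Write result batteries as TSV
#'
#' One row per exposure battery with all estimator and diagnostic columns.
#' Numeric fields survive a write/read round trip to at least 12
#' significant digits.
#'
#' @param batteries list of [MRBattery-class] objects (may be empty).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeBatteries <- function(batteries, path) {
  if (length(batteries) == 0) {
    tab <- battery_row(new("MRBattery", exposureId = "x", outcomeId = "y",
                           status = "ok", reason = "", results = list(),
                           diagnostics = list(), nSnpInitial = 0L,
                           nSnpFinal = 0L, nPleiotropyFiltered = 0L,
                           removed = list(), provenance = list()))[0, ]
  } else {
    tab <- do.call(rbind, lapply(batteries, battery_row))
  }
  con <- suppressWarnings(try(file(path, "w"), silent = TRUE))
  if (inherits(con, "try-error"))
    stop("cannot write to path: ", path, call. = FALSE)
  close(con)
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a battery TSV back as a data.frame
#' @param path file path written by [writeBatteries()].
#' @return data.frame.
#' @export
readBatteries <- function(path) {
  data.table::fread(path, data.table = FALSE, showProgress = FALSE)
}
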