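# Stepwise cleaning of summary statistics with a per-check filter report.

SUPPORTED_CHECKS <- c("drop_missing_beta", "drop_invalid_alleles",
                      "drop_indels", "drop_se_nonpositive",
                      "drop_p_out_of_range", "drop_eaf_out_of_range",
                      "drop_duplicate_rsid", "drop_same_alleles")

# p-values of exactly 0 are clamped here rather than dropped
P_FLOOR <- 1e-320

#' Clean a summary-statistics table
#'
#' Applies an ordered, customizable list of row-level validity checks, each
#' appending one entry to the filter report. The default list applies every
#' supported check in a fixed order. Cleaning is monotone (rows are only ever
#' removed) and idempotent.
#'
#' Supported checks:
#' \describe{
#'   \item{drop_missing_beta}{remove rows with missing effect size.}
#'   \item{drop_invalid_alleles}{remove rows whose `ea`/`nea` (when the
#'     columns are present) are not non-empty strings over A/C/G/T.}
#'   \item{drop_indels}{remove rows where either allele is more than one
#'     base long.}
#'   \item{drop_se_nonpositive}{remove rows with a present, non-positive
#'     standard error (missing se is retained; it may be derivable from p).}
#'   \item{drop_p_out_of_range}{remove rows with p outside (0, 1]; p equal to
#'     0 is clamped to 1e-320 instead of dropped.}
#'   \item{drop_eaf_out_of_range}{remove rows with eaf outside \[0, 1\]
#'     (missing eaf retained).}
#'   \item{drop_duplicate_rsid}{among rows sharing an rsid keep the lowest p,
#'     ties broken by first occurrence.}
#'   \item{drop_same_alleles}{remove rows with `ea == nea`.}
#' }
#'
#' @param ss a `sumstats` table (or plain data frame; coerced).
#' @param checks character vector of check names, applied in order.
#' @return the cleaned `sumstats` table; the per-check report is appended to
#'   [filter_log()] and also attached as attribute `"cleaning_report"` (a
#'   tibble with `check`, `removed`, `remaining`).
#' @examples
#' ss <- as_sumstats(data.frame(rsid = c("rs1", "rs2"), beta = c(0.1, NA),
#'                              se = c(0.02, 0.03), p = c(1e-4, 0.5)))
#' cleaned <- clean_sumstats(ss)
#' attr(cleaned, "cleaning_report")
#' @export
clean_sumstats <- function(ss, checks = SUPPORTED_CHECKS) {
  if (!inherits(ss, "sumstats")) ss <- as_sumstats(ss)
  unknown <- setdiff(checks, SUPPORTED_CHECKS)
  if (length(unknown) > 0) {
    abort(paste0("unknown check name(s): ", paste(unknown, collapse = ", ")))
  }
  report <- tibble(check = character(), removed = integer(),
                   remaining = integer())
  for (chk in checks) {
    n0 <- nrow(ss)
    keep <- switch(chk,
      drop_missing_beta = {
        if (!"beta" %in% names(ss)) rep(TRUE, n0) else !is.na(ss$beta)
      },
      drop_invalid_alleles = {
        ok <- rep(TRUE, n0)
        for (f in c("ea", "nea")) {
          if (f %in% names(ss)) {
            ok <- ok & !is.na(ss[[f]]) & grepl("^[ACGT]+$", ss[[f]])
          }
        }
        ok
      },
      drop_indels = {
        ok <- rep(TRUE, n0)
        for (f in c("ea", "nea")) {
          if (f %in% names(ss)) ok <- ok & (is.na(ss[[f]]) | nchar(ss[[f]]) == 1L)
        }
        ok
      },
      drop_se_nonpositive = {
        if (!"se" %in% names(ss)) rep(TRUE, n0) else is.na(ss$se) | ss$se > 0
      },
      drop_p_out_of_range = {
        if (!"p" %in% names(ss)) rep(TRUE, n0) else {
          p <- ss$p
          clamp <- !is.na(p) & p == 0
          if (any(clamp)) ss$p[clamp] <- P_FLOOR
          p <- ss$p
          is.na(p) | (p > 0 & p <= 1)
        }
      },
      drop_eaf_out_of_range = {
        if (!"eaf" %in% names(ss)) rep(TRUE, n0) else {
          is.na(ss$eaf) | (ss$eaf >= 0 & ss$eaf <= 1)
        }
      },
      drop_duplicate_rsid = {
        if (!"rsid" %in% names(ss) || n0 == 0) rep(TRUE, n0) else {
          p <- if ("p" %in% names(ss)) ss$p else rep(NA_real_, n0)
          ord <- order(ss$rsid, ifelse(is.na(p), Inf, p), seq_len(n0))
          first <- !duplicated(ss$rsid[ord])
          keep_idx <- sort(seq_len(n0)[ord][first])
          seq_len(n0) %in% keep_idx
        }
      },
      drop_same_alleles = {
        if (!all(c("ea", "nea") %in% names(ss))) rep(TRUE, n0) else {
          is.na(ss$ea) | is.na(ss$nea) | ss$ea != ss$nea
        }
      }
    )
    steps <- attr(ss, "steps")
    ss2 <- ss[keep, , drop = FALSE]
    attr(ss2, "steps") <- steps
    class(ss2) <- class(ss)
    ss <- log_step(ss2, chk, n0, nrow(ss2))
    report <- dplyr::bind_rows(report,
      tibble(check = chk, removed = n0 - nrow(ss), remaining = nrow(ss)))
  }
  attr(ss, "cleaning_report") <- report
  ss
}

#' Derive the standard error from an effect size and p-value
#'
#' `se = |beta| / z` with `z` the upper `1 - p/2` standard-normal quantile.
#' Vectorized; rows where the derivation is undefined (p outside (0,1),
#' `beta == 0` with p < 1, or p == 1) return `NA`.
#'
#' @param beta effect-size estimates.
#' @param p two-sided p-values in (0, 1).
#' @return standard errors (same length), `NA` where non-derivable.
#' @examples
#' derive_se(0.1, 0.05)   # ~ 0.05102
#' @export
derive_se <- function(beta, p) {
  z <- qnorm(p / 2, lower.tail = FALSE)   # accurate for very small p
  out <- abs(beta) / z
  bad <- is.na(p) | p <= 0 | p >= 1 | (beta == 0 & p < 1) | !is.finite(out)
  out[bad] <- NA_real_
  out
}

#' Derive the p-value from an effect size and standard error
#'
#' `p = 2 * (1 - Phi(|beta/se|))`, floored at 1e-320 so extreme associations
#' never report p = 0.
#'
#' @param beta effect-size estimates.
#' @param se standard errors, all > 0.
#' @return two-sided p-values.
#' @examples
#' derive_p(1, 1)   # ~ 0.3173
#' @export
derive_p <- function(beta, se) {
  if (any(!is.na(se) & se <= 0)) abort("se must be > 0")
  p <- 2 * pnorm(-abs(beta / se))
  pmax(p, P_FLOOR)
}

#' Fill missing se from p and missing p from se, in place
#'
#' Applies [derive_se()] / [derive_p()] only where the target is missing and
#' the source is available; existing values are never overwritten.
#'
#' @param ss a `sumstats` table with a `beta` column.
#' @return the table with `se` and `p` filled where derivable; counts of
#'   filled rows recorded in [filter_log()] (as zero-removal steps).
#' @export
fill_missing_stats <- function(ss) {
  if (!"beta" %in% names(ss)) abort("fill_missing_stats requires a beta column")
  if (!"se" %in% names(ss)) ss$se <- NA_real_
  if (!"p" %in% names(ss)) ss$p <- NA_real_
  need_se <- is.na(ss$se) & !is.na(ss$p)
  ss$se[need_se] <- derive_se(ss$beta[need_se], ss$p[need_se])
  need_p <- is.na(ss$p) & !is.na(ss$se) & ss$se > 0
  ss$p[need_p] <- derive_p(ss$beta[need_p], ss$se[need_p])
  n <- nrow(ss)
  ss <- log_step(ss, paste0("derive_se(", sum(need_se), " filled)"), n, n)
  ss <- log_step(ss, paste0("derive_p(", sum(need_p), " filled)"), n, n)
  ss
}
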