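# Exposure/outcome merging, allele harmonization, palindromic resolution,
# proxy substitution.

#' Merge exposure instruments with outcome summary statistics
#'
#' Inner join on rsid; when a reference panel is supplied, instruments absent
#' from the outcome data are replaced by their best LD proxy that *is*
#' present in the outcome, with the proxy's alleles translated back into the
#' target SNP's allele frame via the signed r (r < 0 means the proxy's A1
#' tags the target's A2).  Proxies whose outcome alleles cannot be resolved
#' against the panel coding are skipped.
#'
#' @param exposure,outcome cleaned `sumstats` tables; the exposure is
#'   typically the clumped instrument set.
#' @param panel optional `ref_panel` for proxy search.
#' @param r2_min,window_kb proxy-search thresholds.
#' @return a raw merged tibble (one row per instrument found or proxied) with
#'   columns `rsid`, `chrom`, `pos`, `ea_exp`, `nea_exp`, `beta_exp`,
#'   `se_exp`, `eaf_exp`, `ea_out`, `nea_out`, `beta_out`, `se_out`,
#'   `eaf_out`, `proxy_used`, `proxy_rsid`, `proxy_r`; attribute
#'   `"query_report"` counts matched / proxied / dropped instruments.
#'   Zero overlap with no proxies raises a condition of class
#'   `"mrkit_no_instruments"`.
#' @export
query_outcome <- function(exposure, outcome, panel = NULL,
                          r2_min = 0.8, window_kb = 500) {
  for (nm in c("rsid", "ea", "nea", "beta", "se")) {
    if (!nm %in% names(exposure)) abort(paste0("exposure lacks column ", nm))
    if (!nm %in% names(outcome)) abort(paste0("outcome lacks column ", nm))
  }
  get_or_na <- function(df, nm) if (nm %in% names(df)) df[[nm]] else NA_real_
  rows <- list()
  n_direct <- 0L; n_proxied <- 0L; n_dropped <- 0L
  out_idx_all <- match(exposure$rsid, outcome$rsid)
  for (k in seq_len(nrow(exposure))) {
    oi <- out_idx_all[k]
    proxy_used <- FALSE; proxy_rsid <- NA_character_; proxy_r <- NA_real_
    ea_out <- NA_character_; nea_out <- NA_character_
    if (is.na(oi) && !is.null(panel)) {
      px <- find_proxies(panel, exposure$rsid[k], candidates = outcome$rsid,
                         r2_min = r2_min, window_kb = window_kb)
      ti <- match(exposure$rsid[k], panel$variants$rsid)
      if (nrow(px) > 0 && !is.na(ti)) {
        ta1 <- panel$variants$a1[ti]; ta2 <- panel$variants$a2[ti]
        for (pk in seq_len(nrow(px))) {
          cand_oi <- match(px$rsid[pk], outcome$rsid)
          pea <- outcome$ea[cand_oi]; pnea <- outcome$nea[cand_oi]
          # proxy outcome alleles must match the panel coding of the proxy
          frame_ok <- (pea == px$a1[pk] && pnea == px$a2[pk]) ||
                      (pea == px$a2[pk] && pnea == px$a1[pk])
          if (!frame_ok) next
          # translate each proxy allele to the target frame
          translate <- function(al) {
            if (px$r[pk] >= 0) {
              if (al == px$a1[pk]) ta1 else ta2
            } else {
              if (al == px$a1[pk]) ta2 else ta1
            }
          }
          ea_out <- translate(pea); nea_out <- translate(pnea)
          oi <- cand_oi
          proxy_used <- TRUE; proxy_rsid <- px$rsid[pk]; proxy_r <- px$r[pk]
          break
        }
      }
    }
    if (is.na(oi)) { n_dropped <- n_dropped + 1L; next }
    if (!proxy_used) {
      n_direct <- n_direct + 1L
      ea_out <- outcome$ea[oi]; nea_out <- outcome$nea[oi]
    } else n_proxied <- n_proxied + 1L
    rows[[length(rows) + 1L]] <- tibble(
      rsid = exposure$rsid[k],
      chrom = if ("chrom" %in% names(exposure)) exposure$chrom[k]
              else NA_character_,
      pos = if ("pos" %in% names(exposure)) exposure$pos[k] else NA_integer_,
      ea_exp = exposure$ea[k], nea_exp = exposure$nea[k],
      beta_exp = exposure$beta[k], se_exp = exposure$se[k],
      eaf_exp = get_or_na(exposure, "eaf")[k],
      ea_out = ea_out, nea_out = nea_out,
      beta_out = outcome$beta[oi], se_out = outcome$se[oi],
      eaf_out = get_or_na(outcome, "eaf")[oi],
      proxy_used = proxy_used, proxy_rsid = proxy_rsid, proxy_r = proxy_r)
  }
  if (length(rows) == 0) {
    abort("no instruments found in the outcome data (and no usable proxies)",
          class = "mrkit_no_instruments")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "query_report") <- tibble(
    instruments = nrow(exposure), matched = n_direct,
    proxied = n_proxied, dropped = n_dropped)
  out
}

#' Harmonize merged exposure/outcome rows to a common effect allele
#'
#' Aligns outcome effects to the exposure's effect allele. Per row: matching
#' allele pairs are kept; swapped pairs get `beta_out` negated and `eaf_out`
#' complemented; otherwise complementary-strand recoding (A<->T, C<->G) of
#' the outcome alleles is attempted before the same rules; incompatible rows
#' are dropped.  Palindromic pairs ({A,T} or {C,G}) cannot be resolved from
#' labels:
#' \describe{
#'   \item{action 1}{trust the labels (treat like any other pair).}
#'   \item{action 2}{infer strand from allele frequencies: after label
#'     alignment, keep when both eafs fall on the same side of 0.5, flip
#'     when on opposite sides, and drop as ambiguous when either eaf lies
#'     within `[palindromic_eaf_threshold, 1 - palindromic_eaf_threshold]`
#'     or is missing.}
#'   \item{action 3}{drop every palindromic row.}
#' }
#' Indel rows are dropped (strand logic is undefined for them). The default
#' action 2 with threshold 0.42 follows the convention established for
#' two-sample MR harmonization.
#'
#' @param merged the output of [query_outcome()] (or a previously harmonized
#'   table — harmonization is involutive).
#' @param action 1, 2 or 3 (default 2).
#' @param palindromic_eaf_threshold ambiguity threshold for action 2
#'   (default 0.42; eafs in `[0.42, 0.58]` are ambiguous).
#' @return an `mr_harmonized` tibble with a single allele pair per row
#'   (`ea`, `nea`, exposure-defined; `ea_out`/`nea_out` kept equal to them so
#'   the function is closed on its output), effect columns, proxy columns,
#'   `palindromic` flag and `action_taken`; attribute `"harmonization_report"`
#'   counts every outcome.
#' @export
harmonize_pair <- function(merged, action = 2,
                           palindromic_eaf_threshold = 0.42) {
  if (!action %in% 1:3) abort("action must be 1, 2 or 3")
  thr <- palindromic_eaf_threshold
  if (!(thr > 0 && thr <= 0.5)) abort("threshold must be in (0, 0.5]")
  if ("ea" %in% names(merged) && !"ea_exp" %in% names(merged)) {
    merged$ea_exp <- merged$ea; merged$nea_exp <- merged$nea
  }
  has_proxy <- all(c("proxy_used", "proxy_rsid", "proxy_r") %in%
                     names(merged))
  n <- nrow(merged)
  counts <- c(kept = 0L, flipped = 0L, strand_recoded = 0L,
              palindromic_kept = 0L, palindromic_flipped = 0L,
              dropped_indel = 0L, dropped_incompatible = 0L,
              dropped_palindromic = 0L, dropped_ambiguous_eaf = 0L,
              dropped_missing_eaf = 0L)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    ea <- merged$ea_exp[k]; nea <- merged$nea_exp[k]
    eo <- merged$ea_out[k]; no <- merged$nea_out[k]
    bo <- merged$beta_out[k]; fo <- merged$eaf_out[k]
    fe <- if ("eaf_exp" %in% names(merged)) merged$eaf_exp[k] else NA_real_
    if (any(nchar(c(ea, nea, eo, no)) != 1)) {
      counts["dropped_indel"] <- counts["dropped_indel"] + 1L
      next
    }
    pal <- is_palindromic(ea, nea)
    if (pal && action == 3) {
      counts["dropped_palindromic"] <- counts["dropped_palindromic"] + 1L
      next
    }
    recoded <- FALSE
    if (!(identical(c(eo, no), c(ea, nea)) ||
          identical(c(eo, no), c(nea, ea)))) {
      eo2 <- complement_alleles(eo); no2 <- complement_alleles(no)
      if (identical(c(eo2, no2), c(ea, nea)) ||
          identical(c(eo2, no2), c(nea, ea))) {
        eo <- eo2; no <- no2; recoded <- TRUE
      } else {
        counts["dropped_incompatible"] <- counts["dropped_incompatible"] + 1L
        next
      }
    }
    flipped <- FALSE
    if (identical(c(eo, no), c(nea, ea))) {
      bo <- -bo; fo <- 1 - fo; flipped <- TRUE
    }
    act <- if (recoded) "strand_recoded" else if (flipped) "flipped" else "kept"
    if (pal && action == 2) {
      if (is.na(fe) || is.na(fo)) {
        counts["dropped_missing_eaf"] <- counts["dropped_missing_eaf"] + 1L
        next
      }
      ambiguous <- (fe >= thr && fe <= 1 - thr) || (fo >= thr && fo <= 1 - thr)
      if (ambiguous) {
        counts["dropped_ambiguous_eaf"] <- counts["dropped_ambiguous_eaf"] + 1L
        next
      }
      same_side <- (fe < 0.5) == (fo < 0.5)
      if (!same_side) {
        bo <- -bo; fo <- 1 - fo
        act <- "palindromic_flipped"
      } else {
        act <- "palindromic_kept"
      }
    }
    counts[if (act %in% names(counts)) act else "kept"] <-
      counts[if (act %in% names(counts)) act else "kept"] + 1L
    rows[[k]] <- tibble(
      rsid = merged$rsid[k],
      ea = ea, nea = nea,
      beta_exp = merged$beta_exp[k], se_exp = merged$se_exp[k], eaf_exp = fe,
      beta_out = bo, se_out = merged$se_out[k], eaf_out = fo,
      ea_out = ea, nea_out = nea,
      palindromic = pal,
      proxy_used = if (has_proxy) merged$proxy_used[k] else FALSE,
      proxy_rsid = if (has_proxy) merged$proxy_rsid[k] else NA_character_,
      proxy_r = if (has_proxy) merged$proxy_r[k] else NA_real_,
      action_taken = act)
  }
  dropped_eaf <- counts["dropped_missing_eaf"]
  if (dropped_eaf > 0) {
    warn(paste0(dropped_eaf, " palindromic row(s) dropped: eaf missing on ",
                "one side under action 2"))
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  attr(out, "harmonization_report") <- tibble(outcome = names(counts),
                                              n = unname(counts))
  class(out) <- c("mr_harmonized", class(tibble()))
  out
}
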