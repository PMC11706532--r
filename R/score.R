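# Polygenic risk scoring and per-SNP association testing.

#' Compute polygenic risk scores
#'
#' For each weight SNP found in the target fileset the effect allele is
#' aligned to the panel's allele coding: if (ea, nea) equals (a1, a2) the
#' dosage is used as-is; if it equals (a2, a1) the complement `2 - dosage` is
#' used; any other combination is an allele mismatch and the SNP is dropped.
#' The score is the plain weighted sum `score_j = sum_i beta_i * dosage_ij`
#' of effect-allele dosages (a sum score, not an average; note that
#' re-expressing a weight for the other allele shifts every sample's score
#' by the same constant `2 * beta`).  Missing individual dosages are imputed
#' with the SNP's sample-mean dosage (default) or the SNP is dropped
#' entirely (`missing = "strict"`).  SNPs absent from the panel are replaced
#' by their best LD proxy when `proxy_panel` is given (the weight's sign is
#' flipped when the proxy's signed r is negative), else dropped.
#'
#' @param ss a `sumstats` table with `rsid`, `ea`, `nea`, `beta`.
#' @param panel the `ref_panel` to score (its samples receive scores).
#' @param proxy_panel optional `ref_panel` supplying LD for proxy search.
#' @param r2_min,window_kb proxy-search thresholds (see [find_proxies()]).
#' @param missing `"impute"` (sample-mean dosage, default) or `"strict"`
#'   (drop SNPs with any missing dosage).
#' @return a `prs_result` tibble: `sample_id`, `score`, `n_snps_used`,
#'   `n_missing_imputed`; attribute `"snp_log"` details each input SNP's
#'   fate (`used`, `proxied`, `allele_mismatch`, `not_found`,
#'   `dropped_missing`).
#' @examples
#' \dontrun{
#' prs <- compute_prs(weights, read_plink("target"))
#' }
#' @export
compute_prs <- function(ss, panel, proxy_panel = NULL,
                        r2_min = 0.8, window_kb = 500,
                        missing = c("impute", "strict")) {
  missing <- match.arg(missing)
  need <- c("rsid", "ea", "nea", "beta")
  if (!all(need %in% names(ss))) {
    abort(paste0("PRS requires columns: ", paste(need, collapse = ", ")))
  }
  v <- panel$variants
  n_samp <- nrow(panel$dosage)
  score <- numeric(n_samp)
  n_used <- 0L
  n_imputed <- 0L
  log <- list()
  for (k in seq_len(nrow(ss))) {
    rsid <- ss$rsid[k]; ea <- ss$ea[k]; nea <- ss$nea[k]; beta <- ss$beta[k]
    ci <- match(rsid, v$rsid)
    proxy_rsid <- NA_character_; proxy_r <- NA_real_
    if (is.na(ci) && !is.null(proxy_panel)) {
      # proxy must be LD-resolvable in the proxy panel and present in the
      # scoring target; translate the weight into the proxy's allele frame
      px <- find_proxies(proxy_panel, rsid, candidates = v$rsid,
                         r2_min = r2_min, window_kb = window_kb)
      ti <- match(rsid, proxy_panel$variants$rsid)
      if (nrow(px) > 0 && !is.na(ti)) {
        ta1 <- proxy_panel$variants$a1[ti]
        ta2 <- proxy_panel$variants$a2[ti]
        # weight expressed for the target's a1 allele
        beta_t <- if (ea == ta1 && nea == ta2) beta
                  else if (ea == ta2 && nea == ta1) -beta
                  else NA_real_
        if (!is.na(beta_t)) {
          best <- px[1, ]
          ci <- match(best$rsid, v$rsid)
          # r < 0: the proxy's a1 (proxy-panel coding) tags the target's a2;
          # the usual alignment below reconciles the scoring panel's coding
          beta <- beta_t * sign(best$r)
          ea <- best$a1; nea <- best$a2
          proxy_rsid <- best$rsid; proxy_r <- best$r
        }
      }
      if (is.na(ci)) {
        log[[k]] <- tibble(rsid = rsid, status = "not_found",
                           proxy_rsid = NA_character_, proxy_r = NA_real_)
        next
      }
    } else if (is.na(ci)) {
      log[[k]] <- tibble(rsid = rsid, status = "not_found",
                         proxy_rsid = NA_character_, proxy_r = NA_real_)
      next
    }
    if (ea == v$a1[ci] && nea == v$a2[ci]) {
      d <- unname(panel$dosage[, ci])
    } else if (ea == v$a2[ci] && nea == v$a1[ci]) {
      d <- 2 - unname(panel$dosage[, ci])
    } else {
      log[[k]] <- tibble(rsid = rsid, status = "allele_mismatch",
                         proxy_rsid = proxy_rsid, proxy_r = proxy_r)
      next
    }
    miss <- is.na(d)
    if (any(miss)) {
      if (missing == "strict") {
        log[[k]] <- tibble(rsid = rsid, status = "dropped_missing",
                           proxy_rsid = proxy_rsid, proxy_r = proxy_r)
        next
      }
      d[miss] <- mean(d[!miss])
      n_imputed <- n_imputed + sum(miss)
    }
    score <- score + beta * d
    n_used <- n_used + 1L
    log[[k]] <- tibble(rsid = rsid,
                       status = if (is.na(proxy_rsid)) "used" else "proxied",
                       proxy_rsid = proxy_rsid, proxy_r = proxy_r)
  }
  if (n_used == 0L) abort("zero usable SNPs for PRS")
  out <- tibble(sample_id = as.character(panel$fam$iid), score = score,
                n_snps_used = n_used, n_missing_imputed = n_imputed)
  attr(out, "snp_log") <- dplyr::bind_rows(log)
  class(out) <- c("prs_result", class(out))
  out
}

#' Per-SNP association testing against a phenotype
#'
#' Regresses the phenotype on each variant's A1 dosage (plus optional
#' covariates): ordinary least squares for quantitative phenotypes, logistic
#' regression via iteratively reweighted least squares for binary ones.
#' Samples with a missing dosage are excluded per SNP.  Monomorphic SNPs and
#' non-convergent logistic fits are flagged, not estimated.
#'
#' @param panel a `ref_panel`.
#' @param phenotype numeric vector (one value per panel sample, in `fam`
#'   order) or a data frame with columns `id`, `value` matched to sample ids.
#' @param covariates optional numeric matrix / data frame of per-sample
#'   covariates.
#' @param model `"linear"` or `"logistic"` (phenotype must be 0/1).
#' @return a tibble: `rsid`, `beta`, `se`, `p`, `n`, `status`
#'   (`"ok"`, `"monomorphic"`, `"no_convergence"`).
#' @export
snp_association <- function(panel, phenotype, covariates = NULL,
                            model = c("linear", "logistic")) {
  model <- match.arg(model)
  if (is.data.frame(phenotype)) {
    idx <- match(as.character(panel$fam$iid), as.character(phenotype[[1]]))
    phenotype <- as.numeric(phenotype[[2]][idx])
  }
  n_samp <- nrow(panel$dosage)
  if (length(phenotype) != n_samp) {
    abort("phenotype length must equal the panel sample count")
  }
  if (model == "logistic" &&
      !all(stats::na.omit(phenotype) %in% c(0, 1))) {
    abort("logistic model requires a binary 0/1 phenotype")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_samp) abort("covariate row count mismatch")
  }
  m <- ncol(panel$dosage)
  res <- vector("list", m)
  for (j in seq_len(m)) {
    d <- panel$dosage[, j]
    ok <- !is.na(d) & !is.na(phenotype)
    if (!is.null(covariates)) ok <- ok & complete.cases(covariates)
    dd <- d[ok]; yy <- phenotype[ok]
    rsid <- panel$variants$rsid[j]
    if (length(dd) < 3 || var(dd) == 0) {
      res[[j]] <- tibble(rsid = rsid, beta = NA_real_, se = NA_real_,
                         p = NA_real_, n = sum(ok), status = "monomorphic")
      next
    }
    X <- if (is.null(covariates)) data.frame(dosage = dd)
         else data.frame(dosage = dd, covariates[ok, , drop = FALSE])
    fit <- if (model == "linear") {
      lm(yy ~ ., data = X)
    } else {
      suppressWarnings(glm(yy ~ ., data = X, family = binomial()))
    }
    if (model == "logistic" && !fit$converged) {
      res[[j]] <- tibble(rsid = rsid, beta = NA_real_, se = NA_real_,
                         p = NA_real_, n = sum(ok), status = "no_convergence")
      next
    }
    est <- coef(fit)["dosage"]
    se <- sqrt(diag(vcov(fit))["dosage"])
    p <- if (model == "linear") {
      2 * pt(-abs(est / se), df = fit$df.residual)
    } else {
      2 * pnorm(-abs(est / se))
    }
    res[[j]] <- tibble(rsid = rsid, beta = unname(est), se = unname(se),
                       p = unname(max(p, P_FLOOR)), n = sum(ok),
                       status = "ok")
  }
  dplyr::bind_rows(res)
}
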