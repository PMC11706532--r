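# Simulation-based horizontal-pleiotropy detection (MR-PRESSO style):
# global test on the weighted residual sum of squares around leave-one-out
# IVW fits, per-SNP outlier test, and a distortion test on the outlier-
# corrected estimate.  Deterministic for any worker count under one seed:
# every simulation iteration draws from its own derived substream and
# iterations are merged in iteration order.

ivw_slope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

# leave-one-out IVW slopes for every SNP at once
loo_slopes <- function(bx, by, w) {
  s_xy <- sum(w * bx * by)
  s_xx <- sum(w * bx^2)
  (s_xy - w * bx * by) / (s_xx - w * bx^2)
}

presso_rss <- function(bx, by, w, weighted) {
  theta_loo <- loo_slopes(bx, by, w)
  resid2 <- (by - theta_loo * bx)^2
  if (weighted) resid2 <- w * resid2
  list(resid = resid2, rss = sum(resid2))
}

#' MR-PRESSO: global, outlier and distortion tests
#'
#' For each SNP the expected outcome effect is taken from the leave-one-out
#' IVW slope; the observed statistic is the weighted residual sum of squares
#' `RSS = sum_i w_i (beta_out_i - theta_(-i) * beta_exp_i)^2` with
#' `w_i = 1/se_out_i^2` (set `weighted = FALSE` for unweighted residuals).
#' Its null distribution is simulated by drawing, in each of `n_sim`
#' iterations, `beta_exp* ~ N(beta_exp, se_exp)` and
#' `beta_out* ~ N(theta_(-i) * beta_exp, se_out)` and recomputing the
#' statistic identically (including the leave-one-out fits).  P-values use
#' the add-one convention `(1 + #{RSS* >= RSS}) / (n_sim + 1)` so the floor
#' is `1/(n_sim + 1)`, never zero.
#'
#' Per-SNP outlier p-values compare each observed residual with its own
#' simulated distribution, are Bonferroni-scaled by the SNP count and capped
#' at 1; SNPs below `outlier_alpha` form the outlier set.  The distortion
#' test contrasts the IVW estimate on all SNPs with the estimate excluding
#' outliers, `100 * (theta_all - theta_no) / |theta_no|` percent, and
#' obtains a p-value by repeatedly removing equally many randomly chosen
#' non-outlier SNPs and recomputing the analogous coefficient.
#'
#' @param h a harmonized table with >= 4 SNPs (columns `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; missing `se_exp` falls back to 0 with a warning).
#' @param n_sim simulation iterations (>= 100, default 1000).
#' @param outlier_alpha significance level for outlier calls on the
#'   Bonferroni-adjusted p-values (default 0.05).
#' @param seed one user seed; per-iteration substreams derive from it.
#' @param n_workers parallel workers (forked); results are bit-identical
#'   for any worker count.
#' @param weighted use `1/se_out^2`-weighted residuals (default `TRUE`).
#' @param n_distortion null draws for the distortion test (default `n_sim`).
#' @return an `mr_presso` list: `rss_obs`, `global_p`, `sim_rss_summary`,
#'   `snp_results` (tibble: rsid, residual, p_outlier), `outliers` (rsid
#'   vector), `theta_all`, `theta_no_outliers` (one-row `mr_result`s),
#'   `distortion_pct`, `distortion_p`, `n_sim`.
#' @examples
#' h <- data.frame(beta_exp = rnorm(10, 0.1, 0.01), se_exp = 0.01,
#'                 se_out = 0.005)
#' h$beta_out <- 0.2 * h$beta_exp + rnorm(10, 0, 0.005)
#' mr_presso(h, n_sim = 200, seed = 3)
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1,
                      n_workers = 1, weighted = TRUE, n_distortion = n_sim) {
  mr_check_h(h)
  n <- nrow(h)
  if (n < 4) abort("MR-PRESSO requires at least 4 SNPs")
  if (n_sim < 100) abort("n_sim must be >= 100")
  if (!(outlier_alpha > 0 && outlier_alpha < 1)) {
    abort("outlier_alpha must be in (0, 1)")
  }
  bx <- h$beta_exp; by <- h$beta_out
  sx <- h$se_exp; sy <- h$se_out
  if (is.null(sx) || all(is.na(sx))) {
    warn("se_exp missing; simulating exposure effects without error (se = 0)")
    sx <- rep(0, n)
  }
  sx[is.na(sx)] <- 0
  w <- 1 / sy^2
  obs <- presso_rss(bx, by, w, weighted)
  theta_loo <- loo_slopes(bx, by, w)
  mu_y <- theta_loo * bx

  iter_seeds <- derive_seeds(seed, n_sim + 1L)
  one_iter <- function(t) {
    set.seed(iter_seeds[t])
    bxs <- rnorm(n, bx, sx)
    bys <- rnorm(n, mu_y, sy)
    sim <- presso_rss(bxs, bys, w, weighted)
    c(sim$rss, sim$resid)
  }
  sims <- if (n_workers > 1) {
    chunks <- split(seq_len(n_sim),
                    cut(seq_len(n_sim), n_workers, labels = FALSE))
    parts <- parallel::mclapply(chunks, function(id) lapply(id, one_iter),
                                mc.cores = n_workers)
    unlist(parts, recursive = FALSE)
  } else {
    lapply(seq_len(n_sim), one_iter)
  }
  sims <- do.call(rbind, sims)             # n_sim x (1 + n), iteration order
  rss_sim <- sims[, 1]
  resid_sim <- sims[, -1, drop = FALSE]

  global_p <- (1 + sum(rss_sim >= obs$rss)) / (n_sim + 1)
  p_raw <- (1 + colSums(resid_sim >= rep(obs$resid, each = n_sim))) /
    (n_sim + 1)
  p_adj <- pmin(p_raw * n, 1)
  outliers <- which(p_adj < outlier_alpha)
  rsid <- if ("rsid" %in% names(h)) h$rsid else as.character(seq_len(n))

  theta_all <- mr_ivw(h)
  theta_no <- NULL
  distortion_pct <- NA_real_
  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < n) {
    keep <- setdiff(seq_len(n), outliers)
    theta_no <- mr_ivw(h[keep, , drop = FALSE])
    distortion_pct <- 100 * (theta_all$estimate - theta_no$estimate) /
      abs(theta_no$estimate)
    n_out <- length(outliers)
    if (length(keep) > n_out) {
      set.seed(iter_seeds[n_sim + 1L])
      null_d <- vapply(seq_len(n_distortion), function(i) {
        drop_set <- sample(keep, n_out)
        sub <- setdiff(seq_len(n), drop_set)
        th <- ivw_slope(bx[sub], by[sub], w[sub])
        100 * (theta_all$estimate - th) / abs(th)
      }, numeric(1))
      distortion_p <- mean(abs(null_d) >= abs(distortion_pct))
    }
  } else if (length(outliers) == n) {
    abort("every SNP was flagged as an outlier; no corrected estimate")
  }
  structure(list(
    rss_obs = obs$rss,
    global_p = global_p,
    sim_rss_summary = stats::quantile(rss_sim, c(0.5, 0.9, 0.95, 0.99)),
    snp_results = tibble(rsid = rsid, residual = obs$resid,
                         p_outlier = p_adj),
    outliers = rsid[outliers],
    theta_all = theta_all,
    theta_no_outliers = theta_no,
    distortion_pct = distortion_pct,
    distortion_p = distortion_p,
    n_sim = n_sim,
    outlier_alpha = outlier_alpha),
    class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("# MR-PRESSO (", x$n_sim, " simulations)\n", sep = "")
  cat("  global test: RSS =", format(x$rss_obs, digits = 5),
      ", p =", format(x$global_p, digits = 4), "\n")
  cat("  outliers:", if (length(x$outliers)) paste(x$outliers, collapse = ", ")
                     else "none", "\n")
  if (!is.na(x$distortion_pct)) {
    cat("  distortion:", format(x$distortion_pct, digits = 4), "% (p =",
        format(x$distortion_p, digits = 4), ")\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mr_presso <- function(x, ...) {
  out <- x$snp_results
  out$outlier <- out$rsid %in% x$outliers
  out
}

#' @exportS3Method generics::glance
glance.mr_presso <- function(x, ...) {
  tibble(rss_obs = x$rss_obs, global_p = x$global_p,
         n_outliers = length(x$outliers),
         theta_all = x$theta_all$estimate,
         theta_no_outliers = if (is.null(x$theta_no_outliers)) NA_real_
                             else x$theta_no_outliers$estimate,
         distortion_pct = x$distortion_pct,
         distortion_p = x$distortion_p)
}
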