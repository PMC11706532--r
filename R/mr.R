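# The two-sample MR estimator family on a harmonized table.
#
# Every estimator consumes columns beta_exp, se_exp, beta_out, se_out.
# Naming below: bx/by for the exposure/outcome effects, w = 1/se_out^2.

mr_check_h <- function(h, need_se_exp = FALSE) {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(h))) {
    abort(paste0("harmonized table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  invisible(h)
}

mr_result_row <- function(method, estimate, se, p, n_snp,
                          ci_level = 0.95, crit = qnorm(0.975), ...) {
  tibble(method = method, estimate = estimate, se = se,
         ci_lower = estimate - crit * se, ci_upper = estimate + crit * se,
         p = p, n_snp = n_snp, ...)
}

#' Per-SNP Wald ratio estimates
#'
#' First-order ratios `r_i = beta_out / beta_exp` with standard errors
#' `se1_i = se_out / |beta_exp|` — the shared kernel of the median and mode
#' estimators.  Rows with `beta_exp == 0` are dropped with a warning rather
#' than producing infinite ratios.
#'
#' @param h a harmonized table.
#' @return a tibble `rsid` (if present), `ratio`, `se1`, plus the input
#'   effect columns for the rows retained.
#' @export
mr_ratios <- function(h) {
  mr_check_h(h)
  zero <- !is.na(h$beta_exp) & h$beta_exp == 0
  if (all(zero)) abort("all exposure effects are zero; ratios undefined")
  if (any(zero)) {
    warn(paste0(sum(zero), " instrument(s) with zero exposure effect dropped"))
    h <- h[!zero, , drop = FALSE]
  }
  tibble(rsid = if ("rsid" %in% names(h)) h$rsid else NA_character_,
         ratio = h$beta_out / h$beta_exp,
         se1 = h$se_out / abs(h$beta_exp),
         beta_exp = h$beta_exp, se_exp = h$se_exp,
         beta_out = h$beta_out, se_out = h$se_out)
}

#' Inverse-variance-weighted estimator
#'
#' `theta = sum(bx*by*w) / sum(bx^2*w)` with `w = 1/se_out^2` — the weighted
#' regression of outcome on exposure effects through the origin.  The fixed
#' -effect standard error is `(sum bx^2 w)^(-1/2)`; the multiplicative
#' random-effects variant (default) inflates it by
#' `max(1, sqrt(Q/(n-1)))`.  P-values are two-sided normal.
#'
#' @param h a harmonized table (>= 1 SNP fixed, >= 2 random).
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param heterogeneity also report Cochran's Q, its df and p.
#' @return a one-row `mr_result` tibble.
#' @export
mr_ivw <- function(h, mode = c("multiplicative_random", "fixed"),
                   heterogeneity = FALSE) {
  mode <- match.arg(mode)
  mr_check_h(h)
  n <- nrow(h)
  if (n < 1 || (mode == "multiplicative_random" && n < 2)) {
    abort(paste0("IVW (", mode, ") requires at least ",
                 if (mode == "fixed") 1 else 2, " SNPs"))
  }
  bx <- h$beta_exp; by <- h$beta_out; w <- 1 / h$se_out^2
  theta <- sum(bx * by * w) / sum(bx^2 * w)
  se <- 1 / sqrt(sum(bx^2 * w))
  Q <- sum(w * (by - theta * bx)^2)
  if (mode == "multiplicative_random") {
    se <- se * max(1, sqrt(Q / (n - 1)))
  }
  p <- 2 * pnorm(-abs(theta / se))
  label <- if (mode == "fixed") "IVW (fixed)" else "IVW"
  out <- mr_result_row(label, theta, se, p, n)
  if (heterogeneity) {
    out$Q <- Q; out$Q_df <- n - 1
    out$Q_p <- pchisq(Q, df = n - 1, lower.tail = FALSE)
  }
  out
}

#' MR-Egger regression
#'
#' Rows are oriented so every exposure effect is non-negative (both betas
#' negated where `beta_exp < 0`), then outcome effects are regressed on
#' exposure effects by weighted least squares with intercept, weights
#' `1/se_out^2`.  Standard errors are inflated by
#' `max(1, sqrt(RSS_w/(n-2)))`; slope and intercept p-values use a
#' t distribution with n-2 df (confidence intervals likewise t-based —
#' this departs from the normal CIs of the other estimators).  The intercept
#' indexes directional pleiotropy.
#'
#' @param h a harmonized table with >= 3 SNPs.
#' @return a one-row `mr_result` tibble with `intercept`, `intercept_se`,
#'   `intercept_p` extras.
#' @export
mr_egger <- function(h) {
  mr_check_h(h)
  n <- nrow(h)
  if (n < 3) abort("MR-Egger requires at least 3 SNPs")
  flip <- h$beta_exp < 0
  bx <- abs(h$beta_exp)
  by <- ifelse(flip, -h$beta_out, h$beta_out)
  w <- 1 / h$se_out^2
  # weighted normal equations for [intercept, slope]
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  if (det <= 0) abort("degenerate design in MR-Egger (no exposure spread)")
  intercept <- (swx2 * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  rss <- sum(w * (by - intercept - slope * bx)^2)
  sigma2 <- max(1, rss / (n - 2))
  se_slope <- sqrt(sigma2 * sw / det)
  se_int <- sqrt(sigma2 * swx2 / det)
  crit <- qt(0.975, df = n - 2)
  out <- mr_result_row("MR-Egger", slope, se_slope,
                       2 * pt(-abs(slope / se_slope), df = n - 2), n,
                       crit = crit)
  out$intercept <- intercept
  out$intercept_se <- se_int
  out$intercept_p <- 2 * pt(-abs(intercept / se_int), df = n - 2)
  out
}

# interpolated weighted median of ratios at cumulative midpoint 0.5
weighted_median_point <- function(r, wts) {
  ord <- order(r)
  r <- r[ord]; wts <- wts[ord] / sum(wts)
  s <- cumsum(wts) - wts / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

# parametric bootstrap of a ratio-based point estimator
boot_se <- function(h, n_boot, seed, point_fun) {
  n <- nrow(h)
  seeds <- derive_seeds(seed, 1)
  set.seed(seeds[1])
  bx <- matrix(rnorm(n * n_boot, h$beta_exp, h$se_exp), nrow = n)
  by <- matrix(rnorm(n * n_boot, h$beta_out, h$se_out), nrow = n)
  est <- vapply(seq_len(n_boot), function(b) {
    bxb <- bx[, b]
    keep <- bxb != 0
    point_fun(by[, b][keep] / bxb[keep], h$se_out[keep] / abs(bxb[keep]))
  }, numeric(1))
  sd(est)
}

#' Median-based estimators (simple and weighted)
#'
#' Orders the per-SNP Wald ratios and interpolates at cumulative weight 0.5
#' (equal weights for the simple median, inverse-variance `1/se1^2` for the
#' weighted).  The standard error is the standard deviation of the estimate
#' over `n_boot` parametric resamples drawing
#' `beta_exp* ~ N(beta_exp, se_exp)` and `beta_out* ~ N(beta_out, se_out)`;
#' p-values are two-sided normal.  The median consistently estimates the
#' causal effect as long as valid instruments contribute more than half of
#' the weight.
#'
#' @param h a harmonized table with >= 3 SNPs.
#' @param weights `"inverse_variance"` (default) or `"equal"`.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return a one-row `mr_result` tibble.
#' @export
mr_median <- function(h, weights = c("inverse_variance", "equal"),
                      n_boot = 1000, seed = 1) {
  weights <- match.arg(weights)
  mr_check_h(h)
  rt <- mr_ratios(h)
  n <- nrow(rt)
  if (n < 3) abort("median estimator requires at least 3 SNPs")
  wts <- if (weights == "equal") rep(1, n) else 1 / rt$se1^2
  theta <- weighted_median_point(rt$ratio, wts)
  pf <- if (weights == "equal") {
    function(r, se1) weighted_median_point(r, rep(1, length(r)))
  } else {
    function(r, se1) weighted_median_point(r, 1 / se1^2)
  }
  se <- boot_se(rt, n_boot, seed, pf)
  label <- if (weights == "equal") "Simple median" else "Weighted median"
  mr_result_row(label, theta, se, 2 * pnorm(-abs(theta / se)), n)
}

# kernel-density mode of the ratios on a fixed grid
mode_point <- function(r, wts, phi, grid_n = 10000) {
  wts <- wts / sum(wts)
  n <- length(r)
  s <- sd(r)
  raw_mad <- median(abs(r - median(r)))
  bw <- phi * 0.9 * min(s, raw_mad / 0.6745) * n^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(median(r))  # degenerate density
  grid <- seq(mean(r) - 5 * s, mean(r) + 5 * s, length.out = grid_n)
  dens <- dnorm(outer(grid, r, "-") / bw) %*% wts
  grid[which.max(dens)]   # which.max takes the first (smallest) on ties
}

#' Mode-based estimators (simple and weighted)
#'
#' The estimate is the argmax of a Gaussian kernel density over the per-SNP
#' Wald ratios, evaluated on a fixed 10,000-point grid spanning
#' `mean(ratio) +/- 5 sd(ratio)`.  Bandwidth
#' `h = phi * 0.9 * min(sd(r), MAD(r)/0.6745) * n^(-1/5)` (raw MAD); the
#' `phi` factor rescales it.  Weights are `1/se1^2` (normalized) for the
#' weighted mode, equal otherwise.  Standard errors come from the same
#' parametric bootstrap as the median; p-values are two-sided normal.
#' If every ratio is identical the bandwidth degenerates and that common
#' value is returned.
#'
#' @param h a harmonized table with >= 3 SNPs.
#' @param weighted use inverse-variance weights (default `FALSE`).
#' @param phi bandwidth factor > 0 (default 1).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param grid_n density evaluation grid size (default 10000).
#' @return a one-row `mr_result` tibble.
#' @export
mr_mode <- function(h, weighted = FALSE, phi = 1, n_boot = 1000, seed = 1,
                    grid_n = 10000) {
  if (phi <= 0) abort("phi must be > 0")
  mr_check_h(h)
  rt <- mr_ratios(h)
  n <- nrow(rt)
  if (n < 3) abort("mode estimator requires at least 3 SNPs")
  wts_fun <- if (weighted) function(se1) 1 / se1^2
             else function(se1) rep(1, length(se1))
  theta <- mode_point(rt$ratio, wts_fun(rt$se1), phi, grid_n)
  se <- boot_se(rt, n_boot, seed,
                function(r, se1) mode_point(r, wts_fun(se1), phi, grid_n))
  label <- if (weighted) "Weighted mode" else "Simple mode"
  mr_result_row(label, theta, se, 2 * pnorm(-abs(theta / se)), n)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum (beta_exp^2 / se_out^2) * (ratio - theta)^2` with `n - 1`
#' degrees of freedom and an upper-tail chi-square p-value.  Large Q signals
#' heterogeneity of the per-SNP ratios around `theta` — a symptom of
#' horizontal pleiotropy or invalid instruments.
#'
#' @param h a harmonized table with >= 2 SNPs.
#' @param theta the pooled estimate the residuals are taken around
#'   (default: the IVW estimate).
#' @return a tibble `Q`, `df`, `p`.
#' @export
mr_cochran_q <- function(h, theta = NULL) {
  mr_check_h(h)
  n <- nrow(h)
  if (n < 2) abort("Cochran's Q requires at least 2 SNPs")
  if (is.null(theta)) theta <- mr_ivw(h)$estimate
  w <- 1 / h$se_out^2
  r <- h$beta_out / h$beta_exp
  Q <- sum((h$beta_exp^2 * w) * (r - theta)^2)
  tibble(Q = Q, df = n - 1, p = pchisq(Q, df = n - 1, lower.tail = FALSE))
}

#' Configuration for an MR analysis
#'
#' @param methods which estimators to run; any of `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"simple_median"`, `"simple_mode"`,
#'   `"weighted_mode"`.
#' @param n_boot parametric-bootstrap iterations for median/mode standard
#'   errors (>= 1, default 1000).
#' @param phi mode bandwidth factor (> 0, default 1).
#' @param seed one user seed; all bootstrap substreams derive from it.
#' @param heterogeneity attach Cochran's Q to the IVW row.
#' @return an `mr_config` list.
#' @export
mr_config <- function(methods = c("ivw", "egger", "weighted_median",
                                  "simple_mode", "weighted_mode"),
                      n_boot = 1000, phi = 1, seed = 1,
                      heterogeneity = FALSE) {
  known <- c("ivw", "ivw_fixed", "egger", "weighted_median", "simple_median",
             "simple_mode", "weighted_mode")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    abort(paste0("unknown method name(s): ", paste(bad, collapse = ", ")))
  }
  if (n_boot < 1) abort("n_boot must be >= 1")
  if (phi <= 0) abort("phi must be > 0")
  structure(list(methods = methods, n_boot = n_boot, phi = phi, seed = seed,
                 heterogeneity = heterogeneity), class = "mr_config")
}

#' Run a set of MR estimators on a harmonized table
#'
#' Dispatches the configured methods and stacks their result rows.  Results
#' are deterministic under a fixed `cfg$seed`: each method receives its own
#' deterministically derived substream, so the set or order of requested
#' methods does not perturb any individual result.
#'
#' @param h a harmonized table ([harmonize_pair()] output or any data frame
#'   with `beta_exp`, `se_exp`, `beta_out`, `se_out`).
#' @param cfg an [mr_config()].
#' @return an `mr_result` tibble, one row per method: `method`, `estimate`,
#'   `se`, `ci_lower`, `ci_upper`, `p`, `n_snp`, plus Egger intercept and
#'   heterogeneity columns where applicable.
#' @examples
#' h <- data.frame(beta_exp = c(0.1, 0.12, 0.08, 0.11),
#'                 se_exp = 0.01, beta_out = c(0.021, 0.023, 0.017, 0.022),
#'                 se_out = 0.005)
#' run_mr(h, mr_config(methods = c("ivw", "egger"), seed = 7))
#' @export
run_mr <- function(h, cfg = mr_config()) {
  stopifnot(inherits(cfg, "mr_config"))
  seeds <- derive_seeds(cfg$seed, 7)
  rows <- lapply(cfg$methods, function(m) {
    switch(m,
      ivw = mr_ivw(h, heterogeneity = cfg$heterogeneity),
      ivw_fixed = mr_ivw(h, mode = "fixed",
                         heterogeneity = cfg$heterogeneity),
      egger = mr_egger(h),
      weighted_median = mr_median(h, "inverse_variance", cfg$n_boot,
                                  seed = seeds[1]),
      simple_median = mr_median(h, "equal", cfg$n_boot, seed = seeds[2]),
      simple_mode = mr_mode(h, weighted = FALSE, phi = cfg$phi,
                            n_boot = cfg$n_boot, seed = seeds[3]),
      weighted_mode = mr_mode(h, weighted = TRUE, phi = cfg$phi,
                              n_boot = cfg$n_boot, seed = seeds[4]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mr_result", class(out))
  out
}

#' Plot-ready bundle for MR results
#'
#' Per-SNP points (exposure effect, outcome effect) with both error bars,
#' oriented so every exposure effect is non-negative (the Egger convention),
#' plus one line spec per method: the method's slope with a zero intercept
#' for all methods except MR-Egger, which carries its estimated intercept.
#'
#' @param h the harmonized table the results came from.
#' @param results an `mr_result` tibble from [run_mr()].
#' @return a list with `points` (tibble: rsid, beta_exp, se_exp, beta_out,
#'   se_out) and `lines` (tibble: method, slope, intercept).
#' @export
mr_plot_data <- function(h, results) {
  if (nrow(h) == 0) abort("empty harmonized table")
  if (nrow(results) == 0) abort("no MR results to plot")
  flip <- h$beta_exp < 0
  points <- tibble(
    rsid = if ("rsid" %in% names(h)) h$rsid else as.character(seq_len(nrow(h))),
    beta_exp = abs(h$beta_exp), se_exp = h$se_exp,
    beta_out = ifelse(flip, -h$beta_out, h$beta_out), se_out = h$se_out)
  lines <- tibble(method = results$method, slope = results$estimate,
                  intercept = ifelse(results$method == "MR-Egger" &
                                       "intercept" %in% names(results),
                                     results$intercept %null% 0, 0))
  list(points = points, lines = lines)
}

#' Scatter plot of instrument effects with fitted MR lines
#'
#' @param h a harmonized table.
#' @param results an `mr_result` tibble.
#' @return a ggplot object.
#' @export
plot_mr <- function(h, results) {
  pd <- mr_plot_data(h, results)
  ggplot2::ggplot(pd$points,
                  ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_abline(data = pd$lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.mr_result <- function(object, h, ...) plot_mr(h, object)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.mr_result <- function(x, ...) {
  tibble(term = x$method, estimate = x$estimate, std.error = x$se,
         statistic = x$estimate / x$se, p.value = x$p,
         conf.low = x$ci_lower, conf.high = x$ci_upper)
}

#' @exportS3Method generics::glance
glance.mr_result <- function(x, ...) {
  ivw <- x[x$method == "IVW", ]
  tibble(n_methods = nrow(x),
         n_snp = max(x$n_snp),
         ivw_estimate = if (nrow(ivw)) ivw$estimate[1] else NA_real_,
         ivw_p = if (nrow(ivw)) ivw$p[1] else NA_real_)
}
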