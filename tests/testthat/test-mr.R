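test_that("ratio estimates are elementwise Wald ratios", {
  h <- tibble::tibble(beta_exp = c(0.5, -0.2, 0.1, 0.3, 0.25),
                      se_exp = 0.01,
                      beta_out = c(0.1, 0.06, -0.02, 0.09, 0.05),
                      se_out = c(0.05, 0.01, 0.02, 0.03, 0.04))
  rt <- mr_ratios(h)
  expect_equal(rt$ratio, h$beta_out / h$beta_exp)
  expect_equal(rt$se1, h$se_out / abs(h$beta_exp))
  expect_equal(rt$ratio[1], 0.2)
  expect_equal(rt$se1[1], 0.1)
  # joint sign change leaves the ratio unchanged
  h2 <- h; h2$beta_exp <- -h2$beta_exp; h2$beta_out <- -h2$beta_out
  expect_equal(mr_ratios(h2)$ratio, rt$ratio)
  # zero exposure effects are dropped with a warning
  h3 <- h; h3$beta_exp[2] <- 0
  expect_warning(rt3 <- mr_ratios(h3), "zero exposure")
  expect_equal(nrow(rt3), 4)
})

test_that("IVW reduces to the single-SNP Wald ratio and hand example", {
  one <- tibble::tibble(beta_exp = 0.4, se_exp = 0.01, beta_out = 0.1,
                        se_out = 0.02)
  res <- mr_ivw(one, mode = "fixed")
  expect_equal(res$estimate, 0.25)
  expect_equal(res$se, 0.02 / 0.4)
  # two-SNP closed form
  two <- tibble::tibble(beta_exp = c(1, 1), se_exp = 0.01,
                        beta_out = c(0.5, 0.7), se_out = c(0.1, 0.1))
  res2 <- mr_ivw(two, mode = "fixed")
  expect_equal(res2$estimate, 0.6, tolerance = 1e-12)
  expect_equal(res2$se, sqrt(1 / 200), tolerance = 1e-12)
  # random-effects inflation: Q = 2, n - 1 = 1 -> factor sqrt(2)
  res2r <- mr_ivw(two, mode = "multiplicative_random")
  expect_equal(res2r$se, sqrt(1 / 200) * sqrt(2), tolerance = 1e-12)
  expect_error(mr_ivw(one), "at least 2")
})

test_that("IVW equals the weighted regression-through-origin oracle", {
  for (seed in 1:10) {
    h <- random_h(50, seed)
    got <- mr_ivw(h, mode = "fixed")
    fit <- lm(beta_out ~ beta_exp - 1, data = h, weights = 1 / h$se_out^2)
    expect_equal(got$estimate, unname(coef(fit)[1]), tolerance = 1e-10)
    # lm's se uses RSS/(n-1); rescale to the fixed-effect convention
    se_lm <- sqrt(diag(vcov(fit)))[1] / summary(fit)$sigma
    expect_equal(got$se, unname(se_lm), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact line and matches the WLS oracle", {
  col <- tibble::tibble(beta_exp = c(1, 2, 3), se_exp = 0.01,
                        beta_out = c(0.6, 1.1, 1.6), se_out = 0.1)
  res <- mr_egger(col)
  expect_equal(res$intercept, 0.1, tolerance = 1e-10)
  expect_equal(res$estimate, 0.5, tolerance = 1e-10)
  expect_error(mr_egger(col[1:2, ]), "at least 3")
  for (seed in 11:20) {
    h <- random_h(30, seed, pleio_sd = 0.01)
    got <- mr_egger(h)
    w <- 1 / h$se_out^2
    bx <- abs(h$beta_exp)
    by <- ifelse(h$beta_exp < 0, -h$beta_out, h$beta_out)
    fit <- lm(by ~ bx, weights = w)
    expect_equal(got$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(got$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    sig <- summary(fit)$sigma
    infl <- max(1, sig) / sig
    expect_equal(got$se, unname(sqrt(diag(vcov(fit)))[2]) * infl,
                 tolerance = 1e-10)
  }
})

test_that("Egger detects planted directional pleiotropy", {
  set.seed(404)
  n <- 30
  bx <- abs(rnorm(n, 0.1, 0.03))
  sy <- runif(n, 0.004, 0.01)
  by <- 0.05 + 0.3 * bx + rnorm(n, 0, sy)
  h <- tibble::tibble(beta_exp = bx, se_exp = 0.01, beta_out = by,
                      se_out = sy)
  res <- mr_egger(h)
  expect_lt(abs(res$intercept - 0.05), 3 * res$intercept_se)
  expect_lt(res$intercept_p, 0.05)
})

test_that("the weighted median interpolates the ratio order statistics", {
  h <- tibble::tibble(beta_exp = 1, se_exp = 0.01,
                      beta_out = c(0.1, 0.2, 0.9), se_out = 0.1)
  res <- mr_median(h, weights = "equal", n_boot = 50, seed = 1)
  expect_equal(res$estimate, 0.2)   # middle order statistic
  # a ratio carrying nearly all the weight dominates
  h2 <- tibble::tibble(beta_exp = 1, se_exp = 0.01,
                       beta_out = c(0.15, 0.5, 0.8, 0.82),
                       se_out = c(1e-4, 1, 1, 1))
  res2 <- mr_median(h2, weights = "inverse_variance", n_boot = 50, seed = 1)
  expect_equal(res2$estimate, 0.15, tolerance = 1e-3)
  expect_error(mr_median(h[1:2, ]), "at least 3")
})

test_that("median beats IVW under 40% invalid weight (breakdown property)", {
  set.seed(555)
  wins <- 0L
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    n <- 40
    invalid <- seq_len(round(0.4 * n))
    bx <- rnorm(n, 0.12, 0.03)
    sy <- runif(n, 0.004, 0.008)
    alpha <- ifelse(seq_len(n) %in% invalid, 0.02, 0)
    by <- 0.2 * bx + alpha + rnorm(n, 0, sy)
    h <- tibble::tibble(beta_exp = bx, se_exp = 0.01, beta_out = by,
                        se_out = sy)
    med <- mr_median(h, n_boot = 20, seed = r)$estimate
    ivw <- mr_ivw(h)$estimate
    if (abs(med - 0.2) < abs(ivw - 0.2)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- tibble::tibble(beta_exp = 1, se_exp = 0.01,
                      beta_out = c(rep(0.2, 7), rep(1.0, 3)),
                      se_out = 0.05)
  res <- mr_mode(h, weighted = FALSE, phi = 1, n_boot = 50, seed = 2)
  expect_lt(abs(res$estimate - 0.2), 0.01)
  # all ratios identical: degenerate density returns that value
  h2 <- tibble::tibble(beta_exp = 1, se_exp = 0.01,
                       beta_out = rep(0.3, 5), se_out = 0.05)
  res2 <- mr_mode(h2, n_boot = 50, seed = 3)
  expect_equal(res2$estimate, 0.3)
  # all weight on one SNP
  h3 <- tibble::tibble(beta_exp = 1, se_exp = 0.01,
                       beta_out = c(0.4, 0.9, 1.4), se_out = c(1e-5, 1, 1))
  res3 <- mr_mode(h3, weighted = TRUE, n_boot = 50, seed = 4)
  expect_lt(abs(res3$estimate - 0.4), 0.01)
})

test_that("Cochran's Q matches hand arithmetic and is zero when homogeneous", {
  two <- tibble::tibble(beta_exp = c(1, 1), se_exp = 0.01,
                        beta_out = c(0.5, 0.7), se_out = c(0.1, 0.1))
  q <- mr_cochran_q(two, theta = 0.6)
  expect_equal(q$Q, 2.0, tolerance = 1e-12)
  expect_equal(q$df, 1)
  same <- tibble::tibble(beta_exp = c(1, 2, 4), se_exp = 0.01,
                         beta_out = c(0.3, 0.6, 1.2), se_out = 0.1)
  q2 <- mr_cochran_q(same, theta = 0.3)
  expect_equal(q2$Q, 0, tolerance = 1e-12)
  expect_equal(q2$p, 1)
})

test_that("Q is calibrated under the null generative model", {
  set.seed(777)
  stats <- replicate(150, {
    n <- 25
    bx <- rnorm(n, 0.1, 0.03)
    sy <- runif(n, 0.004, 0.01)
    by <- 0.2 * bx + rnorm(n, 0, sy)
    h <- tibble::tibble(beta_exp = bx, se_exp = 0, beta_out = by,
                        se_out = sy)
    q <- mr_cochran_q(h, theta = mr_ivw(h)$estimate)
    c(q$Q / q$df, q$p)
  })
  expect_lt(abs(mean(stats[1, ]) - 1), 0.15)      # Q/df near 1
  ks <- suppressWarnings(ks.test(stats[2, ], "punif"))
  expect_gt(ks$p.value, 0.01)                     # Q-p near uniform
})

test_that("run_mr dispatches, is seed-deterministic and carries heterogeneity", {
  h <- random_h(10, 99)
  cfg <- mr_config(n_boot = 50, seed = 11, heterogeneity = TRUE)
  res <- run_mr(h, cfg)
  expect_equal(nrow(res), 5)
  expect_equal(res$method,
               c("IVW", "MR-Egger", "Weighted median", "Simple mode",
                 "Weighted mode"))
  expect_false(any(is.na(res$Q[res$method == "IVW"])))
  res_again <- run_mr(h, cfg)
  expect_identical(res, res_again)
  expect_error(mr_config(methods = "magic"), "unknown method")
  # estimators are invariant under row permutation
  set.seed(1)
  perm <- sample(10)
  resp <- run_mr(h[perm, ], cfg)
  expect_equal(resp$estimate, res$estimate, tolerance = 1e-12)
})

test_that("bootstrap se stabilizes as n_boot doubles", {
  h <- random_h(30, 321)
  se1 <- mr_median(h, n_boot = 1000, seed = 5)$se
  se2 <- mr_median(h, n_boot = 2000, seed = 5)$se
  expect_lt(abs(se2 - se1) / se1, 0.1)
})

test_that("plot data carries oriented points and per-method lines", {
  h <- random_h(5, 12)
  h$beta_exp[2] <- -h$beta_exp[2]
  res <- run_mr(h, mr_config(methods = c("ivw", "egger"), n_boot = 20,
                             seed = 2))
  pd <- mr_plot_data(h, res)
  expect_equal(nrow(pd$points), 5)
  expect_true(all(pd$points$beta_exp >= 0))
  expect_equal(pd$lines$intercept[pd$lines$method == "IVW"], 0)
  expect_equal(pd$lines$intercept[pd$lines$method == "MR-Egger"],
               res$intercept[res$method == "MR-Egger"])
  p <- plot_mr(h, res)
  expect_s3_class(p, "ggplot")
  expect_error(mr_plot_data(h[0, ], res), "empty")
})

test_that("tidy and glance methods return broom-shaped tibbles", {
  h <- random_h(10, 77)
  res <- run_mr(h, mr_config(methods = c("ivw", "egger"), n_boot = 20,
                             seed = 3))
  td <- generics::tidy(res)
  expect_equal(names(td), c("term", "estimate", "std.error", "statistic",
                            "p.value", "conf.low", "conf.high"))
  gl <- generics::glance(res)
  expect_equal(gl$n_snp, 10)
  expect_equal(gl$ivw_estimate, res$estimate[res$method == "IVW"])
})
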