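test_that("summaries use sample SD and reproduce simple cases", {
  bank <- default_bank_cached()
  pool <- sample_pool(pool_spec(30, bank, default_params_cached(), seed = 2))
  sc <- score_responses(pool, bank)
  sm <- summarize_scores(sc)
  expect_setequal(sm$subtest,
                  c("crt", "rspm", "hbt", "srt_incongruent", "srt_congruent"))
  hbt <- sc$totals$hbt
  expect_equal(sm$mean[sm$subtest == "hbt"], mean(hbt))
  expect_equal(sm$sd[sm$subtest == "hbt"], sd(hbt))
  expect_equal(sm$percent_correct[sm$subtest == "hbt"],
               100 * mean(hbt) / 9)
  expect_error(summarize_scores(sc, character(0)), "empty")
})

test_that("Spearman correlation matches the rank-difference formula", {
  expect_equal(spearman_corr(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_corr(1:8, -(1:8))$rho, -1)
  # tie-free 6-point example against 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(3.1, 0.2, 5.5, 2.2, 9.9, 4.4)
  y <- c(1.0, 4.0, 2.5, 8.0, 0.5, 3.3)
  d <- rank(x) - rank(y)
  rho_formula <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  est <- spearman_corr(x, y)
  expect_equal(est$rho, rho_formula, tolerance = 1e-10)
  tt <- rho_formula * sqrt(4 / (1 - rho_formula^2))
  expect_equal(est$p, 2 * pt(-abs(tt), 4), tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("Welch t: identical groups, raw/summary equivalence, t.test cross-check", {
  w0 <- welch_t(5, 1, 20, 5, 1, 20)
  expect_equal(w0$t, 0)
  expect_equal(sum(w0$ci), 0, tolerance = 1e-12)

  withr::with_seed(6, {
    x <- rnorm(18, 1, 1.3)
    y <- rnorm(33, 0, 0.7)
  })
  wr <- welch_t(x = x, y = y)
  ws <- welch_t(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  expect_equal(wr$t, ws$t, tolerance = 1e-12)
  expect_equal(wr$df, ws$df, tolerance = 1e-12)
  tt <- t.test(x, y)
  expect_equal(wr$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(wr$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(wr$ci, as.vector(tt$conf.int), tolerance = 1e-10)
  expect_error(welch_t(1, 0, 10, 2, 0, 10), "zero")
})

test_that("Welch t reduces to the pooled t for equal SDs and sizes", {
  withr::with_seed(14, {
    for (r in 1:5) {
      x <- rnorm(12); y <- rnorm(12)
      s <- sd(c(x - mean(x), y - mean(y)) )
      w <- welch_t(mean(x), sd(x), 12, mean(y), sd(y), 12)
      # equal n: Welch statistic equals the pooled statistic when s1 = s2;
      # here compare against pooled t with the actual (near-equal-var) data
      pooled <- t.test(x, y, var.equal = TRUE)
      wt <- welch_t(mean(x), sd(x), 12, mean(y), sd(x), 12)
      expect_equal(wt$t, (mean(x) - mean(y)) / (sd(x) * sqrt(2 / 12)),
                   tolerance = 1e-12)
      expect_equal(wt$df, 22, tolerance = 1e-9)
    }
  })
})

test_that("chi-square contrast matches the closed-form 2x2 statistic", {
  bank <- tiny_bank()
  # 10 passed all correct, 10 failed all incorrect -> chi2 = 20
  resp <- make_responses(q1 = c(rep("A", 10), rep("B", 10)),
                         q2 = rep("valid", 20))
  sc_ids <- resp$worker_id
  scr <- structure(list(threshold = 2L, passed = sc_ids[1:10],
                        failed = sc_ids[11:20]), class = "screen_result")
  res <- chisq_pass_fail(resp, "q1", bank, scr)
  a <- 10; b <- 0; cc <- 0; d <- 10; n <- 20
  chi_closed <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(res$statistic, chi_closed, tolerance = 1e-10)
  expect_equal(res$df, 1L)

  # identical correct proportions -> statistic 0
  resp2 <- make_responses(q1 = rep(c("A", "B"), 10), q2 = rep("valid", 20))
  scr2 <- structure(list(threshold = 2L, passed = resp2$worker_id[1:10],
                         failed = resp2$worker_id[11:20]),
                    class = "screen_result")
  expect_equal(chisq_pass_fail(resp2, "q1", bank, scr2)$statistic, 0,
               tolerance = 1e-12)

  # swapping the group labels leaves the statistic unchanged
  scr_sw <- structure(list(threshold = 2L, passed = scr$failed,
                           failed = scr$passed), class = "screen_result")
  expect_equal(chisq_pass_fail(resp, "q1", bank, scr_sw)$statistic,
               res$statistic, tolerance = 1e-12)

  # zero marginal -> degenerate flag
  resp3 <- make_responses(q1 = rep("A", 20), q2 = rep("valid", 20))
  res3 <- chisq_pass_fail(resp3, "q1", bank, scr)
  expect_true(res3$degenerate)
  expect_true(is.na(res3$p))
})

test_that("hierarchical regression matches explicit normal-equations algebra", {
  # 12-row fixture, fixed numbers
  dat <- data.frame(
    y   = c(5.1, 3.2, 6.8, 2.2, 7.7, 4.4, 5.9, 3.3, 6.1, 2.8, 7.2, 4.9),
    age = c(23, 45, 31, 52, 28, 39, 61, 33, 47, 56, 26, 42),
    gen = c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 0),
    edu = c(1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 1, 0),
    iq  = c(108, 95, 112, 90, 118, 101, 99, 97, 110, 92, 116, 103),
    crt = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 1)
  )
  blocks <- list(c("age", "gen", "edu"), "iq", "crt")
  fit <- hierarchical_regression(dat, "y", blocks)

  z <- function(v) (v - mean(v)) / sd(v)
  zd <- as.data.frame(lapply(dat, z))
  for (j in seq_along(blocks)) {
    preds <- unique(unlist(blocks[seq_len(j)]))
    X <- cbind(1, as.matrix(zd[preds]))
    beta <- solve(t(X) %*% X, t(X) %*% zd$y)
    expect_equal(unname(fit[[j]]$coefficients$beta), as.vector(beta),
                 tolerance = 1e-10)
    res <- zd$y - X %*% beta
    r2 <- 1 - sum(res^2) / sum((zd$y - mean(zd$y))^2)
    expect_equal(fit[[j]]$r_squared, r2, tolerance = 1e-10)
  }
  # F change against its definition
  r2_2 <- fit[[2]]$r_squared; r2_3 <- fit[[3]]$r_squared
  dF <- ((r2_3 - r2_2) / 1) / ((1 - r2_3) / (12 - 5 - 1))
  expect_equal(fit[[3]]$delta_f, dF, tolerance = 1e-10)
  expect_equal(fit[[3]]$delta_df, c(1, 6))
  # nested R2 never decreases; adjusted R2 bounded by R2
  expect_true(all(vapply(fit, `[[`, numeric(1), "delta_r_squared") > -1e-12))
  expect_true(all(vapply(fit, function(f) f$adj_r_squared <= f$r_squared,
                         logical(1))))
})

test_that("regression degenerate designs are reported, not silently dropped", {
  dat <- data.frame(y = rnorm(10), a = 1:10)
  dat$b <- dat$a
  expect_error(hierarchical_regression(dat, "y", list(c("a", "b"))),
               "collinear")
  # outcome equal to a block-1 predictor: R2 = 1 then no further gain
  dat2 <- data.frame(y = 1:12 + 0, a = 1:12, q = rnorm(12))
  fit <- suppressWarnings(hierarchical_regression(dat2, "y", list("a", "q")))
  expect_equal(fit[[1]]$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit[[2]]$delta_r_squared, 0, tolerance = 1e-10)
})

test_that("IQ mapping is a pool-referenced affine rescaling", {
  expect_equal(estimate_iq(5, 5, 2), 100)
  expect_equal(estimate_iq(7, 5, 2), 115)
  expect_error(estimate_iq(5, 5, 0), "positive")

  # affine invariance: standardized coefficients identical for raw vs mapped
  withr::with_seed(23, {
    dat <- data.frame(y = rnorm(40), rspm = sample(0:9, 40, TRUE),
                      g = rbinom(40, 1, 0.5))
  })
  dat$iq <- estimate_iq(dat$rspm, mean(dat$rspm), sd(dat$rspm))
  f_raw <- hierarchical_regression(dat, "y", list(c("g", "rspm")))
  f_iq <- hierarchical_regression(dat, "y", list(c("g", "iq")))
  expect_equal(f_raw[[1]]$coefficients$beta, f_iq[[1]]$coefficients$beta,
               tolerance = 1e-10)
})

test_that("orthogonal predictors keep their zero-order correlation as beta", {
  withr::with_seed(29, {
    x1 <- rnorm(64)
    x2 <- rnorm(64)
    x2 <- resid(lm(x2 ~ x1))  # exactly orthogonal in-sample
    y <- 0.5 * x1 + 0.3 * x2 + rnorm(64, sd = 0.4)
  })
  dat <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- hierarchical_regression(dat, "y", list(c("x1", "x2")))
  co <- fit[[1]]$coefficients
  expect_equal(co$beta[co$term == "x2"], cor(y, x2), tolerance = 1e-10)
})
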