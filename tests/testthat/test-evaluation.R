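test_that("error_percent follows the signed printed formula", {
  expect_equal(error_percent(2.0, 1.8), 10)
  expect_equal(error_percent(c(1.5, 3), c(1.5, 3)), c(0, 0))
  expect_equal(error_percent(2, 2.5), -25)
  expect_error(error_percent(0, 1), "0")
  expect_error(error_percent(1:3, 1:2), "length mismatch")
})

test_that("fit_metrics matches definitions and the PRESS oracle", {
  obs <- c(1, 2, 3, 4, 5)
  expect_equal(fit_metrics(obs, obs, p = 2)$r2, 1)
  expect_equal(fit_metrics(obs, obs, p = 2)$rmse, 0)
  expect_equal(fit_metrics(obs, rep(mean(obs), 5), p = 1)$r2, 0)
  expect_error(fit_metrics(obs, obs, p = 5), "n > p")
  expect_error(fit_metrics(rep(1, 5), rep(1, 5), p = 2), "zero variance")

  set.seed(50)
  x <- matrix(rnorm(40), 20, 2)
  y <- 1 + x %*% c(2, -1) + rnorm(20, 0, 0.5)
  design <- cbind(1, x)
  fit <- lm.fit(design, y)
  pred <- design %*% fit$coefficients
  fm <- fit_metrics(as.numeric(y), as.numeric(pred), p = 3, design = design)
  expect_equal(fm$press, brute_press(x, as.numeric(y)), tolerance = 1e-9)
  expect_gte(fm$press, sum((y - pred)^2))  # PRESS dominates SSE
  # SSE-form information criteria
  sse <- sum((y - pred)^2)
  expect_equal(fm$aic, 20 * log(sse / 20) + 2 * 3)
  expect_equal(fm$bic, 20 * log(sse / 20) + 3 * log(20))
  expect_equal(fm$ase, sse / 20)
  expect_equal(fm$rmse, sqrt(sse / 17))
})

test_that("r2 is invariant to affine rescaling of trait units", {
  set.seed(51)
  obs <- rnorm(30, 10, 2)
  pred <- obs + rnorm(30, 0, 1)
  f1 <- fit_metrics(obs, pred, p = 2)
  f2 <- fit_metrics(2.54 * obs + 7, 2.54 * pred + 7, p = 2)
  expect_equal(f1$r2, f2$r2)
})

test_that("validation statistics match independent recomputation", {
  obs <- c(1.2, 2.5, 3.1, 4.0)
  vs <- validation_stats(obs, obs + 1)
  expect_equal(vs$mean_error, 1)
  expect_equal(vs$sd_error, 0)
  vs2 <- validation_stats(obs, obs)
  expect_equal(vs2$mean_error, 0)
  expect_equal(vs2$sd_error, 0)
  expect_equal(vs2$r2, 1)

  set.seed(52)
  pred <- obs * 1.1 + rnorm(4, 0, 0.3)
  vs3 <- validation_stats(obs, pred)
  err <- pred - obs
  expect_equal(vs3$mean_error, sum(err) / 4, tolerance = 1e-9)
  expect_equal(vs3$sd_error, sqrt(sum((err - mean(err))^2) / 3),
               tolerance = 1e-9)
  expect_equal(vs3$r2, textbook_r(obs, pred)^2, tolerance = 1e-9)
  expect_error(validation_stats(obs, pred[1:3]), "length mismatch")
})

test_that("pearson_r agrees with the textbook formula", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  set.seed(53)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pearson_r(x, y), textbook_r(x, y))
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("paired t-test matches hand computation and null behaviour", {
  a <- c(2.1, 3.4, 1.8, 4.2, 3.0)
  b <- c(1.9, 3.9, 1.5, 4.8, 2.6)
  ht <- paired_t_test(a, b)
  expect_equal(ht$t, hand_paired_t(a, b), tolerance = 1e-9)
  expect_equal(ht$df, 4)
  expect_equal(ht$p_value,
               2 * pt(abs(hand_paired_t(a, b)), 4, lower.tail = FALSE),
               tolerance = 1e-9)

  set.seed(54)
  x <- rnorm(200)
  expect_gt(paired_t_test(x, x + rnorm(200, 0, 0.5))$p_value, 0.05)
  expect_error(paired_t_test(a, a), "zero-variance")
})

test_that("anova_tukey separates strong effects and not null groups", {
  set.seed(55)
  g <- rep(c("A", "B", "C"), each = 10)
  null_vals <- rnorm(30)
  tk0 <- anova_tukey(null_vals, g)
  expect_true(all(tk0$letters == tk0$letters[1]))  # one shared letter

  vals <- rnorm(30, ifelse(g == "C", 10, 0), 1)  # 10 pooled SDs apart
  tk1 <- anova_tukey(vals, g)
  expect_false(tk1$letters["C"] %in% tk1$letters[c("A", "B")])
  expect_lt(tk1$p_value, 1e-6)

  # symmetric under relabeling
  relab <- c(A = "Z", B = "Y", C = "X")[g]
  tk2 <- anova_tukey(vals, relab)
  expect_identical(unname(tk2$letters[c("Z", "Y", "X")]),
                   unname(tk1$letters[c("A", "B", "C")]))
  expect_error(anova_tukey(rnorm(5), rep("A", 5)), "2 groups")
  expect_error(anova_tukey(rnorm(3), c("A", "A", "B")), "at least 2 values")
})

test_that("cubic yield regression matches its oracle", {
  set.seed(56)
  lai <- runif(30, 0.8, 2.6)
  exact <- 1500 + 1800 * lai - 150 * lai^2 + 8 * lai^3
  yf <- suppressWarnings(fit_yield_cubic(lai, exact))  # perfect-fit warning
  expect_equal(yf$r2, 1)
  expect_equal(yf$coefficients, c(1500, 1800, -150, 8), tolerance = 1e-6)

  yf0 <- fit_yield_cubic(lai, rep(4000, 30))
  expect_equal(yf0$r2, 0)
  expect_false(yf0$significant)

  noisy <- exact + rnorm(30, 0, 100)
  yf2 <- fit_yield_cubic(lai, noisy)
  pred <- cbind(1, lai, lai^2, lai^3) %*% yf2$coefficients
  expect_equal(yf2$r2, r_squared(noisy, as.numeric(pred)), tolerance = 1e-9)
  expect_true(yf2$significant)
  expect_error(fit_yield_cubic(rep(1, 10), rnorm(10)), "constant trait")
  expect_error(fit_yield_cubic(1:4, 1:4), "at least 5")
})
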