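test_that("frozen models carry the published constants", {
  r1 <- frozen_model("reg1")
  expect_equal(r1$coefficients,
               c(28.82, 13.77, -7.91, 14.88, 25.86))
  expect_identical(r1$intercept, -39.74)
  expect_identical(r1$trait, "LAI")

  r2 <- frozen_model("reg2")
  expect_identical(r2$coefficients, 505.84)
  expect_identical(r2$intercept, 0.134)
  expect_identical(r2$mode, "product")
  expect_setequal(r2$predictor_names, c("bgi", "ppr", "nppr", "ngrdi", "ncpi"))

  r3 <- frozen_model("reg3")
  expect_identical(r3$intercept, -144.24)
  expect_equal(r3$coefficients[r3$predictor_names == "nppr"], 254.26)

  r4 <- frozen_model("reg4")
  expect_identical(r4$coefficients, 3372.55)
  expect_identical(r4$intercept, 19.96)
  expect_identical(r4$trait, "LG")

  expect_error(frozen_model("reg9"), "unknown model id")
})

test_that("estimate_trait evaluates both modes and flags negatives", {
  zeros <- as.data.frame(setNames(as.list(rep(0, 6)), vi_names()))
  e1 <- estimate_trait(zeros, frozen_model("reg1"))
  expect_equal(as.numeric(e1), -39.74)
  expect_true(attr(e1, "below_zero"))

  e4 <- estimate_trait(zeros, frozen_model("reg4"))
  expect_equal(as.numeric(e4), 19.96)
  expect_false(attr(e4, "below_zero"))

  vi <- data.frame(bgi = 0.25, ppr = 0.6, ngrdi = 1 / 3, ncpi = 1 / 3,
                   nppr = 4 / 3)
  expect_equal(as.numeric(estimate_trait(vi, frozen_model("reg1"))),
               12.53, tolerance = 1e-3)
  expect_error(estimate_trait(vi[, -1], frozen_model("reg1")),
               "missing predictor")
})

test_that("sum-mode estimates are affine with slope equal to the coefficient", {
  model <- frozen_model("reg1")
  vi <- generate_vi_table(1, "reg1", 0, seed = 4)[, vi_names()]
  base <- as.numeric(estimate_trait(vi, model))
  for (k in seq_along(model$predictor_names)) {
    vip <- vi
    vip[[model$predictor_names[k]]] <- vip[[model$predictor_names[k]]] + 1
    expect_equal(as.numeric(estimate_trait(vip, model)) - base,
                 model$coefficients[k])
  }
})

test_that("OLS refit on noiseless frozen-model tables recovers all constants", {
  specs <- list(reg1 = list(trait = "LAI", mode = "sum"),
                reg2 = list(trait = "LAI", mode = "product"),
                reg3 = list(trait = "LG", mode = "sum"),
                reg4 = list(trait = "LG", mode = "product"))
  for (id in names(specs)) {
    frozen <- frozen_model(id)
    tab <- generate_vi_table(200, id, 0, seed = 17)
    refit <- fit_linear_trait_model(tab, specs[[id]]$trait,
                                    frozen$predictor_names, specs[[id]]$mode)
    expect_equal(refit$coefficients, frozen$coefficients, tolerance = 1e-6)
    expect_equal(refit$intercept, frozen$intercept, tolerance = 1e-6)
  }
})

test_that("OLS refit is invariant to duplicating rows and rejects collinearity", {
  tab <- generate_vi_table(60, "reg1", 0.1, seed = 21)
  fit1 <- fit_linear_trait_model(tab, "LAI", reg1_predictors, "sum")
  fit2 <- fit_linear_trait_model(rbind(tab, tab), "LAI", reg1_predictors, "sum")
  expect_equal(fit2$coefficients, fit1$coefficients)
  expect_equal(fit2$intercept, fit1$intercept)

  tab$dup <- 2 * tab$bgi
  tab2 <- tab
  tab2$rgr <- 2 * tab2$bgi  # perfectly collinear pair among candidates
  expect_error(fit_linear_trait_model(tab2, "LAI", c("bgi", "rgr"), "sum"),
               "rank-deficient")
  expect_error(fit_linear_trait_model(tab[1:5, ], "LAI", reg1_predictors,
                                      "sum"), "more rows")
})

test_that("OLS coefficients are unbiased and shrink like 1/sqrt(n)", {
  frozen <- frozen_model("reg1")
  set.seed(31)
  rmse <- sapply(c(50, 800), function(n) {
    est <- replicate(200, {
      tab <- generate_vi_table(n, "reg1", 0.5,
                               seed = sample.int(1e6, 1))
      fit_linear_trait_model(tab, "LAI", reg1_predictors, "sum")$coefficients[1]
    })
    c(mean = mean(est), se = sd(est) / sqrt(length(est)), rmse = sd(est))
  })
  # unbiased within 3 Monte-Carlo standard errors at both sizes
  expect_lt(abs(rmse["mean", 1] - 28.82), 3 * rmse["se", 1])
  expect_lt(abs(rmse["mean", 2] - 28.82), 3 * rmse["se", 2])
  # 16x more rows: RMSE ratio near 4
  expect_gt(rmse["rmse", 1] / rmse["rmse", 2], 3.2)
  expect_lt(rmse["rmse", 1] / rmse["rmse", 2], 5.0)
})

test_that("stepwise selection recovers the true predictor sets", {
  tab1 <- generate_vi_table(300, "reg1", 0, seed = 12)
  sw1 <- stepwise_select(tab1, "LAI")
  expect_setequal(sw1$selected, reg1_predictors)
  expect_false("rgr" %in% sw1$selected)

  tab3 <- generate_vi_table(300, "reg3", 0, seed = 13)
  sw3 <- stepwise_select(tab3, "LG")
  expect_setequal(sw3$selected, reg3_predictors)

  # accepted steps never increase the criterion
  expect_true(all(diff(sw1$criterion_path) < 0))

  # trait independent of every candidate: intercept-only selection
  set.seed(14)
  tab0 <- generate_vi_table(200, "reg1", 0, seed = 14)
  tab0$LAI <- rnorm(200)
  sw0 <- stepwise_select(tab0, "LAI")
  expect_length(sw0$selected, 0L)
})

test_that("model JSON round trip preserves the model", {
  for (id in c("reg1", "reg2", "reg3", "reg4")) {
    m <- frozen_model(id)
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    m2 <- read_model_json(path)
    expect_identical(m2$coefficients, m$coefficients)
    expect_identical(m2$intercept, m$intercept)
    expect_identical(m2$predictor_names, m$predictor_names)
    expect_identical(m2$mode, m$mode)
  }
})
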