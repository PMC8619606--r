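test_that("noiseless polynomial data are fit exactly", {
  x <- seq(1, 6, by = 0.5)
  m2 <- fit_pla_model(x, 2 * x^2 + 3, degree = 2)
  expect_equal(m2$r2, 1.0, tolerance = 1e-12)
  expect_equal(m2$rmse, 0, tolerance = 1e-8)
  expect_equal(unname(m2$coefficients[c("b0", "b1", "b2")]), c(3, 0, 2),
               tolerance = 1e-8)

  m1 <- fit_pla_model(1:5, 1:5, degree = 1)
  expect_equal(unname(m1$coefficients[["b1"]]), 1, tolerance = 1e-12)
  expect_equal(unname(m1$coefficients[["b0"]]), 0, tolerance = 1e-12)
  expect_equal(m1$r2, 1.0)

  expect_error(fit_pla_model(rep(2, 10), 1:10), "constant")
  expect_error(fit_pla_model(1:3, 1:3, degree = 2), "at least")
  expect_error(fit_pla_model(1:3, 1:4), "equal length")
})

test_that("a noisy generating line is recovered within three standard errors", {
  set.seed(314)
  x <- runif(60, 5, 15)
  y <- 20 * x - 50 + rnorm(60, 0, 8)
  m <- fit_pla_model(x, y, degree = 1)
  fit <- lm(y ~ x)
  se <- summary(fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(m$coefficients[["b1"]] - 20), 3 * se)
  expect_lt(m$p_value, 1e-6)
})

test_that("the quadratic fit never explains less variance than the linear fit", {
  set.seed(2718)
  for (i in 1:10) {
    x <- runif(25, 0, 10)
    y <- 3 * x + rnorm(25, 0, 5) + i * 0.1 * x^2
    expect_gte(fit_pla_model(x, y, 2)$r2, fit_pla_model(x, y, 1)$r2 - 1e-12)
  }
})

test_that("model RMSE agrees with the calibration module's definition", {
  set.seed(12)
  x <- runif(30, 5, 15)
  y <- 10 * x + rnorm(30, 0, 10)
  m <- fit_pla_model(x, y, degree = 2)
  expect_equal(m$rmse, rmse(evaluate_model(m, x), y), tolerance = 1e-12)
})

test_that("published equations evaluate with their printed coefficients", {
  pm <- published_models()
  expect_equal(nrow(pm), 11)
  expect_false(any(c("alpha", "beta") %in% pm$predictor))  # discarded
  dsl1 <- pm[pm$predictor == "DSL1", ]
  expect_equal(dsl1$b1, 18.38)
  expect_equal(dsl1$b0, 64.325)
  expect_equal(dsl1$r2, 0.485)
  expect_equal(dsl1$p_value, 0.0103)

  expect_equal(evaluate_model(pm[pm$predictor == "VL1", ], 0), -92.945)
  expect_equal(evaluate_model(pm[pm$predictor == "MR", ], 0), 1.035)
  expect_equal(evaluate_model(pm[pm$predictor == "VL2", ], 5.80),
               37.68 * 5.80 - 111.21)
  # quadratic evaluation uses all three coefficients
  expect_equal(evaluate_model(pm[pm$predictor == "MR", ], 10),
               1.2284 * 100 - 0.1746 * 10 + 1.035)
})

test_that("model selection keeps informative descriptors and discards the angles", {
  # area depends linearly on VL2 and on nothing else directly; angles carry
  # no information at all
  smp <- sample_cultivar(cultivar_presets()$CS, n = 60, seed = 55, cv = 0)
  smp$SLA_cm2 <- 37 * smp$VL2 - 100
  sel <- model_selection(smp, alpha_level = 0.05)
  expect_true(all(c("alpha", "beta") %in% sel$discarded))
  expect_equal(sel$models$predictor[1], "VL2")  # exact relation: rank 1 by RMSE
  expect_lt(sel$models$rmse[1], 1e-8)
  expect_equal(sel$models$r2[1], 1, tolerance = 1e-10)
  # ranking is by ascending RMSE
  expect_true(!is.unsorted(sel$models$rmse))
})

test_that("fully size-coupled noiseless data keep every length descriptor", {
  smp <- make_allometric_sample(ka_true = 0.95, n = 40, seed = 77, cv = 0,
                                size_cor = 0.995)
  sel <- model_selection(smp)
  lens <- c("MR", "VL1", "VR1", "DV1", "VL2", "VR2", "DV2",
            "DSL1", "DSR1", "DSL2", "DSR2")
  expect_true(all(lens %in% sel$models$predictor))
  expect_true(all(sel$models$r2[sel$models$predictor %in% lens] > 0.9))
})

test_that("everything discarded yields an empty ranking with a warning", {
  set.seed(6)
  df <- data.frame(MR = runif(20, 5, 15), SLA_cm2 = runif(20, 50, 150))
  # pure noise: force discard by an extreme threshold
  expect_warning(sel <- model_selection(df, alpha_level = 1e-12,
                                        predictors = "MR"),
                 "discarded")
  expect_equal(nrow(sel$models), 0)
})

test_that("the published models show the left-side advantage", {
  sc <- side_comparison(published_models())
  p <- sc$pairs
  vl1 <- p[p$left == "VL1", ]
  expect_equal(vl1$winner, "left")
  expect_equal(vl1$r2_left, 0.988)
  expect_equal(vl1$r2_right, 0.739)
  dsl2 <- p[p$left == "DSL2", ]
  expect_equal(dsl2$winner, "left")
  expect_equal(dsl2$r2_left, 0.806)
  expect_equal(dsl2$r2_right, 0.752)
  expect_equal(sc$overall, "left")

  expect_error(side_comparison(data.frame(predictor = "MR", r2 = 1,
                                          rmse = 0)),
               "pair")
})
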