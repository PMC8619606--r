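test_that("leaf size classification matches the published class assignments", {
  expect_equal(classify_leaf_size(9753)$name, "Mesophyll")
  expect_equal(classify_leaf_size(9753)$code, "8.5")
  expect_equal(classify_leaf_size(21617)$name, "Macrophyll")
  # boundary convention: 18,225 mm^2 belongs to the upper class
  expect_equal(classify_leaf_size(18225)$code, "8.6")
  expect_equal(classify_leaf_size(18224.999)$code, "8.5")
  # unit coherence: cm^2 input is converted, not reinterpreted
  expect_equal(classify_leaf_size(97.53, unit = "cm2")$code,
               classify_leaf_size(9753)$code)
  # out-of-scale areas are reported, not thrown
  expect_equal(classify_leaf_size(100)$code, "unclassified")
  expect_equal(classify_leaf_size(2e5)$code, "unclassified")
  expect_error(classify_leaf_size(-5), "positive")
})

test_that("classification partitions the configured range", {
  set.seed(3)
  areas <- runif(500, 4500, 164025 - 1e-9)
  cls <- classify_leaf_size(areas)
  expect_true(all(cls$code %in% c("8.5", "8.6")))
  expect_true(all((areas < 18225) == (cls$code == "8.5")))
})

test_that("leaf CSV write/read round trips bit-exactly", {
  smp <- lapply(c("CS", "Vi"), function(cu)
    sample_cultivar(cultivar_presets()[[cu]], n = 8, seed = 13, cv = 0.05))
  path <- tempfile(fileext = ".csv")
  write_leaves(smp, path)
  back <- read_leaves(path)
  expect_length(back, 2)
  expect_equal(names(back), c("CS", "Vi"))
  for (i in 1:2) {
    expect_s3_class(back[[i]], "cultivar_sample")
    expect_equal(as.data.frame(back[[i]]), as.data.frame(smp[[i]]),
                 tolerance = 0)  # identical decimal values
  }
})

test_that("CSV reading reports schema problems precisely", {
  smp <- sample_cultivar(cultivar_presets()$CS, n = 4, seed = 2)
  path <- tempfile(fileext = ".csv")
  df <- as.data.frame(smp)
  df$SLA_cm2 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_leaves(path), "SLA_cm2")

  df <- as.data.frame(smp)
  df$operator <- "AB"
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(read_leaves(path), "operator")

  df <- as.data.frame(smp)
  df$MR <- as.character(df$MR)
  df$MR[3] <- "9;21"  # malformed numeric under the documented schema
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_leaves(path), "'MR', row 3")
})

test_that("a six-cultivar synthetic file splits into six samples of thirty", {
  smp <- lapply(cultivar_presets(), sample_cultivar, n = 30, seed = 61,
                cv = 0.05)
  path <- tempfile(fileext = ".csv")
  write_leaves(smp, path)
  back <- read_leaves(path)
  expect_length(back, 6)
  expect_true(all(vapply(back, nrow, integer(1)) == 30))
})

test_that("the pipeline is deterministic and structurally complete", {
  smp <- lapply(cultivar_presets()[c("CS", "MH", "Vi")], sample_cultivar,
                n = 20, seed = 71, cv = 0.05)
  cfg <- pipeline_config()
  r1 <- run_pipeline(cfg, smp)
  r2 <- run_pipeline(cfg, smp)
  expect_identical(r1, r2)
  expect_length(r1$calibration, 3)
  expect_equal(nrow(r1$blocks), 3 * 2 * cfg$window)  # cultivars x constants
  expect_equal(nrow(r1$selected), 6)
  expect_s3_class(r1$models, "pla_model_selection")
  expect_equal(nrow(r1$size_class), 3)
  # report printing is exercised without error
  expect_output(print(r1), "surface constants")
})

test_that("an allometric dataset recovers its constant for every cultivar", {
  smp <- lapply(cultivar_presets(), function(p)
    sample_cultivar(p, n = 20, seed = 81, area_rule = "allometric",
                    ka_true = 0.97, cv = 0, dv_choice = "DV1"))
  rep <- run_pipeline(pipeline_config(), smp)
  sel <- rep$selected
  expect_true(all(sel$selected_KA[sel$constant == "KA1"] == 0.97))
})

test_that("pipeline inputs can come straight from a CSV path", {
  smp <- sample_cultivar(cultivar_presets()$CS, n = 12, seed = 91, cv = 0.05)
  path <- tempfile(fileext = ".csv")
  write_leaves(smp, path)
  rep <- run_pipeline(pipeline_config(), path)
  expect_equal(rep$selected$cultivar, c("CS", "CS"))
  expect_equal(rep$size_class$name, "Mesophyll")
})

test_that("configuration rejects invalid settings", {
  expect_error(pipeline_config(ka_grid = list(min = 0.5, max = 1.5, step = 0)))
  expect_error(pipeline_config(alpha_level = 1.5))
  expect_error(pipeline_config(ruler_step = -1))
  expect_error(run_pipeline(pipeline_config(), list()), "no samples")
})
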