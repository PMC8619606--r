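test_that("descriptor validation rejects infeasible leaves with a named diagnostic", {
  d <- unclass(cs_mean_descriptors())
  expect_silent(validate_descriptors(d))

  bad <- d; bad[["DSR1"]] <- bad[["VR1"]] + 1  # sinus beyond both flanking tips
  expect_error(validate_descriptors(bad), "DSR1")
  expect_error(build_leaf_shape(structure(bad, class = "leaf_descriptors")),
               "DSR1")

  bad <- d; bad[["MR"]] <- -1
  expect_error(validate_descriptors(bad), "MR")
  bad <- d; bad[["alpha"]] <- 95
  expect_error(validate_descriptors(bad), "alpha")
  bad <- d[-1]
  expect_error(validate_descriptors(bad), "MR")
})

test_that("ruler quantization rounds lengths half away from zero and leaves angles alone", {
  d <- leaf_descriptors(9.213, 7.54, 7.92, 10.82, 5.80, 5.94, 11.52,
                        3.69, 3.49, 3.52, 3.57, 44.46, 54.91)
  q <- quantize_ruler(d, step = 0.05)
  expect_equal(q[["MR"]], 9.20)
  d2 <- d; d2[["MR"]] <- 9.225
  expect_equal(quantize_ruler(d2, step = 0.05)[["MR"]], 9.25)  # half-up tie
  expect_equal(q[["alpha"]], 44.46)
  expect_equal(q[["beta"]], 54.91)
  expect_error(quantize_ruler(d, step = 0), "positive")
  expect_error(quantize_ruler(d, step = -0.1), "positive")
})

test_that("a symmetric descriptor set builds a mirror-symmetric outline", {
  d <- leaf_descriptors(9, 7.5, 7.5, 10, 5.5, 5.5, 11,
                        3.5, 3.5, 3.3, 3.3, 45, 50)
  sh <- build_leaf_shape(d, left_angle_factor = 1)
  L <- sh$landmarks
  pairs <- rbind(c("VL1", "VR1"), c("VL2", "VR2"),
                 c("SL1", "SR1"), c("SL2", "SR2"))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(L[pairs[i, 1], "x"], -L[pairs[i, 2], "x"], tolerance = 1e-12)
    expect_equal(L[pairs[i, 1], "y"], L[pairs[i, 2], "y"], tolerance = 1e-12)
  }
  expect_equal(unname(L["MR", "x"]), 0, tolerance = 1e-12)
  m <- measure_descriptors(sh)
  expect_equal(m[["DSL1"]], m[["DSR1"]], tolerance = 1e-12)
})

test_that("the mean-descriptor leaf builds a valid 10-vertex polygon with the frozen area", {
  sh <- build_leaf_shape(cs_mean_descriptors())
  expect_s3_class(sh, "leaf_shape")
  expect_equal(nrow(sh$outline) - 1, 10)
  # against the independent shoelace oracle on the emitted vertices, and
  # against the frozen regression value
  a <- polygon_area(sh)
  expect_equal(a, shoelace_oracle(sh$outline), tolerance = 1e-12)
  expect_equal(a, 45.23175387, tolerance = 1e-7)
})

test_that("polygon_area is the shoelace area and rejects degenerate input", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1.0)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(polygon_area(tri), 6.0)
  # orientation independent
  expect_equal(polygon_area(tri[3:1, ]), 6.0)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("mirror reflection leaves the polygon area unchanged", {
  set.seed(42)
  for (i in 1:20) {
    sh <- build_leaf_shape(random_feasible_descriptors())
    v <- sh$outline
    mirrored <- cbind(-v[, 1], v[, 2])
    expect_equal(polygon_area(mirrored), polygon_area(sh), tolerance = 1e-12)
  }
})

test_that("the self-intersection detector finds crossing outlines", {
  bowtie <- rbind(a = c(0, 0), b = c(1, 1), c = c(1, 0), d = c(0, 1))
  bowtie <- rbind(bowtie, bowtie[1, , drop = FALSE])
  hit <- vineleaf:::polygon_self_intersection(bowtie)
  expect_false(is.null(hit))
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_null(vineleaf:::polygon_self_intersection(square))
})

test_that("rasterization fills pixel centres and pixel_area counts them", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  r <- rasterize(sq, 0.5)
  expect_equal(sum(r$grid), 4)  # grid aligned to the square: 4 interior centres
  expect_equal(pixel_area(r), 1.0)
  expect_error(rasterize(sq, 2), "extent")
  expect_error(rasterize(sq, 0), "positive")

  empty <- r; empty$grid[] <- FALSE
  expect_equal(pixel_area(empty), 0.0)

  set.seed(7)
  for (i in 1:5) {
    sh <- build_leaf_shape(random_feasible_descriptors())
    expect_gte(sum(rasterize(sh, 0.2)$grid), 1)
    pa <- pixel_area(rasterize(sh, 0.025))
    expect_lt(abs(pa - polygon_area(sh)) / polygon_area(sh), 0.05)
  }
})

test_that("pixel area of the mean-descriptor leaf matches the exact area at fine pitch", {
  sh <- build_leaf_shape(cs_mean_descriptors())
  pa <- pixel_area(rasterize(sh, 0.01))
  expect_lt(abs(pa - polygon_area(sh)) / polygon_area(sh), 0.005)
})

test_that("measure_descriptors inverts build_leaf_shape", {
  d <- cs_mean_descriptors()
  m <- measure_descriptors(build_leaf_shape(d))
  gen <- c("MR", "VL1", "VR1", "VL2", "VR2",
           "DSL1", "DSR1", "DSL2", "DSR2", "alpha", "beta")
  expect_equal(unclass(m)[gen], unclass(d)[gen], tolerance = 1e-9)

  # DV1 fixed by direct coordinate arithmetic on the emitted tips
  L <- build_leaf_shape(d)$landmarks
  dv1 <- sqrt(sum((L["VL1", ] - L["VR1", ])^2))
  expect_equal(m[["DV1"]], dv1, tolerance = 1e-12)
  expect_equal(m[["DV1"]], 10.83175254, tolerance = 1e-7)  # frozen

  # asymmetric skeletons round-trip too
  m2 <- measure_descriptors(build_leaf_shape(d, left_angle_factor = 1.15))
  expect_equal(unclass(m2)[gen], unclass(d)[gen], tolerance = 1e-9)

  sh <- build_leaf_shape(d)
  sh$landmarks <- NULL
  expect_error(measure_descriptors(sh), "landmark")
})

test_that("smoothing keeps landmarks on the outline and areas comparable", {
  d <- cs_mean_descriptors()
  sm <- build_leaf_shape(d, smoothing = TRUE, smooth_points = 16)
  plain <- build_leaf_shape(d)
  # every landmark must still lie on the smoothed outline
  for (nm in rownames(plain$landmarks)) {
    gap <- min(sqrt(rowSums(sweep(sm$outline, 2,
                                  plain$landmarks[nm, ])^2)))
    expect_lt(gap, 1e-8)
  }
  expect_lt(abs(polygon_area(sm) - polygon_area(plain)) / polygon_area(plain),
            0.15)
})

test_that("shape and raster exports round-trip their payloads", {
  sh <- build_leaf_shape(cs_mean_descriptors())
  csv <- tempfile(fileext = ".csv")
  write_shape_csv(sh, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(sh$outline))
  expect_equal(back$x_cm, unname(sh$outline[, 1]))

  skip_if_not_installed("png")
  skip_if_not_installed("jsonlite")
  r <- rasterize(sh, 0.05)
  p <- tempfile(fileext = ".png")
  write_raster_png(r, p)
  img <- png::readPNG(p)
  expect_equal(sum(img == 0), sum(r$grid))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$pixel_pitch_cm, 0.05)
})
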