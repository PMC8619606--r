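#' Fit a polynomial leaf-area prediction model
#'
#' Ordinary least squares of reference area on a single descriptor, linear
#' (`degree = 1`) or quadratic (`degree = 2`). Accuracy statistics follow
#' the conventions used throughout the package: R-squared as the
#' explained-variance fraction, the p-value of the overall F test, and the
#' RMSE of the fitted residuals with population normalization (divide by
#' n), matching the calibration module's [rmse()].
#'
#' @param x descriptor values (cm or degrees).
#' @param y reference leaf areas (cm^2).
#' @param degree 1 or 2.
#' @param predictor optional descriptor name carried in the result.
#' @return An object of class `pla_model`: list with `predictor`, `degree`,
#'   `coefficients` (named `b0`, `b1`, `b2`; `b2` absent for degree 1),
#'   `r2`, `adj_r2`, `p_value`, `rmse`, `n`.
#' @examples
#' m <- fit_pla_model(1:6, 2 * (1:6)^2 + 3, degree = 2)
#' m$r2      # 1
#' m$rmse    # ~0
#' @export
fit_pla_model <- function(x, y, degree = 1, predictor = NA_character_) {
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < degree + 2) stop("need at least degree + 2 = ", degree + 2, " points")
  if (stats::var(x) == 0) stop("constant predictor: cannot fit")
  fit <- if (degree == 1) stats::lm(y ~ x) else stats::lm(y ~ x + I(x^2))
  sm <- suppressWarnings(summary(fit))  # noiseless data: perfect-fit warning
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_
       else stats::pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
                      lower.tail = FALSE)
  co <- stats::coef(fit)
  coefs <- c(b0 = unname(co[1]), b1 = unname(co[2]))
  if (degree == 2) coefs <- c(coefs, b2 = unname(co[3]))
  structure(list(predictor = predictor, degree = degree,
                 coefficients = coefs,
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 p_value = as.numeric(p),
                 rmse = sqrt(mean(stats::residuals(fit)^2)), n = n),
            class = "pla_model")
}

#' Evaluate a prediction model at a descriptor value
#'
#' Polynomial evaluation `PLA = b0 + b1 x (+ b2 x^2)`. Accepts a fitted
#' `pla_model` or one row of [published_models()].
#'
#' @param model a `pla_model` or a single-row data frame with columns
#'   `b0`, `b1`, `b2` (`b2` may be `NA` for linear models).
#' @param x descriptor value(s).
#' @return predicted leaf area (cm^2), vectorized over `x`.
#' @examples
#' pm <- published_models()
#' evaluate_model(pm[pm$predictor == "VL2", ], 5.80)  # 107.334
#' @export
evaluate_model <- function(model, x) {
  if (inherits(model, "pla_model")) {
    co <- model$coefficients
    b0 <- co[["b0"]]; b1 <- co[["b1"]]
    b2 <- if ("b2" %in% names(co)) co[["b2"]] else 0
  } else if (is.data.frame(model) && nrow(model) == 1) {
    b0 <- model$b0; b1 <- model$b1
    b2 <- if (!is.null(model$b2) && !is.na(model$b2)) model$b2 else 0
  } else stop("model must be a pla_model or a single-row model table")
  b0 + b1 * x + b2 * x^2
}

#' The published single-descriptor prediction equations
#'
#' The eleven polynomial leaf-area prediction equations published for the
#' pooled six-cultivar data, one per length descriptor, with their printed
#' accuracy statistics. The angle descriptors alpha and beta are absent by
#' design: no statistically certain relation to area was found for them, so
#' they were discarded. Coefficients and statistics are reference values
#' carried verbatim, not refit by this package (the underlying per-leaf
#' data are not public).
#'
#' @return data frame with columns `predictor`, `eq`, `degree`, `b2`, `b1`,
#'   `b0`, `r2`, `p_label` (`"<0.001"` or the exact value as text),
#'   `p_value` (numeric where printed exactly, `NA` for `<0.001`), `rmse`.
#' @examples
#' nrow(published_models())  # 11
#' @export
published_models <- function() {
  m <- function(predictor, eq, b2, b1, b0, r2, p_label, p_value, rmse)
    data.frame(predictor = predictor, eq = eq,
               degree = if (is.na(b2)) 1L else 2L,
               b2 = b2, b1 = b1, b0 = b0, r2 = r2,
               p_label = p_label, p_value = p_value, rmse = rmse)
  rbind(
    m("MR",   1L,  1.2284,  -0.1746,    1.035, 0.965, "<0.001", NA, 19.7330),
    m("VL1",  2L,  0.3662,  22.575,   -92.945, 0.988, "<0.001", NA, 17.1495),
    m("VR1",  3L, -0.5495,  40.855,  -180.18,  0.739, "<0.001", NA, 43.7254),
    m("DV1",  4L, -0.1114,  22.493,  -141.23,  0.846, "<0.001", NA, 34.8094),
    m("VL2",  5L,  NA,      37.68,   -111.21,  0.997, "<0.001", NA, 22.9111),
    m("VR2",  6L,  1.489,   17.61,    -47.077, 0.917, "<0.001", NA, 32.4634),
    m("DV2",  7L,  NA,      19.713,  -115.45,  0.959, "<0.001", NA, 27.4804),
    m("DSL1", 8L,  NA,      18.38,     64.325, 0.485, "0.0103", 0.0103, 70.1936),
    m("DSR1", 9L,  NA,      18.231,    66.478, 0.477, "0.0119", 0.0119, 70.3778),
    m("DSL2", 10L, NA,      31.157,     7.935, 0.806, "<0.001", NA, 61.7832),
    m("DSR2", 11L, NA,      31.23,      4.4471, 0.752, "<0.001", NA, 63.2706)
  )
}

#' Fit, screen and rank prediction models for every descriptor
#'
#' For each descriptor, fits the linear and the quadratic model, keeps the
#' better of the two by adjusted R-squared, discards descriptors whose
#' overall-F p-value is at or above `alpha_level` (this is what removes the
#' angles alpha and beta on realistic data), and ranks the kept models by
#' RMSE, best first.
#'
#' @param sample a `cultivar_sample`, a list of them (pooled), or any data
#'   frame with descriptor columns and `SLA_cm2`.
#' @param alpha_level significance threshold for the overall F test
#'   (default 0.05).
#' @param predictors descriptor names to consider; defaults to all
#'   thirteen.
#' @return An object of class `pla_model_selection`: list with `models`
#'   (data frame ranked by RMSE: `predictor`, `degree`, `b2`, `b1`, `b0`,
#'   `r2`, `adj_r2`, `p_value`, `rmse`, `n`), `fits` (the `pla_model`
#'   objects, named), and `discarded` (character). If everything is
#'   discarded, `models` has zero rows and a warning is raised.
#' @export
model_selection <- function(sample, alpha_level = 0.05,
                            predictors = descriptor_names()) {
  if (is.list(sample) && !is.data.frame(sample))
    sample <- do.call(rbind, sample)
  if (alpha_level <= 0 || alpha_level >= 1)
    stop("alpha_level must be in (0, 1)")
  col_of <- function(p) switch(p, alpha = "alpha_deg", beta = "beta_deg", p)
  y <- sample$SLA_cm2
  fits <- list(); discarded <- character()
  for (p in predictors) {
    x <- sample[[col_of(p)]]
    if (is.null(x)) stop("sample lacks column for predictor ", p)
    f1 <- fit_pla_model(x, y, 1, predictor = p)
    f2 <- fit_pla_model(x, y, 2, predictor = p)
    f <- if (f2$adj_r2 > f1$adj_r2) f2 else f1
    if (is.na(f$p_value) || f$p_value >= alpha_level) {
      discarded <- c(discarded, p)
    } else {
      fits[[p]] <- f
    }
  }
  if (length(fits) == 0) {
    warning("all predictors discarded at alpha_level = ", alpha_level)
    models <- data.frame(predictor = character(), degree = integer(),
                         b2 = numeric(), b1 = numeric(), b0 = numeric(),
                         r2 = numeric(), adj_r2 = numeric(),
                         p_value = numeric(), rmse = numeric(), n = integer())
  } else {
    models <- do.call(rbind, lapply(fits, function(f) {
      co <- f$coefficients
      data.frame(predictor = f$predictor, degree = f$degree,
                 b2 = if ("b2" %in% names(co)) co[["b2"]] else NA_real_,
                 b1 = co[["b1"]], b0 = co[["b0"]],
                 r2 = f$r2, adj_r2 = f$adj_r2, p_value = f$p_value,
                 rmse = f$rmse, n = f$n)
    }))
    models <- models[order(models$rmse), ]
    rownames(models) <- NULL
  }
  structure(list(models = models, fits = fits, discarded = discarded,
                 alpha_level = alpha_level),
            class = "pla_model_selection")
}

#' @export
print.pla_model_selection <- function(x, ...) {
  cat("Leaf-area prediction models (ranked by RMSE; alpha =",
      x$alpha_level, "):\n")
  if (nrow(x$models) > 0)
    print(transform(x$models, r2 = round(r2, 3), adj_r2 = round(adj_r2, 3),
                    rmse = round(rmse, 4)), row.names = FALSE)
  if (length(x$discarded) > 0)
    cat("discarded (no statistical certainty):",
        paste(x$discarded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pla_model <- function(x, ...) {
  co <- x$coefficients
  eq <- paste0("PLA = ", signif(co[["b0"]], 6))
  eq <- paste0(eq, " + ", signif(co[["b1"]], 6), " x")
  if ("b2" %in% names(co)) eq <- paste0(eq, " + ", signif(co[["b2"]], 6), " x^2")
  cat("Polynomial leaf-area model",
      if (!is.na(x$predictor)) paste0("(", x$predictor, ")") else "", "\n  ",
      eq, "\n  R2 = ", round(x$r2, 3), ", p = ", format.pval(x$p_value),
      ", RMSE = ", round(x$rmse, 4), " cm^2, n = ", x$n, "\n", sep = "")
  invisible(x)
}

homologous_pairs <- function() {
  list(c("VL1", "VR1"), c("VL2", "VR2"), c("DSL1", "DSR1"), c("DSL2", "DSR2"))
}

#' Left- versus right-side prediction accuracy
#'
#' Vine leaves are measurably asymmetric, and the side of the leaf a
#' descriptor is taken from affects how well it predicts area. For each
#' homologous descriptor pair (VL1/VR1, VL2/VR2, DSL1/DSR1, DSL2/DSR2)
#' present in the model table, reports the R-squared and RMSE differences
#' (left minus right) and which side wins (higher R-squared; RMSE breaks
#' ties). The overall winner is the side winning more pairs, with the mean
#' R-squared difference breaking a tie.
#'
#' @param models a `pla_model_selection`, the data frame from its `models`
#'   element, or [published_models()].
#' @return An object of class `side_comparison`: list with `pairs` (data
#'   frame `left`, `right`, `r2_left`, `r2_right`, `delta_r2`,
#'   `rmse_left`, `rmse_right`, `delta_rmse`, `winner`) and `overall`
#'   (`"left"` or `"right"`).
#' @examples
#' side_comparison(published_models())$overall  # "left"
#' @export
side_comparison <- function(models) {
  if (inherits(models, "pla_model_selection")) models <- models$models
  if (!is.data.frame(models) ||
      !all(c("predictor", "r2", "rmse") %in% names(models)))
    stop("models must carry columns predictor, r2, rmse")
  rows <- list()
  for (pr in homologous_pairs()) {
    il <- match(pr[1], models$predictor)
    ir <- match(pr[2], models$predictor)
    if (is.na(il) || is.na(ir)) next
    r2l <- models$r2[il]; r2r <- models$r2[ir]
    rl <- models$rmse[il]; rr <- models$rmse[ir]
    winner <- if (r2l > r2r) "left" else if (r2r > r2l) "right"
              else if (rl < rr) "left" else "right"
    rows[[length(rows) + 1]] <- data.frame(
      left = pr[1], right = pr[2], r2_left = r2l, r2_right = r2r,
      delta_r2 = r2l - r2r, rmse_left = rl, rmse_right = rr,
      delta_rmse = rl - rr, winner = winner)
  }
  if (length(rows) == 0)
    stop("no homologous left/right pair present in the model table")
  pairs <- do.call(rbind, rows)
  nl <- sum(pairs$winner == "left"); nr <- sum(pairs$winner == "right")
  overall <- if (nl > nr) "left" else if (nr > nl) "right"
             else if (mean(pairs$delta_r2) >= 0) "left" else "right"
  structure(list(pairs = pairs, overall = overall), class = "side_comparison")
}

#' @export
print.side_comparison <- function(x, ...) {
  cat("Left vs right prediction accuracy (winner per homologous pair):\n")
  print(transform(x$pairs, r2_left = round(r2_left, 3),
                  r2_right = round(r2_right, 3),
                  delta_r2 = round(delta_r2, 3),
                  rmse_left = round(rmse_left, 2),
                  rmse_right = round(rmse_right, 2),
                  delta_rmse = round(delta_rmse, 2)), row.names = FALSE)
  cat("overall:", x$overall, "side predicts leaf area more accurately\n")
  invisible(x)
}
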