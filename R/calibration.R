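#' Allometric measured leaf area
#'
#' The core allometric law: the lamina area is proportional to the product
#' of the midrib length and the tip distance of one order of lateral veins,
#' `MLA = MR * DV * KA`, where `KA` is a cultivar-specific surface constant
#' (KA1 when DV is the first-order tip distance DV1, KA2 for DV2).
#'
#' @param MR midrib length (cm), vectorized.
#' @param DV vein tip distance DV1 or DV2 (cm), vectorized.
#' @param KA surface constant (unitless, > 0).
#' @return measured leaf area (cm^2).
#' @examples
#' measured_leaf_area(10, 10, 1.0)  # 100
#' @export
measured_leaf_area <- function(MR, DV, KA) {
  if (any(MR <= 0) || any(DV <= 0) || any(KA <= 0))
    stop("MR, DV and KA must all be strictly positive")
  MR * DV * KA
}

#' Mean error between estimated and reference areas
#'
#' `ME = mean(MLA) - mean(SLA)`: the bias of the estimate at the sample
#' level, sign preserved (negative = underestimate). This is a difference
#' of means, not a mean of absolute residuals, which is why it can sit near
#' zero while the per-leaf RMSE stays large.
#'
#' @param MLA_per_leaf estimated areas (cm^2).
#' @param SLA_per_leaf reference areas (cm^2), same length.
#' @return ME in cm^2.
#' @export
mean_error <- function(MLA_per_leaf, SLA_per_leaf) {
  if (length(MLA_per_leaf) != length(SLA_per_leaf))
    stop("MLA and SLA vectors must have equal length")
  if (length(MLA_per_leaf) == 0) stop("empty input")
  mean(MLA_per_leaf) - mean(SLA_per_leaf)
}

#' Root mean squared per-leaf error
#'
#' `RMSE = sqrt(mean((MLA_i - SLA_i)^2))` over leaves (population
#' normalization, divide by n). Always at least `|ME|`.
#'
#' @inheritParams mean_error
#' @return RMSE in cm^2.
#' @export
rmse <- function(MLA_per_leaf, SLA_per_leaf) {
  if (length(MLA_per_leaf) != length(SLA_per_leaf))
    stop("MLA and SLA vectors must have equal length")
  if (length(MLA_per_leaf) == 0) stop("empty input")
  sqrt(mean((MLA_per_leaf - SLA_per_leaf)^2))
}

#' Select a surface constant from a candidate grid
#'
#' The documented selection rule: minimum RMSE first, ties broken by
#' minimum absolute ME, remaining ties by the smaller KA. Exposed on its
#' own so the rule can be applied to externally tabulated candidate grids
#' as well as to grids computed by [calibrate_ka()].
#'
#' @param grid data frame with columns `KA`, `ME`, `RMSE`.
#' @return the selected KA (a single number).
#' @export
select_ka <- function(grid) {
  if (!all(c("KA", "ME", "RMSE") %in% names(grid)))
    stop("grid needs columns KA, ME, RMSE")
  if (nrow(grid) == 0) stop("empty candidate grid")
  grid$KA[order(grid$RMSE, abs(grid$ME), grid$KA)][1]
}

#' Calibrate the surface constant KA by grid search
#'
#' For every candidate KA on the grid, computes the per-leaf measured area
#' `MLA = MR * DV * KA`, then the sample mean MLA, the mean error ME and the
#' per-leaf RMSE against the reference areas, and selects the constant by
#' [select_ka()]'s rule (minimum RMSE, |ME| tie-break). The full candidate
#' table is returned for reporting.
#'
#' @param sample a `cultivar_sample` (columns `MR`, `DV1`/`DV2`, `SLA_cm2`).
#' @param dv_choice `"DV1"` (calibrates KA1) or `"DV2"` (KA2).
#' @param grid list with `min`, `max`, `step` for the KA candidates;
#'   default 0.50 to 1.50 in steps of 0.01.
#' @return An object of class `ka_grid_result`: list with `cultivar`,
#'   `dv_choice`, `grid` (data frame `KA`, `MLA_mean`, `ME`, `RMSE`),
#'   `selected_KA` and `sla_mean`.
#' @examples
#' s <- make_allometric_sample(ka_true = 1.07, n = 12, seed = 3, cv = 0)
#' calibrate_ka(s, "DV1")$selected_KA  # 1.07
#' @export
calibrate_ka <- function(sample, dv_choice = c("DV1", "DV2"),
                         grid = list(min = 0.50, max = 1.50, step = 0.01)) {
  dv_choice <- match.arg(dv_choice)
  if (is.null(sample) || nrow(sample) == 0) stop("empty sample")
  if (!all(c("MR", dv_choice, "SLA_cm2") %in% names(sample)))
    stop("sample lacks required columns: MR, ", dv_choice, ", SLA_cm2")
  if (!is.numeric(grid$step) || grid$step <= 0) stop("grid step must be positive")
  kas <- seq(grid$min, grid$max, by = grid$step)
  # guard against accumulated fp error in seq()
  kas <- round(kas, 10)
  prod_md <- sample$MR * sample[[dv_choice]]
  sla <- sample$SLA_cm2
  res <- vapply(kas, function(ka) {
    mla <- prod_md * ka
    c(MLA_mean = mean(mla), ME = mean(mla) - mean(sla),
      RMSE = sqrt(mean((mla - sla)^2)))
  }, numeric(3))
  gdf <- data.frame(KA = kas, MLA_mean = res["MLA_mean", ],
                    ME = res["ME", ], RMSE = res["RMSE", ])
  structure(list(cultivar = if ("cultivar" %in% names(sample))
                              as.character(sample$cultivar[1]) else NA_character_,
                 dv_choice = dv_choice, grid = gdf,
                 selected_KA = select_ka(gdf), sla_mean = mean(sla)),
            class = "ka_grid_result")
}

#' @export
print.ka_grid_result <- function(x, ...) {
  cat("KA calibration (", if (x$dv_choice == "DV1") "KA1" else "KA2",
      if (!is.na(x$cultivar)) paste0(", cultivar ", x$cultivar) else "",
      "): selected KA = ", format(x$selected_KA), "\n", sep = "")
  near <- which(x$grid$KA == x$selected_KA)
  idx <- max(1, near - 2):min(nrow(x$grid), near + 2)
  print(transform(x$grid[idx, ], MLA_mean = round(MLA_mean, 2),
                  ME = round(ME, 2), RMSE = round(RMSE, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Calibration report in the published five-column layout
#'
#' For each sample and each constant (KA1 over DV1, KA2 over DV2), runs the
#' grid calibration and extracts the `window` candidates centred on the
#' selected KA, formatted as the published blocks: rows `SLA (cm2)`, `KA`,
#' `MLA (cm2)` (2 dp), `ME` (2 dp) and `RMSE` (4 dp).
#'
#' @param samples a `cultivar_sample` or list of them.
#' @param window odd number of grid cells per block (default 5).
#' @param grid KA grid passed to [calibrate_ka()].
#' @return data frame with one row per (cultivar, constant, candidate):
#'   columns `cultivar`, `constant`, `SLA`, `KA`, `MLA`, `ME`, `RMSE`
#'   (numeric, rounded as printed), plus attribute `selected` (data frame of
#'   selected constants).
#' @export
table3_report <- function(samples, window = 5,
                          grid = list(min = 0.50, max = 1.50, step = 0.01)) {
  if (inherits(samples, "cultivar_sample")) samples <- list(samples)
  n_grid <- length(seq(grid$min, grid$max, by = grid$step))
  if (window > n_grid) stop("window (", window, ") larger than the grid (",
                            n_grid, " candidates)")
  half <- floor(window / 2)
  blocks <- list(); sel <- list()
  for (s in samples) {
    for (dv in c("DV1", "DV2")) {
      cal <- calibrate_ka(s, dv, grid)
      i <- which(cal$grid$KA == cal$selected_KA)
      lo <- max(1, min(i - half, nrow(cal$grid) - window + 1))
      idx <- lo:(lo + window - 1)
      g <- cal$grid[idx, ]
      blocks[[length(blocks) + 1]] <- data.frame(
        cultivar = cal$cultivar,
        constant = if (dv == "DV1") "KA1" else "KA2",
        SLA = round(cal$sla_mean, 2),
        KA = g$KA,
        MLA = round(g$MLA_mean, 2),
        ME = round(g$ME, 2),
        RMSE = round(g$RMSE, 4))
      sel[[length(sel) + 1]] <- data.frame(
        cultivar = cal$cultivar,
        constant = if (dv == "DV1") "KA1" else "KA2",
        selected_KA = cal$selected_KA)
    }
  }
  out <- do.call(rbind, blocks)
  attr(out, "selected") <- do.call(rbind, sel)
  out
}

#' Published surface-constant candidate grids
#'
#' The five-candidate calibration blocks published for the six cultivars
#' and both constants (KA1 against MR x DV1, KA2 against MR x DV2), carried
#' verbatim: mean reference area `SLA`, candidate `KA`, mean estimated area
#' `MLA`, mean error `ME` and `RMSE` (all areas cm^2). These tabulated
#' candidates are the inputs for reproducing the published constant
#' selection (see [select_ka()]); they are reference values, not computed
#' by this package.
#'
#' @return data frame with columns `cultivar` (CS, Ch, MH, MI, MO, Vi),
#'   `constant` ("KA1"/"KA2"), `SLA`, `KA`, `MLA`, `ME`, `RMSE`.
#' @examples
#' g <- printed_ka_grids()
#' select_ka(g[g$cultivar == "MO" & g$constant == "KA2", ])  # 1.07
#' @export
printed_ka_grids <- function() {
  blk <- function(cultivar, constant, SLA, KA, MLA, ME, RMSE)
    data.frame(cultivar = cultivar, constant = constant, SLA = SLA,
               KA = KA, MLA = MLA, ME = ME, RMSE = RMSE)
  rbind(
    blk("CS", "KA1", 97.53, c(0.95, 0.96, 0.97, 0.98, 0.99),
        c(95.02, 96.02, 97.02, 98.02, 99.02),
        c(-2.51, -1.51, -0.51, 0.49, 1.49),
        c(4.9137, 4.4959, 4.2794, 4.2948, 4.5397)),
    blk("CS", "KA2", 97.53, c(0.90, 0.91, 0.92, 0.93, 0.94),
        c(95.88, 96.95, 98.01, 99.08, 100.14),
        c(-1.65, -0.58, 0.48, 1.55, 2.61),
        c(3.4282, 3.0539, 3.0338, 3.3741, 3.9835)),
    blk("Ch", "KA1", 154.07, c(0.89, 0.90, 0.91, 0.92, 0.93),
        c(151.29, 152.98, 154.69, 156.39, 158.09),
        c(-2.79, -1.09, 0.61, 2.31, 4.01),
        c(18.0852, 17.7521, 17.5824, 17.5809, 17.7476)),
    blk("Ch", "KA2", 154.07, c(0.91, 0.92, 0.93, 0.94, 0.95),
        c(150.19, 151.84, 153.49, 155.14, 156.79),
        c(-3.88, -2.23, -0.58, 1.07, 2.72),
        c(8.9994, 8.2622, 7.8268, 7.7444, 8.0259)),
    blk("MH", "KA1", 302.83, c(0.90, 0.91, 0.92, 0.93, 0.94),
        c(294.89, 298.17, 301.44, 304.72, 307.99),
        c(-7.94, -4.67, -1.39, 1.89, 5.16),
        c(52.6654, 52.3765, 52.3025, 53.1656, 53.8714)),
    blk("MH", "KA2", 302.83, c(0.93, 0.94, 0.95, 0.96, 0.97),
        c(294.89, 298.83, 302.01, 305.19, 308.37),
        c(-7.18, -4.00, -0.82, 2.36, 5.54),
        c(41.2034, 40.9519, 40.9538, 41.2089, 41.7126)),
    blk("MI", "KA1", 110.03, c(0.91, 0.92, 0.93, 0.94, 0.95),
        c(107.58, 108.76, 109.95, 111.13, 112.31),
        c(-2.45, -1.27, -0.08, 1.10, 2.28),
        c(12.1725, 12.0021, 11.9556, 12.4616, 12.8615)),
    blk("MI", "KA2", 110.03, c(1.06, 1.07, 1.08, 1.09, 1.10),
        c(108.14, 109.16, 110.18, 111.19, 112.11),
        c(-1.89, -0.87, 0.15, 1.17, 2.19),
        c(16.8639, 16.7988, 16.7971, 16.8588, 16.9831)),
    blk("MO", "KA1", 110.27, c(0.89, 0.90, 0.91, 0.92, 0.93),
        c(108.21, 109.42, 110.64, 111.85, 113.07),
        c(-2.06, -0.85, 0.34, 1.58, 2.80),
        c(8.8879, 8.5431, 8.3732, 8.3887, 8.5888)),
    blk("MO", "KA2", 110.27, c(1.05, 1.06, 1.07, 1.08, 1.09),
        c(108.46, 109.49, 110.53, 111.56, 112.59),
        c(-1.81, -0.78, 0.25, 1.29, 2.32),
        c(6.2165, 6.0236, 6.0199, 6.2057, 6.5649)),
    blk("Vi", "KA1", 216.17, c(0.95, 0.96, 0.97, 0.98, 0.99),
        c(211.59, 213.82, 216.05, 218.28, 220.50),
        c(-4.57, -2.35, -0.12, 2.11, 4.33),
        c(13.8312, 13.1502, 12.8298, 12.8971, 13.3459)),
    blk("Vi", "KA2", 216.17, c(0.91, 0.92, 0.93, 0.94, 0.95),
        c(210.63, 212.95, 215.26, 217.58, 219.89),
        c(-5.53, -3.22, -0.90, 1.41, 3.72),
        c(19.3721, 18.8042, 18.5139, 18.5145, 18.8057))
  )
}
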