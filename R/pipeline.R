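#' Leaf size classes
#'
#' The two size classes relevant to vine leaves on the standard leaf-size
#' scale: 8.5 Mesophyll, 4500 to 18,225 mm^2, and 8.6 Macrophyll, 18,225 to
#' 164,025 mm^2. Intervals are lower-inclusive and upper-exclusive, so a
#' lamina of exactly 18,225 mm^2 is Macrophyll; areas outside both ranges
#' are reported as unclassified rather than an error.
#'
#' @return data frame with columns `code`, `name`, `lower`, `upper` (mm^2).
#' @export
size_classes <- function() {
  data.frame(code = c("8.5", "8.6"),
             name = c("Mesophyll", "Macrophyll"),
             lower = c(4500, 18225),
             upper = c(18225, 164025))
}

#' Classify a leaf area into a size class
#'
#' @param area leaf area (vectorized).
#' @param unit `"mm2"` (default) or `"cm2"`; cm^2 values are converted to
#'   mm^2 (x100) before the interval lookup.
#' @param classes class table as from [size_classes()].
#' @return data frame with columns `area_mm2`, `code`, `name`; `code` is
#'   `"unclassified"` outside every configured class.
#' @examples
#' classify_leaf_size(97.53, unit = "cm2")$name   # Mesophyll
#' classify_leaf_size(21617)$name                 # Macrophyll
#' @export
classify_leaf_size <- function(area, unit = c("mm2", "cm2"),
                               classes = size_classes()) {
  unit <- match.arg(unit)
  if (any(area <= 0)) stop("area must be strictly positive")
  mm2 <- if (unit == "cm2") area * 100 else area
  idx <- vapply(mm2, function(a) {
    i <- which(a >= classes$lower & a < classes$upper)
    if (length(i) == 1) i else NA_integer_
  }, integer(1))
  data.frame(area_mm2 = mm2,
             code = ifelse(is.na(idx), "unclassified", classes$code[idx]),
             name = ifelse(is.na(idx), "unclassified", classes$name[idx]))
}

leaf_csv_columns <- function() {
  c("cultivar", "leaf_id", "MR", "VL1", "VR1", "DV1", "VL2", "VR2", "DV2",
    "DSL1", "DSR1", "DSL2", "DSR2", "alpha_deg", "beta_deg", "SLA_cm2")
}

#' Read per-leaf descriptor tables from CSV
#'
#' Reads the documented schema (`cultivar, leaf_id, MR, VL1, VR1, DV1, VL2,
#' VR2, DV2, DSL1, DSR1, DSL2, DSR2, alpha_deg, beta_deg, SLA_cm2`; decimal
#' point, UTF-8) and splits it into one `cultivar_sample` per cultivar, row
#' order preserved. Unknown columns are dropped with a warning; a missing
#' mandatory column or a malformed numeric cell is an error naming the
#' column (and row).
#'
#' @param path CSV file path.
#' @return named list of `cultivar_sample` objects, in order of first
#'   appearance.
#' @export
read_leaves <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- leaf_csv_columns()
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), need)
  if (length(extra) > 0)
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  raw <- raw[, need]
  num_cols <- setdiff(need, "cultivar")
  for (cn in num_cols) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & trimws(v) != "")
      if (length(bad) > 0)
        stop("malformed numeric cell in column '", cn, "', row ", bad[1],
             ": '", v[bad[1]], "'")
      raw[[cn]] <- conv
    }
    if (anyNA(raw[[cn]]))
      stop("missing value in column '", cn, "', row ",
           which(is.na(raw[[cn]]))[1])
  }
  split_idx <- split(seq_len(nrow(raw)), factor(raw$cultivar,
                                                levels = unique(raw$cultivar)))
  lapply(split_idx, function(i) {
    s <- raw[i, ]
    rownames(s) <- NULL
    class(s) <- c("cultivar_sample", "data.frame")
    s
  })
}

#' Write per-leaf tables to CSV
#'
#' Inverse of [read_leaves()]: accepts one `cultivar_sample` or a list and
#' writes a single CSV in the documented schema. Values are written as
#' full-precision decimal strings so a write/read round trip is lossless.
#'
#' @param samples a `cultivar_sample` or list of them.
#' @param path output CSV path.
#' @export
write_leaves <- function(samples, path) {
  if (inherits(samples, "cultivar_sample")) samples <- list(samples)
  df <- do.call(rbind, lapply(samples, function(s) as.data.frame(s)))
  df <- df[, leaf_csv_columns()]
  for (cn in setdiff(leaf_csv_columns(), "cultivar"))
    df[[cn]] <- format(df[[cn]], digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the knobs of [run_pipeline()] with their defaults: the KA
#' candidate grid, the significance threshold for discarding predictors,
#' how the printed dispersions are read when simulating, the ruler
#' resolution and scan pitch of the geometry stages, and the seed for any
#' stochastic stage.
#'
#' @param ka_grid list `min`, `max`, `step` of KA candidates.
#' @param alpha_level overall-F significance threshold.
#' @param dispersion `"se"` or `"sd"` reading of published dispersions.
#' @param ruler_step ruler resolution (cm).
#' @param raster_pitch scan pixel pitch (cm).
#' @param window report window width (candidates per calibration block).
#' @param seed integer seed; mandatory for stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(ka_grid = list(min = 0.50, max = 1.50, step = 0.01),
                            alpha_level = 0.05,
                            dispersion = c("se", "sd"),
                            ruler_step = 0.05, raster_pitch = 0.02,
                            window = 5, seed = NULL) {
  dispersion <- match.arg(dispersion)
  stopifnot(ka_grid$step > 0, ka_grid$min > 0, ka_grid$max > ka_grid$min,
            alpha_level > 0, alpha_level < 1,
            ruler_step > 0, raster_pitch > 0, window >= 1)
  structure(list(ka_grid = ka_grid, alpha_level = alpha_level,
                 dispersion = dispersion, ruler_step = ruler_step,
                 raster_pitch = raster_pitch, window = window, seed = seed),
            class = "pipeline_config")
}

#' Run the full leaf-area analysis
#'
#' End-to-end orchestration over a per-leaf dataset: per cultivar, both
#' surface-constant calibrations (KA1 on MR x DV1, KA2 on MR x DV2) with
#' their report blocks, the size class of the mean reference area; pooled
#' over all leaves, the per-descriptor prediction models with the
#' non-significant descriptors discarded, and the left-versus-right
#' accuracy comparison. Deterministic: the same input and configuration
#' always produce the identical report.
#'
#' @param config a [pipeline_config()].
#' @param input a CSV path (see [read_leaves()]), a `cultivar_sample`, or a
#'   list of them.
#' @return An object of class `leaf_area_report`: list with `calibration`
#'   (per cultivar: `ka1`, `ka2` as `ka_grid_result`s), `blocks` (the
#'   [table3_report()] data frame), `selected` (data frame of selected
#'   constants), `models` (a `pla_model_selection`), `sides` (a
#'   `side_comparison` or `NULL`), `size_class` (per-cultivar class of the
#'   mean reference area) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), input) {
  if (is.character(input)) input <- read_leaves(input)
  if (inherits(input, "cultivar_sample")) input <- list(input)
  if (length(input) == 0) stop("pipeline stage 'input': no samples")
  calib <- list()
  size_rows <- list()
  for (s in input) {
    cv <- as.character(s$cultivar[1])
    ka1 <- calibrate_ka(s, "DV1", config$ka_grid)
    ka2 <- calibrate_ka(s, "DV2", config$ka_grid)
    calib[[cv]] <- list(ka1 = ka1, ka2 = ka2)
    cls <- classify_leaf_size(mean(s$SLA_cm2), unit = "cm2")
    size_rows[[cv]] <- data.frame(cultivar = cv,
                                  mean_sla_cm2 = mean(s$SLA_cm2),
                                  code = cls$code, name = cls$name)
  }
  blocks <- table3_report(input, window = config$window, grid = config$ka_grid)
  pooled <- do.call(rbind, lapply(input, as.data.frame))
  models <- model_selection(pooled, alpha_level = config$alpha_level)
  sides <- tryCatch(side_comparison(models), error = function(e) NULL)
  structure(list(calibration = calib, blocks = blocks,
                 selected = attr(blocks, "selected"),
                 models = models, sides = sides,
                 size_class = do.call(rbind, size_rows),
                 config = config),
            class = "leaf_area_report")
}

#' @export
print.leaf_area_report <- function(x, ...) {
  cat("== Vine leaf-area analysis ==\n\nSelected surface constants:\n")
  print(x$selected, row.names = FALSE)
  cat("\nSize class of the mean reference area:\n")
  print(transform(x$size_class, mean_sla_cm2 = round(mean_sla_cm2, 2)),
        row.names = FALSE)
  cat("\n")
  print(x$models)
  if (!is.null(x$sides)) { cat("\n"); print(x$sides) }
  invisible(x)
}
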