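#' Foliar descriptors of a single vine leaf
#'
#' Constructs and validates the set of thirteen foliar descriptors used
#' throughout the package. Lengths are in centimetres, angles in degrees.
#'
#' The descriptors are: midrib length `MR`; first-order lateral vein lengths
#' `VL1` (left) and `VR1` (right) and the distance `DV1` between their tips;
#' second-order lateral vein lengths `VL2`/`VR2` and tip distance `DV2`;
#' sinus-base-to-lamina-base distances `DSL1`, `DSR1` (upper sinuses) and
#' `DSL2`, `DSR2` (lower sinuses); `alpha`, the angle between the midrib and
#' the first-order right vein; and `beta`, the angle between the first- and
#' second-order right veins.
#'
#' @param MR,VL1,VR1,DV1,VL2,VR2,DV2 vein lengths and tip distances (cm).
#' @param DSL1,DSR1,DSL2,DSR2 sinus-base distances (cm).
#' @param alpha,beta vein angles (degrees).
#' @return An object of class `leaf_descriptors`: a named numeric vector of
#'   the thirteen descriptors.
#' @examples
#' d <- leaf_descriptors(MR = 9.21, VL1 = 7.54, VR1 = 7.92, DV1 = 10.82,
#'                       VL2 = 5.80, VR2 = 5.94, DV2 = 11.52,
#'                       DSL1 = 3.69, DSR1 = 3.49, DSL2 = 3.52, DSR2 = 3.57,
#'                       alpha = 44.46, beta = 54.91)
#' @export
leaf_descriptors <- function(MR, VL1, VR1, DV1, VL2, VR2, DV2,
                             DSL1, DSR1, DSL2, DSR2, alpha, beta) {
  vals <- vapply(list(MR, VL1, VR1, DV1, VL2, VR2, DV2,
                      DSL1, DSR1, DSL2, DSR2, alpha, beta),
                 function(v) as.numeric(v)[1], numeric(1))
  d <- stats::setNames(vals, descriptor_names())
  validate_descriptors(d)
  structure(d, class = "leaf_descriptors")
}

#' Names of the length-valued and angle-valued descriptors
#' @keywords internal
descriptor_length_names <- function() {
  c("MR", "VL1", "VR1", "DV1", "VL2", "VR2", "DV2",
    "DSL1", "DSR1", "DSL2", "DSR2")
}

descriptor_angle_names <- function() c("alpha", "beta")

descriptor_names <- function() {
  c(descriptor_length_names(), descriptor_angle_names())
}

left_descriptor_names <- function() c("VL1", "VL2", "DSL1", "DSL2")
right_descriptor_names <- function() c("VR1", "VR2", "DSR1", "DSR2")

#' Validate a descriptor vector
#'
#' Checks the feasibility constraints that every descriptor set must satisfy:
#' all lengths strictly positive, angles in (0, 90) degrees, and each sinus
#' distance shorter than both of its flanking vein lengths (a sinus base
#' lies between its two lobes, so it cannot reach past either tip).
#'
#' @param d named numeric vector with the thirteen descriptor names.
#' @return `d`, invisibly, if valid; otherwise an error naming the offending
#'   descriptor.
#' @export
validate_descriptors <- function(d) {
  need <- descriptor_names()
  missing <- setdiff(need, names(d))
  if (length(missing) > 0)
    stop("missing descriptor(s): ", paste(missing, collapse = ", "))
  d <- d[need]
  if (any(!is.finite(d)))
    stop("non-finite descriptor(s): ",
         paste(need[!is.finite(d)], collapse = ", "))
  len <- d[descriptor_length_names()]
  if (any(len <= 0))
    stop("non-positive length descriptor(s): ",
         paste(names(len)[len <= 0], collapse = ", "))
  for (a in descriptor_angle_names())
    if (d[[a]] <= 0 || d[[a]] >= 90)
      stop(a, " must lie strictly between 0 and 90 degrees, got ", d[[a]])
  # sinus feasibility: flanking veins are (MR, V1) for sinus 1, (V1, V2) for sinus 2
  flank <- list(DSR1 = c("MR", "VR1"), DSL1 = c("MR", "VL1"),
                DSR2 = c("VR1", "VR2"), DSL2 = c("VL1", "VL2"))
  for (s in names(flank)) {
    lim <- min(d[flank[[s]]])
    if (d[[s]] >= lim)
      stop("infeasible sinus distance: ", s, " (", d[[s]],
           ") must be shorter than flanking veins ",
           paste(flank[[s]], collapse = "/"), " (min ", lim, ")")
  }
  invisible(d)
}

#' Test descriptor feasibility without raising an error
#' @keywords internal
descriptors_feasible <- function(d) {
  !inherits(try(validate_descriptors(d), silent = TRUE), "try-error")
}

#' Quantize descriptor lengths to ruler resolution
#'
#' Emulates measurement with a ruler of a given resolution: each length is
#' rounded to the nearest multiple of `step`; angles are left unchanged
#' (they are read off an image, not a ruler). Ties are rounded half away
#' from zero so the operation is reproducible across platforms.
#'
#' @param descriptors a [leaf_descriptors] object (or named numeric vector).
#' @param step ruler resolution in cm; default 0.05 cm (half a millimetre).
#' @return descriptors with quantized lengths, same class as the input.
#' @examples
#' d <- leaf_descriptors(9.213, 7.54, 7.92, 10.82, 5.8, 5.94, 11.52,
#'                       3.69, 3.49, 3.52, 3.57, 44.46, 54.91)
#' quantize_ruler(d)[["MR"]]  # 9.20
#' @export
quantize_ruler <- function(descriptors, step = 0.05) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0)
    stop("step must be a single positive number")
  out <- descriptors
  ln <- descriptor_length_names()
  x <- unclass(descriptors)[ln]
  # half-away-from-zero; the epsilon keeps ties that are not exactly
  # representable in binary (e.g. 9.225/0.05) on the documented side
  out[ln] <- sign(x) * floor(abs(x) / step + 0.5 + 1e-9) * step
  out
}

#' @export
print.leaf_descriptors <- function(x, ...) {
  cat("Vine leaf descriptors (lengths cm, angles deg):\n")
  print(round(unclass(x), 3))
  invisible(x)
}
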