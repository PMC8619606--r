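# Independent oracles and fixture generators shared by the tests.

# Shoelace area written independently of the package (signed sum over the
# vertex fan from the origin), used to cross-check polygon_area().
shoelace_oracle <- function(v) {
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + (v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2])
  }
  abs(s) / 2
}

# Mean descriptors of the 'Cabernet Sauvignon' preset, as a plain call.
cs_mean_descriptors <- function() {
  leaf_descriptors(MR = 9.21, VL1 = 7.54, VR1 = 7.92, DV1 = 10.82,
                   VL2 = 5.80, VR2 = 5.94, DV2 = 11.52,
                   DSL1 = 3.69, DSR1 = 3.49, DSL2 = 3.52, DSR2 = 3.57,
                   alpha = 44.46, beta = 54.91)
}

# Random feasible descriptor sets: jitter a random cultivar preset's centre
# multiplicatively and resample until feasible. Pure function of the RNG
# state, so callers fix the seed.
random_feasible_descriptors <- function() {
  presets <- cultivar_presets()
  repeat {
    p <- presets[[sample(length(presets), 1)]]
    d <- p$center
    ln <- c("MR", "VL1", "VR1", "DV1", "VL2", "VR2", "DV2",
            "DSL1", "DSR1", "DSL2", "DSR2")
    d[ln] <- d[ln] * stats::runif(length(ln), 0.85, 1.15)
    d[c("alpha", "beta")] <- d[c("alpha", "beta")] +
      stats::runif(2, -8, 8)
    ok <- tryCatch({ validate_descriptors(d); TRUE },
                   error = function(e) FALSE)
    if (ok) return(structure(d, class = "leaf_descriptors"))
  }
}

# Zero-dispersion copy of a cultivar summary (degenerate generator used to
# isolate single noise sources in tests).
zero_sd_summary <- function(cultivar = "CS") {
  s <- cultivar_presets()[[cultivar]]
  s$sd[] <- 0
  s$pm[] <- 0
  s
}
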