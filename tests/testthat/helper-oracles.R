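# Shared independent oracles used across test files.

# brute-force Pearson r (textbook formula, independent of the engine)
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# recompute the expected per-volume window correlations of a replayed run
# directly from the raw inputs, independently of the engine internals
expected_window_r <- function(atl_raw, scc_raw, timeline, motion = NULL,
                              config = engine_config()) {
  out <- data.frame(volume = integer(0), r = numeric(0))
  b <- timeline$blocks
  baseline <- NULL
  for (bi in seq_len(nrow(b))) {
    vols <- seq.int(b$start_volume[bi], length.out = b$n_volumes[bi])
    if (b$condition[bi] == "SUBTRACTION") {
      baseline <- c(mean(atl_raw[vols + 1]), mean(scc_raw[vols + 1]))
      next
    }
    wa <- numeric(0); ws <- numeric(0)
    for (pos in seq_along(vols)) {
      if (pos <= config$discard_volumes) next
      v <- vols[pos]
      if (!is.null(motion) && !motion_gate(motion[v + 1, ], config)$include)
        next
      wa <- c(wa, atl_raw[v + 1] - baseline[1])
      ws <- c(ws, scc_raw[v + 1] - baseline[2])
      if (length(wa) >= config$window_volumes) {
        win <- seq.int(length(wa) - config$window_volumes + 1, length(wa))
        out <- rbind(out, data.frame(volume = v,
                                     r = stats::cor(wa[win], ws[win])))
      }
    }
  }
  out
}

# a full-grid rectangular mask with a known support size
flat_mask <- function(dim = c(10, 10, 2)) {
  g <- nf_grid(dim, voxel_mm = c(1, 1, 1))
  make_sphere_roi(roi_spec("FLAT", c(0, 0, 0), radius_mm = 1e3), g)
}

# activation map with prescribed per-voxel statistics on a mask's grid
stat_map <- function(stats_vec, grid) {
  structure(list(statistic = array(stats_vec, grid$dim),
                 statistic_type = "t", contrast = c("GUILT", "SUBTRACTION"),
                 df = NA_integer_, grid = grid, hrf = FALSE),
            class = "activation_map")
}
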