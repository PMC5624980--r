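# Independent oracles and fixture builders used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force convex hull area: Andrew's monotone chain over the full point
# cloud + shoelace. Independent of the package's chull-based implementation.
brute_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  half_hull <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h[-length(h)]
  }
  hull <- c(half_hull(1:n), half_hull(n:1))
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# corners of all foreground pixels of a mask, for the hull oracle
mask_corner_points <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  list(
    x = c(pts[, 2] - 0.5, pts[, 2] + 0.5, pts[, 2] + 0.5, pts[, 2] - 0.5),
    y = c(pts[, 1] - 0.5, pts[, 1] - 0.5, pts[, 1] + 0.5, pts[, 1] + 0.5)
  )
}

# Direct-summation curve-parameter oracle on one pulse vector.
oracle_features <- function(v, trigger = 0, ups = 1) {
  above <- which(v > trigger)
  if (!length(above)) {
    return(list(maximum = max(v), total = sum(v), length = length(v) * ups,
                sample_length = 0, fill_factor = 0))
  }
  i1 <- min(above); i2 <- max(above)
  n_env <- i2 - i1 + 1
  list(
    maximum = max(v),
    total = sum(v),
    length = length(v) * ups,
    sample_length = n_env * ups,
    fill_factor = min(1, sum(v[i1:i2]) / (max(v) * n_env))
  )
}

# Build a tbl_pulse from a named list: id -> list(FWS = ..., SWS = ..., ...)
toy_pulses <- function(particles, um_per_sample = 1, saturation_level = 1e4,
                       ..., validate = TRUE) {
  rows <- list()
  for (id in names(particles)) {
    for (ch in names(particles[[id]])) {
      v <- particles[[id]][[ch]]
      rows[[paste(id, ch)]] <- tibble::tibble(
        particle_id = id, channel = ch,
        sample_index = seq_along(v) - 1L, value = v)
    }
  }
  pulse_tbl(dplyr::bind_rows(rows),
            measurement_meta(um_per_sample = um_per_sample,
                             saturation_level = saturation_level, ...),
            validate = validate)
}

# Trapezoidal FWS pulse: linear rise over n_up, plateau at `peak` over
# n_plateau, fall over n_down; strictly positive everywhere.
trapezoid_pulse <- function(n_up, n_plateau, n_down, peak = 1e4,
                            flank_top = 0.95 * peak) {
  c(seq(flank_top / (n_up + 1), flank_top, length.out = n_up),
    rep(peak, n_plateau),
    seq(flank_top, flank_top / (n_down + 1), length.out = n_down))
}

# One synthetic feature-table row, centred well inside the hyphae gate by
# default; override fields to move it around the gating tree.
feature_row <- function(...,
                        fws_maximum = 800, fws_total = 3e4, fws_length = 60,
                        fws_sample_length = 55, fws_fill_factor = 0.6,
                        sws_total = 1e4, sws_maximum = 300, sws_length = 60,
                        sws_sample_length = 50, sws_fill_factor = 0.5,
                        fl_green_total = 500,
                        saturation_level = 1e4,
                        particle_id = "x1") {
  over <- list(...)
  row <- tibble::tibble(
    particle_id = particle_id,
    fws_maximum = fws_maximum, fws_total = fws_total, fws_length = fws_length,
    fws_sample_length = fws_sample_length, fws_fill_factor = fws_fill_factor,
    sws_maximum = sws_maximum, sws_total = sws_total, sws_length = sws_length,
    sws_sample_length = sws_sample_length, sws_fill_factor = sws_fill_factor,
    fl_green_total = fl_green_total
  )
  for (k in names(over)) row[[k]] <- over[[k]]
  derive_ratios(row, saturation_level = saturation_level)
}
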