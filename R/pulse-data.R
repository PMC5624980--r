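#' Measurement metadata for a list-mode dataset
#'
#' Bundles the acquisition calibration and the per-measurement bookkeeping
#' needed to turn particle counts into concentrations of undiluted broth.
#'
#' @param um_per_sample Spatial calibration of the pulse sampling, in
#'   micrometres per sample point. Instrument-specific; there is no universal
#'   default, so it must be supplied (the simulator uses 1 um/sample).
#' @param saturation_level Detector saturation in arbitrary units. Forward
#'   scatter clips at this level on dense pellet cores (default `1e4`).
#' @param pump_speed Sample pump speed in ul/s (default 15).
#' @param duration Measurement duration in seconds (default 80, i.e. 1200 ul
#'   of diluted sample at the default pump speed).
#' @param dilution_factor Fold dilution of the broth before measurement
#'   (default 1000).
#' @param sample_label Free-text sample identifier.
#' @param timepoint Process time of the sample in hours (may be `NA`).
#'
#' @return A list of class `measurement_meta`.
#' @export
#' @examples
#' measurement_meta(um_per_sample = 1)
measurement_meta <- function(um_per_sample,
                             saturation_level = 1e4,
                             pump_speed = 15,
                             duration = 80,
                             dilution_factor = 1000,
                             sample_label = "",
                             timepoint = NA_real_) {
  stopifnot(is.numeric(um_per_sample), length(um_per_sample) == 1)
  if (!is.finite(um_per_sample) || um_per_sample <= 0)
    abort("`um_per_sample` must be a positive number.")
  if (!is.finite(saturation_level) || saturation_level <= 0)
    abort("`saturation_level` must be a positive number.")
  if (!is.finite(pump_speed) || pump_speed <= 0)
    abort("`pump_speed` must be a positive number (ul/s).")
  if (!is.finite(duration) || duration <= 0)
    abort("`duration` must be a positive number (s).")
  if (!is.finite(dilution_factor) || dilution_factor <= 0)
    abort("`dilution_factor` must be a positive number.")
  structure(
    list(
      um_per_sample = as.numeric(um_per_sample),
      saturation_level = as.numeric(saturation_level),
      pump_speed = as.numeric(pump_speed),
      duration = as.numeric(duration),
      dilution_factor = as.numeric(dilution_factor),
      sample_label = as.character(sample_label),
      timepoint = as.numeric(timepoint)
    ),
    class = "measurement_meta"
  )
}

#' @export
print.measurement_meta <- function(x, ...) {
  cat("<measurement_meta>\n")
  cat(sprintf("  calibration : %g um/sample, saturation %g a.u.\n",
              x$um_per_sample, x$saturation_level))
  cat(sprintf("  volume      : %g ul/s x %g s = %g ul (dilution 1:%g)\n",
              x$pump_speed, x$duration, x$pump_speed * x$duration,
              x$dilution_factor))
  if (nzchar(x$sample_label) || !is.na(x$timepoint))
    cat(sprintf("  sample      : %s (t = %g h)\n", x$sample_label, x$timepoint))
  invisible(x)
}

#' Assemble a pulse-shape list-mode table
#'
#' The in-memory representation of a list-mode dataset is a long tibble with
#' one row per sampled intensity value:
#' `particle_id`, `channel`, `sample_index` (0-based, contiguous within a
#' particle-channel), `value` (a.u., non-negative, clipped at the saturation
#' level). Measurement metadata travels in the `meta` attribute.
#'
#' @param pulses A data frame with columns `particle_id`, `channel`,
#'   `sample_index`, `value`.
#' @param meta A [measurement_meta()] object.
#' @param validate Check the invariants (mandatory FWS/SWS per particle,
#'   0-based contiguous sample indices, values in `[0, saturation_level]`).
#'
#' @return A tibble of class `tbl_pulse`.
#' @export
pulse_tbl <- function(pulses, meta, validate = TRUE) {
  if (!inherits(meta, "measurement_meta"))
    abort("`meta` must be a measurement_meta object.")
  pulses <- as_tibble(pulses)
  required <- c("particle_id", "channel", "sample_index", "value")
  missing_cols <- setdiff(required, names(pulses))
  if (length(missing_cols))
    abort(paste0("pulse table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  pulses <- pulses[required]
  pulses$channel <- as.character(pulses$channel)
  pulses$sample_index <- as.integer(pulses$sample_index)
  pulses$value <- as.numeric(pulses$value)
  # canonical row order so that writing and re-reading is an identity
  pulses <- pulses[order(pulses$particle_id,
                         match(pulses$channel, pm_channels),
                         pulses$sample_index), , drop = FALSE]
  out <- structure(pulses, meta = meta,
                   class = c("tbl_pulse", class(tibble())))
  if (validate) validate_pulses(out)
  out
}

#' @rdname pulse_tbl
#' @param x A `tbl_pulse`.
#' @export
pulse_meta <- function(x) {
  m <- attr(x, "meta", exact = TRUE)
  if (is.null(m)) abort("object carries no measurement_meta attribute.")
  m
}

#' @rdname pulse_tbl
#' @export
validate_pulses <- function(pulses) {
  meta <- pulse_meta(pulses)
  bad_chan <- setdiff(unique(pulses$channel), pm_channels)
  if (length(bad_chan))
    abort(paste0("unknown channel name(s): ", paste(bad_chan, collapse = ", ")))
  if (any(!is.finite(pulses$value)) || any(pulses$value < 0))
    abort("pulse values must be finite and non-negative.")
  if (any(pulses$value > meta$saturation_level + 1e-9))
    abort("pulse values exceed the saturation level; data are expected clipped at acquisition.")
  chk <- pulses |>
    group_by(.data$particle_id, .data$channel) |>
    summarise(
      n = n(),
      ok_idx = all(.data$sample_index == seq_len(n()) - 1L),
      .groups = "drop_last"
    ) |>
    summarise(
      has_fws = "FWS" %in% .data$channel,
      has_sws = "SWS" %in% .data$channel,
      ok_idx = all(.data$ok_idx),
      .groups = "drop"
    )
  bad_idx <- chk$particle_id[!chk$ok_idx]
  if (length(bad_idx))
    abort(paste0("non-monotone or non-contiguous sample_index for particle(s): ",
                 paste(head(bad_idx, 5), collapse = ", ")))
  bad_mand <- chk$particle_id[!(chk$has_fws & chk$has_sws)]
  if (length(bad_mand))
    abort(paste0("mandatory channel (FWS and/or SWS) missing for particle(s): ",
                 paste(head(bad_mand, 5), collapse = ", ")))
  invisible(pulses)
}

#' @export
print.tbl_pulse <- function(x, ...) {
  m <- attr(x, "meta", exact = TRUE)
  n_part <- dplyr::n_distinct(x$particle_id)
  cat(sprintf("# A pulse-shape list-mode table: %d particles, %d rows\n",
              n_part, nrow(x)))
  if (!is.null(m))
    cat(sprintf("# %g um/sample, saturation %g a.u., %g ul measured\n",
                m$um_per_sample, m$saturation_level,
                m$pump_speed * m$duration))
  NextMethod()
}
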