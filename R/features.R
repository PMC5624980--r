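#' Extract curve parameters from pulse shapes
#'
#' Computes, per particle and channel, the five standard pulse-shape curve
#' parameters:
#'
#' * `maximum` — maximum of the signal curve (a.u.);
#' * `total` — area beneath the curve, a unit-width Riemann sum of all
#'   samples (a.u.);
#' * `length` — length of the recorded signal, `n_samples * um_per_sample`
#'   (um);
#' * `sample_length` — length of the signal above the trigger level: the
#'   contiguous envelope from the first to the last above-trigger sample,
#'   interior dips included (um);
#' * `fill_factor` — similarity of the curve to a block in `[0, 1]`: the mean
#'   of the envelope samples divided by the maximum. A rectangular pulse
#'   scores 1; a pulse entirely below trigger scores 0.
#'
#' and the derived quantities used by the gating tree (see [derive_ratios()]).
#' Columns are named `<channel>_<parameter>` in lower case
#' (e.g. `sws_total`, `fws_fill_factor`, `fl_green_total`).
#'
#' @param pulses A [pulse_tbl()] (long list-mode table with metadata), or a
#'   plain long data frame if `um_per_sample` and `saturation_level` are
#'   given.
#' @param trigger_level Trigger level in a.u. (strictly-above comparison).
#'   The instrument trigger is not part of the data file, so it is an
#'   explicit argument; default 0.
#' @param um_per_sample,saturation_level Overrides for the metadata fields;
#'   taken from `pulse_meta(pulses)` when absent.
#'
#' @return A tibble with one row per particle.
#' @export
#' @examples
#' run <- simulate_run(sim_params(n = 20), seed = 1)
#' extract_features(run$pulses)
extract_features <- function(pulses, trigger_level = 0,
                             um_per_sample = NULL, saturation_level = NULL) {
  meta <- attr(pulses, "meta", exact = TRUE)
  um_per_sample <- um_per_sample %||% meta$um_per_sample
  saturation_level <- saturation_level %||% meta$saturation_level
  if (is.null(um_per_sample) || is.null(saturation_level))
    abort("supply `um_per_sample` and `saturation_level` (or a tbl_pulse with metadata).")
  if (!nrow(pulses)) {
    return(tibble(particle_id = character()))
  }
  trig <- trigger_level
  ups <- um_per_sample

  per_chan <- pulses |>
    group_by(.data$particle_id, .data$channel) |>
    arrange(.data$sample_index, .by_group = TRUE) |>
    summarise(
      maximum = max(.data$value),
      total = sum(.data$value),
      n = n(),
      i1 = if (any(.data$value > trig)) min(which(.data$value > trig)) else NA_integer_,
      i2 = if (any(.data$value > trig)) max(which(.data$value > trig)) else NA_integer_,
      env_sum = if (is.na(i1)) 0 else sum(.data$value[i1:i2]),
      .groups = "drop"
    ) |>
    mutate(
      length = .data$n * ups,
      n_env = ifelse(is.na(.data$i1), 0L, .data$i2 - .data$i1 + 1L),
      sample_length = .data$n_env * ups,
      fill_factor = ifelse(
        .data$n_env > 0 & .data$maximum > 0,
        pmin(1, .data$env_sum / (.data$maximum * .data$n_env)),
        0
      )
    ) |>
    select("particle_id", "channel", "maximum", "total", "length",
           "sample_length", "fill_factor")

  wide <- per_chan |>
    tidyr::pivot_wider(
      id_cols = "particle_id",
      names_from = "channel",
      values_from = c("maximum", "total", "length", "sample_length", "fill_factor"),
      names_glue = "{tolower(channel)}_{.value}"
    )
  # stable column order: particle_id, then channel blocks
  chans <- intersect(tolower(pm_channels), unique(tolower(per_chan$channel)))
  params <- c("maximum", "total", "length", "sample_length", "fill_factor")
  ord <- c("particle_id",
           unlist(lapply(chans, function(ch) paste0(ch, "_", params))))
  wide <- wide[intersect(ord, names(wide))]
  derive_ratios(wide, saturation_level = saturation_level)
}

#' Derived gating ratios
#'
#' Adds the quantities the pellet gate consumes:
#' `fws_max_over_fill` (FWS maximum / FWS fill factor, a.u.),
#' `sws_total_over_sample_length` (SWS total / SWS sample length, a.u./um)
#' and the flag `fws_saturated` (FWS maximum at or above the saturation
#' level, the signature of a dense pellet core). Ratios with a zero
#' denominator are `NA` and route the particle to `unclassified` downstream.
#'
#' @param features A feature table from [extract_features()] containing at
#'   least the FWS and SWS blocks.
#' @param saturation_level Detector saturation level (a.u.).
#' @return `features` with the three derived columns (recomputed if present).
#' @export
derive_ratios <- function(features, saturation_level) {
  need <- c("fws_maximum", "fws_fill_factor", "sws_total", "sws_sample_length")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols))
    abort(paste0("feature table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  features |>
    mutate(
      fws_max_over_fill = ifelse(.data$fws_fill_factor > 0,
                                 .data$fws_maximum / .data$fws_fill_factor,
                                 NA_real_),
      sws_total_over_sample_length = ifelse(.data$sws_sample_length > 0,
                                            .data$sws_total / .data$sws_sample_length,
                                            NA_real_),
      fws_saturated = .data$fws_maximum >= saturation_level
    )
}

#' Export a feature table as CSV
#'
#' One row per particle, one column per channel-parameter plus the derived
#' ratios (and, if present, class labels) — the scalar hand-off consumed by
#' spreadsheet or cytometry software.
#'
#' @param features A feature (or classified) table.
#' @param path Output path.
#' @export
export_features_csv <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}
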