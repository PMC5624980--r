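#' Plot one particle's pulse shapes
#'
#' Intensity-vs-position curves for the selected channels, with the
#' saturation level as a horizontal line and, for saturated FWS pulses, the
#' detected core interval as vertical lines — the standard way to inspect a
#' pellet's annulus and core.
#'
#' @param pulses A [pulse_tbl()].
#' @param particle_id Particle to plot.
#' @param channels Channels to show.
#' @param show_core Draw the detected FWS core interval when the pulse is
#'   saturated.
#' @param trigger_level Trigger level used for the core envelope.
#' @return A ggplot object.
#' @export
plot_pulse <- function(pulses, particle_id, channels = c("FWS", "SWS"),
                       show_core = TRUE, trigger_level = 0) {
  meta <- pulse_meta(pulses)
  pid <- particle_id
  dat <- pulses |>
    filter(.data$particle_id == pid, .data$channel %in% channels) |>
    mutate(position_um = .data$sample_index * meta$um_per_sample)
  if (!nrow(dat)) abort(paste0("no such particle: ", pid))
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$position_um, .data$value,
                                         colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = meta$saturation_level,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "position (um)", y = "intensity (a.u.)",
                  title = paste("particle", pid)) +
    ggplot2::theme_minimal()
  fws <- dat$value[dat$channel == "FWS"]
  if (show_core && length(fws) && any(fws >= meta$saturation_level)) {
    core <- detect_core(fws, meta$saturation_level, trigger_level,
                        meta$um_per_sample)
    p <- p + ggplot2::geom_vline(
      xintercept = c(core$core_start, core$core_end) * meta$um_per_sample,
      linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot a size distribution
#'
#' @param dist A [size_distribution()] tibble.
#' @return A ggplot column chart of relative frequency per size bin.
#' @export
plot_size_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(.data$bin_mid, .data$freq)) +
    ggplot2::geom_col(width = if (nrow(dist)) diff(range(dist$bin_left)) /
                        max(1, nrow(dist) - 1) * 0.9 else 1,
                      fill = "steelblue") +
    ggplot2::labs(x = "sample length (um)", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Plot class composition over process time
#'
#' Stacked-area views of a [morphology_timecourse()]: either the per-class
#' element concentrations or the SWS biomass fractions.
#'
#' @param timecourse A timecourse tibble.
#' @param what `"concentration"` or `"sws_fraction"`.
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(timecourse,
                                 what = c("sws_fraction", "concentration")) {
  what <- match.arg(what)
  ggplot2::ggplot(timecourse,
                  ggplot2::aes(.data$timepoint, .data[[what]],
                               fill = .data$class)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "process time (h)",
                  y = if (what == "sws_fraction") "SWS fraction (%)"
                      else "elements / ml") +
    ggplot2::theme_minimal()
}
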