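#' Detect the pellet core in a forward-scatter pulse
#'
#' A pellet's dense core saturates the forward-scatter detector. The core
#' interval runs from the first to the last saturated sample (half-open
#' `[core_start, core_end)`, 0-based sample units); interior unsaturated dips
#' — degraded or vacuolized core regions — belong to the core. The annular
#' flanks are the above-trigger signal on either side of the core, and the
#' particle length is the above-trigger envelope of the FWS signal.
#'
#' @param samples Numeric vector: one particle's FWS pulse samples.
#' @param saturation_level Detector saturation (a.u.).
#' @param trigger_level Trigger level (a.u., strictly-above).
#' @param um_per_sample Spatial calibration (um per sample).
#' @param sat_tol Tolerance below `saturation_level` still counted as
#'   saturated (default 0; acquisition clips exactly at the level).
#'
#' @return A one-row tibble: `core_start`, `core_end` (0-based, half-open),
#'   `particle_length`, `annular_diameter`, `core_diameter` (um), `rad`
#'   (relative annular diameter, annular diameter / particle length) and
#'   `compactness` (fraction of core samples at saturation).
#' @export
#' @examples
#' pulse <- c(seq(500, 9500, length.out = 13), rep(1e4, 74),
#'            seq(9500, 500, length.out = 13))
#' detect_core(pulse, saturation_level = 1e4)
detect_core <- function(samples, saturation_level, trigger_level = 0,
                        um_per_sample = 1, sat_tol = 0) {
  if (!length(samples)) abort("empty pulse.")
  env <- which(samples > trigger_level)
  if (!length(env)) abort("pulse entirely below trigger level; no signal envelope.")
  e1 <- min(env); e2 <- max(env)
  sat <- which(samples >= saturation_level - sat_tol)
  if (!length(sat))
    abort("no saturated FWS sample: pellet metrics are defined only for saturated (pellet) pulses.")
  s1 <- min(sat); s2 <- max(sat)
  n_particle <- e2 - e1 + 1L
  n_core <- s2 - s1 + 1L
  n_sat_in_core <- sum(samples[s1:s2] >= saturation_level - sat_tol)
  particle_length <- n_particle * um_per_sample
  core_diameter <- n_core * um_per_sample
  tibble(
    core_start = s1 - 1L,           # 0-based
    core_end = s2,                  # half-open [core_start, core_end)
    particle_length = particle_length,
    annular_diameter = particle_length - core_diameter,
    core_diameter = core_diameter,
    rad = (particle_length - core_diameter) / particle_length,
    compactness = n_sat_in_core / n_core
  )
}

#' @rdname detect_core
#' @export
compute_rad <- function(samples, saturation_level, trigger_level = 0,
                        um_per_sample = 1, sat_tol = 0) {
  detect_core(samples, saturation_level, trigger_level, um_per_sample,
              sat_tol)$rad
}

#' @rdname detect_core
#' @export
compute_compactness <- function(samples, saturation_level, trigger_level = 0,
                                um_per_sample = 1, sat_tol = 0) {
  detect_core(samples, saturation_level, trigger_level, um_per_sample,
              sat_tol)$compactness
}

#' Pellet descriptors for a classified run
#'
#' Computes relative annular diameter and core compactness from the FWS pulse
#' of every pellet in a run.
#'
#' @param pulses A [pulse_tbl()].
#' @param particles Optional classified feature table ([classify_particles()]);
#'   when given, only rows with `class == "pellet"` are measured. Otherwise
#'   `particle_ids` selects the pellets explicitly.
#' @param particle_ids Explicit particle ids to measure (ignored when
#'   `particles` is given).
#' @param trigger_level Trigger level (a.u.).
#' @param sat_tol Saturation tolerance, see [detect_core()].
#' @return A tibble with one row per pellet: id, `particle_length`,
#'   `annular_diameter`, `core_diameter`, `core_start`, `core_end`, `rad`,
#'   `compactness`.
#' @export
pellet_metrics <- function(pulses, particles = NULL, particle_ids = NULL,
                           trigger_level = 0, sat_tol = 0) {
  meta <- pulse_meta(pulses)
  if (!is.null(particles)) {
    if (!"class" %in% names(particles))
      abort("`particles` must be a classified feature table (with a `class` column).")
    particle_ids <- particles$particle_id[particles$class == "pellet"]
  }
  if (is.null(particle_ids))
    abort("supply either `particles` (classified) or `particle_ids`.")
  empty <- tibble(particle_id = character(), core_start = integer(),
                  core_end = integer(), particle_length = double(),
                  annular_diameter = double(), core_diameter = double(),
                  rad = double(), compactness = double())
  if (!length(particle_ids)) return(empty)
  fws <- pulses |>
    filter(.data$channel == "FWS", .data$particle_id %in% particle_ids) |>
    arrange(.data$particle_id, .data$sample_index)
  out <- fws |>
    group_by(.data$particle_id) |>
    reframe(detect_core(.data$value, saturation_level = meta$saturation_level,
                        trigger_level = trigger_level,
                        um_per_sample = meta$um_per_sample,
                        sat_tol = sat_tol))
  out[c("particle_id", setdiff(names(out), "particle_id"))]
}
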