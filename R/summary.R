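#' Per-class SWS biomass fractions
#'
#' The SWS fraction of a morphological class is its share of the summed SWS
#' total signal, in percent:
#' `100 * sum(SWS total | class) / sum(SWS total | all elements)`.
#' Because SWS total scales with element volume, this is a biomass-volume
#' weighted class distribution, unlike raw element counts. By default the
#' denominator runs over the classified viable elements (the four
#' morphological classes); `include_unclassified = TRUE` adds unclassified
#' viable particles to the denominator.
#'
#' @param particles Classified feature table with `sws_total` and `class`.
#' @param include_unclassified Include unclassified viable particles in the
#'   denominator (their share is then reported as its own row).
#' @return A tibble `class`, `sws_total`, `sws_fraction` (percent; all four
#'   morphological classes always present, absent ones at 0). Fractions sum
#'   to 100.
#' @export
sws_fractions <- function(particles, include_unclassified = FALSE) {
  keep <- as.character(particles$class) %in% pm_morph_classes
  if (include_unclassified)
    keep <- keep | as.character(particles$class) == "unclassified"
  dat <- particles[keep, , drop = FALSE]
  if (!nrow(dat) || !any(dat$sws_total > 0))
    abort("no classified particle with positive SWS total; fractions undefined.")
  lev <- if (include_unclassified) c(pm_morph_classes, "unclassified") else
    pm_morph_classes
  dat |>
    count(class = factor(as.character(.data$class), levels = lev),
          wt = .data$sws_total, name = "sws_total", .drop = FALSE) |>
    mutate(sws_fraction = 100 * .data$sws_total / sum(.data$sws_total))
}

#' Element concentrations in undiluted broth
#'
#' Converts per-class particle counts into concentrations per ml of
#' undiluted broth: `count / (pump_speed * duration) * dilution_factor`,
#' with the analyzed volume `pump_speed * duration` in ul converted to ml.
#'
#' @param counts A tibble with columns `class` and `n` ([class_counts()]),
#'   or a named numeric vector of counts.
#' @param meta A [measurement_meta()] (pump speed ul/s, duration s, dilution
#'   fold).
#' @return A tibble `class`, `n`, `volume_ml` (diluted sample analyzed),
#'   `concentration` (elements per ml undiluted broth).
#' @export
#' @examples
#' m <- measurement_meta(um_per_sample = 1, pump_speed = 15, duration = 80,
#'                       dilution_factor = 1000)
#' class_concentrations(tibble::tibble(class = "pellet", n = 120), m)
class_concentrations <- function(counts, meta) {
  stopifnot(inherits(meta, "measurement_meta"))
  if (is.numeric(counts) && !is.null(names(counts)))
    counts <- tibble(class = names(counts), n = as.integer(counts))
  if (any(counts$n < 0)) abort("counts must be non-negative.")
  volume_ml <- meta$pump_speed * meta$duration / 1000
  counts |>
    mutate(volume_ml = volume_ml,
           concentration = .data$n / volume_ml * meta$dilution_factor)
}

#' Pool replicate concentration measurements
#'
#' Replicate measurements of the same sample are pooled per class by a
#' volume-weighted mean, with the between-replicate standard deviation
#' reported alongside.
#'
#' @param replicates A list of concentration tables ([class_concentrations()]).
#' @return A tibble `class`, `n_replicates`, `concentration` (volume-weighted
#'   mean), `concentration_sd`.
#' @export
pool_replicates <- function(replicates) {
  if (length(replicates) < 2)
    abort("need at least two replicate measurements to pool.")
  bind_rows(replicates, .id = "replicate") |>
    group_by(.data$class) |>
    summarise(
      n_replicates = n(),
      concentration_sd = sd(.data$concentration),
      concentration = sum(.data$concentration * .data$volume_ml) /
        sum(.data$volume_ml),
      .groups = "drop"
    ) |>
    select("class", "n_replicates", "concentration", "concentration_sd")
}

#' Per-class size distributions
#'
#' Relative size histograms of the classified elements. "Size" is the sample
#' length of the configured gating channel (SWS by default); histograms are
#' normalized to the number of elements in the selected class union, so
#' frequencies sum to 1.
#'
#' Predefined unions: `"hyphal_aggregates"` (small clumps + large clumps +
#' pellets) and `"large_elements"` (large clumps + pellets); otherwise any
#' subset of the four class names.
#'
#' @param particles Classified feature table.
#' @param classes A union keyword or character vector of classes.
#' @param breaks Bin edges in um; default 20 equal-width bins from 0 to the
#'   99.5th percentile of the selected sizes.
#' @param size_col Feature column holding the size (default
#'   `"sws_sample_length"`).
#' @return A tibble `bin_left`, `bin_right`, `bin_mid`, `n`, `freq`
#'   (empty when no element matches).
#' @export
size_distribution <- function(particles, classes = "hyphal_aggregates",
                              breaks = NULL, size_col = "sws_sample_length") {
  classes <- switch(classes[1],
    hyphal_aggregates = c("small_clump", "large_clump", "pellet"),
    large_elements = c("large_clump", "pellet"),
    all = pm_morph_classes,
    classes
  )
  bad <- setdiff(classes, pm_morph_classes)
  if (length(bad))
    abort(paste0("unknown class(es): ", paste(bad, collapse = ", ")))
  sizes <- particles[[size_col]][as.character(particles$class) %in% classes]
  sizes <- sizes[!is.na(sizes)]
  empty <- tibble(bin_left = double(), bin_right = double(),
                  bin_mid = double(), n = integer(), freq = double())
  if (!length(sizes)) return(empty)
  if (is.null(breaks)) {
    upper <- quantile(sizes, 0.995, names = FALSE)
    if (upper <= 0) upper <- max(sizes, 1)
    breaks <- seq(0, upper, length.out = 21)
  }
  breaks <- sort(unique(breaks))
  counts <- tabulate(findInterval(sizes, breaks,
                                  rightmost.closed = TRUE, all.inside = TRUE),
                     nbins = length(breaks) - 1)
  tibble(
    bin_left = breaks[-length(breaks)],
    bin_right = breaks[-1],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    n = counts,
    freq = counts / length(sizes)
  )
}

#' Summarize one classified run
#'
#' Per-class counts, concentrations, SWS fractions and sample-length
#' statistics for a single measurement, plus mean pellet descriptors when
#' pellet metrics are supplied.
#'
#' @param particles Classified feature table.
#' @param meta The run's [measurement_meta()].
#' @param pellets Optional [pellet_metrics()] table.
#' @param size_col Size column used for the per-class length statistics.
#' @return A tibble with one row per morphological class: `timepoint`,
#'   `sample_label`, `class`, `n`, `concentration`, `sws_fraction`,
#'   `mean_sample_length`, `sd_sample_length`, and (on pellet rows)
#'   `mean_rad`, `mean_compactness`.
#' @export
summarize_run <- function(particles, meta, pellets = NULL,
                          size_col = "sws_sample_length") {
  counts <- class_counts(particles) |>
    filter(.data$class %in% pm_morph_classes) |>
    mutate(class = factor(as.character(.data$class), levels = pm_morph_classes))
  conc <- class_concentrations(counts, meta)
  fr <- sws_fractions(particles) |> select("class", "sws_fraction")
  lens <- particles |>
    filter(as.character(.data$class) %in% pm_morph_classes) |>
    group_by(class = factor(as.character(.data$class),
                            levels = pm_morph_classes)) |>
    summarise(mean_sample_length = mean(.data[[size_col]]),
              sd_sample_length = sd(.data[[size_col]]),
              .groups = "drop")
  out <- conc |>
    left_join(fr, by = "class") |>
    left_join(lens, by = "class") |>
    mutate(timepoint = meta$timepoint, sample_label = meta$sample_label,
           .before = 1)
  if (!is.null(pellets) && nrow(pellets)) {
    out$mean_rad <- ifelse(out$class == "pellet", mean(pellets$rad), NA_real_)
    out$mean_compactness <- ifelse(out$class == "pellet",
                                   mean(pellets$compactness), NA_real_)
  } else {
    out$mean_rad <- NA_real_
    out$mean_compactness <- NA_real_
  }
  out
}

#' Stack run summaries into a time course
#'
#' @param summaries A list of [summarize_run()] tables (one per sample /
#'   timepoint).
#' @return A tidy long tibble ordered by `timepoint` then `class`; empty
#'   input gives an empty tibble.
#' @export
morphology_timecourse <- function(summaries) {
  if (!length(summaries)) {
    return(tibble(timepoint = double(), sample_label = character(),
                  class = character(), n = integer(),
                  concentration = double(), sws_fraction = double()))
  }
  bind_rows(summaries) |> arrange(.data$timepoint, .data$class)
}

#' Replicate measurement error
#'
#' Mean, standard deviation and percent coefficient of variation per
#' parameter across replicate measurements of the same sample — the
#' measurement-error framework (errors in % and absolute units).
#'
#' @param replicates A data frame with one row per replicate; all numeric
#'   columns are treated as parameters unless `params` narrows them.
#' @param params Optional character vector of parameter columns.
#' @return A tibble `parameter`, `n`, `mean`, `sd`, `cv_pct`
#'   (`sd / mean * 100`; `NA` when the mean is 0).
#' @export
#' @examples
#' replicate_error(tibble::tibble(rad = c(0.30, 0.33), compactness = c(0.9, 0.92)))
replicate_error <- function(replicates, params = NULL) {
  replicates <- as_tibble(replicates)
  if (nrow(replicates) < 2)
    abort("need at least two replicates to estimate a measurement error.")
  num <- names(replicates)[vapply(replicates, is.numeric, logical(1))]
  params <- params %||% num
  bad <- setdiff(params, num)
  if (length(bad))
    abort(paste0("non-numeric parameter column(s): ", paste(bad, collapse = ", ")))
  replicates |>
    select(all_of(params)) |>
    tidyr::pivot_longer(everything(), names_to = "parameter") |>
    group_by(.data$parameter) |>
    summarise(n = sum(!is.na(.data$value)),
              mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              .groups = "drop") |>
    mutate(cv_pct = ifelse(.data$mean != 0, .data$sd / .data$mean * 100,
                           NA_real_)) |>
    arrange(match(.data$parameter, params))
}
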