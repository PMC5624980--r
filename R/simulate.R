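#' Parameters of the synthetic pulse-shape simulator
#'
#' The simulator generates per-particle FWS/SWS/FL_GREEN pulse shapes for the
#' four morphological classes plus medium background, with ground-truth
#' labels and pellet geometry, so the whole pipeline can be exercised without
#' instrument data. Class geometry priors are drawn inside the default gates
#' with a configurable relative margin, emulating the phenomenology of each
#' class:
#'
#' * hyphae — short, low-amplitude single-lobe pulses;
#' * small clumps — short multi-lobe pulses of intermediate SWS total;
#' * large clumps — long irregular pulses whose FWS stays below saturation
#'   (no dense core);
#' * pellets — long ramp-plateau-ramp FWS pulses whose plateau is generated
#'   above the saturation level and clipped to it (the dense core), with a
#'   configurable annular fraction (true RAD) and, for degraded cores,
#'   interior dips (true compactness < 1);
#' * background — particles whose total green fluorescence stays below the
#'   viability threshold.
#'
#' Multiplicative lognormal noise is applied before saturation clipping, so
#' pellet plateaus sit exactly at the saturation level, as at acquisition.
#' All geometry is drawn in integer sample units so that ground truth is
#' recoverable exactly up to one sample width.
#'
#' @param n Number of particles.
#' @param mixture Named class probabilities (must sum to 1).
#' @param um_per_sample,saturation_level Acquisition calibration.
#' @param gate_margin Relative margin by which class priors stay inside their
#'   gates (default 0.10).
#' @param hyphae,small_clump,large_clump,pellet,background Per-class geometry
#'   priors (ranges in um / a.u.; see defaults).
#' @param noise `sigma`: lognormal sigma of the multiplicative sample noise;
#'   `baseline`: additive baseline (default 0 so the above-trigger envelope
#'   equals the generated extent).
#' @param fl_green Total green fluorescence ranges for viable particles and
#'   background.
#' @param meta A [measurement_meta()] for the run.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n = 1000,
                       mixture = c(hyphae = 0.40, small_clump = 0.30,
                                   large_clump = 0.20, pellet = 0.07,
                                   background = 0.03),
                       um_per_sample = 1,
                       saturation_level = 1e4,
                       gate_margin = 0.10,
                       hyphae = list(sample_length = c(30, 90),
                                     sws_total = c(3e3, 1.5e4)),
                       small_clump = list(sample_length = c(40, 88),
                                          sws_total = c(2.2e4, 7.2e4),
                                          lobes = c(2, 4)),
                       large_clump = list(sample_length = c(120, 250),
                                          sws_total_per_um = c(250, 700),
                                          fws_peak_frac = c(0.3, 0.85)),
                       pellet = list(sample_length = c(150, 280),
                                     sws_total_per_um = c(1000, 2000),
                                     annular_fraction = c(0.15, 0.5),
                                     compactness = c(0.55, 0.95),
                                     degraded_prob = 0.3,
                                     fws_overdrive = c(1.5, 2.5)),
                       background = list(sample_length = c(5, 30),
                                         sws_total = c(50, 500)),
                       noise = list(sigma = 0.05, baseline = 0),
                       fl_green = list(viable_total = c(200, 5000),
                                       background_total = c(1, 20)),
                       meta = NULL) {
  meta <- meta %||% measurement_meta(um_per_sample = um_per_sample,
                                     saturation_level = saturation_level)
  p <- structure(
    list(n = n, mixture = mixture, um_per_sample = um_per_sample,
         saturation_level = saturation_level, gate_margin = gate_margin,
         hyphae = hyphae, small_clump = small_clump,
         large_clump = large_clump, pellet = pellet,
         background = background, noise = noise, fl_green = fl_green,
         meta = meta),
    class = "sim_params"
  )
  validate_sim_params(p)
}

#' @rdname sim_params
#' @param params A `sim_params` list.
#' @param config Gating configuration the priors must respect.
#' @export
validate_sim_params <- function(params, config = gate_config()) {
  mx <- params$mixture
  if (any(mx < 0) || abs(sum(mx) - 1) > 1e-9)
    abort("mixture probabilities must be non-negative and sum to 1.")
  bad <- setdiff(names(mx),
                 c(pm_morph_classes, "background"))
  if (length(bad))
    abort(paste0("unknown mixture class(es): ", paste(bad, collapse = ", ")))
  if (params$n < 0 || params$n != round(params$n))
    abort("`n` must be a non-negative integer.")
  m <- params$gate_margin
  lo <- function(x) x * (1 + m)   # must exceed threshold x by the margin
  hi <- function(x) x * (1 - m)   # must stay below threshold x by the margin
  chk <- function(ok, msg) if (!ok) abort(paste0(
    "simulator priors incompatible with gate margins: ", msg))
  h <- params$hyphae; sc <- params$small_clump
  lc <- params$large_clump; pl <- params$pellet
  cfg <- config
  chk(h$sample_length[1] >= lo(cfg$hyphae$sample_length_min) &&
        h$sample_length[2] <= hi(cfg$hyphae$sample_length_max),
      "hyphae sample length outside the hyphae gate.")
  chk(h$sws_total[2] <= hi(cfg$small_clump$sws_total_min),
      "hyphae SWS total reaches into the small-clump gate.")
  chk(h$sample_length[2] <= hi(cfg$hyphae$fws_length_max),
      "hyphae FWS length reaches the hyphae FWS-length bound.")
  chk(sc$sample_length[1] >= lo(cfg$small_clump$sample_length_min) &&
        sc$sample_length[2] <= hi(cfg$large_gate$sample_length_min),
      "small-clump sample length must stay below the large-element gate.")
  chk(sc$sws_total[1] >= lo(cfg$small_clump$sws_total_min) &&
        sc$sws_total[2] <= hi(cfg$small_clump$sws_total_max),
      "small-clump SWS total outside the small-clump gate.")
  chk(sc$sample_length[1] >= lo(cfg$small_clump$fws_length_min),
      "small-clump FWS length below the small-clump gate.")
  chk(lc$sample_length[1] >= lo(cfg$large_gate$sample_length_min),
      "large-clump sample length below the large-element gate.")
  chk(lc$sample_length[1] * lc$sws_total_per_um[1] >=
        lo(cfg$large_gate$sws_total_min),
      "large-clump SWS total below the large-element gate.")
  chk(lc$fws_peak_frac[2] <= 0.9,
      "large-clump FWS peak must stay clearly below saturation.")
  chk(pl$sample_length[1] >= lo(cfg$pellet$sample_length_min),
      "pellet sample length below the pellet gate.")
  chk(pl$sws_total_per_um[1] >=
        lo(cfg$pellet$sws_total_over_sample_length_min),
      "pellet SWS total per um below the pellet ratio gate.")
  chk(pl$sample_length[1] * pl$sws_total_per_um[1] >=
        lo(cfg$pellet$sws_total_min),
      "pellet SWS total below the pellet gate.")
  chk(pl$fws_overdrive[1] >= 1.2,
      "pellet FWS overdrive must exceed saturation.")
  chk(params$fl_green$viable_total[1] >= lo(cfg$green_fl_total_min),
      "viable green-fluorescence total below the viability threshold.")
  chk(params$fl_green$background_total[2] <= hi(cfg$green_fl_total_min),
      "background green-fluorescence total reaches the viability threshold.")
  params
}

runif1 <- function(r) runif(1, r[1], r[2])

# raised-cosine lobe strictly positive over n samples
lobe_shape <- function(n, centers, widths, weights) {
  x <- seq_len(n)
  y <- rep(0.05, n)
  for (i in seq_along(centers))
    y <- y + weights[i] * exp(-0.5 * ((x - centers[i]) / widths[i])^2)
  y
}

#' Simulate one particle
#'
#' @param class One of hyphae, small_clump, large_clump, pellet, background.
#' @param params A [sim_params()] object.
#' @param id Particle id string.
#' @return A list with `pulses` (named list of numeric vectors per channel)
#'   and `truth` (one-row tibble: class, true_sample_length, true_rad,
#'   true_compactness).
#' @export
simulate_particle <- function(class, params, id = "p1") {
  ups <- params$um_per_sample
  sat <- params$saturation_level
  sigma <- params$noise$sigma
  baseline <- params$noise$baseline
  pad <- 2L  # below-trigger samples flanking every pulse
  noisy <- function(x) {
    x * exp(rnorm(length(x), 0, sigma)) + baseline
  }
  clip <- function(x) pmin(x, sat)
  true_rad <- NA_real_
  true_compactness <- NA_real_

  if (class == "pellet") {
    p <- params$pellet
    n <- max(10L, round(runif1(p$sample_length) / ups))
    ann <- runif1(p$annular_fraction)
    n_flank <- round(ann * n / 2)
    n_flank <- max(1L, n_flank)
    n_core <- n - 2L * n_flank
    if (n_core < 2L) { n_core <- 2L; n_flank <- (n - n_core) %/% 2L }
    n <- n_core + 2L * n_flank
    overdrive <- runif1(p$fws_overdrive)
    up <- seq(0.05 * sat, 0.75 * sat, length.out = n_flank)
    core <- rep(overdrive * sat, n_core)
    degraded <- runif(1) < p$degraded_prob
    if (degraded && n_core >= 4L) {
      target_c <- runif1(p$compactness)
      n_sat <- max(2L, min(n_core, round(target_c * n_core)))
      n_dip <- n_core - n_sat
      if (n_dip > 0) {
        # carve a contiguous dip in the middle of the core (weakened center)
        dip_start <- ((n_core - n_dip) %/% 2) + 1L
        core[dip_start:(dip_start + n_dip - 1L)] <- 0.6 * sat
      }
      true_compactness <- (n_core - n_dip) / n_core
    } else {
      true_compactness <- 1
    }
    fws <- c(up, core, rev(up))
    true_rad <- (2 * n_flank) / n
    sws_total <- runif1(p$sws_total_per_um) * n * ups
  } else if (class == "large_clump") {
    p <- params$large_clump
    n <- max(10L, round(runif1(p$sample_length) / ups))
    k <- sample(3:6, 1)
    shape <- lobe_shape(n, centers = runif(k, 1, n),
                        widths = runif(k, n / 12, n / 5),
                        weights = runif(k, 0.3, 1))
    fws <- shape / max(shape) * runif1(p$fws_peak_frac) * sat
    sws_total <- runif1(p$sws_total_per_um) * n * ups
  } else if (class == "small_clump") {
    p <- params$small_clump
    n <- max(6L, round(runif1(p$sample_length) / ups))
    k <- sample(p$lobes[1]:p$lobes[2], 1)
    shape <- lobe_shape(n, centers = runif(k, 1, n),
                        widths = runif(k, n / 10, n / 4),
                        weights = runif(k, 0.4, 1))
    fws <- shape / max(shape) * runif(1, 0.05, 0.3) * sat
    sws_total <- runif1(p$sws_total)
  } else if (class == "hyphae") {
    p <- params$hyphae
    n <- max(4L, round(runif1(p$sample_length) / ups))
    shape <- lobe_shape(n, centers = n / 2, widths = n / 3, weights = 1)
    fws <- shape / max(shape) * runif(1, 0.02, 0.15) * sat
    sws_total <- runif1(p$sws_total)
  } else if (class == "background") {
    p <- params$background
    n <- max(3L, round(runif1(p$sample_length) / ups))
    shape <- lobe_shape(n, centers = n / 2, widths = n / 3, weights = 1)
    fws <- shape / max(shape) * runif(1, 0.005, 0.05) * sat
    sws_total <- runif1(p$sws_total)
  } else {
    abort(paste0("unknown class: ", class))
  }

  # SWS: strictly positive hump over the same envelope, scaled to its total
  sws_shape <- lobe_shape(length(fws), centers = length(fws) / 2,
                          widths = length(fws) / 4, weights = 1)
  sws <- sws_shape / sum(sws_shape) * sws_total

  fl_total <- if (class == "background")
    runif1(params$fl_green$background_total)
  else runif1(params$fl_green$viable_total)
  n_fl <- min(5L, length(fws))
  fl <- rep(fl_total / n_fl, n_fl)

  pad0 <- rep(0, pad)
  pulses <- list(
    FWS = clip(c(pad0, noisy(fws), pad0)),
    SWS = clip(c(pad0, noisy(sws), pad0)),
    FL_GREEN = clip(c(pad0, fl, pad0))
  )
  truth <- tibble(
    particle_id = id, class = class,
    true_sample_length = length(fws) * ups,
    true_rad = true_rad, true_compactness = true_compactness
  )
  list(pulses = pulses, truth = truth)
}

#' Simulate a list-mode run with ground truth
#'
#' Draws `params$n` particles from the class mixture and assembles a
#' [pulse_tbl()] plus a truth table. Fully reproducible under a fixed seed.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer RNG seed.
#' @return A list with `pulses` (a `tbl_pulse`) and `truth` (tibble:
#'   `particle_id`, `class`, `true_sample_length`, `true_rad`,
#'   `true_compactness`).
#' @export
#' @examples
#' run <- simulate_run(sim_params(n = 50), seed = 42)
#' head(run$truth)
simulate_run <- function(params = sim_params(), seed = 1L) {
  validate_sim_params(params)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n <- params$n
  meta <- params$meta
  if (n == 0) {
    pulses <- pulse_tbl(tibble(particle_id = character(), channel = character(),
                               sample_index = integer(), value = double()),
                        meta, validate = FALSE)
    return(list(pulses = pulses, truth = tibble(
      particle_id = character(), class = character(),
      true_sample_length = double(), true_rad = double(),
      true_compactness = double())))
  }
  classes <- sample(names(params$mixture), n, replace = TRUE,
                    prob = params$mixture)
  ids <- sprintf("p%06d", seq_len(n))
  sims <- lapply(seq_len(n), function(i)
    simulate_particle(classes[i], params, id = ids[i]))
  chans <- c("FWS", "SWS", "FL_GREEN")
  per_particle <- lapply(sims, function(s) {
    lens <- vapply(s$pulses[chans], length, integer(1))
    list(values = unlist(s$pulses[chans], use.names = FALSE), lens = lens)
  })
  lens_mat <- vapply(per_particle, function(x) x$lens, integer(length(chans)))
  total_per_particle <- colSums(lens_mat)
  pulses <- tibble(
    particle_id = rep(ids, times = total_per_particle),
    channel = unlist(lapply(seq_len(n), function(i)
      rep(chans, times = lens_mat[, i])), use.names = FALSE),
    sample_index = unlist(lapply(as.vector(lens_mat), function(l)
      seq_len(l) - 1L), use.names = FALSE),
    value = unlist(lapply(per_particle, function(x) x$values),
                   use.names = FALSE)
  )
  truth <- bind_rows(lapply(sims, function(s) s$truth))
  list(pulses = pulse_tbl(pulses, meta, validate = FALSE), truth = truth)
}

#' Simulate a time-course scenario
#'
#' A scenario is a tibble with a `timepoint` column (h), an optional `n`
#' column, and one column per mixture class giving its weight at that
#' timepoint (weights are renormalized). One run is simulated per timepoint;
#' timepoints are stamped into each run's metadata. Seeds for the individual
#' runs are derived from `seed`, so two scenarios simulated with different
#' seeds are independent and a repeated call is identical.
#'
#' @param scenario Scenario tibble as described.
#' @param params Base [sim_params()]; mixture and `n` are overridden per
#'   timepoint.
#' @param seed Integer seed.
#' @return A list of `simulate_run()` results, one per timepoint.
#' @export
simulate_timecourse <- function(scenario, params = sim_params(), seed = 1L) {
  stopifnot(is.data.frame(scenario), "timepoint" %in% names(scenario))
  class_cols <- intersect(c(pm_morph_classes, "background"), names(scenario))
  if (!length(class_cols))
    abort("scenario needs at least one mixture-class column.")
  lapply(seq_len(nrow(scenario)), function(i) {
    w <- as.numeric(scenario[i, class_cols])
    if (any(w < 0) || sum(w) <= 0)
      abort("scenario mixture weights must be non-negative with a positive sum.")
    mix <- setNames(rep(0, length(params$mixture)), names(params$mixture))
    mix[class_cols] <- w / sum(w)
    p <- params
    p$mixture <- mix
    if ("n" %in% names(scenario)) p$n <- scenario$n[i]
    p$meta$timepoint <- scenario$timepoint[i]
    simulate_run(p, seed = (seed + 7919L * i) %% .Machine$integer.max)
  })
}

#' Simulate a hairy pellet mask
#'
#' A rasterized disk (the dense core plus annulus) with `hair_count` radial
#' one-pixel-wide hairs — the fixture for the microscopy shape metrics. With
#' no hairs the mask is convex (fullness near 1, roughness near 1); many long
#' hairs drive roughness far above 1 and fullness down.
#'
#' @param radius_core Disk radius in px.
#' @param hair_count Number of radial hairs.
#' @param hair_length Hair length in px.
#' @param um_per_px Pixel size (um).
#' @param seed Integer seed for the hair angles.
#' @return A list: `mask` (logical matrix), `um_per_px`, `truth` (tibble with
#'   the constructed disk area in um^2).
#' @export
simulate_pellet_mask <- function(radius_core = 60, hair_count = 0,
                                 hair_length = 20, um_per_px = 1, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  r <- radius_core
  half <- r + hair_length + 3
  size <- 2 * half + 1
  cx <- half + 1
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  mask <- (xs - cx)^2 + (ys - cx)^2 <= r^2
  if (hair_count > 0) {
    angles <- runif(hair_count, 0, 2 * pi)
    for (a in angles) {
      t <- seq(r - 1, r + hair_length, by = 0.4)
      px <- round(cx + t * cos(a))
      py <- round(cx + t * sin(a))
      ok <- px >= 1 & px <= size & py >= 1 & py <= size
      mask[cbind(py[ok], px[ok])] <- TRUE
      # second strand keeps the hair 4-connected
      mask[cbind(pmin(size, py[ok] + 1), px[ok])] <- TRUE
    }
  }
  list(mask = mask, um_per_px = um_per_px,
       truth = tibble(disk_area = sum((xs - cx)^2 + (ys - cx)^2 <= r^2) *
                        um_per_px^2,
                      radius_core = r, hair_count = hair_count))
}
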