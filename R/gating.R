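#' Viability prefilter
#'
#' A particle counts as a viable hyphal element when its total green
#' fluorescence (fluorescein-diacetate staining) is strictly greater than the
#' configured threshold (default 30 a.u.); everything else is medium
#' background. With `require_fl = FALSE` in the config, particles without a
#' green-fluorescence channel pass the filter (unstained runs).
#'
#' @param features Feature table (needs `fl_green_total` unless
#'   `require_fl = FALSE`).
#' @param config A [gate_config()].
#' @return Logical vector, one element per row.
#' @export
is_viable <- function(features, config = gate_config()) {
  fl <- if ("fl_green_total" %in% names(features))
    features$fl_green_total else rep(NA_real_, nrow(features))
  if (!config$require_fl) {
    out <- is.na(fl) | fl > config$green_fl_total_min
  } else {
    out <- !is.na(fl) & fl > config$green_fl_total_min
    n_missing <- sum(is.na(fl))
    if (n_missing > 0)
      warn(sprintf(
        "%d particle(s) lack a FL_GREEN channel and were classed as background (require_fl = TRUE).",
        n_missing))
  }
  out
}

in_polygon <- function(poly, x, y) {
  ok <- is.finite(x) & is.finite(y)
  res <- rep(FALSE, length(x))
  if (any(ok))
    res[ok] <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                            cbind(x[ok], y[ok]))
  res
}

#' Classify particles into morphological classes
#'
#' Applies the hierarchical gating tree to a feature table: the viability
#' prefilter, then the small/large split on (sample length, SWS total), then
#' within large elements the pellet gate (SWS total, sample length, saturated
#' FWS core, FWS maximum / fill factor, SWS total / sample length) versus
#' large clumps, and within small elements the small-clump gate (which takes
#' precedence in the published overlap of the hyphae and small-clump SWS
#' intervals) versus hyphae. Small elements matching neither gate fall to
#' `config$fallback_small` (default `unclassified`); particles with undefined
#' gating ratios are `unclassified`; non-viable particles are `background`.
#' Every particle receives exactly one class.
#'
#' @param features Feature table from [extract_features()].
#' @param config A [gate_config()].
#' @return `features` plus columns `viable` (logical) and `class` (factor
#'   with levels background, unclassified, hyphae, small_clump, large_clump,
#'   pellet).
#' @export
#' @examples
#' run <- simulate_run(sim_params(n = 100), seed = 1)
#' classified <- classify_particles(extract_features(run$pulses))
#' table(classified$class)
classify_particles <- function(features, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"))
  sl_col <- paste0(tolower(config$sample_length_channel), "_sample_length")
  if (!sl_col %in% names(features))
    abort(paste0("feature table lacks the gating sample-length column `",
                 sl_col, "`."))
  sl <- features[[sl_col]]
  sws_total <- features$sws_total
  fws_length <- features$fws_length
  viable <- is_viable(features, config)

  lg <- config$large_gate
  large <- if (!is.null(lg$polygon)) {
    in_polygon(lg$polygon, sl, sws_total)
  } else {
    !is.na(sl) & !is.na(sws_total) &
      sws_total > lg$sws_total_min & sl > lg$sample_length_min
  }

  p <- config$pellet
  pellet_ok <- large &
    sws_total > p$sws_total_min &
    sl > p$sample_length_min &
    (!p$require_fws_saturated | features$fws_saturated) &
    !is.na(features$fws_max_over_fill) &
    features$fws_max_over_fill > p$fws_max_over_fill_min &
    !is.na(features$sws_total_over_sample_length) &
    features$sws_total_over_sample_length > p$sws_total_over_sample_length_min

  # zero fill factor or zero sample length: gating ratios undefined, the
  # particle cannot be placed in the tree
  ratio_undefined <- is.na(features$fws_max_over_fill) |
    is.na(features$sws_total_over_sample_length)

  sc <- config$small_clump
  small_clump_ok <- !large &
    sl > sc$sample_length_min & sl < sc$sample_length_max &
    (if (!is.null(sc$polygon)) in_polygon(sc$polygon, fws_length, sws_total)
     else sws_total > sc$sws_total_min & sws_total < sc$sws_total_max &
       fws_length > sc$fws_length_min)

  h <- config$hyphae
  hyphae_ok <- !large &
    sl > h$sample_length_min & sl < h$sample_length_max &
    sws_total < h$sws_total_max & fws_length < h$fws_length_max

  cls <- dplyr::case_when(
    !viable ~ "background",
    ratio_undefined ~ "unclassified",
    pellet_ok ~ "pellet",
    large ~ "large_clump",
    small_clump_ok ~ "small_clump",
    hyphae_ok ~ "hyphae",
    .default = config$fallback_small
  )
  features$viable <- viable
  features$class <- factor(cls, levels = pm_classes)
  features
}

#' Classify a whole list-mode run
#'
#' Convenience wrapper: feature extraction, viability prefilter and gating in
#' one call.
#'
#' @param pulses A [pulse_tbl()].
#' @param config A [gate_config()].
#' @param trigger_level Trigger level passed to [extract_features()];
#'   defaults to the config's.
#' @return A list with `particles` (classified feature tibble) and `counts`
#'   (tibble of per-class counts over the viable set; background excluded).
#' @export
classify_run <- function(pulses, config = gate_config(),
                         trigger_level = config$trigger_level) {
  feats <- extract_features(pulses, trigger_level = trigger_level)
  if (!nrow(feats)) {
    counts <- tibble(class = factor(setdiff(pm_classes, "background"),
                                    levels = pm_classes),
                     n = 0L)
    return(list(particles = feats, counts = counts))
  }
  particles <- classify_particles(feats, config)
  list(particles = particles, counts = class_counts(particles))
}

#' @rdname classify_run
#' @param particles A classified feature table.
#' @export
class_counts <- function(particles) {
  particles |>
    filter(.data$class != "background") |>
    count(class = factor(.data$class,
                         levels = setdiff(pm_classes, "background")),
          .drop = FALSE, name = "n")
}

#' Cluster-assisted gate refinement
#'
#' Unsupervised clustering of the (z-scored) curve parameters, reported
#' against the gate classes as a contingency matrix — the workflow used to
#' sharpen manually drawn gate boundaries. Only 2 to 5 clusters are
#' considered meaningful for this four-class morphology.
#'
#' @param particles Classified feature table (needs a `class` column).
#' @param method `"kmeans"` (Hartigan-Wong, 10 restarts, seeded) or
#'   `"hierarchical_average_euclidean"` (average-linkage on Euclidean
#'   distances).
#' @param k Number of clusters, between 2 and 5.
#' @param columns Feature columns to cluster on; the default is the
#'   scatter-geometry block the gates themselves use.
#' @param transform `"log10"` (default; scatter intensities are
#'   log-distributed, so log scaling balances size classes spanning orders of
#'   magnitude) or `"identity"` (raw z-scores, which emphasize the extreme
#'   pellet signal magnitudes).
#' @param seed RNG seed for the k-means restarts.
#' @return An object of class `gate_refinement` with elements `cluster`
#'   (integer labels), `contingency` (cluster x class table over viable
#'   particles), `concordance` (purity: the fraction of particles whose
#'   cluster's majority class matches their gate class), `method`, `k`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
refine_gates <- function(particles,
                         method = c("kmeans", "hierarchical_average_euclidean"),
                         k = 4,
                         columns = c("fws_maximum", "fws_total", "fws_length",
                                     "sws_total", "sws_sample_length"),
                         transform = c("log10", "identity"),
                         seed = 1L) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 2 || k > 5)
    abort("`k` must be an integer between 2 and 5.")
  missing_cols <- setdiff(columns, names(particles))
  if (length(missing_cols))
    abort(paste0("feature table lacks clustering column(s): ",
                 paste(missing_cols, collapse = ", ")))
  keep <- stats::complete.cases(particles[columns])
  if ("viable" %in% names(particles)) keep <- keep & particles$viable
  dat <- particles[keep, , drop = FALSE]
  if (nrow(dat) < k)
    abort("need at least `k` complete particles to cluster.")
  x <- as.matrix(dat[columns])
  if (transform == "log10") x <- log10(x + 1)
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  if (method == "kmeans") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    cl <- kmeans(x, centers = k, nstart = 10, iter.max = 100)$cluster
  } else {
    cl <- cutree(hclust(dist(x), method = "average"), k = k)
  }
  cls <- if ("class" %in% names(dat)) droplevels(factor(dat$class)) else
    factor(rep("unlabelled", nrow(dat)))
  contingency <- table(cluster = cl, class = cls)
  concordance <- sum(apply(contingency, 1, max)) / sum(contingency)
  structure(
    list(cluster = cl, particle_id = dat$particle_id,
         contingency = contingency, concordance = concordance,
         method = method, k = k, n = nrow(dat), columns = columns,
         transform = transform),
    class = "gate_refinement"
  )
}

#' Concordance of a clustering with a grouping of the gate classes
#'
#' Collapses the cluster-vs-class contingency onto unions of gate classes
#' (e.g. small vs large elements) and scores the fraction of particles whose
#' cluster's majority group matches their own.
#'
#' @param refinement A [refine_gates()] result.
#' @param groups Named list of class unions; default the small/large split.
#' @return A single number in `[0, 1]`.
#' @export
group_concordance <- function(refinement,
                              groups = list(
                                small = c("hyphae", "small_clump"),
                                large = c("large_clump", "pellet"))) {
  tab <- refinement$contingency
  collapsed <- vapply(groups, function(g) {
    cols <- intersect(g, colnames(tab))
    if (!length(cols)) return(rep(0, nrow(tab)))
    rowSums(tab[, cols, drop = FALSE])
  }, numeric(nrow(tab)))
  if (is.null(dim(collapsed))) collapsed <- matrix(collapsed, nrow = 1)
  sum(apply(collapsed, 1, max)) / sum(collapsed)
}

#' @export
print.gate_refinement <- function(x, ...) {
  cat(sprintf("<gate_refinement> %s, k = %d, n = %d, concordance = %.3f\n",
              x$method, x$k, x$n, x$concordance))
  print(x$contingency)
  invisible(x)
}

#' @rdname refine_gates
#' @param x A `gate_refinement` object.
#' @param ... Unused.
#' @method tidy gate_refinement
#' @export
tidy.gate_refinement <- function(x, ...) {
  as_tibble(as.data.frame(x$contingency, responseName = "n")) |>
    mutate(cluster = as.integer(as.character(.data$cluster))) |>
    group_by(.data$cluster) |>
    mutate(cluster_fraction = .data$n / sum(.data$n)) |>
    ungroup()
}

#' @rdname refine_gates
#' @method glance gate_refinement
#' @export
glance.gate_refinement <- function(x, ...) {
  tibble(method = x$method, k = x$k, n = x$n, concordance = x$concordance)
}
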