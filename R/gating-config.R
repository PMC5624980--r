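#' Gating configuration for the morphological decision tree
#'
#' All numeric thresholds of the hierarchical gating tree, externally
#' configurable. The defaults are the published class definitions for the
#' flow-cytometry side of the method:
#'
#' * viability prefilter: total green fluorescence (fluorescein diacetate)
#'   strictly greater than 30 a.u.;
#' * large vs small elements: SWS total > 2e4 a.u. AND sample length > 100 um;
#' * hyphae: sample length between 10 and 150 um, SWS total < 4e4, FWS length
#'   < 190 um;
#' * small clumps: sample length between 10 and 150 um, SWS total between
#'   1.8e4 and 9e4, FWS length > 18 um;
#' * pellets: SWS total > 4e4, sample length > 120 um, saturated FWS core,
#'   FWS maximum / FWS fill factor > 7.5e3, SWS total / sample length > 8e2.
#'
#' All inequalities are strict, matching the "higher than"/"bigger than"/
#' "below" definitions; boundary equality falls to the complementary class.
#' The published large-element and small-clump gates are drawn as polygons in
#' scatter plots and are not numerically published; the rectangular defaults
#' above approximate them and explicit polygons can be supplied
#' (`large_gate$polygon` on (sample length, SWS total); `small_clump$polygon`
#' on (FWS length, SWS total)), as ordered vertex matrices in axis units.
#'
#' @param ... Named overrides of the default fields. Nested lists are merged
#'   field-by-field, e.g. `gate_config(pellet = list(sample_length_min = 130))`.
#'
#' @return A list of class `gate_config`.
#' @export
#' @examples
#' cfg <- gate_config()
#' cfg$pellet$sws_total_min      # 4e4
#' cfg$pellet$sample_length_min  # 120
gate_config <- function(...) {
  defaults <- list(
    green_fl_total_min = 30,
    require_fl = TRUE,
    # channel whose sample length feeds the size gates (and size histograms)
    sample_length_channel = "SWS",
    trigger_level = 0,
    large_gate = list(sws_total_min = 2e4, sample_length_min = 100,
                      polygon = NULL),
    hyphae = list(sample_length_min = 10, sample_length_max = 150,
                  sws_total_max = 4e4, fws_length_max = 190),
    small_clump = list(sample_length_min = 10, sample_length_max = 150,
                       sws_total_min = 1.8e4, sws_total_max = 9e4,
                       fws_length_min = 18, polygon = NULL),
    pellet = list(sws_total_min = 4e4, sample_length_min = 120,
                  require_fws_saturated = TRUE,
                  fws_max_over_fill_min = 7.5e3,
                  sws_total_over_sample_length_min = 8e2),
    fallback_small = "unclassified"
  )
  cfg <- merge_config(defaults, list(...))
  validate_gate_config(cfg)
}

merge_config <- function(base, override) {
  if (!length(override)) return(base)
  if (is.null(names(override)) || any(!nzchar(names(override))))
    abort("gating-config overrides must be named.")
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    abort(paste0("unknown gating-config key(s): ",
                 paste(unknown, collapse = ", ")))
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(override[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' @rdname gate_config
#' @param cfg A gating-config list to validate.
#' @export
validate_gate_config <- function(cfg) {
  chk_pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      abort(paste0("gating config: `", what, "` must be a positive number."))
  }
  chk_pos(cfg$green_fl_total_min, "green_fl_total_min")
  chk_pos(cfg$large_gate$sws_total_min, "large_gate$sws_total_min")
  chk_pos(cfg$large_gate$sample_length_min, "large_gate$sample_length_min")
  for (g in c("hyphae", "small_clump", "pellet"))
    for (k in setdiff(names(cfg[[g]]), c("polygon", "require_fws_saturated")))
      chk_pos(cfg[[g]][[k]], paste0(g, "$", k))
  if (cfg$hyphae$sample_length_min >= cfg$hyphae$sample_length_max)
    abort("gating config: hyphae sample-length interval bounds are inverted.")
  if (cfg$small_clump$sample_length_min >= cfg$small_clump$sample_length_max)
    abort("gating config: small-clump sample-length interval bounds are inverted.")
  if (cfg$small_clump$sws_total_min >= cfg$small_clump$sws_total_max)
    abort("gating config: small-clump SWS-total interval bounds are inverted.")
  # the pellet gate must nest inside the large-element gate
  if (cfg$pellet$sws_total_min < cfg$large_gate$sws_total_min ||
      cfg$pellet$sample_length_min < cfg$large_gate$sample_length_min)
    abort("gating config: pellet gate must lie inside the large-element gate.")
  if (!cfg$sample_length_channel %in% c("SWS", "FWS"))
    abort("gating config: sample_length_channel must be \"SWS\" or \"FWS\".")
  if (!cfg$fallback_small %in% c("hyphae", "unclassified"))
    abort("gating config: fallback_small must be \"hyphae\" or \"unclassified\".")
  for (g in c("large_gate", "small_clump")) {
    p <- cfg[[g]]$polygon
    if (!is.null(p)) {
      p <- as.matrix(p)
      if (ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
        abort(paste0("gating config: ", g,
                     "$polygon must be a finite matrix of >= 3 (x, y) vertices."))
      cfg[[g]]$polygon <- p
    }
  }
  structure(cfg, class = "gate_config")
}

#' Read / write a gating configuration file
#'
#' The on-disk schema is a human-readable nested YAML document mirroring the
#' [gate_config()] fields; absent keys take the published defaults. Polygons
#' are lists of `[x, y]` vertex pairs in axis units.
#'
#' @param path File path.
#' @return A validated `gate_config`.
#' @export
read_gate_config <- function(path) {
  if (!file.exists(path)) abort(paste0("gating config not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort(paste0("malformed gating config: ",
                                                   conditionMessage(e))))
  raw <- raw %||% list()
  for (g in c("large_gate", "small_clump"))
    if (!is.null(raw[[g]]$polygon))
      raw[[g]]$polygon <- do.call(rbind, lapply(raw[[g]]$polygon, as.numeric))
  do.call(gate_config, raw)
}

#' @rdname read_gate_config
#' @param cfg A `gate_config`.
#' @export
write_gate_config <- function(cfg, path) {
  out <- unclass(cfg)
  for (g in c("large_gate", "small_clump")) {
    if (!is.null(out[[g]]$polygon))
      out[[g]]$polygon <- apply(out[[g]]$polygon, 1, as.list, simplify = FALSE)
    else out[[g]]$polygon <- NULL
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.gate_config <- function(x, ...) {
  cat("<gate_config>\n")
  cat(sprintf("  viability : FL_GREEN total > %g (require_fl = %s)\n",
              x$green_fl_total_min, x$require_fl))
  cat(sprintf("  large     : SWS total > %g & sample length > %g um%s\n",
              x$large_gate$sws_total_min, x$large_gate$sample_length_min,
              if (is.null(x$large_gate$polygon)) "" else " [polygon]"))
  cat(sprintf("  hyphae    : SL (%g, %g) um, SWS total < %g, FWS length < %g um\n",
              x$hyphae$sample_length_min, x$hyphae$sample_length_max,
              x$hyphae$sws_total_max, x$hyphae$fws_length_max))
  cat(sprintf("  small cl. : SL (%g, %g) um, SWS total (%g, %g), FWS length > %g um%s\n",
              x$small_clump$sample_length_min, x$small_clump$sample_length_max,
              x$small_clump$sws_total_min, x$small_clump$sws_total_max,
              x$small_clump$fws_length_min,
              if (is.null(x$small_clump$polygon)) "" else " [polygon]"))
  cat(sprintf("  pellet    : SWS total > %g, SL > %g um, saturated FWS, max/fill > %g, total/SL > %g\n",
              x$pellet$sws_total_min, x$pellet$sample_length_min,
              x$pellet$fws_max_over_fill_min,
              x$pellet$sws_total_over_sample_length_min))
  invisible(x)
}
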