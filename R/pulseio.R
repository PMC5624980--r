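#' Read and write pulse-shape list-mode files
#'
#' The vendor acquisition format is proprietary, so the package defines two
#' open on-disk dialects and uses them everywhere:
#'
#' * `csv_long` — a UTF-8 CSV with columns
#'   `particle_id,channel,sample_index,value` ('.' decimal separator,
#'   0-based contiguous `sample_index`), preceded by a `#`-prefixed key-value
#'   header block carrying the [measurement_meta()] fields.
#' * `parquet` — the same long table as an Apache Parquet file; the metadata
#'   travels in the file so the round trip is lossless and bit-exact.
#'
#' `read_pulses(write_pulses(x))` reproduces `x` exactly for both dialects.
#'
#' @param path File path.
#' @param dialect `"csv_long"` or `"parquet"`. For `read_pulses` the default
#'   is guessed from the file extension (`.parquet` vs anything else).
#' @return `read_pulses`: a [pulse_tbl()] with its `measurement_meta`
#'   attribute. `write_pulses`: the path, invisibly.
#' @export
#' @examples
#' run <- simulate_run(sim_params(n = 5), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_pulses(run$pulses, f)
#' identical(as.data.frame(read_pulses(f)), as.data.frame(run$pulses))
read_pulses <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dialect <- dialect %||%
    (if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv_long")
  dialect <- match.arg(dialect, c("csv_long", "parquet"))
  if (dialect == "parquet") {
    tab <- arrow::read_parquet(path)
    meta <- attr(tab, "meta", exact = TRUE)
    if (is.null(meta)) abort("parquet file carries no measurement metadata.")
    meta <- do.call(measurement_meta, meta[setdiff(names(meta), "class")])
    attr(tab, "meta") <- NULL
    return(pulse_tbl(tab, meta))
  }
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  kv <- parse_header_block(hdr)
  need <- c("um_per_sample", "saturation_level", "pump_speed", "duration",
            "dilution_factor")
  missing_keys <- setdiff(need, names(kv))
  if (length(missing_keys))
    abort(paste0("csv_long header lacks key(s): ",
                 paste(missing_keys, collapse = ", ")))
  meta <- measurement_meta(
    um_per_sample = as.numeric(kv$um_per_sample),
    saturation_level = as.numeric(kv$saturation_level),
    pump_speed = as.numeric(kv$pump_speed),
    duration = as.numeric(kv$duration),
    dilution_factor = as.numeric(kv$dilution_factor),
    sample_label = kv$sample_label %||% "",
    timepoint = suppressWarnings(as.numeric(kv$timepoint %||% NA_real_))
  )
  tab <- readr::read_csv(
    path, comment = "#", progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      particle_id = readr::col_character(),
      channel = readr::col_character(),
      sample_index = readr::col_integer(),
      # parsed via base strtod (correctly rounded) so the round trip is exact
      value = readr::col_character()
    )
  )
  tab$value <- as.numeric(tab$value)
  tab <- arrange(tab, .data$particle_id, .data$channel, .data$sample_index)
  pulse_tbl(tab, meta)
}

parse_header_block <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  setNames(as.list(vals), keys)
}

#' @rdname read_pulses
#' @param pulses A [pulse_tbl()] (or a plain data frame plus `meta`).
#' @param meta Optional [measurement_meta()]; defaults to the attribute on
#'   `pulses`.
#' @export
write_pulses <- function(pulses, path, dialect = NULL, meta = NULL) {
  meta <- meta %||% pulse_meta(pulses)
  if (!nrow(pulses)) abort("refusing to write an empty list-mode dataset.")
  dialect <- dialect %||%
    (if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv_long")
  dialect <- match.arg(dialect, c("csv_long", "parquet"))
  tab <- as_tibble(as.data.frame(pulses))
  tab$particle_id <- as.character(tab$particle_id)
  if (dialect == "parquet") {
    attr(tab, "meta") <- unclass(meta)
    arrow::write_parquet(tab, path)
    return(invisible(path))
  }
  hdr <- c(
    "# pulsemorph list-mode v1",
    sprintf("# um_per_sample: %s", format(meta$um_per_sample, digits = 17)),
    sprintf("# saturation_level: %s", format(meta$saturation_level, digits = 17)),
    sprintf("# pump_speed: %s", format(meta$pump_speed, digits = 17)),
    sprintf("# duration: %s", format(meta$duration, digits = 17)),
    sprintf("# dilution_factor: %s", format(meta$dilution_factor, digits = 17)),
    sprintf("# sample_label: %s", meta$sample_label),
    sprintf("# timepoint: %s", format(meta$timepoint, digits = 17))
  )
  writeLines(hdr, path)
  # 17 significant digits round-trip IEEE doubles exactly
  tab$value <- sprintf("%.17g", tab$value)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
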