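#' Read an instrument stream from a comma-separated file
#'
#' Parses the data-streamer dialect: comma-delimited records with columns
#' `lightLevel`, `wavelengthLine`, `lightIntensity` and an optional leading
#' `time_s` column. A header row is detected automatically and files are
#' accepted either way; column names are matched case-sensitively. Rows whose
#' fields do not parse as numbers are rejected with their line numbers. When
#' the file has no time column, timestamps are reconstructed from `cadence_hz`
#' as `0, 1/cadence, 2/cadence, ...`.
#'
#' The decimal separator is the dot; locales writing decimal commas must
#' convert upstream.
#'
#' @param source path to the file (or a connection readable by `readLines`).
#' @param cadence_hz readings per second used to reconstruct timestamps when
#'   the file has no `time_s` column.
#' @return a [frequency_stream()].
#' @export
read_stream <- function(source, cadence_hz = NULL) {
  lines <- readLines(source)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) stop("empty stream file", call. = FALSE)
  fields <- strsplit(trimws(lines[lines_keep]), ",", fixed = TRUE)
  fields <- lapply(fields, trimws)
  first <- fields[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  if (has_header) {
    cols <- first
    required <- c("lightLevel", "wavelengthLine", "lightIntensity")
    missing <- setdiff(required, cols)
    if (length(missing)) {
      stop("stream file is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    body_idx <- lines_keep[-1L]
    body <- fields[-1L]
  } else {
    cols <- switch(as.character(length(first)),
                   "3" = c("lightLevel", "wavelengthLine", "lightIntensity"),
                   "4" = c("time_s", "lightLevel", "wavelengthLine",
                           "lightIntensity"),
                   stop("headerless stream must have 3 or 4 columns, found ",
                        length(first), call. = FALSE))
    body_idx <- lines_keep
    body <- fields
  }
  ncol_exp <- length(cols)
  widths_ok <- lengths(body) == ncol_exp
  values <- lapply(body, function(f) suppressWarnings(as.numeric(f)))
  parsed_ok <- widths_ok & !vapply(values, anyNA, logical(1))
  if (!all(parsed_ok)) {
    bad <- body_idx[!parsed_ok]
    stop("malformed stream record(s) at line ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mat <- do.call(rbind, values)
  colnames(mat) <- cols
  df <- as.data.frame(mat)
  if (!"time_s" %in% cols) {
    if (is.null(cadence_hz) || cadence_hz <= 0) {
      stop("file has no time_s column; supply a positive cadence_hz to ",
           "reconstruct timestamps", call. = FALSE)
    }
    df$time_s <- (seq_len(nrow(df)) - 1L) / cadence_hz
  }
  if (nrow(df) > 1L && any(diff(df$time_s) <= 0)) {
    stop("stream timestamps are not strictly increasing", call. = FALSE)
  }
  frequency_stream(df)
}

#' Write an instrument stream to a comma-separated file
#'
#' Deterministic output: fixed column order (`time_s`, `lightLevel`,
#' `wavelengthLine`, `lightIntensity`), a header row, and full
#' round-trippable float precision (`%.17g`); writing the same stream twice
#' yields byte-identical files.
#'
#' @param stream a [frequency_stream()].
#' @param sink output file path.
#' @return `sink`, invisibly.
#' @export
write_stream <- function(stream, sink) {
  stopifnot(inherits(stream, "frequency_stream"))
  cols <- c("time_s", "lightLevel", "wavelengthLine", "lightIntensity")
  header <- paste(cols, collapse = ",")
  if (nrow(stream)) {
    body <- do.call(paste, c(lapply(stream[cols], function(x)
      sprintf("%.17g", x)), sep = ","))
    writeLines(c(header, body), sink)
  } else {
    writeLines(header, sink)
  }
  invisible(sink)
}

#' Read a scenario description from a YAML config
#'
#' A scenario file is a single structured document whose keys mirror the
#' [ellman_scenario()] arguments, with nested blocks for the reaction
#' (`ellman:`), inhibition (`inhibition:`) and sensor (`sensor:`) parameters;
#' any key omitted falls back to the package default. Concentrations are
#' given in mol/L, times in seconds.
#'
#' @param path path to the YAML file.
#' @return an [ellman_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenario_from_list(cfg)
}

#' @rdname read_scenario
#' @param cfg a named list as produced by parsing a scenario document.
#' @export
scenario_from_list <- function(cfg) {
  take <- function(block, builder) {
    if (is.null(block)) builder() else do.call(builder, block)
  }
  ellman_scenario(
    recipe = if (is.null(cfg$recipe)) default_ellman_recipe() else
      cuvette_recipe(as.data.frame(lapply(cfg$recipe, unlist))),
    ellman = take(cfg$ellman, ellman_params),
    inhibition = take(cfg$inhibition, inhibition_params),
    inhibitor_mol_L = cfg$inhibitor_mol_L %||% 0,
    preincubation_s = cfg$preincubation_s %||% 0,
    observation_s = cfg$observation_s %||% 300,
    wavelength_nm = cfg$wavelength_nm %||% 412,
    sensor = take(cfg$sensor, sensor_config),
    seed = cfg$seed,
    dt_s = cfg$dt_s %||% 0.1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
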