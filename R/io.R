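# Tabular I/O: comma-separated files with a '#'-prefixed key: value header
# block carrying scan/course metadata, then a header row and typed columns.

.write_meta <- function(con, meta) {
  for (k in names(meta))
    if (!is.na(meta[[k]])) cat(sprintf("# %s: %s\n", k, meta[[k]]), file = con)
}

.read_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' Read a delimited table with schema checking
#'
#' Reads a comma-separated file (ignoring `#` comment lines), checks that
#' the required columns are present and numeric, and reports malformed
#' rows by line number.
#'
#' @param path File path.
#' @param required_cols Character vector of required column names.
#' @return A data.frame with the file's columns; metadata lines are
#'   attached as attribute `"meta"`.
#' @export
read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  for (cc in required_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric values in column '%s' at data row(s) %s",
                   path, cc, paste(bad, collapse = ", ")))
    df[[cc]] <- v
  }
  attr(df, "meta") <- .read_meta(path)
  df
}

#' Write / read a radial scan file
#'
#' Columns `radius_cm`, `absorbance_AU`; rotor speed, temperature, channel
#' and (for velocity scans) time are carried in the comment header.
#'
#' @param scan A [scan_table].
#' @param path File path.
#' @return `read_scan_table` returns a [scan_table]; `write_scan_table`
#'   returns `path` invisibly.
#' @export
write_scan_table <- function(scan, path) {
  con <- file(path, "w"); on.exit(close(con))
  .write_meta(con, list(rotor_speed_rpm = scan$rotor_speed,
                        temperature_K = scan$temperature,
                        channel_id = scan$channel_id,
                        time_s = scan$time))
  write.csv(data.frame(radius_cm = scan$radius,
                       absorbance_AU = scan$absorbance),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  df <- read_table_checked(path, c("radius_cm", "absorbance_AU"))
  m <- attr(df, "meta")
  scan_table(df$radius_cm, df$absorbance_AU,
             rotor_speed = as.numeric(m$rotor_speed_rpm),
             temperature = as.numeric(m$temperature_K),
             channel_id = m$channel_id %||% "A",
             time = as.numeric(m$time_s %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a repair time-course file
#'
#' Columns `time_s`, `fraction_repaired`; DNA label, buffer, concentration
#' and assay in the comment header.
#'
#' @param tc A [time_course].
#' @param path File path.
#' @return `read_time_course` returns a [time_course].
#' @export
write_time_course <- function(tc, path) {
  con <- file(path, "w"); on.exit(close(con))
  .write_meta(con, list(dna_label = tc$dna_label,
                        buffer_label = tc$buffer_label,
                        dna_conc_M = tc$dna_conc,
                        reaction_volume_L = tc$reaction_volume,
                        assay = tc$assay))
  write.csv(data.frame(time_s = tc$time,
                       fraction_repaired = tc$fraction_repaired),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_time_course
#' @export
read_time_course <- function(path) {
  df <- read_table_checked(path, c("time_s", "fraction_repaired"))
  m <- attr(df, "meta")
  time_course(df$time_s, df$fraction_repaired,
              dna_label = m$dna_label %||% "",
              buffer_label = m$buffer_label %||% "",
              dna_conc = as.numeric(m$dna_conc_M %||% 0.25e-6),
              reaction_volume = as.numeric(m$reaction_volume_L %||% NA),
              assay = m$assay %||% "gel-mobility")
}

#' Write / read a melting-curve file
#'
#' Columns `temperature_K` (or `temperature_C`, converted on read) and
#' `signal`.
#'
#' @param curve A [melt_curve].
#' @param path File path.
#' @return `read_melt_curve` returns a [melt_curve].
#' @export
write_melt_curve <- function(curve, path) {
  con <- file(path, "w"); on.exit(close(con))
  .write_meta(con, list(label = curve$label))
  write.csv(data.frame(temperature_K = curve$temperature,
                       signal = curve$signal),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melt_curve
#' @export
read_melt_curve <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- .read_meta(path)
  if ("temperature_K" %in% names(df)) {
    Tk <- as.numeric(df$temperature_K)
  } else if ("temperature_C" %in% names(df)) {
    Tk <- as.numeric(df$temperature_C) + 273.15
  } else stop(sprintf("%s: need temperature_K or temperature_C column", path))
  if (!"signal" %in% names(df)) stop(sprintf("%s: missing 'signal' column", path))
  melt_curve(Tk, as.numeric(df$signal), label = m$label %||% "")
}
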