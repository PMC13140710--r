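# io module: read and validate plate-reader, FRAP and photon-trace files
# into the shared data model; write results tables.

# ---- constructors -----------------------------------------------------------

#' Single-well ThT fluorescence trace
#'
#' Container for one well's fluorescence-versus-time series from a kinetic
#' plate-reader export, with condition metadata. Times are stored in seconds;
#' readers convert minute/hour columns on load.
#'
#' @param well_id Well label, e.g. `"A1"`.
#' @param time_s Numeric vector of times in seconds, strictly increasing.
#' @param intensity Fluorescence in arbitrary units, same length as `time_s`.
#'   Interior gaps of at most two consecutive missing values are linearly
#'   interpolated; longer gaps fail validation.
#' @param condition Free-text condition label.
#' @param molar_ratio Optional chaperone:substrate molar ratio label, e.g.
#'   `"1:10"`.
#' @param substrate_conc_uM Optional substrate concentration in micromolar.
#' @return An object of class `tht_trace`.
#' @export
tht_trace <- function(well_id, time_s, intensity, condition = NA_character_,
                      molar_ratio = NA_character_,
                      substrate_conc_uM = NA_real_) {
  if (length(time_s) != length(intensity))
    stop_validation("well '%s': time and intensity lengths differ", well_id)
  if (length(time_s) < 10L)
    stop_validation("well '%s': a trace needs at least 10 points, got %d",
                    well_id, length(time_s))
  assert_strictly_increasing(time_s, sprintf("well '%s' time", well_id))
  intensity <- fill_short_gaps(intensity, time_s,
                               what = sprintf("well '%s' intensity", well_id))
  structure(
    list(well_id = as.character(well_id), time_s = as.numeric(time_s),
         intensity = as.numeric(intensity),
         condition = as.character(condition),
         molar_ratio = as.character(molar_ratio),
         substrate_conc_uM = as.numeric(substrate_conc_uM)),
    class = "tht_trace")
}

#' @export
print.tht_trace <- function(x, ...) {
  cat(sprintf("<tht_trace> well %s: %d points over %.0f s, condition '%s'\n",
              x$well_id, length(x$time_s), diff(range(x$time_s)),
              x$condition))
  invisible(x)
}

#' Collection of ThT traces on a common time grid
#'
#' @param traces List of [tht_trace()] objects with unique well ids sharing a
#'   common time grid (within `grid_tol` seconds).
#' @param cycle_s Nominal plate-reader cycle duration in seconds.
#' @param meta Named list of assay-level annotations (gain, temperature, ...).
#' @param grid_tol Tolerance in seconds when checking the shared time grid.
#' @return An object of class `plate_kinetics`.
#' @export
plate_kinetics <- function(traces, cycle_s = NA_real_, meta = list(),
                           grid_tol = 1e-6) {
  if (length(traces) == 0L)
    stop_validation("a plate needs at least one trace")
  ids <- vapply(traces, `[[`, character(1), "well_id")
  if (anyDuplicated(ids))
    stop_validation("duplicated well id '%s'", ids[duplicated(ids)][1])
  ref <- traces[[1]]$time_s
  for (tr in traces) {
    if (length(tr$time_s) != length(ref) ||
        max(abs(tr$time_s - ref)) > grid_tol)
      stop_validation("well '%s' is not on the shared time grid", tr$well_id)
  }
  names(traces) <- ids
  structure(list(traces = traces, cycle_s = as.numeric(cycle_s), meta = meta),
            class = "plate_kinetics")
}

#' @export
print.plate_kinetics <- function(x, ...) {
  cat(sprintf("<plate_kinetics> %d wells x %d cycles (cycle %.0f s)\n",
              length(x$traces), length(x$traces[[1]]$time_s), x$cycle_s))
  invisible(x)
}

#' Three-ROI FRAP intensity series
#'
#' Raw fluorescence-recovery-after-photobleaching data: the bleached region,
#' a reference region (the whole condensate, correcting for acquisition
#' photobleaching) and an off-condensate background region, with the index of
#' the first post-bleach frame.
#'
#' @param time_s Strictly increasing times in seconds.
#' @param roi Bleached-region intensity.
#' @param reference Whole-condensate intensity.
#' @param background Off-condensate intensity.
#' @param bleach_index Integer index of the first post-bleach frame
#'   (`1 < bleach_index <= length(time_s)` and at least one pre-bleach frame).
#' @return An object of class `frap_series`.
#' @export
frap_series <- function(time_s, roi, reference, background, bleach_index) {
  n <- length(time_s)
  if (!all(lengths(list(roi, reference, background)) == n))
    stop_validation("FRAP series: all four series must have equal length")
  assert_strictly_increasing(time_s, "FRAP time")
  bleach_index <- as.integer(bleach_index)
  if (is.na(bleach_index) || bleach_index <= 1L || bleach_index > n)
    stop_validation("bleach_index must lie in (1, %d], got %s", n,
                    format(bleach_index))
  structure(list(time_s = as.numeric(time_s), roi = as.numeric(roi),
                 reference = as.numeric(reference),
                 background = as.numeric(background),
                 bleach_index = bleach_index),
            class = "frap_series")
}

#' @export
print.frap_series <- function(x, ...) {
  cat(sprintf("<frap_series> %d frames (%d pre-bleach), dt ~ %.3f s\n",
              length(x$time_s), x$bleach_index - 1L, median(diff(x$time_s))))
  invisible(x)
}

#' Binned photon-count time trace
#'
#' @param counts Non-negative integer photon counts per bin (at least 100
#'   bins).
#' @param bin_width_ms Bin width in milliseconds, positive.
#' @param channel Channel label, e.g. `"donor"` or `"acceptor"`.
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(counts, bin_width_ms, channel = "donor") {
  assert_scalar_number(bin_width_ms, "bin_width_ms")
  if (bin_width_ms <= 0)
    stop_validation("bin_width_ms must be positive")
  if (length(counts) < 100L)
    stop_validation("a photon trace needs at least 100 bins, got %d",
                    length(counts))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_validation("photon counts must be finite and non-negative (first bad bin %d)",
                    which(!is.finite(counts) | counts < 0)[1])
  counts <- as.integer(round(counts))
  structure(list(counts = counts, bin_width_ms = as.numeric(bin_width_ms),
                 channel = as.character(channel)),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> channel '%s': %d bins x %.3g ms (%.3g s)\n",
              x$channel, length(x$counts), x$bin_width_ms,
              length(x$counts) * x$bin_width_ms / 1000))
  invisible(x)
}

#' Turbidity (optical density) kinetic series
#'
#' @param well_id Well label.
#' @param time_s Strictly increasing times in seconds.
#' @param od Data frame (or named list) of finite OD values, one column per
#'   wavelength label (e.g. `"340"`, `"400"`, `"600"`), rows matching
#'   `time_s`.
#' @return An object of class `turbidity_series`.
#' @export
turbidity_series <- function(well_id, time_s, od) {
  assert_strictly_increasing(time_s, "turbidity time")
  od <- as.data.frame(od, optional = TRUE)
  if (nrow(od) != length(time_s))
    stop_validation("OD rows (%d) do not match time points (%d)",
                    nrow(od), length(time_s))
  if (any(!vapply(od, function(col) all(is.finite(col)), logical(1))))
    stop_validation("OD values must be finite")
  structure(list(well_id = as.character(well_id),
                 time_s = as.numeric(time_s), od = od),
            class = "turbidity_series")
}

# ---- delimiter / time-unit helpers -----------------------------------------

sniff_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L)
    stop_format("'%s' is empty", path)
  cands <- c(",", "\t", ";")
  hits <- vapply(cands, function(d) lengths(gregexpr(d, line, fixed = TRUE)),
                 integer(1))
  hits[hits < 0] <- 0L  # gregexpr returns -1 for no match
  cands[which.max(hits)]
}

# seconds-per-unit inferred from a column name; internal times are seconds
time_unit_factor <- function(colname) {
  nm <- tolower(colname)
  if (grepl("min", nm)) 60
  else if (grepl("h(r|our)?s?($|[^a-z])", nm) || grepl("_h$|\\bh$", nm)) 3600
  else 1
}

read_delim_file <- function(path, header = TRUE) {
  if (!file.exists(path))
    stop_format("file '%s' does not exist", path)
  delim <- sniff_delim(path)
  out <- tryCatch(
    read.table(path, sep = delim, header = header, comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE,
               blank.lines.skip = TRUE),
    error = function(e) stop_format("cannot parse '%s': %s", path,
                                    conditionMessage(e)))
  if (nrow(out) == 0L)
    stop_format("'%s' contains no data rows", path)
  out
}

# ---- plate kinetics ---------------------------------------------------------

#' Read a plate-reader kinetic export
#'
#' Reads wide (first column time, one column per well) or long
#' (`well,time,value`) delimited text into a [plate_kinetics()] object. The
#' delimiter is sniffed from comma, tab and semicolon; a time column whose
#' name contains `"min"` or an hour marker is converted to seconds. Wells
#' whose values are all missing are dropped with a warning; interior gaps of
#' at most two points are linearly interpolated.
#'
#' @param path Path to a delimited text file.
#' @param layout `"auto"` (default), `"wide"` or `"long"`. Auto detection
#'   treats a file with columns named `well`, `time*` and `value` as long.
#' @param cycle_s Nominal cycle time in seconds; defaults to the median time
#'   step.
#' @param meta Named list of assay-level annotations.
#' @return A [plate_kinetics()] object.
#' @export
#' @examples
#' plate <- gen_tht_plate(tht_truth(noise_sd = 0), n_wells = 3,
#'                        duration_s = 6300, cycle_s = 350, seed = 1)$plate
#' f <- tempfile(fileext = ".csv")
#' write_plate_kinetics(plate, f)
#' p2 <- read_plate_kinetics(f)
read_plate_kinetics <- function(path, layout = c("auto", "wide", "long"),
                                cycle_s = NULL, meta = list()) {
  layout <- match.arg(layout)
  df <- read_delim_file(path)
  nms <- tolower(names(df))
  if (layout == "auto") {
    layout <- if (all(c("well", "value") %in% nms) &&
                  any(grepl("^time", nms))) "long" else "wide"
  }

  if (layout == "long") {
    wcol <- which(nms == "well")[1]
    tcol <- which(grepl("^time", nms))[1]
    vcol <- which(nms == "value")[1]
    if (anyNA(c(wcol, tcol, vcol)))
      stop_format("long layout needs columns well, time*, value; got: %s",
                  paste(names(df), collapse = ", "))
    fac <- time_unit_factor(names(df)[tcol])
    df <- df[order(df[[wcol]], df[[tcol]]), ]
    pieces <- split(df, df[[wcol]])
    traces <- lapply(pieces, function(p) {
      if (all(is.na(p[[vcol]]))) return(NULL)
      tht_trace(p[[wcol]][1], p[[tcol]] * fac, p[[vcol]])
    })
  } else {
    if (ncol(df) < 2L)
      stop_format("wide layout needs a time column plus at least one well")
    well_names <- names(df)[-1]
    dup <- well_names[duplicated(well_names)]
    if (length(dup))
      stop_format("duplicated well column '%s'", dup[1])
    fac <- time_unit_factor(names(df)[1])
    time_s <- df[[1]] * fac
    traces <- lapply(well_names, function(w) {
      v <- df[[w]]
      if (all(is.na(v))) return(NULL)
      tht_trace(w, time_s, v)
    })
  }

  dropped <- vapply(traces, is.null, logical(1))
  if (any(dropped))
    warning(sprintf("dropped %d all-missing well(s)", sum(dropped)),
            call. = FALSE)
  traces <- traces[!dropped]
  if (length(traces) == 0L)
    stop_validation("no usable wells in '%s'", path)
  if (is.null(cycle_s))
    cycle_s <- median(diff(traces[[1]]$time_s))
  plate_kinetics(traces, cycle_s = cycle_s, meta = meta)
}

#' Write a plate to delimited text
#'
#' @param plate A [plate_kinetics()] object.
#' @param path Output path.
#' @param layout `"wide"` or `"long"`.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_plate_kinetics <- function(plate, path, layout = c("wide", "long"),
                                 sep = ",") {
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- data.frame(time_s = plate$traces[[1]]$time_s, check.names = FALSE)
    for (tr in plate$traces) df[[tr$well_id]] <- tr$intensity
  } else {
    df <- do.call(rbind, lapply(plate$traces, function(tr)
      data.frame(well = tr$well_id, time_s = tr$time_s,
                 value = tr$intensity)))
  }
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- FRAP -------------------------------------------------------------------

#' Read a three-ROI FRAP intensity table
#'
#' Expects columns `time`, `roi`, `reference` and `background` (a `time_s` /
#' `time_min` suffix selects the unit). The first post-bleach frame is taken
#' from a `# bleach_index=N` comment header if present, otherwise inferred as
#' the frame with the largest single-step drop in the bleached-ROI signal.
#'
#' @param path Path to a delimited text file.
#' @return A [frap_series()] object.
#' @export
read_frap_table <- function(path) {
  if (!file.exists(path))
    stop_format("file '%s' does not exist", path)
  hdr <- grep("^#", readLines(path, n = 20L, warn = FALSE), value = TRUE)
  bleach_index <- NA_integer_
  m <- regmatches(hdr, regexpr("bleach_index\\s*=\\s*[0-9]+", hdr))
  if (length(m))
    bleach_index <- as.integer(sub(".*=\\s*", "", m[1]))

  df <- read_delim_file(path)
  nms <- tolower(names(df))
  tcol <- which(grepl("^time", nms))[1]
  need <- c("roi", "reference", "background")
  idx <- match(need, nms)
  if (is.na(tcol) || anyNA(idx))
    stop_format("FRAP table needs columns time, roi, reference, background; got: %s",
                paste(names(df), collapse = ", "))
  time_s <- df[[tcol]] * time_unit_factor(names(df)[tcol])
  roi <- df[[idx[1]]]

  if (is.na(bleach_index)) {
    drops <- diff(roi)
    if (min(drops) >= 0 || abs(min(drops)) <= 2 * sd(roi) / sqrt(length(roi)))
      stop_format("no bleach_index header and no detectable bleach drop in '%s'",
                  path)
    bleach_index <- which.min(drops) + 1L
  }
  frap_series(time_s, roi, df[[idx[2]]], df[[idx[3]]], bleach_index)
}

#' Write a FRAP series to delimited text
#'
#' @param series A [frap_series()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frap_table <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bleach_index=%d", series$bleach_index), con)
  write.table(data.frame(time_s = series$time_s, roi = series$roi,
                         reference = series$reference,
                         background = series$background),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- photon traces ----------------------------------------------------------

#' Read a binned photon-count trace
#'
#' Accepts either a single column of counts (one row per bin at the requested
#' bin width) or `(time, count)` pairs, which are re-binned by summation onto
#' the requested grid (total counts are conserved exactly). Negative counts
#' are rejected.
#'
#' @param path Path to a delimited text file.
#' @param bin_width_ms Requested bin width in milliseconds.
#' @param channel Channel label attached to the trace.
#' @return A [photon_trace()] object.
#' @export
read_photon_trace <- function(path, bin_width_ms, channel = "donor") {
  df <- read_delim_file(path)
  nms <- tolower(names(df))
  if (ncol(df) >= 2L && any(grepl("^time", nms))) {
    tcol <- which(grepl("^time", nms))[1]
    ccol <- setdiff(seq_len(ncol(df)), tcol)[1]
    tms <- df[[tcol]] * time_unit_factor(names(df)[tcol]) * 1000
    # time columns without a unit marker are taken as milliseconds already
    if (time_unit_factor(names(df)[tcol]) == 1 && !grepl("_s$", nms[tcol]))
      tms <- df[[tcol]]
    counts_in <- df[[ccol]]
    if (any(counts_in < 0, na.rm = TRUE))
      stop_validation("negative photon counts at row %d",
                      which(counts_in < 0)[1])
    idx <- floor(tms / bin_width_ms) + 1L
    counts <- vapply(seq_len(max(idx)),
                     function(i) sum(counts_in[idx == i]), numeric(1))
  } else {
    counts <- df[[1]]
    if (any(counts < 0, na.rm = TRUE))
      stop_validation("negative photon counts at row %d",
                      which(counts < 0)[1])
  }
  photon_trace(counts, bin_width_ms, channel = channel)
}

#' Write a photon trace to delimited text
#'
#' @param trace A [photon_trace()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_photon_trace <- function(trace, path) {
  write.table(data.frame(count = trace$counts), path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- config -----------------------------------------------------------------

#' Read a plain-text key-value run configuration
#'
#' Thin wrapper over YAML so analysis drivers can keep their parameters in a
#' text file next to the data.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_format("the 'yaml' package is required to read config files")
  if (!file.exists(path))
    stop_format("config '%s' does not exist", path)
  yaml::read_yaml(path)
}
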