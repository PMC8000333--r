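#' Single-channel chromatogram
#'
#' Container for a UV-detection chromatographic trace: elution time in
#' minutes paired with detector intensity in absorbance units (AU).
#'
#' @param time Numeric vector of elution times (minutes), strictly increasing.
#' @param intensity Numeric vector of intensities (AU), same length as `time`.
#' @param sample_id Character scalar identifying the injection.
#' @param level Optional nominal concentration of the injected solution
#'   (ug/mL); `NA` when unknown.
#' @param role One of `"calibration"`, `"batch"`, `"reference"`, `"unknown"`.
#' @return An object of class `"chromatogram"`: a list with elements
#'   `sample_id`, `time`, `intensity`, `level`, `role`.
#' @examples
#' ch <- chromatogram(c(0, 0.5, 1), c(0, 1, 0), sample_id = "s1")
#' print(ch)
#' @export
chromatogram <- function(time, intensity, sample_id = "sample",
                         level = NA_real_, role = "unknown") {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity))
    stop("time and intensity must have equal length (", length(time),
         " vs ", length(intensity), ")")
  if (length(time) < 2L)
    stop("a chromatogram needs at least 2 points")
  if (!all(is.finite(time)) || !all(is.finite(intensity)))
    stop("time and intensity must be finite")
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing (violation near index ",
         which(diff(time) <= 0)[1L], ")")
  role <- match.arg(role, c("calibration", "batch", "reference", "unknown"))
  structure(list(sample_id = as.character(sample_id), time = time,
                 intensity = intensity, level = as.numeric(level),
                 role = role),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("Chromatogram", sQuote(x$sample_id), "-", length(x$time), "points,",
      sprintf("%.2f-%.2f min", x$time[1L], x$time[length(x$time)]), "\n")
  if (is.finite(x$level)) cat("  nominal level:", x$level, "ug/mL\n")
  cat("  role:", x$role, " intensity range:",
      sprintf("[%.3g, %.3g] AU", min(x$intensity), max(x$intensity)), "\n")
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  graphics::plot(x$time, x$intensity, type = "l",
                 xlab = "time (min)", ylab = "intensity (AU)",
                 main = x$sample_id, ...)
  invisible(x)
}

#' Read a chromatogram from delimited text or ANDI/netCDF
#'
#' The canonical text layout is two rows: the first row holds the time axis
#' (minutes) and the second the intensities (AU).  A long two-column
#' (row-per-point) layout is auto-detected from the shape.  ANDI/netCDF files
#' are read through the standard `ordinate_values` /
#' `actual_run_time_length` variables (vendor extensions ignored); the ncdf4
#' package must be installed for that format.
#'
#' @param path Path to the file.
#' @param format `"tworow_text"` (default) or `"andi_netcdf"`.
#' @param sep Field separator for text input.
#' @param sample_id,level,role Metadata attached to the returned object;
#'   `sample_id` defaults to the file name without extension.
#' @return A [chromatogram()] object.
#' @export
read_chromatogram <- function(path, format = c("tworow_text", "andi_netcdf"),
                              sep = ",", sample_id = NULL,
                              level = NA_real_, role = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "andi_netcdf") {
    return(read_andi_cdf(path, sample_id = sample_id, level = level,
                         role = role))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty chromatogram file: ", path)
  parse_row <- function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], sep, fixed = TRUE)[[1L]]))
    if (anyNA(v))
      stop("malformed numeric field in row ", i, " of ", path)
    v
  }
  rows <- lapply(seq_along(lines), parse_row)
  n_fields <- lengths(rows)
  if (length(rows) == 2L && all(n_fields >= 2L)) {
    tm <- rows[[1L]]; int <- rows[[2L]]     # canonical wide layout
  } else if (all(n_fields == 2L) && length(rows) >= 2L) {
    m <- do.call(rbind, rows)               # long layout, one point per row
    tm <- m[, 1L]; int <- m[, 2L]
  } else {
    stop("cannot identify layout of ", path,
         ": expected 2 rows of points or 2 columns per row")
  }
  chromatogram(tm, int, sample_id = sample_id, level = level, role = role)
}

read_andi_cdf <- function(path, sample_id, level, role) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("reading ANDI/netCDF chromatograms requires the ncdf4 package")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  ord <- ncdf4::ncvar_get(nc, "ordinate_values")
  tm <- if ("raw_data_retention" %in% names(nc$var)) {
    ncdf4::ncvar_get(nc, "raw_data_retention") / 60  # seconds -> minutes
  } else {
    # uniform grid over the declared run-time window
    t0 <- tryCatch(as.numeric(ncdf4::ncvar_get(nc, "actual_delay_time")),
                   error = function(e) 0)
    dt <- as.numeric(ncdf4::ncvar_get(nc, "actual_sampling_interval"))
    (t0 + dt * (seq_along(ord) - 1)) / 60
  }
  chromatogram(as.numeric(tm), as.numeric(ord), sample_id = sample_id,
               level = level, role = role)
}

#' Write a chromatogram as two-row delimited text
#'
#' @param chrom A [chromatogram()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path, sep = ",") {
  stopifnot(inherits(chrom, "chromatogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(format(chrom$time, digits = 15, trim = TRUE,
                            scientific = FALSE), collapse = sep),
               paste(format(chrom$intensity, digits = 15, trim = TRUE),
                     collapse = sep)), con)
  invisible(path)
}

#' Peak-area table
#'
#' Samples-by-peaks matrix of integrated areas (AU.min).  Peaks are named by
#' retention time (`"peak_7.28"` style); sample rows may carry a nominal
#' concentration for calibration work.
#'
#' @param areas Numeric matrix, samples x peaks, no negative entries.
#' @param sample_ids Row identifiers (defaults to rownames of `areas`).
#' @param peak_names Column identifiers (defaults to colnames), unique.
#' @param levels Optional per-sample nominal concentrations (ug/mL).
#' @return An object of class `"peak_table"`.
#' @export
peak_table <- function(areas, sample_ids = rownames(areas),
                       peak_names = colnames(areas), levels = NULL) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(areas)))
  if (is.null(peak_names)) stop("peak names are required")
  sample_ids <- as.character(sample_ids)
  peak_names <- as.character(peak_names)
  if (length(sample_ids) != nrow(areas) || length(peak_names) != ncol(areas))
    stop("id lengths inconsistent with the areas matrix")
  if (anyDuplicated(peak_names))
    stop("duplicated peak name: ",
         peak_names[duplicated(peak_names)][1L])
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("areas must be finite and non-negative")
  if (!is.null(levels) && length(levels) != nrow(areas))
    stop("levels must have one entry per sample")
  dimnames(areas) <- list(sample_ids, peak_names)
  structure(list(sample_ids = sample_ids, peak_names = peak_names,
                 areas = areas,
                 levels = if (is.null(levels)) NULL else as.numeric(levels)),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("PeakTable:", length(x$sample_ids), "samples x",
      length(x$peak_names), "peaks\n")
  if (!is.null(x$levels))
    cat("  levels (ug/mL):", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.peak_table <- function(x, ...) x$areas

#' Read a peak-area table from delimited text
#'
#' Expects a header of peak names, one row per sample, with the sample id in
#' the first column.  An optional `level` column (any position) is split off
#' into the `levels` field.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicated peak name in header: ",
         names(df)[duplicated(names(df))][1L])
  ids <- as.character(df[[1L]])
  df <- df[-1L]
  levels <- NULL
  if ("level" %in% names(df)) {
    levels <- as.numeric(df[["level"]])
    df <- df[setdiff(names(df), "level")]
  }
  areas <- as.matrix(df)
  if (any(areas < 0)) stop("negative peak area in ", path)
  peak_table(areas, sample_ids = ids, peak_names = colnames(areas),
             levels = levels)
}

#' Write a peak-area table as delimited text
#'
#' @param pt A [peak_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(pt, path, sep = ",") {
  stopifnot(inherits(pt, "peak_table"))
  df <- data.frame(sample_id = pt$sample_ids, check.names = FALSE)
  if (!is.null(pt$levels)) df$level <- pt$levels
  df <- cbind(df, as.data.frame(pt$areas, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of report tables as delimited text
#'
#' Each element of `results` (a named list of data frames) is written as
#' `<dir>/<name>.csv` with numeric columns formatted to a fixed number of
#' decimals.  File naming and formatting are deterministic so repeated runs
#' produce byte-identical output.
#'
#' @param results Named list of data frames.
#' @param dir Output directory (created if missing).
#' @param digits Decimals used for numeric columns (default 2).
#' @param sep Field separator.
#' @return Character vector of file paths written, invisibly.
#' @export
write_report_tables <- function(results, dir, digits = 2, sep = ",") {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]], check.names = FALSE)
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]]))
        df[[j]] <- formatC(df[[j]], format = "f", digits = digits)
    }
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.table(df, p, sep = sep, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
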