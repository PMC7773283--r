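## Readers and writers for the tabular formats the pipeline consumes
## and emits. CSV/TSV with a header row is the native dialect; XLSX
## workbooks are read through readxl when available. Column names are
## mapped through a `dialect` so externally produced tables need not be
## renamed by hand.

#' Table dialect
#'
#' Describes how an external table maps onto the package's field names:
#' a column map, the field separator, and whether flow signs must be
#' flipped (for sources that record caudal flow as positive; internally
#' caudal flow is negative).
#'
#' @param col_map Named character vector mapping internal names to the
#'   file's column names, e.g. \code{c(z = "position_mm")}. Unmapped
#'   fields default to their internal names.
#' @param sep Field separator; \code{","} (default) or \code{"\t"}.
#' @param flip_sign Logical; flip the sign of flow values on read.
#' @return An object of class \code{table_dialect}.
#' @export
table_dialect <- function(col_map = character(), sep = ",", flip_sign = FALSE) {
  structure(list(col_map = col_map, sep = sep, flip_sign = isTRUE(flip_sign)),
            class = "table_dialect")
}

resolve_cols <- function(dialect, fields) {
  out <- setNames(fields, fields)
  if (length(dialect$col_map)) {
    hit <- intersect(names(dialect$col_map), fields)
    out[hit] <- dialect$col_map[hit]
  }
  out
}

read_table_any <- function(path, dialect) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    return(as.data.frame(readxl::read_excel(path)))
  }
  df <- tryCatch(
    read.csv(path, sep = dialect$sep, check.names = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                             call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop(sprintf("empty table: %s", path), call. = FALSE)
  }
  df
}

#' Read an axial geometric profile
#'
#' Reads a per-position table of cord/dura areas and perimeters
#' (columns \code{z}, \code{A_c}, \code{A_d}, \code{P_c}, \code{P_d};
#' mm and mm^2) and returns a validated [axial_profile()] on a uniform
#' grid. Non-uniformly spaced input is linearly resampled onto a
#' uniform grid with the same range and mean spacing, with a warning.
#'
#' @param path CSV/TSV/XLSX file path.
#' @param dialect A [table_dialect()].
#' @return An [axial_profile()].
#' @export
read_axial_profile <- function(path, dialect = table_dialect()) {
  df <- read_table_any(path, dialect)
  cols <- resolve_cols(dialect, c("z", "A_c", "A_d", "P_c", "P_d"))
  missing_cols <- cols[!cols %in% names(df)]
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  z <- as.numeric(df[[cols["z"]]])
  if (any(diff(z) <= 0)) stop("z must be strictly increasing", call. = FALSE)
  vals <- lapply(cols[-1L], function(cn) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value in column %s (row %d)", cn, which(is.na(v))[1L]),
           call. = FALSE)
    }
    v
  })
  names(vals) <- names(cols)[-1L]
  dzs <- diff(z)
  if (max(abs(dzs - mean(dzs))) > 1e-9 * max(mean(dzs), 1)) {
    warning("non-uniform axial spacing; resampling linearly onto a uniform grid")
    zu <- seq(z[1L], z[length(z)], length.out = length(z))
    vals <- lapply(vals, function(v) approx(z, v, xout = zu)$y)
    z <- zu
  }
  z <- z - z[1L]  # anchor the grid at the foramen magnum
  axial_profile(axial_grid(z), A_c = vals$A_c, A_d = vals$A_d,
                P_c = vals$P_c, P_d = vals$P_d)
}

#' Read cardiac-gated flow waveforms
#'
#' Reads a long-format table of per-level CSF flow waveforms (columns
#' \code{level_z} mm, \code{t} s, \code{Q} mL/s, optional \code{T} s)
#' and returns one [flow_waveform()] per axial level, sorted
#' rostral-to-caudal. At least two levels are required (pulse wave
#' velocity estimation is impossible from one).
#'
#' @inheritParams read_axial_profile
#' @return List of [flow_waveform()] objects sorted by \code{level_z}.
#' @export
read_flow_waveforms <- function(path, dialect = table_dialect()) {
  df <- read_table_any(path, dialect)
  cols <- resolve_cols(dialect, c("level_z", "t", "Q"))
  missing_cols <- cols[!cols %in% names(df)]
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  Qv <- suppressWarnings(as.numeric(df[[cols["Q"]]]))
  if (anyNA(Qv)) {
    stop(sprintf("non-numeric flow value at row %d", which(is.na(Qv))[1L]), call. = FALSE)
  }
  if (dialect$flip_sign) Qv <- -Qv
  lev <- as.numeric(df[[cols["level_z"]]])
  tv <- as.numeric(df[[cols["t"]]])
  Tcol <- resolve_cols(dialect, "T")
  Tv <- if (Tcol %in% names(df)) as.numeric(df[[Tcol]]) else rep(NA_real_, nrow(df))
  levels_z <- sort(unique(lev))
  if (length(levels_z) < 2L) {
    stop("need waveforms at >= 2 axial levels", call. = FALSE)
  }
  waves <- lapply(levels_z, function(zl) {
    i <- which(lev == zl)
    o <- order(tv[i]); i <- i[o]
    if (anyDuplicated(tv[i])) stop(sprintf("duplicate time sample at level z = %g", zl),
                                   call. = FALSE)
    Tz <- Tv[i][1L]
    flow_waveform(zl, tv[i], Qv[i], T = if (is.finite(Tz)) Tz else NULL)
  })
  waves
}

#' Write a group summary table
#'
#' Writes long-format group summary records (one row per parameter x
#' group x timepoint cell, with mean and SD) to CSV at full precision,
#' so a read round-trip reproduces the values exactly. Rows are ordered
#' by parameter, then timepoint, then group.
#'
#' @param records Data frame with columns \code{parameter},
#'   \code{unit}, \code{group}, \code{timepoint}, \code{mean},
#'   \code{sd}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_summary_table <- function(records, path) {
  records <- as.data.frame(records)
  need <- c("parameter", "unit", "group", "timepoint", "mean", "sd")
  if (!all(need %in% names(records))) {
    stop(sprintf("summary records need columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  units <- tapply(records$unit, records$parameter, function(u) length(unique(u)))
  if (any(units > 1L)) {
    stop(sprintf("mixed units for parameter(s): %s",
                 paste(names(units)[units > 1L], collapse = ", ")), call. = FALSE)
  }
  ord <- order(match(records$parameter, unique(records$parameter)),
               match(records$timepoint, timepoint_levels()),
               records$group)
  records <- records[ord, need]
  old <- options(digits = 17); on.exit(options(old))
  write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a group summary table written by [write_summary_table()]
#'
#' @param path CSV path.
#' @return Data frame of summary records.
#' @export
read_summary_table <- function(path) {
  df <- read_table_any(path, table_dialect())
  df$mean <- as.numeric(df$mean)
  df$sd <- as.numeric(df$sd)
  df
}

#' Reference cohort group summary
#'
#' Group mean +/- SD summaries of the geometric and hydrodynamic
#' parameters from an eight-animal cynomolgus monkey intrathecal
#' implantation cohort (cervical and lumbar groups; one
#' pre-implantation and two post-implantation scans), in the long
#' format [write_summary_table()] emits. Useful as a realistic
#' aggregation fixture and as a magnitude reference for the synthetic
#' generator's defaults.
#'
#' @return Data frame of summary records.
#' @export
reference_cohort_summary <- function() {
  read_summary_table(system.file("extdata", "nhp_cohort_group_summary.csv",
                                 package = "csfdyn", mustWork = TRUE))
}

#' Pool group summary cells into grand means
#'
#' Aggregates a long-format group summary (one mean per parameter x
#' group x timepoint cell) into a per-parameter grand mean: the
#' unweighted mean of the cell means. With equal group sizes this
#' equals the pooled subject-level mean, and it is how cohort-wide
#' values such as the mean SAS volume are reported.
#'
#' @param records Summary records (see [write_summary_table()]).
#' @param parameters Optional character vector restricting which
#'   parameters to pool.
#' @return Data frame with columns \code{parameter}, \code{unit},
#'   \code{n_cells}, \code{pooled_mean}.
#' @export
pooled_summary <- function(records, parameters = NULL) {
  records <- as.data.frame(records)
  if (!is.null(parameters)) records <- records[records$parameter %in% parameters, ]
  if (nrow(records) == 0L) stop("no records to pool", call. = FALSE)
  sp <- split(records, records$parameter)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(parameter = d$parameter[1L],
               unit = d$unit[1L],
               n_cells = nrow(d),
               pooled_mean = mean(d$mean))
  }))
  rownames(out) <- NULL
  out[order(match(out$parameter, unique(records$parameter))), , drop = FALSE]
}
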