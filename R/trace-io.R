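#' Read a current trace from a plain-text table
#'
#' The on-disk dialect is a comma-separated two-column table
#' (`time_s,current_pA`) preceded by `#`-prefixed metadata lines of the form
#' `# key: value`. Instrument vendor formats are out of scope; traces are
#' exchanged in this open dialect only.
#'
#' The sampling rate is taken from the header or from `...` overrides; when
#' absent it is inferred from the median time step. Files whose time stamps
#' deviate from a uniform grid by more than 1% of the median step are
#' rejected.
#'
#' @param path Path to a trace file.
#' @param ... Metadata overrides (`voltage_mV`, `sampling_rate_Hz`,
#'   `bandwidth_Hz`, `channel_id`), taking precedence over the file header.
#' @return A [blm_trace()].
#' @export
read_trace <- function(path, ...) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "blm_error_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    abort("no samples in trace file", class = "blm_error_no_samples")
  }
  meta <- parse_header(header)
  overrides <- list(...)
  meta[names(overrides)] <- overrides

  dat <- tryCatch(
    readr::read_csv(I(paste(body, collapse = "\n")),
      col_names = c("time_s", "current_pA"),
      col_types = "dd", progress = FALSE
    ),
    warning = function(w) abort("non-numeric rows in trace file",
      class = "blm_error_bad_rows")
  )
  if (anyNA(dat$time_s) || anyNA(dat$current_pA)) {
    abort("non-numeric rows in trace file", class = "blm_error_bad_rows")
  }
  if (nrow(dat) < 2) {
    abort("fewer than 2 samples", class = "blm_error_short_trace")
  }

  dt <- diff(dat$time_s)
  dt_med <- median(dt)
  if (dt_med <= 0 || any(abs(dt - dt_med) > 0.01 * dt_med)) {
    abort("irregular sampling: time steps deviate from uniform by > 1%",
      class = "blm_error_irregular_sampling")
  }
  rate <- meta$sampling_rate_Hz %||% (1 / dt_med)
  blm_trace(dat$current_pA,
    sampling_rate_Hz = rate,
    voltage_mV = meta$voltage_mV %||% 100,
    bandwidth_Hz = meta$bandwidth_Hz %||% (rate / 20),
    t0_s = dat$time_s[1],
    channel_id = meta$channel_id %||% basename(path)
  )
}

parse_header <- function(header) {
  out <- list()
  for (ln in header) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- m[2]
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (is.na(num)) val else num
    }
  }
  out
}

#' Write a current trace
#'
#' Emits the dialect [read_trace()] accepts; the header always carries
#' `voltage_mV`, `sampling_rate_Hz` and `bandwidth_Hz` so a round trip
#' preserves the acquisition metadata.
#'
#' @param trace A [blm_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "blm_trace"))
  m <- trace_meta(trace)
  header <- c(
    sprintf("# voltage_mV: %.10g", m$voltage_mV),
    sprintf("# sampling_rate_Hz: %.10g", m$sampling_rate_Hz),
    sprintf("# bandwidth_Hz: %.10g", m$bandwidth_Hz),
    sprintf("# channel_id: %s", m$channel_id)
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.8f,%.6f", trace$time_s, trace$current_pA), con)
  invisible(path)
}

event_table_cols <- c(
  "start_s", "end_s", "lifetime_ms", "mean_current_pA", "peak_current_pA",
  "mean_conductance_pS", "peak_conductance_pS", "class_label"
)

#' Read or write an event table
#'
#' Idealized events travel as a CSV with columns `start_s, end_s,
#' lifetime_ms, mean_current_pA, peak_current_pA, mean_conductance_pS,
#' peak_conductance_pS, class_label` (extra columns such as `membrane_id`
#' round-trip untouched). Class labels must be one of [event_classes()].
#'
#' @param path Path of the event CSV.
#' @return `read_event_table()` returns a tibble of events.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "blm_error_missing_file")
  }
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(event_table_cols, names(ev))
  if (length(missing) > 0) {
    abort(paste0("event table lacks columns: ", paste(missing, collapse = ", ")),
      class = "blm_error_bad_table")
  }
  bad <- setdiff(unique(ev$class_label), event_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown event class label: ", paste(bad, collapse = ", ")),
      class = "blm_error_bad_label")
  }
  ev
}

#' @rdname read_event_table
#' @param events A tibble of events with at least the standard columns.
#' @export
write_event_table <- function(events, path) {
  missing <- setdiff(event_table_cols, names(events))
  if (length(missing) > 0) {
    abort(paste0("event table lacks columns: ", paste(missing, collapse = ", ")),
      class = "blm_error_bad_table")
  }
  bad <- setdiff(unique(events$class_label), event_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown event class label: ", paste(bad, collapse = ", ")),
      class = "blm_error_bad_label")
  }
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

#' Read or write an AFM height map
#'
#' Height maps travel as plain-text numeric matrices (rows of space-separated
#' nm values) with a `# pixel_size_nm: <v>` header line.
#'
#' @param path Path of the map file.
#' @return `read_height_map()` returns a `blm_heightmap`: a numeric matrix
#'   with a `pixel_size_nm` attribute.
#' @export
read_height_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "blm_error_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header(grep("^#", lines, value = TRUE))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1 || any(vapply(rows, anyNA, logical(1)))) {
    abort("height map is not a rectangular numeric grid",
      class = "blm_error_bad_grid")
  }
  grid <- do.call(rbind, rows)
  new_heightmap(grid, meta$pixel_size_nm %||% 1)
}

#' @rdname read_height_map
#' @param map A `blm_heightmap` (see [synth_height_map()]).
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "blm_heightmap"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm: %.10g", attr(map, "pixel_size_nm")), con)
  writeLines(apply(unclass(map), 1, function(r) paste(sprintf("%.5f", r), collapse = " ")), con)
  invisible(path)
}

new_heightmap <- function(grid, pixel_size_nm) {
  stopifnot(is.matrix(grid), all(is.finite(grid)), pixel_size_nm > 0)
  structure(grid, class = c("blm_heightmap", "matrix", "array"),
    pixel_size_nm = pixel_size_nm)
}
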