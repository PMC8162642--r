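#' Read a trace table
#'
#' Reads the delimited-text (CSV) trace format with header
#' `cell_id, embryo_id, ap_position, time_min, ms2_au, pp7_au`; one row per
#' (cell, time).  Missing fluorescence values may be written as an empty
#' field or the token `NaN` and are stored as `NA`.  Rows are returned
#' grouped by cell with times sorted; duplicate (cell, time) rows and
#' malformed fields are errors that name the offending line.
#'
#' @param path Path to the CSV file.
#' @return A trace tibble (see [tx_trace()]).
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # base read.csv: strtod parsing is exactly rounded, so the CSV round trip
  # is bit-lossless for doubles written in shortest round-trip notation
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  need <- c("cell_id", "embryo_id", "ap_position", "time_min", "ms2_au",
            "pp7_au")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  na_tokens <- c("", "NA", "NaN")
  as_num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    out[x %in% na_tokens] <- NA_real_
    bad <- which(is.na(out) & !(x %in% na_tokens))
    if (length(bad)) {
      stop("malformed row in ", path, " at line ", bad[1] + 1,
           ": cannot parse ", col, " value '", x[bad[1]], "'")
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  tr <- tibble(cell_id = raw$cell_id, embryo_id = raw$embryo_id,
               ap_position = as_num("ap_position"),
               time_min = as_num("time_min"),
               ms2_au = as_num("ms2_au"), pp7_au = as_num("pp7_au"))
  if (any(is.na(tr$time_min)) || any(tr$cell_id %in% na_tokens)) {
    bad <- which(is.na(tr$time_min) | tr$cell_id %in% na_tokens)[1]
    stop("malformed row in ", path, " at line ", bad + 1,
         ": cell_id and time_min are required")
  }
  dup <- duplicated(tr[, c("cell_id", "time_min")])
  if (any(dup)) {
    stop("duplicate (cell_id, time_min) row in ", path, " at line ",
         which(dup)[1] + 1)
  }
  tr <- dplyr::arrange(tr, .data$cell_id, .data$time_min)
  validate_trace(tr)
  tr
}

#' Write a trace table
#'
#' Writes the CSV trace format read by [read_traces()].  Missing values are
#' written as `NaN`; a read-write-read round trip is lossless.
#'
#' @param traces A trace tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  validate_trace(traces)
  cols <- c("cell_id", "embryo_id", "ap_position", "time_min", "ms2_au",
            "pp7_au")
  readr::write_csv(traces[, cols], path, na = "NaN")
  invisible(path)
}

run_config_defaults <- function() {
  list(
    geometry = unclass(reporter_geometry()),
    inference = list(n_steps = 30000, n_adapt = 100, burn_in = 0.25,
                     n_knots = 5, dr_penalty_sd = 1, refine = 4,
                     ci_level = 0.9),
    curation = list(fit_threshold = 0.8, burst_fraction_threshold = 0.3,
                    burst_window_min = 1),
    simulation = list(n_cells = 30, noise_sd = c(0.5, 2), dt = 0.25,
                      duration = 18, burst_fraction = 0),
    seed = 1
  )
}

#' Read and resolve a run configuration
#'
#' Reads a structured key-value (YAML) configuration with top-level sections
#' `geometry`, `inference`, `curation`, `simulation` and `seed`, overlaying
#' the supplied values onto the package defaults.  Unknown keys at any level
#' are rejected.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A named list of resolved settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_section <- function(def, usr, where) {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown)) {
      stop("unknown config key", if (length(unknown) > 1) "s", " in ",
           where, ": ", paste(unknown, collapse = ", "))
    }
    utils::modifyList(def, usr)
  }
  unknown_top <- setdiff(names(user), names(defaults))
  if (length(unknown_top)) {
    stop("unknown config section: ", paste(unknown_top, collapse = ", "))
  }
  out <- defaults
  for (sec in names(user)) {
    out[[sec]] <- if (is.list(defaults[[sec]])) {
      merge_section(defaults[[sec]], user[[sec]], sec)
    } else {
      user[[sec]]
    }
  }
  out
}

#' Write the resolved configuration of a run
#'
#' Every pipeline stage emits a JSON copy of the fully resolved settings it
#' ran with (including all seeds) next to its outputs, for reproducibility.
#'
#' @param config Resolved configuration list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
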