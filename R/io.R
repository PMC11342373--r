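#' Read a peak table from delimited text
#'
#' Comma-separated, UTF-8, `.` decimal; required columns `sample_id`,
#' `transition_id`, `area`, `rt`, optional `snr`. Unknown transition ids
#' (when a panel is supplied) and duplicate (sample, transition) keys are
#' rejected with the offending row numbers.
#'
#' @param path File path.
#' @param panel Optional `pfas_panel` for transition-id validation.
#' @return Tibble (sample_id, transition_id, area, rt, snr).
#' @export
read_peak_table <- function(path, panel = NULL) {
  # suppressed: readr warns when a named parser has no matching column;
  # the schema check directly below reports that case itself
  tbl <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      sample_id = readr::col_character(),
                      transition_id = readr::col_character(),
                      area = readr::col_double(),
                      rt = readr::col_double(),
                      .default = readr::col_double()
                    ))
  )
  required <- c("sample_id", "transition_id", "area", "rt")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"snr" %in% names(tbl)) tbl$snr <- NA_real_
  bad <- which(is.na(tbl$area) | is.na(tbl$rt) |
                 is.na(tbl$sample_id) | is.na(tbl$transition_id))
  if (length(bad)) {
    stop("malformed peak-table row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(tbl$sample_id, tbl$transition_id)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (sample_id, transition_id) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (!is.null(panel)) {
    unknown <- which(!tbl$transition_id %in% panel$transitions$transition_id)
    if (length(unknown)) {
      stop("unknown transition id(s) at row(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  tbl[, c("sample_id", "transition_id", "area", "rt", "snr")]
}

#' Write a peak table
#' @param peak_table Tibble in the peak-table schema.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peak_table, path) {
  readr::write_csv(peak_table, path)
  invisible(path)
}

sample_roles <- c("procedural_blank", "mfs_calibrant", "spiked", "unknown")

#' Read a sample sheet from delimited text
#'
#' Columns: `sample_id`, `role`, `matrix_category`, `matrix_name`,
#' `spike_level_ng_kg`, `batch_id`. Roles must be one of
#' `procedural_blank`, `mfs_calibrant`, `spiked`, `unknown`; spiked and
#' calibrant rows need a spike level.
#'
#' @param path File path.
#' @return Sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  tbl <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      sample_id = readr::col_character(),
                      role = readr::col_character(),
                      matrix_category = readr::col_character(),
                      matrix_name = readr::col_character(),
                      spike_level_ng_kg = readr::col_double(),
                      batch_id = readr::col_character()
                    ))
  )
  required <- c("sample_id", "role", "matrix_category", "matrix_name",
                "spike_level_ng_kg", "batch_id")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  }
  bad_role <- which(!tbl$role %in% sample_roles)
  if (length(bad_role)) {
    hint <- tbl$role[bad_role[1]]
    contains <- sample_roles[grepl(hint, sample_roles, fixed = TRUE)]
    sugg <- if (length(contains)) {
      contains[1]
    } else {
      sample_roles[which.min(utils::adist(hint, sample_roles))]
    }
    stop("unknown role \"", hint, "\" at row ", bad_role[1],
         "; did you mean \"", sugg, "\"?")
  }
  bad_cat <- which(!tbl$matrix_category %in% pfas_categories())
  if (length(bad_cat)) {
    stop("unknown matrix_category at row(s): ",
         paste(utils::head(bad_cat, 5), collapse = ", "))
  }
  needs_level <- tbl$role %in% c("spiked")
  if (any(needs_level & (is.na(tbl$spike_level_ng_kg) |
                           tbl$spike_level_ng_kg <= 0))) {
    stop("spiked samples require a positive spike_level_ng_kg")
  }
  if (any(tbl$role == "mfs_calibrant" & is.na(tbl$spike_level_ng_kg))) {
    stop("mfs_calibrant samples require a spike_level_ng_kg (0 allowed)")
  }
  tbl[, required]
}

#' Write a sample sheet
#' @param samples Sample sheet tibble.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' Write long-format chromatogram traces
#' @param traces Tibble (sample_id, transition_id, time_min, intensity).
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read long-format chromatogram traces
#' @param path File path.
#' @return Tibble (sample_id, transition_id, time_min, intensity).
#' @export
read_traces <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    transition_id = readr::col_character(),
                    time_min = readr::col_double(),
                    intensity = readr::col_double()
                  ))
}
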