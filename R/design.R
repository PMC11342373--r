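#' Matrix categories covered by the validation design
#' @export
pfas_categories <- function() {
  c("leafy", "bulb_leek", "root", "fruit", "other")
}

#' Default matrix-fortified standard calibration levels (ng/kg)
#'
#' Twelve levels spanning 0 to 2000 ng/kg, covering four decades so that
#' both trace background levels and incident contamination fall on the
#' calibration line.
#' @export
mfs_levels_default <- function() {
  c(0, 0.5, 1.0, 2.5, 5.0, 10, 25, 50, 100, 500, 1000, 2000)
}

# representative matrices per category (mirrors a realistic produce set)
category_matrices <- list(
  leafy     = c("spinach", "endive", "kale", "iceberg_lettuce", "turkish_lettuce", "chard", "batavia_lettuce"),
  bulb_leek = c("onion", "onion_2", "leek", "garlic", "red_onion", "scallions", "chives"),
  root      = c("potato", "beets_peeled", "beets_unpeeled", "carrot_peeled", "carrot_unpeeled", "potato_peeled", "potato_unpeeled"),
  fruit     = c("apple", "strawberry", "white_grape", "plum", "pear", "red_berries", "apple_2"),
  other     = c("zucchini", "cauliflower", "broccoli", "snow_peas", "rhubarb", "pumpkin", "cucumber")
)

#' Design a one-day validation batch for a matrix category
#'
#' Lays out the sample set of a single validation day: a 12-level
#' matrix-fortified standard (MFS) calibration ladder prepared in the
#' category's representative matrix (P1), six further matrices (P2-P7) each
#' analyzed unspiked and spiked at 2.5, 50 and 500 ng/kg with all analytes,
#' and duplicate procedural blanks.
#'
#' @param category Matrix category, one of [pfas_categories()].
#' @param seed Integer seed stored with the design; simulation from this
#'   design is fully reproducible.
#' @param mfs_levels Calibration levels in ng/kg; must be strictly
#'   increasing and include 0.
#' @param spike_levels Validation spike levels in ng/kg (positive).
#' @param n_matrices Number of validation matrices (default 6).
#' @param n_procedural_blanks Number of procedural blanks (>= 2).
#' @return A `batch_design` object: list with the design parameters and a
#'   `samples` tibble (sample_id, role, matrix_category, matrix_name,
#'   spike_level_ng_kg, batch_id).
#' @examples
#' d <- design_validation_batch("leafy", seed = 1)
#' dplyr::count(d$samples, role)
#' @export
design_validation_batch <- function(category, seed,
                                    mfs_levels = mfs_levels_default(),
                                    spike_levels = c(2.5, 50, 500),
                                    n_matrices = 6,
                                    n_procedural_blanks = 2) {
  category <- match.arg(category, pfas_categories())
  if (is.unsorted(mfs_levels, strictly = TRUE) || mfs_levels[1] != 0) {
    stop("mfs_levels must be strictly increasing and include 0")
  }
  if (any(spike_levels <= 0)) stop("spike_levels must be positive")
  if (n_procedural_blanks < 2) stop("n_procedural_blanks must be >= 2")

  mats <- category_matrices[[category]]
  batch_id <- sprintf("%s_d1", category)

  blanks <- tibble::tibble(
    sample_id = sprintf("%s_blank_%d", category, seq_len(n_procedural_blanks)),
    role = "procedural_blank",
    matrix_category = category,
    matrix_name = "none",
    spike_level_ng_kg = 0
  )
  mfs <- tibble::tibble(
    sample_id = sprintf("%s_mfs_L%02d", category, seq_along(mfs_levels)),
    role = "mfs_calibrant",
    matrix_category = category,
    matrix_name = mats[1],
    spike_level_ng_kg = mfs_levels
  )
  val_mats <- mats[1 + seq_len(n_matrices)]
  validation <- tidyr::expand_grid(
    matrix_name = val_mats,
    spike_level_ng_kg = c(0, spike_levels)
  ) |>
    dplyr::mutate(
      sample_id = sprintf(
        "%s_%s_s%g", category, .data$matrix_name, .data$spike_level_ng_kg
      ),
      role = dplyr::if_else(.data$spike_level_ng_kg > 0, "spiked", "unknown"),
      matrix_category = category
    ) |>
    dplyr::select(
      "sample_id", "role", "matrix_category", "matrix_name", "spike_level_ng_kg"
    )

  samples <- dplyr::bind_rows(blanks, mfs, validation) |>
    dplyr::mutate(batch_id = batch_id)

  structure(
    list(
      category = category,
      mfs_levels = mfs_levels,
      spike_levels = spike_levels,
      n_matrices = n_matrices,
      n_procedural_blanks = n_procedural_blanks,
      seed = as.integer(seed),
      samples = samples
    ),
    class = "batch_design"
  )
}

#' @export
print.batch_design <- function(x, ...) {
  cat(
    "<batch_design> category=", x$category,
    " | ", length(x$mfs_levels), " MFS levels, ",
    x$n_matrices, " matrices x ", length(x$spike_levels), " spikes, ",
    x$n_procedural_blanks, " procedural blanks (seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
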