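#' Build the default 20-analyte PFAS panel
#'
#' Constructs the compound panel used throughout the pipeline: 20 PFAS
#' analytes (10 perfluoroalkyl carboxylates, 5 perfluoroalkyl sulfonates and
#' 5 other PFAS including HFPO-DA and the chlorinated polyfluoroether
#' sulfonates), 12 isotopically labeled internal standards added before
#' sample preparation, and 2 injection standards (13C8-PFOA, 13C8-PFOS)
#' added just before injection.
#'
#' Every analyte carries a quantifier transition and, except for PFPeA, a
#' qualifier transition; PFPeA has only one abundant product ion and instead
#' carries a pseudo transition (precursor -> precursor at low collision
#' energy) so that a relative ion abundance can still be computed. PFOS is
#' quantified on m/z 499 > 99 (the more selective, less sensitive channel)
#' with 499 > 80 as qualifier, so that a bile-acid (TDCA-like) interference
#' on 499 > 80 perturbs the ion ratio rather than the quantitative result.
#'
#' Analytes without their own labeled internal standard borrow a surrogate,
#' chosen primarily by retention time. Transition m/z values, retention
#' times and ion fractions are editable fixture values representative of
#' this compound class, not measured constants; replace them with your
#' instrument's values via the `panel` argument of downstream functions.
#'
#' @return An object of class `pfas_panel`: a list of tibbles
#'   `analytes` (analyte_id, chain_class, is_id, expected_rt),
#'   `transitions` (compound_id, transition_id, precursor_mz, product_mz,
#'   role, true_ion_fraction) covering analytes, internal standards and
#'   injection standards, `internal_standards` (is_id, expected_rt) and
#'   `injection_standards` (id, expected_rt).
#' @examples
#' panel <- build_default_panel()
#' panel$analytes
#' @export
build_default_panel <- function() {
  analytes <- tibble::tribble(
    ~analyte_id,     ~chain_class,  ~is_id,           ~expected_rt,
    "PFPeA",         "carboxylate", "13C3-PFPeA",     1.90,
    "PFHxA",         "carboxylate", "13C2-PFHxA",     2.70,
    "PFHpA",         "carboxylate", "13C4-PFHpA",     3.60,
    "PFOA",          "carboxylate", "13C4-PFOA",      4.50,
    "PFNA",          "carboxylate", "13C5-PFNA",      5.30,
    "PFDA",          "carboxylate", "13C2-PFDA",      6.10,
    "PFUnDA",        "carboxylate", "13C2-PFUnDA",    6.80,
    "PFDoDA",        "carboxylate", "13C2-PFDoDA",    7.40,
    "PFTrDA",        "carboxylate", "13C2-PFDoDA",    7.95,
    "PFTeDA",        "carboxylate", "13C2-PFDoDA",    8.45,
    "PFBS",          "sulfonate",   "13C3-PFBS",      2.50,
    "PFHxS",         "sulfonate",   "18O2-PFHxS",     4.30,
    "PFHpS",         "sulfonate",   "13C4-PFOS",      5.10,
    "PFOS",          "sulfonate",   "13C4-PFOS",      5.90,
    "PFDS",          "sulfonate",   "13C4-PFOS",      7.20,
    "PFOSA",         "other",       "13C2-PFDoDA",    10.20,
    "HFPO-DA",       "other",       "13C3-HFPO-DA",   3.90,
    "DONA",          "other",       "13C4-PFOA",      4.10,
    "9Cl-PF3ONS",    "other",       "13C4-PFOS",      6.00,
    "11Cl-PF3OUdS",  "other",       "13C2-PFUnDA",    7.60
  )

  # quantifier / qualifier m/z and ion fractions (fixture values)
  tr <- tibble::tribble(
    ~compound_id,    ~precursor_mz, ~product_mz, ~role,        ~true_ion_fraction,
    "PFPeA",         263.0,         219.0,       "quantifier", 0.70,
    "PFPeA",         263.0,         263.0,       "pseudo",     0.20,
    "PFHxA",         313.0,         269.0,       "quantifier", 0.60,
    "PFHxA",         313.0,         119.0,       "qualifier",  0.25,
    "PFHpA",         363.0,         319.0,       "quantifier", 0.60,
    "PFHpA",         363.0,         169.0,       "qualifier",  0.25,
    "PFOA",          413.0,         369.0,       "quantifier", 0.60,
    "PFOA",          413.0,         169.0,       "qualifier",  0.25,
    "PFNA",          463.0,         419.0,       "quantifier", 0.60,
    "PFNA",          463.0,         219.0,       "qualifier",  0.25,
    "PFDA",          513.0,         469.0,       "quantifier", 0.60,
    "PFDA",          513.0,         269.0,       "qualifier",  0.25,
    "PFUnDA",        563.0,         519.0,       "quantifier", 0.60,
    "PFUnDA",        563.0,         269.0,       "qualifier",  0.25,
    "PFDoDA",        613.0,         569.0,       "quantifier", 0.60,
    "PFDoDA",        613.0,         319.0,       "qualifier",  0.25,
    "PFTrDA",        663.0,         619.0,       "quantifier", 0.55,
    "PFTrDA",        663.0,         169.0,       "qualifier",  0.25,
    "PFTeDA",        713.0,         669.0,       "quantifier", 0.55,
    "PFTeDA",        713.0,         169.0,       "qualifier",  0.25,
    "PFBS",          299.0,         80.0,        "quantifier", 0.65,
    "PFBS",          299.0,         99.0,        "qualifier",  0.20,
    "PFHxS",         399.0,         80.0,        "quantifier", 0.65,
    "PFHxS",         399.0,         99.0,        "qualifier",  0.20,
    "PFHpS",         449.0,         80.0,        "quantifier", 0.65,
    "PFHpS",         449.0,         99.0,        "qualifier",  0.20,
    "PFOS",          499.0,         99.0,        "quantifier", 0.15,
    "PFOS",          499.0,         80.0,        "qualifier",  0.60,
    "PFDS",          599.0,         80.0,        "quantifier", 0.65,
    "PFDS",          599.0,         99.0,        "qualifier",  0.20,
    "PFOSA",         498.0,         78.0,        "quantifier", 0.55,
    "PFOSA",         498.0,         48.0,        "qualifier",  0.25,
    "HFPO-DA",       285.0,         169.0,       "quantifier", 0.55,
    "HFPO-DA",       285.0,         185.0,       "qualifier",  0.25,
    "DONA",          377.0,         251.0,       "quantifier", 0.60,
    "DONA",          377.0,         85.0,        "qualifier",  0.20,
    "9Cl-PF3ONS",    531.0,         351.0,       "quantifier", 0.60,
    "9Cl-PF3ONS",    531.0,         83.0,        "qualifier",  0.20,
    "11Cl-PF3OUdS",  631.0,         451.0,       "quantifier", 0.60,
    "11Cl-PF3OUdS",  631.0,         83.0,        "qualifier",  0.20
  )

  internal_standards <- tibble::tribble(
    ~is_id,          ~expected_rt, ~precursor_mz, ~product_mz,
    "13C3-PFPeA",    1.90,         266.0,         222.0,
    "13C2-PFHxA",    2.70,         315.0,         270.0,
    "13C4-PFHpA",    3.60,         367.0,         322.0,
    "13C4-PFOA",     4.50,         417.0,         372.0,
    "13C5-PFNA",     5.30,         468.0,         423.0,
    "13C2-PFDA",     6.10,         515.0,         470.0,
    "13C2-PFUnDA",   6.80,         565.0,         520.0,
    "13C2-PFDoDA",   7.40,         615.0,         570.0,
    "13C3-PFBS",     2.50,         302.0,         80.0,
    "18O2-PFHxS",    4.30,         403.0,         84.0,
    "13C4-PFOS",     5.90,         503.0,         80.0,
    "13C3-HFPO-DA",  3.90,         288.0,         169.0
  )

  injection_standards <- tibble::tribble(
    ~id,          ~expected_rt, ~precursor_mz, ~product_mz,
    "13C8-PFOA",  4.50,         421.0,         376.0,
    "13C8-PFOS",  5.90,         507.0,         80.0
  )

  std_tr <- dplyr::bind_rows(
    dplyr::transmute(internal_standards,
      compound_id = .data$is_id,
      precursor_mz = .data$precursor_mz,
      product_mz = .data$product_mz,
      role = "quantifier",
      true_ion_fraction = 0.8
    ),
    dplyr::transmute(injection_standards,
      compound_id = .data$id,
      precursor_mz = .data$precursor_mz,
      product_mz = .data$product_mz,
      role = "quantifier",
      true_ion_fraction = 0.8
    )
  )

  transitions <- dplyr::bind_rows(tr, std_tr) |>
    dplyr::mutate(
      transition_id = sprintf(
        "%s_%g>%g", .data$compound_id, .data$precursor_mz, .data$product_mz
      ),
      .before = "precursor_mz"
    )

  panel <- list(
    analytes = analytes,
    transitions = transitions,
    internal_standards = internal_standards[, c("is_id", "expected_rt")],
    injection_standards = injection_standards[, c("id", "expected_rt")]
  )
  class(panel) <- "pfas_panel"
  validate_panel(panel)
  panel
}

#' Validate the structural invariants of a PFAS panel
#'
#' Checks that every analyte has exactly one quantifier transition, at least
#' two transitions overall (qualifier or pseudo), a resolvable internal
#' standard, positive precursor masses with product m/z not exceeding the
#' precursor, and per-analyte ion fractions summing to at most 1. Pseudo
#' transitions must have product m/z equal to the precursor m/z.
#'
#' @param panel A `pfas_panel` object.
#' @return `panel`, invisibly, if valid; otherwise an error describing the
#'   first violated invariant.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "pfas_panel"))
  an <- panel$analytes
  tr <- dplyr::filter(panel$transitions, .data$compound_id %in% an$analyte_id)

  nq <- tr |>
    dplyr::filter(.data$role == "quantifier") |>
    dplyr::count(.data$compound_id)
  if (!all(an$analyte_id %in% nq$compound_id) || any(nq$n != 1)) {
    stop("every analyte must have exactly one quantifier transition")
  }
  ntr <- dplyr::count(tr, .data$compound_id)
  if (any(ntr$n < 2)) {
    stop("every analyte needs >= 2 transitions (qualifier or pseudo)")
  }
  if (any(tr$precursor_mz <= 0) || any(tr$product_mz > tr$precursor_mz)) {
    stop("transition m/z values invalid (precursor <= 0 or product > precursor)")
  }
  pseudo <- dplyr::filter(tr, .data$role == "pseudo")
  if (any(pseudo$product_mz != pseudo$precursor_mz)) {
    stop("pseudo transitions must have product m/z equal to precursor m/z")
  }
  fr <- tr |>
    dplyr::summarise(s = sum(.data$true_ion_fraction), .by = "compound_id")
  if (any(fr$s > 1 + 1e-12)) {
    stop("per-analyte ion fractions must sum to <= 1")
  }
  if (!all(an$is_id %in% panel$internal_standards$is_id)) {
    stop("analyte maps to an unknown internal standard")
  }
  invisible(panel)
}

#' @export
print.pfas_panel <- function(x, ...) {
  cat(
    "<pfas_panel> ", nrow(x$analytes), " analytes, ",
    nrow(x$internal_standards), " internal standards, ",
    nrow(x$injection_standards), " injection standards\n",
    sep = ""
  )
  invisible(x)
}

# quantifier transition id per analyte
panel_quantifiers <- function(panel) {
  panel$transitions |>
    dplyr::filter(
      .data$compound_id %in% panel$analytes$analyte_id,
      .data$role == "quantifier"
    ) |>
    dplyr::select(analyte_id = "compound_id", "transition_id")
}

# second transition (qualifier, or pseudo where no qualifier exists)
panel_qualifiers <- function(panel) {
  panel$transitions |>
    dplyr::filter(
      .data$compound_id %in% panel$analytes$analyte_id,
      .data$role %in% c("qualifier", "pseudo")
    ) |>
    dplyr::mutate(is_pseudo = .data$role == "pseudo") |>
    dplyr::select(analyte_id = "compound_id", "transition_id", "is_pseudo")
}
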