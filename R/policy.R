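#' Regulatory threshold policy
#'
#' International honey-quality regulations (Codex Alimentarius and the EU
#' honey directive) prescribe limits for the physicochemical parameters
#' screened by this package. A `honey_policy` object collects those limits
#' so every compliance rule reads them from one place.
#'
#' @details Defaults:
#' \describe{
#'   \item{econd_flower_max}{0.8 mS/cm; flower honey must stay below, honeydew
#'     above. Drives botanical reclassification, not a compliance code.}
#'   \item{econd_low_flag}{0.1 mS/cm; conductivity below this is flagged
#'     `LOW_ECOND` (suspect grade).}
#'   \item{sugar_sum_min_blossom}{60 g/100 g minimum glucose + fructose for
#'     blossom (nectar) honey.}
#'   \item{sugar_sum_min_honeydew}{45 g/100 g minimum for honeydew honey and
#'     honeydew blends.}
#'   \item{sucrose_max_default}{5 g/100 g.}
#'   \item{sucrose_max_exception}{10 g/100 g for the types in
#'     `sucrose_exception_types` (acacia, whose nectar is naturally
#'     sucrose-rich).}
#'   \item{hmf_max}{40 mg/kg 5-hydroxymethylfurfural.}
#'   \item{acidity_max}{50 meq/kg free acidity.}
#'   \item{diastase_min}{8 Schade units (DN).}
#'   \item{moisture_max}{20 \%.}
#'   \item{insoluble_max}{0.1 \% water-insoluble solids (0.5 \% for pressed
#'     honey, `insoluble_max_pressed`).}
#'   \item{blend_econd_min}{0.70 mS/cm; flower honey with a sub-blossom sugar
#'     sum but conductivity at or above this (and below 0.8) is flagged as a
#'     possible nectar/honeydew blend.}
#' }
#'
#' @param overrides named list (or NULL) overriding any default; unknown
#'   names or non-positive limits are errors.
#' @return A `honey_policy` list.
#' @examples
#' default_policy()$hmf_max
#' load_policy(list(hmf_max = 30))$hmf_max
#' @export
default_policy <- function() {
  structure(list(
    econd_flower_max       = 0.8,
    econd_low_flag         = 0.1,
    sugar_sum_min_blossom  = 60,
    sugar_sum_min_honeydew = 45,
    sucrose_max_default    = 5,
    sucrose_max_exception  = 10,
    sucrose_exception_types = "acacia",
    hmf_max                = 40,
    acidity_max            = 50,
    diastase_min           = 8,
    moisture_max           = 20,
    insoluble_max          = 0.1,
    insoluble_max_pressed  = 0.5,
    blend_econd_min        = 0.70
  ), class = "honey_policy")
}

#' @rdname default_policy
#' @param path optional path to a flat YAML file whose keys mirror the policy
#'   fields; ignored when `overrides` is given directly.
#' @export
load_policy <- function(overrides = NULL, path = NULL) {
  pol <- default_policy()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("policy file not found: ", path)
    overrides <- yaml::read_yaml(path)
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("policy overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(pol))
    if (length(unknown)) {
      stop("unknown policy key(s): ", paste(unknown, collapse = ", "))
    }
    pol[names(overrides)] <- overrides
  }
  validate_policy(pol)
  pol
}

validate_policy <- function(pol) {
  numeric_fields <- setdiff(names(pol), "sucrose_exception_types")
  for (f in numeric_fields) {
    v <- pol[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("policy limit '", f, "' must be a single positive number")
    }
  }
  if (pol$sugar_sum_min_honeydew >= pol$sugar_sum_min_blossom) {
    stop("honeydew sugar floor must be below the blossom floor")
  }
  if (pol$sucrose_max_exception <= pol$sucrose_max_default) {
    stop("exception sucrose ceiling must exceed the default ceiling")
  }
  if (!all(pol$sucrose_exception_types %in% honey_types())) {
    stop("sucrose exception types must be valid honey types")
  }
  invisible(pol)
}

#' Closed vocabularies for honey records
#'
#' @return Character vectors of the recognized botanical types, regions and
#'   harvest years.
#' @export
honey_types <- function() {
  c("acacia", "honeydew", "linden", "monofloral", "polyfloral", "sunflower")
}

#' @rdname honey_types
#' @export
honey_regions <- function() {
  c("Western", "Belgrade", "Northern", "Central", "Eastern", "Southern")
}

#' @rdname honey_types
#' @export
honey_years <- function() 2018:2023

# limit of quantification for sucrose and 5-HMF; censored cells store this
loq_value <- function() 0.5
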