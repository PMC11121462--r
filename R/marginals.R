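#' Calibrated per-type marginal specifications
#'
#' Published descriptive statistics (mean, SD, min, max per botanical type)
#' for the nine physicochemical parameters of Serbian honey, used as
#' truncated-normal marginals by the synthetic generator. Sucrose and 5-HMF
#' minima are 0 with censoring applied at the 0.50 limit of quantification
#' downstream. The monofloral sucrose marginal is synthetic (every published
#' monofloral value sat below the LOQ, so no mean/SD was reported): it is
#' chosen entirely below 0.50 so all draws censor. Printed SDs of 0.00 for
#' insoluble matter are replaced by 0.004 to keep the copula margin
#' non-degenerate.
#'
#' @return A tibble with columns `type`, `parameter`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
marginal_specs <- function() {
  rows <- list(
    # type, parameter, mean, sd, min, max
    c("acacia", "glu", 27.40, 3.87, 16.02, 40.00),
    c("acacia", "fru", 40.83, 5.83, 13.60, 53.10),
    c("acacia", "suc", 1.19, 1.79, 0, 16.58),
    c("acacia", "hmf", 5.71, 8.20, 0, 54.80),
    c("acacia", "mc", 16.19, 1.07, 13.50, 19.80),
    c("acacia", "acid", 11.44, 5.05, 2.30, 31.43),
    c("acacia", "dia", 13.06, 7.64, 3.90, 114.00),
    c("acacia", "ins", 0.01, 0.01, 0, 0.07),
    c("acacia", "econd", 0.20, 0.10, 0.03, 0.69),
    c("honeydew", "glu", 29.33, 5.17, 16.19, 38.85),
    c("honeydew", "fru", 37.84, 6.32, 22.65, 49.72),
    c("honeydew", "suc", 0.46, 0.61, 0, 2.70),
    c("honeydew", "hmf", 6.34, 12.66, 0, 63.41),
    c("honeydew", "mc", 16.36, 2.10, 13.40, 26.00),
    c("honeydew", "acid", 30.17, 8.07, 6.00, 46.00),
    c("honeydew", "dia", 12.80, 3.14, 8.40, 19.80),
    c("honeydew", "ins", 0.01, 0.004, 0, 0.01),
    c("honeydew", "econd", 1.14, 0.27, 0.82, 1.80),
    c("linden", "glu", 29.20, 3.91, 17.18, 35.74),
    c("linden", "fru", 35.39, 5.82, 21.80, 44.80),
    c("linden", "suc", 0.64, 1.08, 0, 5.60),
    c("linden", "hmf", 5.41, 6.37, 0, 21.80),
    c("linden", "mc", 16.61, 1.10, 14.20, 19.80),
    c("linden", "acid", 16.33, 6.90, 5.50, 34.72),
    c("linden", "dia", 12.90, 2.36, 8.40, 19.07),
    c("linden", "ins", 0.01, 0.004, 0, 0.01),
    c("linden", "econd", 0.48, 0.19, 0.04, 0.78),
    c("monofloral", "glu", 31.67, 7.53, 13.44, 36.10),
    c("monofloral", "fru", 35.41, 5.17, 26.66, 42.09),
    c("monofloral", "suc", 0.35, 0.10, 0.05, 0.49),
    c("monofloral", "hmf", 11.84, 19.74, 0, 59.20),
    c("monofloral", "mc", 17.20, 2.04, 15.40, 22.00),
    c("monofloral", "acid", 15.08, 8.16, 7.50, 30.00),
    c("monofloral", "dia", 11.90, 2.87, 9.70, 18.18),
    c("monofloral", "ins", 0.01, 0.004, 0.005, 0.02),
    c("monofloral", "econd", 0.25, 0.16, 0.12, 0.52),
    c("polyfloral", "glu", 31.39, 4.60, 15.72, 44.80),
    c("polyfloral", "fru", 38.68, 5.20, 18.94, 53.64),
    c("polyfloral", "suc", 0.63, 1.41, 0, 16.34),
    c("polyfloral", "hmf", 8.31, 12.36, 0, 93.50),
    c("polyfloral", "mc", 16.45, 1.13, 13.00, 19.90),
    c("polyfloral", "acid", 21.04, 9.33, 4.00, 61.26),
    c("polyfloral", "dia", 12.90, 3.43, 0.50, 32.54),
    c("polyfloral", "ins", 0.01, 0.01, 0, 0.10),
    c("polyfloral", "econd", 0.40, 0.15, 0.03, 0.79),
    c("sunflower", "glu", 34.57, 3.98, 24.10, 40.42),
    c("sunflower", "fru", 37.83, 3.26, 30.61, 45.34),
    c("sunflower", "suc", 0.34, 0.23, 0, 1.03),
    c("sunflower", "hmf", 4.85, 8.34, 0, 40.80),
    c("sunflower", "mc", 17.51, 1.37, 14.90, 19.90),
    c("sunflower", "acid", 23.00, 7.22, 8.61, 37.50),
    c("sunflower", "dia", 13.45, 2.50, 9.60, 17.42),
    c("sunflower", "ins", 0.01, 0.01, 0, 0.04),
    c("sunflower", "econd", 0.39, 0.09, 0.15, 0.54)
  )
  tibble::tibble(
    type = vapply(rows, `[`, character(1), 1L),
    parameter = vapply(rows, `[`, character(1), 2L),
    mean = as.numeric(vapply(rows, `[`, character(1), 3L)),
    sd = as.numeric(vapply(rows, `[`, character(1), 4L)),
    min = as.numeric(vapply(rows, `[`, character(1), 5L)),
    max = as.numeric(vapply(rows, `[`, character(1), 6L))
  )
}

#' Pooled correlation targets between the nine parameters
#'
#' Published Pearson correlations among the physicochemical parameters of
#' 609 honey samples; the synthetic generator imposes this dependence via a
#' Gaussian copula (after nearest-positive-definite repair if needed).
#'
#' @return A symmetric 9 x 9 matrix with unit diagonal, dimnames in the
#'   canonical parameter order.
#' @export
correlation_targets <- function() {
  p <- measurement_cols()
  R <- diag(9)
  dimnames(R) <- list(p, p)
  set <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set("glu", "fru", 0.237); set("glu", "suc", -0.129); set("glu", "hmf", 0.096)
  set("glu", "mc", 0.046); set("glu", "acid", 0.189); set("glu", "dia", 0.004)
  set("glu", "ins", -0.007); set("glu", "econd", 0.144)
  set("fru", "suc", -0.057); set("fru", "hmf", -0.087); set("fru", "mc", -0.081)
  set("fru", "acid", -0.076); set("fru", "dia", -0.047); set("fru", "ins", 0.074)
  set("fru", "econd", -0.105)
  set("suc", "hmf", 0.001); set("suc", "mc", -0.044); set("suc", "acid", -0.150)
  set("suc", "dia", -0.023); set("suc", "ins", -0.066); set("suc", "econd", -0.144)
  set("hmf", "mc", -0.085); set("hmf", "acid", 0.107); set("hmf", "dia", -0.129)
  set("hmf", "ins", -0.032); set("hmf", "econd", 0.011)
  set("mc", "acid", 0.147); set("mc", "dia", 0.027); set("mc", "ins", 0.017)
  set("mc", "econd", 0.061)
  set("acid", "dia", 0.034); set("acid", "ins", 0.028); set("acid", "econd", 0.570)
  set("dia", "ins", -0.034); set("dia", "econd", 0.022)
  set("ins", "econd", -0.023)
  R
}

#' Study design sample counts
#'
#' Final per-type, per-year and per-region sample counts of the 609-sample
#' survey the generator emulates.
#'
#' @return Named integer vectors.
#' @export
study_type_counts <- function() {
  c(acacia = 213L, honeydew = 29L, linden = 34L, monofloral = 8L,
    polyfloral = 302L, sunflower = 23L)
}

#' @rdname study_type_counts
#' @export
study_year_counts <- function() {
  c("2018" = 209L, "2019" = 80L, "2020" = 78L, "2021" = 108L,
    "2022" = 113L, "2023" = 21L)
}

#' @rdname study_type_counts
#' @export
study_region_counts <- function() {
  c(Western = 114L, Belgrade = 205L, Northern = 149L, Central = 29L,
    Eastern = 92L, Southern = 20L)
}
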