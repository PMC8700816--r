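#' Bundled three-oil nanoemulsion mixture experiment
#'
#' A published 17-run I-optimal mixture experiment on the lipid phase of an
#' oil-in-water nanoemulsion: fractions of cumin (EO_CU), carvi (EO_CA) and
#' coriander (EO_CO) essential oils, with four measured responses per run
#' (means of triplicate measurements):
#' \itemize{
#'   \item `d32_um` — Sauter mean droplet diameter, um;
#'   \item `ic50_mgml` — DPPH radical-scavenging IC50, mg/mL;
#'   \item `bsubtilis_cfu` — surviving B. subtilis colony count, CFU/mL;
#'   \item `ecoli_cfu` — surviving E. coli colony count, CFU/mL.
#' }
#' The design replicates the centroid four times and two binary blends twice
#' each, giving 5 pure-error degrees of freedom. The blend reported as
#' optimal in the source study (19.07\% / 60.09\% / 20.84\%) is included for
#' reference. Reported measurement SDs are stored as printed (`sd_` columns)
#' but enter no computation here.
#'
#' @return a list with elements `design` (a [mixture_design()]),
#'   `responses` (data frame, one row per run), and `optimal_blend`
#'   (named fractions).
#' @export
nanoemulsion_runs <- function() {
  comp <- matrix(c(
    0.333333, 0.333333, 0.333333,
    0,        0.5,      0.5,
    0.166667, 0.666667, 0.166667,
    0.5,      0,        0.5,
    0.5,      0,        0.5,
    0,        0,        1,
    0,        0.5,      0.5,
    0.333333, 0.333333, 0.333333,
    1,        0,        0,
    0.166667, 0.166667, 0.666667,
    0.666667, 0.333333, 0,
    0.333333, 0.333333, 0.333333,
    0,        1,        0,
    0.666667, 0,        0.333333,
    0.333333, 0.666667, 0,
    0.5,      0.5,      0,
    0.333333, 0.333333, 0.333333), ncol = 3, byrow = TRUE)
  design <- mixture_design(comp, names = c("EO_CU", "EO_CA", "EO_CO"))
  responses <- data.frame(
    run = 1:17,
    d32_um = c(1.37, 1.55, 0.505, 2.599, 2.597, 4.67, 1.55, 1.1, 2.1,
               3.31, 1.8, 1.38, 1.67, 2, 0.523, 1.3, 1.36),
    sd_d32 = c(0.0616, 0.0408, 0.12, 0.0804, 0.005, 0.037, 0.024, 0.155,
               0.147, 0.123, 0.0816, 0.014, 0.035, 0.049, 0.012, 0.041,
               0.014),
    pdi = c(0.61, 0.63, 0.15, 0.56, 0.58, 0.97, 0.51, 0.57, 0.55, 0.84,
            0.444, 0.441, 0.60, 0.79, 0.23, 0.53, 0.52),
    ic50_mgml = c(8.99, 9.126, 7, 11.578, 11.578, 15.789, 9.15, 8.5,
                  10.59, 13.56, 9.986, 8.9, 9.865, 10.056, 7.3, 8.76,
                  8.99),
    sd_ic50 = c(0.281, 0.020, 0.417, 0.011, 0.223, 0.125, 0.086, 0.072,
                0.184, 0.283, 0.119, 0.377, 0.093, 0.110, 0.035, 0.248,
                0.265),
    bsubtilis_cfu = 1e5 * c(2.366, 1.732, 1.105, 10.333, 9.666, 24.333,
                            0.577, 1.154, 6.060, 6.666, 1.666, 2.082,
                            1.732, 2.645, 0.333, 2.081, 1.154),
    sd_bsubtilis = c(214, 105, 95, 133, 283, 972, 246, 548, 865, 147,
                     617, 658, 223, 542, 690, 630, 158),
    ecoli_cfu = 1e6 * c(4.85, 3.05, 0.4, 30.12, 40.19, 60.24, 2.745, 8.8,
                        29.3, 24.35, 15.7, 12.766, 12.933, 23.066, 0.51,
                        13.666, 9.166),
    sd_ecoli = c(110, 468, 432, 502, 166, 1031, 333, 301, 1146, 194, 386,
                 45, 227, 11, 180, 20, 27))
  list(design = design, responses = responses,
       optimal_blend = c(EO_CU = 0.1907, EO_CA = 0.6009, EO_CO = 0.2084))
}

#' Default model specifications for the bundled nanoemulsion study
#'
#' Term sets and response transforms under which the bundled data were
#' modeled: reduced-cubic Scheffe polynomials on the square-root scale for
#' droplet size and IC50 (the scale on which replicate variance is stable
#' and the published coefficient magnitudes are reproduced), a reduced
#' cubic on the raw scale for the B. subtilis count, and a quadratic on the
#' raw scale for the E. coli count.
#'
#' @return named list, one element per response, each with `terms` and
#'   `transform`.
#' @export
nanoemulsion_models <- function() {
  list(
    d32_um = list(
      terms = c("A", "B", "C", "AB", "AC", "BC", "AB(A-B)", "AC(A-C)",
                "BC(B-C)"),
      transform = "sqrt"),
    ic50_mgml = list(
      terms = c("A", "B", "C", "AB", "AC", "BC", "AB(A-B)", "AC(A-C)",
                "BC(B-C)"),
      transform = "sqrt"),
    bsubtilis_cfu = list(
      terms = c("A", "B", "C", "AB", "AC", "BC", "AC(A-C)", "BC(B-C)"),
      transform = "identity"),
    ecoli_cfu = list(
      terms = c("A", "B", "C", "AB", "AC", "BC"),
      transform = "identity"))
}

#' Fit the default models to the bundled study
#'
#' Convenience wrapper: fits every model of [nanoemulsion_models()] to the
#' bundled 17-run data.
#'
#' @return named list of [scheffe_fit()] objects.
#' @export
nanoemulsion_fits <- function() {
  fx <- nanoemulsion_runs()
  specs <- nanoemulsion_models()
  lapply(stats::setNames(names(specs), names(specs)), function(nm)
    scheffe_fit(fx$design, fx$responses[[nm]], specs[[nm]]$terms,
                specs[[nm]]$transform))
}
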