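#' Sauter mean diameter (d3.2)
#'
#' Surface-weighted mean droplet diameter of a size distribution:
#' d3.2 = sum(n_i d_i^3) / sum(n_i d_i^2). Homogeneous of degree 1 in the
#' diameters and bounded by their range.
#'
#' @param d droplet diameters (any length unit, > 0).
#' @param n droplet counts (>= 0, at least one positive).
#' @return the Sauter mean diameter in the units of `d`.
#' @export
sauter_mean <- function(d, n) {
  if (length(d) != length(n)) stop("d and n must have equal length")
  if (any(d <= 0)) stop("all diameters must be positive")
  if (any(n < 0) || !any(n > 0)) stop("counts must be non-negative with at least one positive")
  denom <- sum(n * d^2)
  if (denom == 0) stop("zero denominator in Sauter mean")
  sum(n * d^3) / denom
}

#' DPPH radical-scavenging inhibition percentage
#'
#' I(\%) = 100 (A_blank - A_sample) / A_blank, from blank and sample
#' absorbances of the DPPH assay.
#'
#' @param A_blank blank (control) absorbance, > 0.
#' @param A_sample sample absorbance.
#' @return inhibition percentage.
#' @export
dpph_inhibition <- function(A_blank, A_sample) {
  if (any(A_blank <= 0)) stop("A_blank must be positive")
  100 * (A_blank - A_sample) / A_blank
}

#' IC50 by log-linear interpolation of a dose-response series
#'
#' Interpolates inhibition versus log10(concentration) between the pair of
#' adjacent observations bracketing 50\% inhibition. Serial-dilution assays
#' are geometric in concentration, hence the log scale.
#'
#' @param conc concentrations (mg/mL), strictly increasing.
#' @param inhibition inhibition percentages aligned with `conc`.
#' @return the interpolated IC50 (mg/mL).
#' @export
ic50 <- function(conc, inhibition) {
  if (length(conc) != length(inhibition) || length(conc) < 2)
    stop("need at least two aligned (concentration, inhibition) points")
  if (any(diff(conc) <= 0)) stop("concentrations must be strictly increasing")
  if (any(conc <= 0)) stop("concentrations must be positive")
  hit <- which(abs(inhibition - 50) < 1e-12)
  if (length(hit)) return(conc[hit[1]])
  br <- which((inhibition[-length(inhibition)] - 50) *
              (inhibition[-1] - 50) < 0)
  if (!length(br))
    stop("50% inhibition is not bracketed by the observed dose-response points")
  i <- br[1]
  lx <- log10(conc[c(i, i + 1)])
  y <- inhibition[c(i, i + 1)]
  10^(lx[1] + (50 - y[1]) * diff(lx) / diff(y))
}

#' Droplet growth ratio during storage
#'
#' R = (d_n - d_0) / d_0, the relative change of the Sauter diameter between
#' day 0 and day n.
#'
#' @param d_n diameter at day n.
#' @param d_0 diameter at day 0 (> 0).
#' @return dimensionless growth ratio.
#' @export
droplet_growth_ratio <- function(d_n, d_0) {
  if (any(d_0 <= 0)) stop("d_0 must be positive")
  (d_n - d_0) / d_0
}

#' Fractional inhibitory concentration index (FICI)
#'
#' Checkerboard synergy index for a two-agent combination:
#' FICI = MIC_A(combo)/MIC_A(alone) + MIC_B(combo)/MIC_B(alone).
#' Default interpretation follows the conventional breakpoints
#' (<= 0.5 synergy; > 0.5 to 1 additive; > 1 to 4 indifferent;
#' > 4 antagonism); the breakpoints are configurable since reporting
#' conventions differ between laboratories.
#'
#' @param mic_a_alone,mic_b_alone MICs of each agent alone (> 0).
#' @param mic_a_combo,mic_b_combo MICs of each agent in combination (> 0).
#' @param breakpoints numeric vector `c(synergy, additive, indifferent)`:
#'   upper FICI limits of the first three categories.
#' @return list with `fici` (numeric) and `category` (character).
#' @export
fici <- function(mic_a_alone, mic_b_alone, mic_a_combo, mic_b_combo,
                 breakpoints = c(synergy = 0.5, additive = 1,
                                 indifferent = 4)) {
  vals <- c(mic_a_alone, mic_b_alone, mic_a_combo, mic_b_combo)
  if (any(vals <= 0)) stop("all MIC values must be positive")
  if (length(breakpoints) != 3 || any(diff(breakpoints) <= 0))
    stop("breakpoints must be three increasing upper limits")
  v <- mic_a_combo / mic_a_alone + mic_b_combo / mic_b_alone
  category <- if (v <= breakpoints[1]) "synergy"
    else if (v <= breakpoints[2]) "additive"
    else if (v <= breakpoints[3]) "indifferent"
    else "antagonism"
  list(fici = v, category = category)
}
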