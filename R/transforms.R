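#' Response transforms
#'
#' Scheffe mixture fits are often performed on a transformed response
#' (variance stabilization); coefficients and the ANOVA then live on the
#' transformed scale while predictions are reported in original units via
#' the inverse map. Supported transforms: `identity`, `sqrt`, `ln`,
#' `inverse`, `inverse_sqrt`, and `power` (y^lambda, lambda != 0).
#'
#' @param name transform name.
#' @param lambda exponent, used only by `"power"`.
#' @return an object of class `"response_transform"` with elements `name`,
#'   `forward`, `inverse`, and `domain_ok` (predicate for valid inputs).
#' @export
response_transform <- function(name = c("identity", "sqrt", "ln", "inverse",
                                        "inverse_sqrt", "power"),
                               lambda = NULL) {
  name <- match.arg(name)
  tf <- switch(name,
    identity = list(forward = identity, inverse = identity,
                    domain_ok = function(y) is.finite(y)),
    sqrt = list(forward = sqrt, inverse = function(z) z^2,
                domain_ok = function(y) is.finite(y) & y >= 0),
    ln = list(forward = log, inverse = exp,
              domain_ok = function(y) is.finite(y) & y > 0),
    inverse = list(forward = function(y) 1 / y, inverse = function(z) 1 / z,
                   domain_ok = function(y) is.finite(y) & y > 0),
    inverse_sqrt = list(forward = function(y) 1 / sqrt(y),
                        inverse = function(z) 1 / z^2,
                        domain_ok = function(y) is.finite(y) & y > 0),
    power = {
      if (is.null(lambda) || lambda == 0)
        stop("power transform needs a non-zero lambda")
      force(lambda)
      list(forward = function(y) y^lambda,
           inverse = function(z) z^(1 / lambda),
           domain_ok = function(y) is.finite(y) & y > 0)
    })
  structure(c(tf, list(name = name, lambda = lambda)),
            class = "response_transform")
}

as_transform <- function(x) {
  if (inherits(x, "response_transform")) return(x)
  if (is.character(x) && length(x) == 1) return(response_transform(x))
  stop("cannot interpret response transform")
}
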