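#' Fit a Scheffe mixture polynomial by least squares
#'
#' The response is optionally transformed (see [response_transform()]);
#' coefficients, residual statistics and the ANOVA all refer to the
#' transformed scale. Fit statistics follow the response-surface software
#' conventions: SD = sqrt(MSE), R^2, adjusted R^2, predicted R^2 computed
#' from the PRESS statistic (leave-one-out via the hat matrix,
#' PRESS = sum (e_r / (1 - h_rr))^2), and CV% = 100 * SD / mean(transformed
#' response).
#'
#' @param design a [mixture_design()].
#' @param response numeric vector of per-run response values (original
#'   units), aligned with the design runs.
#' @param terms character vector of Scheffe term strings; must include all
#'   q linear terms (mixture models carry no intercept).
#' @param transform a transform name or [response_transform()] object.
#' @return an object of class `"scheffe_fit"`.
#' @export
scheffe_fit <- function(design, response, terms, transform = "identity") {
  stopifnot(inherits(design, "mixture_design"))
  q <- ncol(design$blends)
  response <- as.numeric(response)
  if (length(response) != nrow(design$blends))
    stop("response length must match the number of runs")
  tl <- parse_terms(terms, q)
  lin <- vapply(tl, function(t) t$kind == "linear", logical(1))
  if (sum(lin) != q)
    stop("all ", q, " linear terms must be present (no-intercept model)")
  tf <- as_transform(transform)
  bad <- which(!tf$domain_ok(response))
  if (length(bad))
    stop(sprintf("response value at run %s invalid under '%s' transform",
                 paste(design$run_ids[bad], collapse = ", "), tf$name))
  z <- tf$forward(response)

  X <- term_expand(design$blends, tl)
  if (nrow(X) < ncol(X))
    stop("fewer runs than model terms")
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-10)
    stop("model matrix is rank-deficient (reciprocal condition number < 1e-10)")
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, z)
  fitted_z <- drop(X %*% beta)
  e <- z - fitted_z
  h <- rowSums(qr.Q(qr_x)[, seq_len(ncol(X)), drop = FALSE]^2)

  n <- length(z)
  p <- ncol(X)
  zbar <- mean(z)
  ss_tot <- sum((z - zbar)^2)
  ss_res <- sum(e^2)
  press <- sum((e / (1 - h))^2)
  mse <- ss_res / (n - p)
  r2 <- 1 - ss_res / ss_tot
  structure(list(
    design = design, terms = terms, term_list = tl, transform = tf,
    response = response, z = z, X = X,
    coefficients = stats::setNames(beta, colnames(X)),
    fitted_z = fitted_z, residuals = e, leverage = h,
    n = n, p = p,
    ss_total = ss_tot, ss_residual = ss_res, press = press,
    sd = sqrt(mse), mse = mse,
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - p),
    r2_pred = 1 - press / ss_tot,
    cv_pct = 100 * sqrt(mse) / zbar),
    class = "scheffe_fit")
}

#' @export
print.scheffe_fit <- function(x, digits = 5, ...) {
  cat(sprintf("Scheffe mixture fit (%d runs, %d terms, transform: %s)\n",
              x$n, x$p, x$transform$name))
  cat("Coefficients (transformed scale):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("SD = %.4g  R2 = %.2f%%  R2adj = %.2f%%  R2pred = %.2f%%  CV = %.2f%%\n",
              x$sd, 100 * x$r2, 100 * x$r2_adj, 100 * x$r2_pred, x$cv_pct))
  invisible(x)
}

#' Predict from a Scheffe fit in original response units
#'
#' Evaluates the fitted polynomial at new blends on the transformed scale,
#' then applies the inverse transform. For the `sqrt` transform a negative
#' polynomial value has no pre-image; it is clamped to zero and the result
#' carries a `"clamped"` attribute naming the affected rows.
#'
#' @param object a [scheffe_fit()].
#' @param newdata a blend, matrix of blends, or `mixture_design`; default
#'   the fitted design.
#' @param ... unused.
#' @return numeric vector of predictions in original units.
#' @export
predict.scheffe_fit <- function(object, newdata = NULL, ...) {
  q <- ncol(object$design$blends)
  m <- if (is.null(newdata)) object$design$blends
       else if (inherits(newdata, "mixture_design")) newdata$blends
       else if (inherits(newdata, "blend")) matrix(unclass(newdata), nrow = 1)
       else if (is.null(dim(newdata)) && length(newdata) == q)
         matrix(as.numeric(newdata), nrow = 1)
       else as.matrix(newdata)
  zhat <- drop(term_expand(m, object$term_list) %*% object$coefficients)
  tf <- object$transform
  clamped <- integer(0)
  if (tf$name == "sqrt") {
    clamped <- which(zhat < 0)
    if (length(clamped)) {
      warning("negative sqrt-scale prediction clamped to 0 at row(s) ",
              paste(clamped, collapse = ", "))
      zhat[clamped] <- 0
    }
  }
  out <- tf$inverse(zhat)
  if (length(clamped)) attr(out, "clamped") <- clamped
  out
}
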