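#' Mixture ANOVA with lack-of-fit / pure-error split
#'
#' Builds the ANOVA table in the layout used by response-surface software
#' for mixture models:
#' \itemize{
#'   \item the "Linear Mixture" row carries the Type I (sequential) sum of
#'     squares of the q linear terms after the mean, on q - 1 df;
#'   \item each non-linear term carries its partial (drop-one) SS from the
#'     full model, on 1 df;
#'   \item the residual is split into Lack of Fit and Pure Error, with
#'     Pure Error SS the within-replicate-group squared deviations of the
#'     transformed response;
#'   \item model and term F statistics are tested against the residual mean
#'     square; the Lack-of-Fit F against the pure-error mean square.
#' }
#' With no replicated runs (zero pure-error df) the split is omitted and the
#' returned table carries attribute `lof_omitted = TRUE`.
#'
#' @param fit a [scheffe_fit()].
#' @return a data frame of class `"mixture_anova"` with columns
#'   `source`, `ss`, `df`, `ms`, `F`, `p`.
#' @export
mixture_anova <- function(fit) {
  stopifnot(inherits(fit, "scheffe_fit"))
  design <- fit$design
  z <- fit$z
  n <- fit$n
  p <- fit$p
  q <- ncol(design$blends)

  ss_tot <- fit$ss_total
  ss_res <- fit$ss_residual
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1
  df_res <- n - p
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  perfect <- ss_res <= 1e-12 * max(ss_tot, 1)

  f_of <- function(ms) {
    if (is.na(ms_res)) return(NA_real_)
    if (perfect || ms_res == 0) return(Inf)
    ms / ms_res
  }
  p_of <- function(f, df1, df2) {
    if (!is.finite(f)) return(if (is.na(f)) NA_real_ else 0)
    stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  # Type I SS of the linear mixture terms after the mean
  lin_terms <- fit$terms[vapply(fit$term_list, function(t)
    t$kind == "linear", logical(1))]
  X_lin <- term_expand(design$blends, parse_terms(lin_terms, q))
  e_lin <- stats::lm.fit(X_lin, z)$residuals
  ss_lin <- ss_tot - sum(e_lin^2)
  df_lin <- q - 1

  # partial (drop-one) SS for each non-linear term
  nl <- fit$terms[vapply(fit$term_list, function(t)
    t$kind != "linear", logical(1))]
  rows <- list(
    list("Model", ss_mod, df_mod, ss_mod / df_mod,
         f_of(ss_mod / df_mod), p_of(f_of(ss_mod / df_mod), df_mod, df_res)),
    list("Linear Mixture", ss_lin, df_lin, ss_lin / df_lin,
         f_of(ss_lin / df_lin), p_of(f_of(ss_lin / df_lin), df_lin, df_res)))
  for (t in nl) {
    sub <- setdiff(fit$terms, t)
    e_sub <- stats::lm.fit(term_expand(design$blends, parse_terms(sub, q)),
                           z)$residuals
    ss_t <- sum(e_sub^2) - ss_res
    rows[[length(rows) + 1]] <-
      list(t, ss_t, 1, ss_t, f_of(ss_t), p_of(f_of(ss_t), 1, df_res))
  }
  rows[[length(rows) + 1]] <-
    list("Residual", ss_res, df_res, ms_res, NA_real_, NA_real_)

  # pure error from replicate groups, on the transformed scale
  df_pe <- pure_error_df(design)
  lof_omitted <- df_pe == 0
  if (!lof_omitted) {
    ss_pe <- sum(unlist(tapply(z, design$replicate_groups,
                               function(v) (v - mean(v))^2)))
    df_lof <- df_res - df_pe
    ss_lof <- ss_res - ss_pe
    ms_pe <- ss_pe / df_pe
    f_lof <- if (df_lof > 0) {
      if (ms_pe == 0) Inf else (ss_lof / df_lof) / ms_pe
    } else NA_real_
    rows[[length(rows) + 1]] <- list("Lack of Fit", ss_lof, df_lof,
      if (df_lof > 0) ss_lof / df_lof else NA_real_,
      f_lof, p_of(f_lof, df_lof, df_pe))
    rows[[length(rows) + 1]] <-
      list("Pure Error", ss_pe, df_pe, ms_pe, NA_real_, NA_real_)
  }
  rows[[length(rows) + 1]] <-
    list("Cor Total", ss_tot, n - 1, NA_real_, NA_real_, NA_real_)

  out <- data.frame(
    source = vapply(rows, function(r) r[[1]], ""),
    ss = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    df = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    ms = vapply(rows, function(r) as.numeric(r[[4]]), 0),
    F = vapply(rows, function(r) as.numeric(r[[5]]), 0),
    p = vapply(rows, function(r) as.numeric(r[[6]]), 0),
    stringsAsFactors = FALSE)
  class(out) <- c("mixture_anova", "data.frame")
  attr(out, "lof_omitted") <- lof_omitted
  attr(out, "transform") <- fit$transform$name
  out
}

#' @export
print.mixture_anova <- function(x, ...) {
  cat(sprintf("Mixture ANOVA (transformed scale: %s)\n", attr(x, "transform")))
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 5)
  df$ms <- signif(df$ms, 5)
  df$F <- signif(df$F, 5)
  df$p <- signif(df$p, 4)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "lof_omitted")))
    cat("Note: no replicated runs; lack-of-fit / pure-error split omitted.\n")
  invisible(x)
}

#' Backward elimination of non-significant non-linear terms
#'
#' Repeatedly refits the model, dropping the non-linear term with the
#' largest partial-F p-value exceeding `alpha`, until every remaining
#' non-linear term is significant at `alpha`. Linear mixture terms are never
#' dropped.
#'
#' @param design a [mixture_design()].
#' @param response per-run response values (original units).
#' @param full_terms starting term vector.
#' @param transform response transform.
#' @param alpha significance threshold in (0, 1).
#' @return the final [scheffe_fit()]; the dropped terms (in drop order) are
#'   available as `attr(, "dropped")`.
#' @export
reduce_model <- function(design, response, full_terms, transform = "identity",
                         alpha = 0.05) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  terms <- full_terms
  dropped <- character(0)
  repeat {
    fit <- scheffe_fit(design, response, terms, transform)
    an <- mixture_anova(fit)
    nl <- an[!(an$source %in% c("Model", "Linear Mixture", "Residual",
                                "Lack of Fit", "Pure Error", "Cor Total")), ]
    if (nrow(nl) == 0) break
    worst <- nl[which.max(nl$p), ]
    if (is.na(worst$p) || worst$p <= alpha) break
    terms <- setdiff(terms, worst$source)
    dropped <- c(dropped, worst$source)
  }
  attr(fit, "dropped") <- dropped
  fit
}
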