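#' Construct a blend (a point on the composition simplex)
#'
#' A blend is a vector of q component proportions, each in \[0, 1\], summing
#' to 1. Input sums may deviate from 1 by up to `tol` (printed design tables
#' are typically rounded, e.g. 0.333333 + 0.333333 + 0.333333); the fractions
#' are renormalized to sum to exactly 1.
#'
#' @param fractions numeric vector of component proportions.
#' @param tol maximum allowed deviation of `sum(fractions)` from 1.
#' @return numeric vector of class `"blend"` summing to exactly 1.
#' @export
blend <- function(fractions, tol = 1e-5) {
  fractions <- as.numeric(fractions)
  if (length(fractions) < 2)
    stop("a blend needs at least 2 components")
  if (any(!is.finite(fractions)) || any(fractions < -1e-12))
    stop("blend fractions must be finite and non-negative")
  s <- sum(fractions)
  if (abs(s - 1) > tol)
    stop(sprintf("blend fractions sum to %.6f, outside 1 +/- %g", s, tol))
  out <- pmax(fractions, 0) / sum(pmax(fractions, 0))
  class(out) <- "blend"
  out
}

#' Construct a mixture design
#'
#' An ordered set of runs (blends), with replicate groups identified by
#' composition equality at tolerance 1e-6 after renormalization. The
#' replicate structure drives the pure-error degrees of freedom of the
#' mixture ANOVA: df_PE = sum over groups of (group size - 1).
#'
#' @param blends a numeric matrix (runs x components), data frame, or list
#'   of blends; rows are renormalized via [blend()].
#' @param run_ids optional run labels (default `1:n`).
#' @param names optional component names (default `"x1"..."xq"`, or the
#'   column names of `blends`).
#' @param tol row-sum tolerance passed to [blend()].
#' @return an object of class `"mixture_design"`: a list with elements
#'   `blends` (n x q matrix, rows summing to 1), `run_ids`,
#'   `replicate_groups` (integer vector assigning each run to a group of
#'   identical compositions), and `names`.
#' @export
mixture_design <- function(blends, run_ids = NULL, names = NULL, tol = 1e-5) {
  if (is.data.frame(blends)) blends <- as.matrix(blends)
  if (is.list(blends) && !is.matrix(blends))
    blends <- do.call(rbind, lapply(blends, as.numeric))
  blends <- as.matrix(blends)
  storage.mode(blends) <- "double"
  if (is.null(names))
    names <- colnames(blends)
  if (is.null(names))
    names <- paste0("x", seq_len(ncol(blends)))
  m <- t(apply(blends, 1, function(r) unclass(blend(r, tol = tol))))
  colnames(m) <- names
  n <- nrow(m)
  if (is.null(run_ids)) run_ids <- seq_len(n)
  if (length(run_ids) != n) stop("run_ids length must match number of runs")
  structure(
    list(blends = m, run_ids = run_ids,
         replicate_groups = replicate_groups(m), names = names),
    class = "mixture_design")
}

# Group runs by composition equality at tolerance `tol` (after
# renormalization). Returns an integer group index per run.
replicate_groups <- function(m, tol = 1e-6) {
  n <- nrow(m)
  grp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (grp[i] > 0L) next
    next_id <- next_id + 1L
    grp[i] <- next_id
    if (i < n) for (j in (i + 1L):n) {
      if (grp[j] == 0L && max(abs(m[i, ] - m[j, ])) <= tol)
        grp[j] <- next_id
    }
  }
  grp
}

#' Pure-error degrees of freedom of a design
#'
#' @param design a [mixture_design()].
#' @return integer: n runs minus number of distinct compositions.
#' @export
pure_error_df <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  nrow(design$blends) - length(unique(design$replicate_groups))
}

#' @export
print.mixture_design <- function(x, ...) {
  n <- nrow(x$blends)
  cat(sprintf("Mixture design: %d runs, %d components (%s)\n",
              n, ncol(x$blends), paste(x$names, collapse = ", ")))
  cat(sprintf("Distinct blends: %d; pure-error df: %d\n",
              length(unique(x$replicate_groups)), pure_error_df(x)))
  df <- as.data.frame(round(x$blends, 6))
  df <- cbind(run = x$run_ids, df, rep_group = x$replicate_groups)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
as.data.frame.mixture_design <- function(x, ...) {
  df <- as.data.frame(x$blends)
  cbind(run = x$run_ids, df)
}
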