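#' Derringer-Suich desirability goals
#'
#' A goal maps a predicted response (original units) to a desirability in
#' \[0, 1\]. For `minimize`, d = 1 at or below the target `T` (default the
#' lower bound `L`), 0 at or above `U`, and `((U - y)/(U - T))^w` between;
#' `maximize` mirrors this; `target` ramps up to `T` and back down to `U`;
#' `in_range` is the 0/1 indicator of \[L, U\].
#'
#' @param direction one of `"minimize"`, `"maximize"`, `"target"`,
#'   `"in_range"`.
#' @param L,T,U lower bound, target, upper bound (response units), with
#'   L <= T <= U.
#' @param weight exponent of the ramp (> 0).
#' @param importance relative importance r >= 1 in the geometric mean.
#' @return object of class `"desirability_goal"`.
#' @export
desirability_goal <- function(direction = c("minimize", "maximize", "target",
                                            "in_range"),
                              L = NULL, T = NULL, U = NULL,
                              weight = 1, importance = 1) {
  direction <- match.arg(direction)
  if (direction == "target" && is.null(T))
    stop("target goal needs T")
  if (is.null(T))
    T <- switch(direction, minimize = L, maximize = U, target = NULL,
                in_range = NULL)
  if (direction == "minimize" && is.null(L)) L <- T
  if (direction == "maximize" && is.null(U)) U <- T
  if (!is.null(L) && !is.null(T) && !is.null(U) && !(L <= T && T <= U))
    stop("goal bounds must satisfy L <= T <= U")
  if (weight <= 0) stop("weight must be positive")
  if (importance < 1) stop("importance must be >= 1")
  structure(list(direction = direction, L = L, T = T, U = U,
                 weight = weight, importance = importance),
            class = "desirability_goal")
}

#' Individual desirability of a predicted response
#'
#' @param yhat predicted response value(s), original units.
#' @param goal a [desirability_goal()].
#' @return desirability value(s) in \[0, 1\].
#' @export
desirability_value <- function(yhat, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  need <- switch(goal$direction, minimize = c("T", "U"),
                 maximize = c("L", "T"), target = c("L", "T", "U"),
                 in_range = c("L", "U"))
  if (any(vapply(goal[need], is.null, logical(1))))
    stop("goal bounds not set; supply L/T/U or complete them from data ",
         "(see optimize_desirability)")
  w <- goal$weight
  d <- switch(goal$direction,
    minimize = {
      if (goal$U == goal$T)
        stop("degenerate goal: U == T leaves the minimize ramp undefined")
      ((goal$U - yhat) / (goal$U - goal$T))^w
    },
    maximize = {
      if (goal$T == goal$L)
        stop("degenerate goal: T == L leaves the maximize ramp undefined")
      ((yhat - goal$L) / (goal$T - goal$L))^w
    },
    target = {
      lo <- ifelse(yhat <= goal$T,
                   (yhat - goal$L) / (goal$T - goal$L),
                   (goal$U - yhat) / (goal$U - goal$T))
      lo^w
    },
    in_range = as.numeric(yhat >= goal$L & yhat <= goal$U))
  d[!is.finite(d)] <- 0
  pmin(1, pmax(0, d))
}

#' Overall desirability
#'
#' Weighted geometric mean D = (prod d_i^{r_i})^{1 / sum r_i}. D is zero
#' whenever any individual desirability is zero (the veto property) and
#' never exceeds the largest d_i.
#'
#' @param ds numeric vector (or matrix, columns = responses) of individual
#'   desirabilities in \[0, 1\].
#' @param importances vector of importances r_i >= 1 (default all 1).
#' @return overall desirability value(s).
#' @export
overall_desirability <- function(ds, importances = NULL) {
  if (is.matrix(ds)) {
    k <- ncol(ds)
    if (is.null(importances)) importances <- rep(1, k)
    exp(drop(log(pmax(ds, 0)) %*% importances) / sum(importances))
  } else {
    if (is.null(importances)) importances <- rep(1, length(ds))
    exp(sum(importances * log(pmax(ds, 0))) / sum(importances))
  }
}

#' Multi-response desirability optimization over the simplex
#'
#' Exhaustive evaluation of overall desirability on a barycentric grid of
#' the composition simplex, followed by a derivative-free polish (Nelder-Mead
#' in the q - 1 free coordinates with projection onto the simplex) from the
#' ten best grid points. Deterministic given `seed`.
#'
#' @param fits named list of [scheffe_fit()] objects (one per response),
#'   sharing the same component basis.
#' @param goals named list of [desirability_goal()]s, names matching `fits`.
#'   Goals without explicit bounds are completed with the observed response
#'   minimum/maximum from the fit's data.
#' @param grid_step barycentric grid step (default 0.005, i.e. 0.5%
#'   compositional resolution).
#' @param seed integer seed recorded in the result (the polish itself is
#'   deterministic).
#' @param polish logical; run the Nelder-Mead refinement (default TRUE).
#' @return object of class `"desirability_optimum"`: list with `blend`
#'   (named fractions), `D`, `predictions`, `desirabilities`, and `trace`
#'   (grid step, number of polish starts, seed).
#' @export
optimize_desirability <- function(fits, goals, grid_step = 0.005, seed = 0,
                                  polish = TRUE) {
  stopifnot(length(fits) >= 1, length(fits) == length(goals))
  if (is.null(names(fits)) || is.null(names(goals)))
    stop("fits and goals must be named lists")
  goals <- goals[names(fits)]
  q <- ncol(fits[[1]]$design$blends)
  for (f in fits) stopifnot(ncol(f$design$blends) == q)
  comp_names <- fits[[1]]$design$names

  goals <- mapply(function(g, f) complete_goal(g, f), goals, fits,
                  SIMPLIFY = FALSE)
  imp <- vapply(goals, `[[`, 0, "importance")

  D_at <- function(m) {
    P <- vapply(fits, function(f) as.numeric(predict(f, m)),
                numeric(nrow(m)))
    if (!is.matrix(P)) P <- matrix(P, nrow = nrow(m))
    ds <- vapply(seq_along(goals), function(j)
      desirability_value(P[, j], goals[[j]]), numeric(nrow(m)))
    if (!is.matrix(ds)) ds <- matrix(ds, nrow = nrow(m))
    overall_desirability(ds, imp)
  }

  grid <- simplex_grid(q, grid_step)
  Dg <- D_at(grid)
  if (all(Dg == 0))
    warning("no feasible optimum: overall desirability is zero everywhere on the grid")
  best_idx <- order(Dg, decreasing = TRUE)[seq_len(min(10, nrow(grid)))]

  best_x <- grid[best_idx[1], ]
  best_D <- Dg[best_idx[1]]
  if (polish && best_D > 0) {
    obj <- function(free) {
      x <- project_simplex_free(free, q)
      -D_at(matrix(x, nrow = 1))
    }
    for (i in best_idx) {
      start <- grid[i, seq_len(q - 1)]
      res <- stats::optim(start, obj, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10))
      if (-res$value > best_D) {
        best_D <- -res$value
        best_x <- project_simplex_free(res$par, q)
      }
    }
  }

  m <- matrix(best_x, nrow = 1)
  preds <- vapply(fits, function(f) as.numeric(predict(f, m)), 0)
  ds <- vapply(seq_along(goals), function(j)
    desirability_value(preds[j], goals[[j]]), 0)
  names(ds) <- names(fits)
  structure(list(
    blend = stats::setNames(as.numeric(best_x), comp_names),
    D = best_D, predictions = preds, desirabilities = ds, goals = goals,
    trace = list(grid_step = grid_step, polish_starts = if (polish) 10 else 0,
                 seed = seed)),
    class = "desirability_optimum")
}

# Fill missing L/T/U of a goal from the observed response range of a fit.
complete_goal <- function(g, fit) {
  stopifnot(inherits(g, "desirability_goal"))
  rng <- range(fit$response)
  if (is.null(g$L)) g$L <- rng[1]
  if (is.null(g$U)) g$U <- rng[2]
  if (is.null(g$T))
    g$T <- switch(g$direction, minimize = g$L, maximize = g$U, g$T)
  if (!(g$L <= g$T && g$T <= g$U)) stop("completed goal violates L <= T <= U")
  g
}

# Map q-1 free coordinates to a simplex point: clamp negatives, rescale if
# the free coordinates overflow, last coordinate is the remainder.
project_simplex_free <- function(free, q) {
  free <- pmax(free, 0)
  s <- sum(free)
  if (s > 1) free <- free / s
  c(free, 1 - sum(free))
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat("Desirability optimum on the simplex\n")
  cat("Blend:", paste(sprintf("%s = %.4f (%.2f%%)", names(x$blend),
                              x$blend, 100 * x$blend), collapse = ", "), "\n")
  cat(sprintf("Overall desirability D = %.4f\n", x$D))
  for (nm in names(x$predictions))
    cat(sprintf("  %s: predicted %.6g (d = %.4f)\n", nm,
                x$predictions[nm], x$desirabilities[nm]))
  invisible(x)
}

#' Ternary desirability grid export
#'
#' Evaluates predictions, individual desirabilities and overall desirability
#' on a barycentric grid, returning a data frame suitable for external
#' contour plotting.
#'
#' @inheritParams optimize_desirability
#' @return data frame with the composition columns, one `yhat_*` and `d_*`
#'   column per response, and `D`.
#' @export
desirability_grid <- function(fits, goals, grid_step = 0.02) {
  stopifnot(length(fits) == length(goals))
  goals <- goals[names(fits)]
  goals <- mapply(function(g, f) complete_goal(g, f), goals, fits,
                  SIMPLIFY = FALSE)
  q <- ncol(fits[[1]]$design$blends)
  grid <- simplex_grid(q, grid_step)
  out <- as.data.frame(grid)
  names(out) <- fits[[1]]$design$names
  ds <- matrix(0, nrow(grid), length(fits))
  for (j in seq_along(fits)) {
    yh <- as.numeric(predict(fits[[j]], grid))
    out[[paste0("yhat_", names(fits)[j])]] <- yh
    ds[, j] <- desirability_value(yh, goals[[j]])
    out[[paste0("d_", names(fits)[j])]] <- ds[, j]
  }
  out$D <- overall_desirability(ds, vapply(goals, `[[`, 0, "importance"))
  out
}
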