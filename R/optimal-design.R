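#' Candidate blends for optimal-design search
#'
#' Enumerates all simplex points whose coordinates are drawn from a stated
#' lattice of fractions and sum to 1, then augments with the overall centroid
#' and the q axial points (centroid shifted halfway toward each vertex) and
#' deduplicates at tolerance 1e-6. The candidate set always contains the q
#' vertices.
#'
#' @param q number of mixture components (>= 2).
#' @param levels numeric vector of lattice fractions in \[0, 1\]; must be
#'   non-empty and include 0 and 1 (so the vertices are representable).
#' @param names optional component names.
#' @return a `mixture_design` holding the candidate blends (one run each).
#' @export
candidate_set <- function(q, levels, names = NULL) {
  if (q < 2) stop("q must be at least 2")
  levels <- sort(unique(as.numeric(levels)))
  if (length(levels) == 0) stop("empty lattice: no usable candidate basis")
  if (any(levels < 0 | levels > 1)) stop("lattice levels must lie in [0, 1]")
  if (!any(abs(levels - 1) < 1e-9) || !any(abs(levels) < 1e-9))
    stop("lattice must include 0 and 1 so the vertices are candidates")
  pts <- lattice_simplex_points(q, levels)
  centroid <- rep(1 / q, q)
  pts <- rbind(pts, centroid)
  if (q >= 3) {
    # axial check blends (centroid shifted halfway toward each vertex);
    # conventional only for 3+ components
    axial <- t(vapply(seq_len(q), function(i) {
      v <- rep(0, q); v[i] <- 1
      (centroid + v) / 2
    }, numeric(q)))
    pts <- rbind(pts, axial)
  }
  pts <- dedupe_blends(pts)
  mixture_design(pts, names = names)
}

# All q-vectors with coordinates in `levels` summing to 1 (within 1e-9).
lattice_simplex_points <- function(q, levels) {
  acc <- matrix(numeric(0), ncol = q)
  rec <- function(prefix, remaining) {
    k <- length(prefix)
    if (k == q - 1) {
      last <- 1 - sum(prefix)
      if (any(abs(levels - last) < 1e-9))
        acc <<- rbind(acc, c(prefix, last))
      return(invisible())
    }
    for (l in levels) {
      if (sum(prefix) + l <= 1 + 1e-9) rec(c(prefix, l), remaining)
    }
  }
  rec(numeric(0), NULL)
  acc
}

dedupe_blends <- function(m, tol = 1e-6) {
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    if (i < nrow(m)) for (j in (i + 1L):nrow(m)) {
      if (keep[j] && max(abs(m[i, ] - m[j, ])) <= tol) keep[j] <- FALSE
    }
  }
  m[keep, , drop = FALSE]
}

#' Uniform barycentric grid over the simplex
#'
#' @param q number of components.
#' @param step grid step in each barycentric coordinate (e.g. 0.02).
#' @return matrix of grid points (rows sum to 1).
#' @export
simplex_grid <- function(q, step = 0.02) {
  k <- round(1 / step)
  lattice_simplex_points(q, (0:k) / k)
}

#' I-optimality criterion: average scaled prediction variance
#'
#' Computes the mean over an evaluation grid of f(x)' (X'X)^{-1} f(x), where
#' f is the Scheffe term-expansion map and X the design's model matrix. Lower
#' is better; it is the criterion minimized by I-optimal design construction.
#'
#' @param design a [mixture_design()].
#' @param terms a term vector (see [parse_terms()]), e.g.
#'   `c("A","B","C","AB","AC","BC","ABC")`.
#' @param eval_grid matrix of simplex points; default a barycentric grid at
#'   step 0.02.
#' @return the average scaled prediction variance (dimensionless).
#' @export
i_criterion <- function(design, terms, eval_grid = NULL) {
  X <- model_matrix(design, terms)
  p <- ncol(X)
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-10)
    stop("design is rank-deficient for this model: I-criterion undefined")
  if (is.null(eval_grid))
    eval_grid <- simplex_grid(ncol(design$blends), 0.02)
  F <- term_expand(eval_grid, parse_terms(terms, ncol(design$blends)))
  M <- solve(xtx)
  mean(rowSums((F %*% M) * F))
}

#' I-optimal run selection by point exchange
#'
#' Greedy exchange search: from each of `n_starts` random initial subsets of
#' the candidate set, repeatedly swap one design run for one unused candidate
#' blend whenever the I-criterion strictly decreases, until no improving swap
#' exists. The best design over all starts is returned. Deterministic given
#' `seed`. The selected runs are distinct blends; replicated runs are added
#' afterwards with [augment_replicates()].
#'
#' @param candidates a candidate `mixture_design` (see [candidate_set()]).
#' @param n_runs number of runs to select (>= number of model terms).
#' @param terms Scheffe term vector defining the model to support.
#' @param n_starts number of random restarts.
#' @param seed integer seed for the random initial subsets.
#' @param eval_grid optional evaluation grid for the criterion.
#' @return a `mixture_design` of `n_runs` selected runs, with attributes
#'   `criterion` (achieved I-criterion) and `seed`.
#' @export
coordinate_exchange <- function(candidates, n_runs, terms, n_starts = 5,
                                seed = 0, eval_grid = NULL) {
  stopifnot(inherits(candidates, "mixture_design"))
  cand <- candidates$blends
  q <- ncol(cand)
  p <- length(terms)
  if (n_runs < p)
    stop(sprintf("n_runs (%d) must be at least the number of terms (%d)",
                 n_runs, p))
  if (n_runs > nrow(cand))
    stop("n_runs exceeds the candidate count; add replicates with ",
         "augment_replicates() instead")
  if (is.null(eval_grid)) eval_grid <- simplex_grid(q, 0.02)
  tl <- parse_terms(terms, q)
  Fc <- term_expand(cand, tl)

  Fg <- term_expand(eval_grid, tl)
  crit_rows <- function(rows) {
    X <- Fc[rows, , drop = FALSE]
    xtx <- crossprod(X)
    if (rcond(xtx) < 1e-10) return(Inf)
    mean(rowSums((Fg %*% solve(xtx)) * Fg))
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  best_rows <- NULL
  best_crit <- Inf
  nc <- nrow(cand)
  for (s in seq_len(n_starts)) {
    rows <- sample.int(nc, n_runs)
    cur <- crit_rows(rows)
    # retry a start whose initial subset is singular
    tries <- 0
    while (!is.finite(cur) && tries < 50) {
      rows <- sample.int(nc, n_runs)
      cur <- crit_rows(rows)
      tries <- tries + 1
    }
    improved <- TRUE
    while (improved && is.finite(cur)) {
      improved <- FALSE
      for (i in seq_along(rows)) {
        for (j in setdiff(seq_len(nc), rows)) {
          trial <- rows
          trial[i] <- j
          ct <- crit_rows(trial)
          if (ct < cur - 1e-12) {
            rows <- trial
            cur <- ct
            improved <- TRUE
          }
        }
      }
    }
    if (cur < best_crit) {
      best_crit <- cur
      best_rows <- rows
    }
  }
  if (!is.finite(best_crit))
    stop("no full-rank design found: candidates do not span the model")
  d <- mixture_design(cand[best_rows, , drop = FALSE],
                      names = candidates$names)
  attr(d, "criterion") <- best_crit
  attr(d, "seed") <- seed
  d
}

#' Augment a design with replicate runs
#'
#' Adds duplicate runs until `n_total` is reached: the centroid-most blend
#' first (the run closest to the overall centroid), then blends in decreasing
#' order of leverage under the given model, cycling as needed. Replicates
#' feed the pure-error degrees of freedom of the lack-of-fit ANOVA.
#'
#' @param design a [mixture_design()].
#' @param n_total target total run count (>= current runs).
#' @param terms term vector used to rank blends by leverage; default the
#'   linear Scheffe terms.
#' @return the augmented `mixture_design`.
#' @export
augment_replicates <- function(design, n_total, terms = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  n <- nrow(design$blends)
  if (n_total < n) stop("n_total is smaller than the current run count")
  if (n_total == n) return(design)
  q <- ncol(design$blends)
  if (is.null(terms)) terms <- component_alias(q)
  X <- model_matrix(design, terms)
  h <- diag(X %*% solve(crossprod(X)) %*% t(X))
  centroid <- rep(1 / q, q)
  dist_c <- apply(design$blends, 1, function(r) sum((r - centroid)^2))
  ord <- c(which.min(dist_c), setdiff(order(h, decreasing = TRUE),
                                      which.min(dist_c)))
  add <- rep(ord, length.out = n_total - n)
  m <- rbind(design$blends, design$blends[add, , drop = FALSE])
  mixture_design(m, names = design$names)
}
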