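#' Scheffe mixture-model terms
#'
#' Terms are written with components aliased `A, B, C, ...` in input order,
#' following the usual mixture-design shorthand:
#' \itemize{
#'   \item `"A"` — linear term x_A (Scheffe models have no intercept);
#'   \item `"AB"` — quadratic blending term x_A x_B;
#'   \item `"AB(A-B)"` — cubic difference term x_A x_B (x_A - x_B);
#'   \item `"ABC"` — cubic triple term x_A x_B x_C.
#' }
#' `parse_terms()` converts the strings to an internal representation;
#' `term_expand()` evaluates them at simplex points.
#'
#' @param terms character vector of term strings.
#' @param q number of components.
#' @return for `parse_terms`, a list of terms, each a list with `kind`
#'   (`"linear"`, `"quadratic"`, `"cubic_diff"` or `"cubic_triple"`) and
#'   `idx` (component indices).
#' @export
parse_terms <- function(terms, q) {
  if (length(terms) == 0) stop("term list must be non-empty")
  if (anyDuplicated(terms)) stop("duplicate terms: ",
    paste(terms[duplicated(terms)], collapse = ", "))
  alias <- component_alias(q)
  idx_of <- function(ch) {
    i <- match(ch, alias)
    if (any(is.na(i))) stop("unknown component letter in term (q = ", q, ")")
    i
  }
  lapply(terms, function(t) {
    t <- gsub(" ", "", t)
    m <- regmatches(t, regexec("^([A-Z])([A-Z])\\(\\1-\\2\\)$", t))[[1]]
    if (length(m) == 3) {
      i <- idx_of(m[2]); j <- idx_of(m[3])
      if (i >= j) stop("cubic difference term must have i < j: ", t)
      return(list(kind = "cubic_diff", idx = c(i, j), label = t))
    }
    if (grepl("^[A-Z]+$", t)) {
      i <- sort(idx_of(strsplit(t, "")[[1]]))
      if (anyDuplicated(i)) stop("repeated component in term: ", t)
      kind <- switch(as.character(length(i)),
                     "1" = "linear", "2" = "quadratic", "3" = "cubic_triple",
                     stop("terms above third order are not supported: ", t))
      return(list(kind = kind, idx = i, label = t))
    }
    stop("cannot parse term: ", t)
  })
}

#' @rdname parse_terms
#' @export
component_alias <- function(q) LETTERS[seq_len(q)]

#' Canonical term sets
#'
#' Convenience constructor for the standard Scheffe models: `"linear"`
#' (q terms), `"quadratic"` (+ all pairwise products), `"special-cubic"`
#' (+ the triple product for q = 3), and `"reduced-cubic"` (quadratic + all
#' cubic difference terms x_i x_j (x_i - x_j)).
#'
#' @param q number of components.
#' @param model one of `"linear"`, `"quadratic"`, `"special-cubic"`,
#'   `"reduced-cubic"`.
#' @return character vector of term strings.
#' @export
scheffe_terms <- function(q, model = c("linear", "quadratic",
                                       "special-cubic", "reduced-cubic")) {
  model <- match.arg(model)
  al <- component_alias(q)
  lin <- al
  pairs <- utils::combn(q, 2)
  quad <- apply(pairs, 2, function(ij) paste0(al[ij[1]], al[ij[2]]))
  cubd <- apply(pairs, 2, function(ij)
    sprintf("%s%s(%s-%s)", al[ij[1]], al[ij[2]], al[ij[1]], al[ij[2]]))
  switch(model,
    linear = lin,
    quadratic = c(lin, quad),
    `special-cubic` = {
      if (q < 3) stop("special-cubic requires q >= 3")
      trip <- apply(utils::combn(q, 3), 2, function(k) paste(al[k], collapse = ""))
      c(lin, quad, trip)
    },
    `reduced-cubic` = c(lin, quad, cubd))
}

# Evaluate parsed terms at a matrix of simplex points (rows).
term_expand <- function(x, term_list) {
  x <- as.matrix(x)
  out <- vapply(term_list, function(t) {
    switch(t$kind,
      linear = x[, t$idx],
      quadratic = x[, t$idx[1]] * x[, t$idx[2]],
      cubic_diff = x[, t$idx[1]] * x[, t$idx[2]] *
        (x[, t$idx[1]] - x[, t$idx[2]]),
      cubic_triple = x[, t$idx[1]] * x[, t$idx[2]] * x[, t$idx[3]])
  }, numeric(nrow(x)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(x))
  colnames(out) <- vapply(term_list, `[[`, "", "label")
  out
}

#' Scheffe model matrix
#'
#' Evaluates each term at each run of a design. There is no intercept
#' column: the mixture constraint sum(x) = 1 makes an intercept redundant
#' with the linear terms.
#'
#' @param design a [mixture_design()] (or a bare matrix of simplex points).
#' @param terms character vector of term strings (see [parse_terms()]).
#' @return numeric matrix, runs x terms.
#' @export
model_matrix <- function(design, terms) {
  m <- if (inherits(design, "mixture_design")) design$blends else as.matrix(design)
  term_expand(m, parse_terms(terms, ncol(m)))
}
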