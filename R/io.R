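#' Read a mixture design (and optional responses) from CSV
#'
#' Expects a header `run,<comp1>,...,<compq>[,<response columns>]`. The
#' composition columns are identified by `components` (by name, so column
#' order is irrelevant); compositions may be fractions or percentages
#' (auto-detected: a composition column maximum above 1.5 implies percent).
#' Rows whose fractions sum outside 1 +/- 1e-5 (after percent conversion)
#' are rejected with their row index.
#'
#' @param path CSV file path.
#' @param components character vector of composition column names; default
#'   every column except `run` that is not a response (i.e. all columns when
#'   `responses = NULL` picks none). If `NULL`, all non-`run` columns whose
#'   name does not appear in `responses` are taken as components.
#' @param responses optional character vector of response column names to
#'   extract alongside the design.
#' @return list with `design` (a [mixture_design()]) and `responses` (data
#'   frame or NULL).
#' @export
read_mixture_data <- function(path, components = NULL, responses = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"run" %in% names(df)) stop("design CSV must have a 'run' column")
  if (is.null(components))
    components <- setdiff(names(df), c("run", responses))
  missing_c <- setdiff(components, names(df))
  if (length(missing_c))
    stop("missing composition columns: ", paste(missing_c, collapse = ", "))
  comp <- as.matrix(df[, components, drop = FALSE])
  if (max(comp, na.rm = TRUE) > 1.5) comp <- comp / 100
  sums <- rowSums(comp)
  bad <- which(abs(sums - 1) > 1e-5)
  if (length(bad))
    stop("composition rows not summing to 1 (tolerance 1e-5): row ",
         paste(bad, collapse = ", "))
  design <- mixture_design(comp, run_ids = df$run, names = components)
  resp <- NULL
  if (!is.null(responses)) {
    missing_r <- setdiff(responses, names(df))
    if (length(missing_r))
      stop("missing response columns: ", paste(missing_r, collapse = ", "))
    if (anyNA(df[, responses]))
      stop("missing response values in: ",
           paste(responses[colSums(is.na(df[, responses, drop = FALSE])) > 0],
                 collapse = ", "))
    resp <- df[, responses, drop = FALSE]
  }
  list(design = design, responses = resp)
}

#' Write a design (with optional responses) to CSV
#'
#' @param design a [mixture_design()].
#' @param path output file path.
#' @param responses optional data frame of per-run responses to append.
#' @export
write_mixture_data <- function(design, path, responses = NULL) {
  df <- as.data.frame(design)
  if (!is.null(responses)) df <- cbind(df, responses)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read model specifications from JSON
#'
#' Schema: a named object per response, e.g.
#' `{"d32_um": {"transform": "sqrt", "terms": ["A","B","C","AB"]}}`.
#'
#' @param path JSON file path.
#' @return named list of `list(terms, transform)`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(cfg, function(m) {
    if (is.null(m$terms)) stop("model config entry lacks 'terms'")
    list(terms = as.character(m$terms),
         transform = if (is.null(m$transform)) "identity" else m$transform)
  })
}

#' Read desirability goals from JSON
#'
#' Schema: named object per response with `direction` and optional `L`,
#' `T`, `U`, `weight`, `importance`; omitted bounds are completed from the
#' observed response range at optimization time.
#'
#' @param path JSON file path.
#' @return named list of [desirability_goal()]s.
#' @export
read_goal_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(cfg, function(g) {
    do.call(desirability_goal, c(
      list(direction = if (is.null(g$direction)) "minimize" else g$direction),
      g[intersect(names(g), c("L", "T", "U", "weight", "importance"))]))
  })
}

#' Run the full mixture-analysis pipeline
#'
#' Fits every configured model, writes per-response coefficient tables and
#' ANOVA tables (CSV), optionally performs backward model reduction, runs
#' the desirability optimization, and writes the optimum as JSON together
#' with a plain-text log carrying the seed and grid parameters. All numeric
#' outputs are deterministic given the configuration.
#'
#' @param design a [mixture_design()].
#' @param responses data frame of responses (columns matched to `models`).
#' @param models named list of `list(terms, transform)` per response.
#' @param goals named list of [desirability_goal()]s (default: minimize
#'   each response over its observed range).
#' @param out_dir output directory (created if needed).
#' @param reduce if TRUE, backward-eliminate non-significant non-linear
#'   terms at `alpha` before optimizing.
#' @param alpha significance level for reduction.
#' @param grid_step barycentric grid step of the optimizer.
#' @param seed integer seed.
#' @return (invisibly) list with `fits`, `anovas`, `optimum`, `files`.
#' @export
run_pipeline <- function(design, responses, models, goals = NULL,
                         out_dir = tempfile("mixrsm_"), reduce = FALSE,
                         alpha = 0.05, grid_step = 0.005, seed = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  missing_r <- setdiff(names(models), names(responses))
  if (length(missing_r))
    stop("pipeline stage 'fit': responses missing for ",
         paste(missing_r, collapse = ", "))
  fits <- list()
  anovas <- list()
  files <- character(0)
  for (nm in names(models)) {
    m <- models[[nm]]
    fits[[nm]] <- if (reduce)
      reduce_model(design, responses[[nm]], m$terms, m$transform, alpha)
    else
      scheffe_fit(design, responses[[nm]], m$terms, m$transform)
    anovas[[nm]] <- mixture_anova(fits[[nm]])
    cf <- data.frame(term = names(fits[[nm]]$coefficients),
                     coefficient = as.numeric(fits[[nm]]$coefficients))
    f1 <- file.path(out_dir, paste0("coefficients_", nm, ".csv"))
    f2 <- file.path(out_dir, paste0("anova_", nm, ".csv"))
    utils::write.csv(cf, f1, row.names = FALSE)
    utils::write.csv(as.data.frame(anovas[[nm]]), f2, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  if (is.null(goals))
    goals <- lapply(stats::setNames(names(fits), names(fits)),
                    function(nm) desirability_goal("minimize",
                      L = min(responses[[nm]]), U = max(responses[[nm]])))
  opt <- optimize_desirability(fits, goals, grid_step = grid_step,
                               seed = seed)
  f3 <- file.path(out_dir, "optimum.json")
  jsonlite::write_json(list(
    blend = as.list(opt$blend),
    blend_pct = as.list(100 * opt$blend),
    D = opt$D,
    predictions = as.list(opt$predictions),
    desirabilities = as.list(opt$desirabilities)),
    f3, auto_unbox = TRUE, digits = NA)
  f4 <- file.path(out_dir, "pipeline.log")
  writeLines(c(
    sprintf("mixrsm %s", as.character(utils::packageVersion("mixrsm"))),
    sprintf("seed: %d", seed),
    sprintf("grid_step: %g", grid_step),
    sprintf("reduce: %s (alpha = %g)", reduce, alpha),
    sprintf("responses: %s", paste(names(models), collapse = ", "))), f4)
  files <- c(files, f3, f4)
  invisible(list(fits = fits, anovas = anovas, optimum = opt,
                 files = files))
}
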