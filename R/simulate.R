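#' Simulate mixture-design responses from a Scheffe surface
#'
#' For each run, the transformed response is the model-matrix row times the
#' true coefficients plus Gaussian noise of standard deviation `noise_sd`
#' (on the transformed scale), then back-transformed to original units.
#' Deterministic given `seed`. For the `sqrt` transform a negative noisy
#' draw has no back-transform; such a draw is resampled once and, if still
#' negative, clamped to zero with a warning.
#'
#' @param design a [mixture_design()].
#' @param coefficients named numeric vector of true coefficients
#'   (transformed scale), names being term strings.
#' @param transform response transform of the generating surface.
#' @param noise_sd Gaussian noise SD on the transformed scale (>= 0).
#' @param seed integer seed.
#' @return numeric vector of simulated responses in original units.
#' @export
simulate_responses <- function(design, coefficients, transform = "identity",
                               noise_sd = 0, seed = 0) {
  stopifnot(inherits(design, "mixture_design"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  tf <- as_transform(transform)
  terms <- names(coefficients)
  if (is.null(terms)) stop("coefficients must be named by term strings")
  X <- model_matrix(design, terms)
  mu <- drop(X %*% coefficients)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  z <- mu + stats::rnorm(length(mu), 0, noise_sd)
  if (tf$name == "sqrt") {
    neg <- which(z < 0)
    if (length(neg)) {
      z[neg] <- mu[neg] + stats::rnorm(length(neg), 0, noise_sd)
      still <- neg[z[neg] < 0]
      if (length(still)) {
        warning("negative sqrt-scale draws clamped to 0 at run(s) ",
                paste(design$run_ids[still], collapse = ", "))
        z[still] <- 0
      }
    }
  }
  if (tf$name %in% c("ln", "inverse", "inverse_sqrt") && any(z <= 0))
    stop("simulated transformed values non-positive: reduce noise_sd")
  tf$inverse(z)
}

#' Simulation configuration emulating the bundled nanoemulsion study
#'
#' Builds a data-generating configuration whose true surfaces are the
#' default-model fits to the bundled 17-run data and whose noise SDs are the
#' corresponding residual standard deviations (transformed scale). Datasets
#' simulated from it therefore have the design structure, coefficient
#' magnitudes and signal-to-noise ratio of the real study.
#'
#' @return list with `design` and, per response, `coefficients`,
#'   `transform`, `noise_sd`.
#' @export
nanoemulsion_sim_config <- function() {
  fits <- nanoemulsion_fits()
  fx <- nanoemulsion_runs()
  cfg <- lapply(fits, function(f)
    list(coefficients = f$coefficients, transform = f$transform$name,
         noise_sd = f$sd))
  list(design = fx$design, responses = cfg)
}

#' Simulate a full response table from a configuration
#'
#' @param cfg a configuration as returned by [nanoemulsion_sim_config()].
#' @param seed integer seed; response r uses `seed + r - 1`.
#' @return data frame of simulated responses, one column per response.
#' @export
simulate_study <- function(cfg, seed = 0) {
  out <- lapply(seq_along(cfg$responses), function(r) {
    rc <- cfg$responses[[r]]
    simulate_responses(cfg$design, rc$coefficients, rc$transform,
                       rc$noise_sd, seed = seed + r - 1)
  })
  names(out) <- names(cfg$responses)
  as.data.frame(out)
}
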