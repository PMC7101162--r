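#' Sampler configuration for the mixture model
#'
#' Collects every knob of the Gibbs sampler. The default iteration schedule
#' is the full production profile (500,000 iterations, 50,000 burn-in,
#' thinning 100); `profile = "desk"` switches to a lighter schedule
#' (50,000 / 5,000 / 10) that gives near-identical summaries on the
#' thickness-scale problems this package targets and runs in seconds.
#'
#' @param k number of mixture components (morphotypes), integer >= 1.
#' @param alpha Dirichlet hyperparameters for the component weights, one
#'   positive value per component. These are the prior relative-abundance
#'   parameters; for field samples use the raw morphotype counts.
#' @param iterations,burn_in,thinning MCMC schedule; `burn_in < iterations`,
#'   `thinning >= 1`.
#' @param chains number of independent chains (default 3).
#' @param gamma_floor lower bound applied to each gamma draw in the
#'   normalized-gamma (Dirichlet) weight update, guarding against numerically
#'   zero weights; default 0.01.
#' @param sort_means relabel each retained draw so component means are
#'   ascending. Required for k >= 3 (label-switching control); off by
#'   default for k <= 2.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param prior_mean_location prior location of each component mean, in um:
#'   a vector of length `k`, a single value recycled, or `NA` (default) for
#'   the empirical abundance-slice anchors of
#'   [empirical_mixture_priors()], computed from the data at fit time.
#' @param prior_mean_precision prior precision of the component means in
#'   1/um^2; `NA` (default) resolves to `1 / sigma_scale^2`.
#' @param precision_shape,precision_rate gamma prior on each component
#'   precision. `precision_rate = NA` (default) resolves to
#'   `precision_shape * sigma_scale^2`, centring the prior precision on
#'   `1 / sigma_scale^2`.
#' @param sigma_scale reference within-component standard deviation, um
#'   (default 0.02); sets the scale of the default precision prior, the
#'   default mean-prior precision, and the anchor-shrinkage likelihood of
#'   [empirical_mixture_priors()].
#' @param component_order `"ascending"` (default) if the components (and
#'   `alpha`) are listed from thinnest to thickest, `"descending"` for the
#'   reverse. Only affects the empirical prior anchors.
#' @param profile `"paper"` (default schedule above) or `"desk"`.
#' @return an object of class `mixture_config` (a validated list).
#' @export
mixture_config <- function(k = 2, alpha = NULL,
                           iterations = NULL, burn_in = NULL, thinning = NULL,
                           chains = 3, gamma_floor = 0.01,
                           sort_means = k >= 3, seed = 1L,
                           prior_mean_location = NA_real_,
                           prior_mean_precision = NA_real_,
                           precision_shape = 10, precision_rate = NA_real_,
                           sigma_scale = 0.02,
                           component_order = c("ascending", "descending"),
                           profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  component_order <- match.arg(component_order)
  sched <- if (profile == "paper") c(500000L, 50000L, 100L)
           else c(50000L, 5000L, 10L)
  if (is.null(iterations)) iterations <- sched[1]
  if (is.null(burn_in)) burn_in <- sched[2]
  if (is.null(thinning)) thinning <- sched[3]
  if (is.null(alpha)) {
    alpha <- if (k == 2) c(20, 80) else if (k == 4) c(10, 35, 35, 20)
             else rep(1, k)
  }
  cfg <- list(k = as.integer(k), alpha = as.numeric(alpha),
              iterations = as.integer(iterations),
              burn_in = as.integer(burn_in),
              thinning = as.integer(thinning),
              chains = as.integer(chains),
              gamma_floor = as.numeric(gamma_floor),
              sort_means = isTRUE(sort_means), seed = as.integer(seed),
              prior_mean_location = as.numeric(prior_mean_location),
              prior_mean_precision = as.numeric(prior_mean_precision),
              precision_shape = as.numeric(precision_shape),
              precision_rate = as.numeric(precision_rate),
              sigma_scale = as.numeric(sigma_scale),
              component_order = component_order,
              profile = profile)
  validate_mixture_config(cfg)
  class(cfg) <- "mixture_config"
  cfg
}

validate_mixture_config <- function(cfg) {
  stopifnot(cfg$k >= 1)
  if (length(cfg$alpha) != cfg$k) {
    stop("alpha must have length k (k = ", cfg$k, ", length(alpha) = ",
         length(cfg$alpha), ")")
  }
  if (any(!is.finite(cfg$alpha)) || any(cfg$alpha <= 0)) {
    stop("alpha entries must be positive and finite")
  }
  if (cfg$burn_in >= cfg$iterations) stop("burn_in must be < iterations")
  if (cfg$thinning < 1) stop("thinning must be >= 1")
  if (!(cfg$gamma_floor > 0)) stop("gamma_floor must be > 0")
  if (cfg$chains < 1) stop("chains must be >= 1")
  if (!is.na(cfg$prior_mean_precision) && !(cfg$prior_mean_precision > 0)) {
    stop("prior_mean_precision must be > 0 (or NA for empirical)")
  }
  if (!(cfg$precision_shape > 0)) stop("precision_shape must be > 0")
  if (!is.na(cfg$precision_rate) && !(cfg$precision_rate > 0)) {
    stop("precision_rate must be > 0 (or NA for empirical)")
  }
  if (!(cfg$sigma_scale > 0)) stop("sigma_scale must be > 0")
  if (!all(is.na(cfg$prior_mean_location)) &&
      !(length(cfg$prior_mean_location) %in% c(1L, cfg$k))) {
    stop("prior_mean_location must be length 1 or k (or NA for empirical)")
  }
  if (cfg$k >= 3 && !cfg$sort_means) {
    stop("sort_means must be TRUE for k >= 3 (label-switching control)")
  }
  invisible(cfg)
}

#' Pipeline-level configuration
#'
#' Non-sampler knobs of the analysis pipeline.
#'
#' @param outlier_multiplier Tukey-fence multiplier for thickness outlier
#'   removal (default 1.5).
#' @param rare_threshold morphotypes with relative abundance strictly below
#'   this proportion are excluded from the mixture model (default 0.01).
#' @param confidence confidence level for count margins of error and
#'   descriptive confidence intervals (default 0.95).
#' @param credible_mass central posterior mass of reported credible
#'   intervals (default 0.68, i.e. the 16th-84th percentile band).
#' @param coccoliths_per_cell assumed coccoliths per cell for the calcite
#'   budget; default `c(10, 23, 48)` (minimum / mean / maximum literature
#'   values).
#' @param calcite_density calcite density in g/cm^3 (default 2.71).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(outlier_multiplier = 1.5, rare_threshold = 0.01,
                            confidence = 0.95, credible_mass = 0.68,
                            coccoliths_per_cell = c(10L, 23L, 48L),
                            calcite_density = 2.71) {
  cfg <- list(outlier_multiplier = as.numeric(outlier_multiplier),
              rare_threshold = as.numeric(rare_threshold),
              confidence = as.numeric(confidence),
              credible_mass = as.numeric(credible_mass),
              coccoliths_per_cell = as.integer(coccoliths_per_cell),
              calcite_density = as.numeric(calcite_density))
  for (p in c("rare_threshold", "confidence", "credible_mass")) {
    if (!(cfg[[p]] > 0 && cfg[[p]] < 1)) stop(p, " must be in (0, 1)")
  }
  if (!(cfg$outlier_multiplier > 0)) stop("outlier_multiplier must be > 0")
  if (!(cfg$calcite_density > 0)) stop("calcite_density must be > 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load pipeline and sampler configuration from a JSON document
#'
#' The document may contain the top-level keys `"pipeline"` and `"mixture"`,
#' each an object whose entries override the corresponding argument of
#' [pipeline_config()] or [mixture_config()]. Unspecified keys keep their
#' defaults; an empty document returns the full default configuration.
#' Unknown keys are an error.
#'
#' @param path path to a JSON file.
#' @return `list(pipeline = <pipeline_config>, mixture = <mixture_config>)`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(doc) == 0) doc <- list()
  unknown <- setdiff(names(doc), c("pipeline", "mixture"))
  if (length(unknown) > 0) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  }
  build <- function(fn, given, allowed) {
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    do.call(fn, given)
  }
  pipe_keys <- setdiff(names(formals(pipeline_config)), "...")
  mix_keys <- setdiff(names(formals(mixture_config)), "...")
  list(pipeline = build(pipeline_config,
                        as.list(doc$pipeline %||% list()), pipe_keys),
       mixture = build(mixture_config,
                       as.list(doc$mixture %||% list()), mix_keys))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
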