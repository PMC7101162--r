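# Seedable generators for all test inputs: the published simulation design
# (16 mixture samples in 8 groups) and full field-like samples with the
# SEM + LM + metadata structure the pipeline consumes.

#' The simulation-study design
#'
#' The eight scenario groups of the validation study, verbatim: groups 1-4
#' are two-component designs (3 replicates each, N = 200) crossing
#' separated (0.100/0.120) against equal (0.110/0.110) true means with
#' weights 25/75 or 10/90; groups 5-8 are four-component designs
#' (1 replicate each, N = 500) with true means 0.085/0.100/0.110/0.125
#' under three weight permutations, plus a wider-spread design
#' 0.080/0.100/0.120/0.140. The common true standard deviation is 0.020.
#' In total 4 x 3 + 4 x 1 = 16 simulated samples.
#'
#' @return a list of 8 `scenario` objects with fields `group`, `n_sims`,
#'   `n`, `k`, `weights`, `true_means`, `true_sd`.
#' @export
table2_scenarios <- function() {
  rows <- list(
    list(1L, 3L, 200L, 2L, c(0.25, 0.75), c(0.100, 0.120)),
    list(2L, 3L, 200L, 2L, c(0.10, 0.90), c(0.100, 0.120)),
    list(3L, 3L, 200L, 2L, c(0.25, 0.75), c(0.110, 0.110)),
    list(4L, 3L, 200L, 2L, c(0.10, 0.90), c(0.110, 0.110)),
    list(5L, 1L, 500L, 4L, c(0.10, 0.35, 0.35, 0.20),
         c(0.085, 0.100, 0.110, 0.125)),
    list(6L, 1L, 500L, 4L, c(0.35, 0.10, 0.35, 0.20),
         c(0.085, 0.100, 0.110, 0.125)),
    list(7L, 1L, 500L, 4L, c(0.35, 0.35, 0.10, 0.20),
         c(0.085, 0.100, 0.110, 0.125)),
    list(8L, 1L, 500L, 4L, c(0.10, 0.35, 0.35, 0.20),
         c(0.080, 0.100, 0.120, 0.140)))
  lapply(rows, function(r) {
    structure(list(group = r[[1]], n_sims = r[[2]], n = r[[3]], k = r[[4]],
                   weights = r[[5]], true_means = r[[6]], true_sd = 0.020),
              class = "scenario")
  })
}

validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario") || is.list(scenario))
  with(scenario, {
    stopifnot(length(weights) == k, length(true_means) == k,
              abs(sum(weights) - 1) < 1e-8, true_sd >= 0, n >= 1)
  })
  invisible(scenario)
}

#' Simulate one pooled thickness sample from a mixture scenario
#'
#' Draws `scenario$n` values: each datum's component label is drawn with
#' the scenario weights, then the value from
#' `Normal(true_means[label], true_sd)`. Values are not truncated at zero;
#' at the design's means and standard deviation the negative-value
#' probability is negligible, and truncation would distort the stated
#' distributions.
#'
#' @param scenario a `scenario` (see [table2_scenarios()]).
#' @param seed integer seed; same seed, same output.
#' @return `list(values = numeric(n), true_labels = integer(n))`.
#' @export
simulate_thickness_sample <- function(scenario, seed) {
  validate_scenario(scenario)
  set.seed(as.integer(seed))
  labels <- sample.int(scenario$k, scenario$n, replace = TRUE,
                       prob = scenario$weights)
  values <- stats::rnorm(scenario$n, scenario$true_means[labels],
                         scenario$true_sd)
  list(values = values, true_labels = labels)
}

#' Specification of a synthetic field sample
#'
#' Describes a field-like sample: per-morphotype proportions, distal-shield
#' length distributions, aspect ratio, thickness distributions, optional
#' CT:L distribution (Type A only), plus cell density and the total number
#' of coccoliths. The defaults mimic a winter coastal sample: Type A
#' dominant (77%, length 3.36 um, thickness 0.131 um) over Group B (22%,
#' 3.18 um, 0.097 um) with a trace of malformed coccoliths, aspect ratio
#' 1.21, thickness spread 0.02 um and cell density 41003 cells/L.
#'
#' @param morphotypes character vector of morphotype codes.
#' @param proportions per-morphotype proportions (sum to 1).
#' @param length_mean,length_sd per-morphotype distal-shield length, um.
#' @param aspect_mean mean aspect ratio (length/width), shared.
#' @param thickness_mean,thickness_sd per-morphotype mean thickness, um.
#' @param ct_l_mean,ct_l_sd CT:L distribution for Type A.
#' @param mass_noise_sd multiplicative (lognormal) noise sd on LM mass; 0
#'   makes the generated mass exactly the volumetric formula value.
#' @param cell_density cells/L.
#' @param n_coccoliths total coccoliths per generated table.
#' @param sample_id sample identifier.
#' @return an object of class `field_sample_spec`.
#' @export
field_sample_spec <- function(morphotypes = c("A", "B", "M"),
                              proportions = c(0.77, 0.22, 0.01),
                              length_mean = c(3.36, 3.18, 2.77),
                              length_sd = c(0.30, 0.35, 0.30),
                              aspect_mean = 1.21,
                              thickness_mean = c(0.131, 0.097, 0.086),
                              thickness_sd = c(0.020, 0.020, 0.020),
                              ct_l_mean = 0.07, ct_l_sd = 0.01,
                              mass_noise_sd = 0.05,
                              cell_density = 41003,
                              n_coccoliths = 300L,
                              sample_id = "synthetic-1") {
  stopifnot(length(proportions) == length(morphotypes),
            abs(sum(proportions) - 1) < 1e-8,
            all(length_sd >= 0), all(thickness_sd >= 0),
            all(morphotypes %in% MORPHOTYPES),
            cell_density >= 0, n_coccoliths >= 1)
  structure(list(morphotypes = morphotypes, proportions = proportions,
                 length_mean = length_mean, length_sd = length_sd,
                 aspect_mean = aspect_mean,
                 thickness_mean = thickness_mean,
                 thickness_sd = thickness_sd,
                 ct_l_mean = ct_l_mean, ct_l_sd = ct_l_sd,
                 mass_noise_sd = mass_noise_sd,
                 cell_density = cell_density,
                 n_coccoliths = as.integer(n_coccoliths),
                 sample_id = sample_id),
            class = "field_sample_spec")
}

#' Simulate a full field sample (SEM table, LM table, metadata)
#'
#' Per coccolith: a morphotype is drawn with the spec proportions; length
#' is normal per morphotype; width is length divided by the aspect ratio;
#' thickness is normal per morphotype; LM mass is the volumetric formula
#' applied to the generated length/width/thickness times multiplicative
#' lognormal noise. Only overcalcified Type A is flagged as such in the LM
#' table (the only morphotype distinguishable in the light microscope);
#' all other rows are `"open"`. Type A rows receive central-tube widths
#' consistent with the spec's CT:L distribution.
#'
#' @param spec a [field_sample_spec()].
#' @param seed integer seed.
#' @return `list(sem = <SEM records>, lm = <LM records>, meta = <metadata
#'   row>)` in the canonical table schemas.
#' @export
simulate_field_sample <- function(spec, seed) {
  stopifnot(inherits(spec, "field_sample_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_coccoliths
  j <- sample.int(length(spec$morphotypes), n, replace = TRUE,
                  prob = spec$proportions)
  len <- stats::rnorm(n, spec$length_mean[j], spec$length_sd[j])
  len <- pmax(len, 0.5)  # guard against non-physical sizes in the tails
  width <- len / spec$aspect_mean
  thick <- stats::rnorm(n, spec$thickness_mean[j], spec$thickness_sd[j])
  thick <- pmax(thick, 1e-3)
  morpho <- spec$morphotypes[j]

  ct_left <- ct_right <- rep(NA_real_, n)
  is_a <- morpho == "A"
  if (any(is_a)) {
    ratio <- pmax(stats::rnorm(sum(is_a), spec$ct_l_mean, spec$ct_l_sd), 0)
    jitter <- stats::rnorm(sum(is_a), 0, 0.01)
    ct_left[is_a] <- pmax(ratio * len[is_a] + jitter, 0)
    ct_right[is_a] <- pmax(ratio * len[is_a] - jitter, 0)
  }
  sem <- data.frame(sample_id = spec$sample_id, morphotype = morpho,
                    length_um = len, width_um = width,
                    ct_left_um = ct_left, ct_right_um = ct_right,
                    stringsAsFactors = FALSE)

  mass <- coccolith_mass(len, width, thick)
  if (spec$mass_noise_sd > 0) {
    mass <- mass * exp(stats::rnorm(n, 0, spec$mass_noise_sd))
  }
  lm <- data.frame(sample_id = spec$sample_id, length_um = len,
                   mass_pg = mass, mean_thickness_um = thick,
                   central_area = ifelse(morpho == "OA", "overcalcified",
                                         "open"),
                   stringsAsFactors = FALSE)

  meta <- data.frame(sample_id = spec$sample_id, station = "synthetic",
                     month = "January", depth_m = 10,
                     cell_density_l = spec$cell_density,
                     stringsAsFactors = FALSE)
  list(sem = sem, lm = lm, meta = meta)
}
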