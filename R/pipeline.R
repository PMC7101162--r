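# Orchestration: wiring preprocessing, the mixture sampler and the
# morphometric estimators into the end-to-end per-sample workflow, plus the
# fixture writer for the simulation design and run manifests. These are the
# functions the exec/coccomix command-line script calls.

#' Fit the full per-sample pipeline
#'
#' For one sample: counts morphotypes on the SEM records, excludes rare
#' morphotypes (< `rare_threshold` relative abundance), removes thickness
#' outliers from the LM records by the single-pass interquartile rule, fits
#' the Gibbs mixture model with one component per retained morphotype and
#' the retained SEM counts as weight hyperpriors (`alpha`), and combines
#' the posterior-median thicknesses with per-morphotype SEM size summaries
#' into a volumetric mass table. If sample metadata are supplied, a calcite
#' budget is added.
#'
#' Components whose split R-hat exceeds `rhat_threshold` abort the fit
#' unless `override_convergence = TRUE`.
#'
#' @param sem SEM records (as from [read_sem_table()]), possibly covering
#'   several samples.
#' @param lm LM records (as from [read_lm_table()]).
#' @param sample_id which sample to fit; default: the single sample id
#'   present.
#' @param pipeline a [pipeline_config()].
#' @param mixture a [mixture_config()] template; `k`, `alpha` and
#'   `sort_means` are derived from the retained morphotypes.
#' @param meta optional metadata (as from [read_sample_meta()]).
#' @param thickness_order optional character vector: the retained
#'   morphotypes in expected ascending mean-thickness order. When `NULL`
#'   (default) the ordering is chosen by profiling the abundance-slice
#'   anchor likelihood over all permutations; supply it when prior
#'   knowledge of the thickness ranking exists.
#' @param rhat_threshold convergence acceptance threshold (default 1.1).
#' @param override_convergence report non-converged components instead of
#'   failing.
#' @return an object of class `cocco_fit`: a list with `abundance`,
#'   `retained`, `outliers`, `posterior` (with morphotype labels),
#'   `mass_table`, and `calcite` (or `NULL`).
#' @export
fit_sample <- function(sem, lm, sample_id = NULL,
                       pipeline = pipeline_config(),
                       mixture = mixture_config(profile = "desk"),
                       meta = NULL, thickness_order = NULL,
                       rhat_threshold = 1.1,
                       override_convergence = FALSE) {
  if (is.null(sample_id)) {
    ids <- unique(sem$sample_id)
    if (length(ids) != 1) {
      stop("sem covers several samples; give sample_id explicitly")
    }
    sample_id <- ids
  }
  sem <- sem[sem$sample_id == sample_id, , drop = FALSE]
  lm <- lm[lm$sample_id == sample_id, , drop = FALSE]
  if (nrow(sem) == 0 || nrow(lm) == 0) {
    stop("no records for sample '", sample_id, "'")
  }

  counts <- table(sem$morphotype)
  counts <- setNames(as.integer(counts), names(counts))
  abundance <- relative_abundance(counts, pipeline$confidence)
  retained <- filter_rare(counts, pipeline$rare_threshold)
  message("sample ", sample_id, ": retained morphotypes ",
          paste(retained, collapse = ", "),
          if (length(retained) < length(counts))
            paste0(" (excluded: ",
                   paste(setdiff(names(counts), retained), collapse = ", "),
                   ")"))

  filt <- remove_outliers(lm$mean_thickness_um, pipeline$outlier_multiplier)
  if (length(filt$removed) > 0) {
    message("sample ", sample_id, ": removed ", length(filt$removed),
            " thickness outlier(s)")
  }

  # components are listed in ascending mean-thickness order; the order of
  # the morphotypes is not known a priori, so choose the permutation of
  # the retained morphotypes whose abundance-slice anchors profile to the
  # highest mixture likelihood. When abundances are similar the choice is
  # weakly identified and the labeling is correspondingly ambiguous.
  k <- length(retained)
  if (is.null(thickness_order)) {
    perms <- all_permutations(k)
    ll <- vapply(perms, function(p) {
      empirical_mixture_priors(filt$kept, as.numeric(counts[retained[p]]),
                               mixture$sigma_scale)$loglik
    }, numeric(1))
    retained <- retained[perms[[which.max(ll)]]]
  } else {
    if (!setequal(thickness_order, retained)) {
      stop("thickness_order must be a permutation of the retained ",
           "morphotypes: ", paste(retained, collapse = ", "))
    }
    retained <- thickness_order
  }

  cfg <- mixture
  cfg$k <- k
  cfg$alpha <- as.numeric(counts[retained])
  cfg$sort_means <- k >= 3
  draws <- run_gibbs(filt$kept, cfg)
  post <- summarize_posterior(draws, pipeline$credible_mass)

  bad <- post$component[!is.na(post$rhat_mu) &
                          (post$rhat_mu > rhat_threshold |
                             post$rhat_sigma > rhat_threshold)]
  if (length(bad) > 0 && !override_convergence) {
    stop("component(s) ", paste(bad, collapse = ", "),
         " failed the R-hat < ", rhat_threshold, " convergence check; ",
         "rerun with override_convergence = TRUE to report them anyway")
  }

  # components carry the ascending-thickness morphotype listing chosen
  # above (sorted draws are ascending by construction for k >= 3)
  post$morphotype <- retained

  sem_sum <- do.call(rbind, lapply(retained, function(m) {
    rows <- sem[sem$morphotype == m, ]
    data.frame(morphotype = m,
               mean_length_um = mean(rows$length_um),
               mean_width_um = mean(rows$width_um),
               stringsAsFactors = FALSE)
  }))
  mass_table <- morphotype_mass_table(
    sem_sum,
    data.frame(morphotype = post$morphotype,
               thickness_um = post$mu_median, stringsAsFactors = FALSE),
    pipeline$calcite_density)

  calcite <- NULL
  if (!is.null(meta)) {
    mrow <- meta[meta$sample_id == sample_id, , drop = FALSE]
    if (nrow(mrow) == 1) {
      calcite <- calcite_budget(mrow, mean(lm$mass_pg),
                                pipeline$coccoliths_per_cell)
    }
  }

  structure(list(sample_id = sample_id, abundance = abundance,
                 retained = retained, outliers = filt$removed,
                 posterior = post, mass_table = mass_table,
                 calcite = calcite, config = cfg),
            class = "cocco_fit")
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' @export
print.cocco_fit <- function(x, ...) {
  cat("Sample", x$sample_id, "\n\nMorphotype abundance:\n")
  print.data.frame(x$abundance, digits = 3, row.names = FALSE)
  cat("\nPosterior thickness summary:\n")
  print(x$posterior)
  cat("\nPer-morphotype mass (pg):\n")
  print.data.frame(x$mass_table, digits = 3, row.names = FALSE)
  if (!is.null(x$calcite)) {
    cat("\nCalcite budget (ug/L):\n")
    print.data.frame(x$calcite, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write the simulation-design fixtures
#'
#' Generates the 16 simulated samples of the published design and writes
#' one CSV per sample (`group<g>_sim<i>.csv`, columns `value`,
#' `true_label`) plus a `scenarios.csv` index. Replicate seeds are split
#' from the master seed exactly as in [run_simulation_study()], so the
#' written fixtures are the study's inputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return paths of the written sample files, invisibly.
#' @export
simulate_table2 <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenarios <- table2_scenarios()
  n_runs <- sum(vapply(scenarios, function(s) s$n_sims, integer(1)))
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  index <- list()
  paths <- character()
  run <- 0L
  for (sc in scenarios) {
    for (sim in seq_len(sc$n_sims)) {
      run <- run + 1L
      s <- simulate_thickness_sample(sc, run_seeds[run])
      path <- file.path(out_dir, sprintf("group%d_sim%d.csv", sc$group, sim))
      utils::write.csv(data.frame(value = s$values,
                                  true_label = s$true_labels),
                       path, row.names = FALSE)
      paths <- c(paths, path)
      index[[run]] <- data.frame(
        group = sc$group, sim = sim, n = sc$n, k = sc$k,
        weights = paste(sc$weights, collapse = "/"),
        true_means = paste(sc$true_means, collapse = "/"),
        true_sd = sc$true_sd, seed = run_seeds[run])
    }
  }
  utils::write.csv(do.call(rbind, index),
                   file.path(out_dir, "scenarios.csv"), row.names = FALSE)
  invisible(paths)
}

#' Write a run manifest
#'
#' Records what a pipeline run did: the command, a configuration snapshot,
#' the master seed, md5 digests of the input files, the output paths and a
#' timestamp, as a JSON document next to the outputs.
#'
#' @param path manifest output path.
#' @param command short command name.
#' @param config configuration object(s) to snapshot.
#' @param seed master seed.
#' @param inputs character vector of input file paths (digested).
#' @param outputs character vector of output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, inputs = character(),
                           outputs = character()) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(command = command,
                   config = unclass_deep(config),
                   seed = seed, input_digests = digests,
                   outputs = as.list(outputs),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
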