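# Closed-form morphometric estimators: volumetric coccolith mass, population
# calcite concentration, central-tube and aspect ratios, and the combination
# of SEM size summaries with mixture-model thickness posteriors.

#' Volumetric coccolith mass
#'
#' Mass of an elliptical calcite slab,
#' `m = pi * (l/2) * (w/2) * t * d`, which comes out directly in
#' picograms when lengths are in um and density in g/cm^3
#' (1 um^3 x 1 g/cm^3 = 1 pg).
#'
#' @param length_um,width_um distal-shield length and width, um (> 0, with
#'   `length >= width`).
#' @param thickness_um mean coccolith thickness, um (>= 0).
#' @param density calcite density, g/cm^3 (default 2.71).
#' @return mass in pg; vectorized over its arguments.
#' @export
coccolith_mass <- function(length_um, width_um, thickness_um,
                           density = 2.71) {
  if (any(length_um <= 0) || any(width_um <= 0)) {
    stop("length and width must be > 0")
  }
  if (any(width_um > length_um)) {
    stop("width exceeds length; the long axis must be the length axis")
  }
  if (any(thickness_um < 0)) stop("thickness must be >= 0")
  if (any(density <= 0)) stop("density must be > 0")
  pi * (length_um / 2) * (width_um / 2) * thickness_um * density
}

#' Population calcite concentration
#'
#' `Ca = CD * m * N_cocco * 1e-6`: cell density (cells/L) times mean
#' coccolith mass (pg) times assumed coccoliths per cell, converted from
#' pg/L to ug/L.
#'
#' @param cell_density cells per litre (>= 0).
#' @param mean_mass mean coccolith mass, pg (>= 0).
#' @param coccoliths_per_cell assumed coccoliths per cell; may be a vector
#'   (e.g. `c(10, 23, 48)` for a plausible range).
#' @return calcite concentration(s) in ug/L.
#' @export
calcite_concentration <- function(cell_density, mean_mass,
                                  coccoliths_per_cell) {
  if (any(cell_density < 0) || any(mean_mass < 0) ||
      any(coccoliths_per_cell < 0)) {
    stop("all inputs must be >= 0")
  }
  cell_density * mean_mass * coccoliths_per_cell * 1e-6
}

#' Central-tube width to length ratio (CT:L)
#'
#' The central-tube width is measured on both sides of the central area
#' along the length axis and averaged; the mean is divided by coccolith
#' length to give a size-independent ratio.
#'
#' @param ct_left,ct_right central-tube width on each side, um (>= 0).
#' @param length_um coccolith length, um (> 0).
#' @return `mean(ct_left, ct_right) / length`; vectorized.
#' @export
ct_l_ratio <- function(ct_left, ct_right, length_um) {
  if (any(length_um <= 0)) stop("length must be > 0")
  if (any(ct_left < 0) || any(ct_right < 0)) {
    stop("central-tube widths must be >= 0")
  }
  (ct_left + ct_right) / 2 / length_um
}

#' Distal-shield aspect ratio
#'
#' @param length_um,width_um distal-shield axes, um; under the axis
#'   convention `length >= width` the ratio is always >= 1.
#' @return `length / width`; vectorized.
#' @export
aspect_ratio <- function(length_um, width_um) {
  if (any(width_um <= 0)) stop("width must be > 0")
  if (any(width_um > length_um)) {
    stop("width exceeds length; the long axis must be the length axis")
  }
  length_um / width_um
}

#' Per-morphotype coccolith mass from SEM sizes and posterior thickness
#'
#' Applies the volumetric mass formula to each morphotype's mean SEM length
#' and width and its posterior-median thickness from the mixture model.
#' Morphotypes present in the SEM summary but absent from the posterior
#' (e.g. excluded as rare, or not estimable) are kept in the table with
#' `estimable = FALSE` and `NA` mass rather than silently dropped.
#'
#' @param sem_summaries data frame with columns `morphotype`,
#'   `mean_length_um`, `mean_width_um`.
#' @param posterior data frame with columns `morphotype` and
#'   `thickness_um` (posterior-median mean thickness), e.g. a
#'   [summarize_posterior()] result joined to its morphotype labels.
#' @param density calcite density, g/cm^3 (default 2.71).
#' @return data frame with columns `morphotype`, `length_um`, `width_um`,
#'   `thickness_um`, `mass_pg`, `estimable`.
#' @export
morphotype_mass_table <- function(sem_summaries, posterior,
                                  density = 2.71) {
  stopifnot(all(c("morphotype", "mean_length_um", "mean_width_um") %in%
                  names(sem_summaries)),
            all(c("morphotype", "thickness_um") %in% names(posterior)))
  idx <- match(sem_summaries$morphotype, posterior$morphotype)
  thick <- posterior$thickness_um[idx]
  estimable <- !is.na(idx) & !is.na(thick)
  mass <- rep(NA_real_, nrow(sem_summaries))
  if (any(estimable)) {
    mass[estimable] <- coccolith_mass(
      sem_summaries$mean_length_um[estimable],
      sem_summaries$mean_width_um[estimable],
      thick[estimable], density)
  }
  data.frame(morphotype = sem_summaries$morphotype,
             length_um = sem_summaries$mean_length_um,
             width_um = sem_summaries$mean_width_um,
             thickness_um = thick, mass_pg = mass,
             estimable = estimable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Calcite budget table across coccoliths-per-cell assumptions
#'
#' Builds the per-sample calcite-concentration table: one row per sample
#' (station, month, depth, cell density, mean mass) and one `TC_<N>`
#' column per assumed coccoliths-per-cell value.
#'
#' @param meta data frame as from [read_sample_meta()].
#' @param mean_mass_pg mean coccolith mass per sample (pg), recycled or one
#'   value per row of `meta`.
#' @param coccoliths_per_cell vector of assumed coccoliths per cell
#'   (default `c(10, 23, 48)`).
#' @return `meta` with a `mass_pg` column and one `TC_<N>` column (ug/L)
#'   per assumption.
#' @export
calcite_budget <- function(meta, mean_mass_pg,
                           coccoliths_per_cell = c(10L, 23L, 48L)) {
  out <- meta
  out$mass_pg <- rep_len(mean_mass_pg, nrow(meta))
  for (n in coccoliths_per_cell) {
    out[[paste0("TC_", n)]] <- calcite_concentration(
      meta$cell_density_l, out$mass_pg, n)
  }
  out
}
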