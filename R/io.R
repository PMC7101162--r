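# CSV readers/writers for the SEM and LM measurement tables and per-sample
# metadata. Canonical headers (case-insensitive on read):
#   SEM:  sample_id, morphotype, length_um, width_um[, ct_left_um, ct_right_um]
#   LM:   sample_id, length_um, mass_pg, mean_thickness_um[, central_area]
#   meta: sample_id, station, month, depth_m, cell_density_l
# All lengths in um, mass in pg, cell density in cells/L. Rows failing a
# validity check are reported with their 1-based data-row index and the read
# aborts, so a returned table is always fully valid.

read_table_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  df[, intersect(c(required, optional), names(df)), drop = FALSE]
}

fail_rows <- function(diagnostics, what) {
  stop(what, " rejected ", length(diagnostics), " row(s):\n  ",
       paste(diagnostics, collapse = "\n  "), call. = FALSE)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a SEM morphometric table
#'
#' One row per SEM-measured coccolith: sample id, morphotype code (one of
#' A, OA, B, M), distal-shield length and width (um), and optionally the
#' central-tube width on each side of the central area (um). Every invalid
#' row is reported with its 1-based data-row index and the read fails, so
#' the returned data frame contains only validated records.
#'
#' Invariants enforced: morphotype in the closed vocabulary; length and
#' width positive and finite with `length >= width` (the distal-shield long
#' axis is the length axis); central-tube widths, when present, nonnegative.
#'
#' @param path path to a CSV file with the canonical SEM header.
#' @return a data frame with columns `sample_id`, `morphotype`, `length_um`,
#'   `width_um`, `ct_left_um`, `ct_right_um` (the latter two `NA` when not
#'   measured).
#' @export
read_sem_table <- function(path) {
  df <- read_table_checked(path,
    required = c("sample_id", "morphotype", "length_um", "width_um"),
    optional = c("ct_left_um", "ct_right_um"))
  if (is.null(df$ct_left_um)) df$ct_left_um <- NA_real_
  if (is.null(df$ct_right_um)) df$ct_right_um <- NA_real_

  out <- data.frame(sample_id = as.character(df$sample_id),
                    morphotype = trimws(as.character(df$morphotype)),
                    length_um = num_or_na(df$length_um),
                    width_um = num_or_na(df$width_um),
                    ct_left_um = num_or_na(df$ct_left_um),
                    ct_right_um = num_or_na(df$ct_right_um),
                    stringsAsFactors = FALSE)
  diag <- character()
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    if (!(r$morphotype %in% MORPHOTYPES)) {
      diag <- c(diag, sprintf(
        "row %d: unknown morphotype code '%s' (expected one of %s)",
        i, r$morphotype, paste(MORPHOTYPES, collapse = ", ")))
      next
    }
    if (is.na(r$length_um) || is.na(r$width_um) ||
        !is.finite(r$length_um) || !is.finite(r$width_um)) {
      diag <- c(diag, sprintf("row %d: non-numeric length/width", i))
      next
    }
    if (r$length_um <= 0 || r$width_um <= 0) {
      diag <- c(diag, sprintf("row %d: length and width must be > 0", i))
      next
    }
    if (r$length_um < r$width_um) {
      diag <- c(diag, sprintf(
        "row %d: length (%.3g) < width (%.3g); axis convention violated",
        i, r$length_um, r$width_um))
      next
    }
    ct <- c(r$ct_left_um, r$ct_right_um)
    if (any(!is.na(ct) & ct < 0)) {
      diag <- c(diag, sprintf("row %d: central-tube width must be >= 0", i))
    }
  }
  if (length(diag) > 0) fail_rows(diag, "read_sem_table")
  out
}

#' Read a light-microscope measurement table
#'
#' One row per LM-measured coccolith: sample id, length (um), mass (pg),
#' mean thickness (um) and the central-area class (`open`,
#' `overcalcified`, or `unknown`; only overcalcified Type A is
#' distinguishable in the light microscope). When the `central_area` column
#' is absent it defaults to `"unknown"`. Enforces finite values, positive
#' length and thickness, nonnegative mass, and `mean_thickness < length`.
#'
#' @param path path to a CSV file with the canonical LM header.
#' @return a data frame with columns `sample_id`, `length_um`, `mass_pg`,
#'   `mean_thickness_um`, `central_area`.
#' @export
read_lm_table <- function(path) {
  df <- read_table_checked(path,
    required = c("sample_id", "length_um", "mass_pg", "mean_thickness_um"),
    optional = "central_area")
  if (is.null(df$central_area)) df$central_area <- "unknown"

  out <- data.frame(sample_id = as.character(df$sample_id),
                    length_um = num_or_na(df$length_um),
                    mass_pg = num_or_na(df$mass_pg),
                    mean_thickness_um = num_or_na(df$mean_thickness_um),
                    central_area = trimws(as.character(df$central_area)),
                    stringsAsFactors = FALSE)
  diag <- character()
  for (i in seq_len(nrow(out))) {
    r <- out[i, ]
    if (!(r$central_area %in% CENTRAL_AREA_CODES)) {
      diag <- c(diag, sprintf(
        "row %d: unknown central_area code '%s' (expected one of %s)",
        i, r$central_area, paste(CENTRAL_AREA_CODES, collapse = ", ")))
      next
    }
    vals <- c(r$length_um, r$mass_pg, r$mean_thickness_um)
    if (any(is.na(vals)) || any(!is.finite(vals))) {
      diag <- c(diag, sprintf("row %d: non-numeric measurement", i))
      next
    }
    if (r$length_um <= 0 || r$mean_thickness_um <= 0 || r$mass_pg < 0) {
      diag <- c(diag, sprintf(
        "row %d: need length > 0, mean_thickness > 0, mass >= 0", i))
      next
    }
    if (r$mean_thickness_um >= r$length_um) {
      diag <- c(diag, sprintf(
        "row %d: mean_thickness (%.3g) must be < length (%.3g)",
        i, r$mean_thickness_um, r$length_um))
    }
  }
  if (length(diag) > 0) fail_rows(diag, "read_lm_table")
  out
}

#' Read per-sample metadata
#'
#' Station, month, depth (m) and cell density (cells/L) per sample id.
#'
#' @param path path to a CSV file with the canonical metadata header.
#' @return a data frame with columns `sample_id`, `station`, `month`,
#'   `depth_m`, `cell_density_l`.
#' @export
read_sample_meta <- function(path) {
  df <- read_table_checked(path,
    required = c("sample_id", "station", "month", "depth_m",
                 "cell_density_l"))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    station = as.character(df$station),
                    month = as.character(df$month),
                    depth_m = num_or_na(df$depth_m),
                    cell_density_l = num_or_na(df$cell_density_l),
                    stringsAsFactors = FALSE)
  diag <- character()
  for (i in seq_len(nrow(out))) {
    if (is.na(out$cell_density_l[i]) || out$cell_density_l[i] < 0) {
      diag <- c(diag, sprintf("row %d: cell_density_l must be >= 0", i))
    }
  }
  if (length(diag) > 0) fail_rows(diag, "read_sample_meta")
  out
}

#' Write a SEM or LM table in the canonical CSV schema
#'
#' Inverse of [read_sem_table()] / [read_lm_table()]: writing a validated
#' record table and re-reading it reproduces the records exactly.
#'
#' @param records a data frame as returned by the corresponding reader.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sem_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sem_table
#' @export
write_lm_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
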