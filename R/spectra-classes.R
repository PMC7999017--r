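#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` is one acquisition: a strictly increasing Raman-shift
#' axis (cm^-1), the measured intensities (arbitrary units) and free-form
#' acquisition metadata (subject id, group label, map position, substrate).
#'
#' @param shifts Numeric vector of Raman shifts in cm^-1, strictly increasing.
#' @param intensities Numeric vector of intensities (a.u.), same length as
#'   `shifts`, all finite.
#' @param meta Named list of metadata (e.g. `subject_id`, `group`, `map_x`,
#'   `map_y`, `substrate`).
#' @return An object of class `raman_spectrum` with elements `shifts`,
#'   `intensities` and `meta`.
#' @export
raman_spectrum <- function(shifts, intensities, meta = list()) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities)) {
    stop("`shifts` and `intensities` must have the same length")
  }
  if (length(shifts) < 1L) stop("empty spectrum")
  if (anyNA(shifts) || any(!is.finite(intensities))) {
    stop("spectrum contains non-finite values")
  }
  if (is.unsorted(shifts, strictly = TRUE)) {
    stop("`shifts` must be strictly increasing")
  }
  structure(list(shifts = shifts, intensities = intensities, meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm-1\n",
              length(x$shifts), min(x$shifts), max(x$shifts)))
  if (!is.null(x$meta$subject_id)) {
    cat(sprintf("  subject %s (%s)\n", x$meta$subject_id,
                x$meta$group %||% "UNKNOWN"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a cohort of spectra
#'
#' A `spectrum_set` holds a list of [raman_spectrum()] objects together with a
#' per-spectrum metadata table (subject id, group label, map position,
#' artifact flag). After resampling all spectra share one common grid and the
#' set can be flattened into a matrix with [spectra_matrix()].
#'
#' @param spectra List of `raman_spectrum` objects.
#' @param meta Data frame with one row per spectrum; must contain columns
#'   `subject_id` and `group` (values `COPD`, `CTRL` or `UNKNOWN`).
#' @param resampled Logical: do all spectra share one identical grid?
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, meta, resampled = FALSE) {
  if (!is.list(spectra) || !all(vapply(spectra, inherits, TRUE, "raman_spectrum"))) {
    stop("`spectra` must be a list of raman_spectrum objects")
  }
  meta <- as.data.frame(meta)
  if (nrow(meta) != length(spectra)) {
    stop("`meta` must have one row per spectrum")
  }
  for (col in c("subject_id", "group")) {
    if (!col %in% names(meta)) stop("`meta` must contain column '", col, "'")
  }
  bad <- !meta$group %in% c("COPD", "CTRL", "UNKNOWN")
  if (any(bad)) {
    stop("unknown group label(s): ", paste(unique(meta$group[bad]), collapse = ", "))
  }
  grid <- NULL
  if (resampled && length(spectra) > 0L) {
    grid <- spectra[[1L]]$shifts
    same <- vapply(spectra, function(s) {
      length(s$shifts) == length(grid) && all(s$shifts == grid)
    }, TRUE)
    if (!all(same)) stop("resampled = TRUE but spectra do not share one grid")
  }
  structure(list(spectra = spectra, meta = meta,
                 resampled = resampled, grid = grid),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra (%s)%s\n", length(x$spectra),
              paste(sprintf("%s: %d", names(table(x$meta$group)),
                            table(x$meta$group)), collapse = ", "),
              if (x$resampled) sprintf(", common grid of %d points", length(x$grid)) else ""))
  invisible(x)
}

#' Number of spectra in a set
#' @param x A `spectrum_set`.
#' @return Integer count.
#' @export
n_spectra <- function(x) length(x$spectra)

#' Flatten a resampled set into a spectra-by-wavenumber matrix
#'
#' @param x A `spectrum_set` whose spectra share one common grid.
#' @return Numeric matrix, one row per spectrum, columns named by the grid.
#' @export
spectra_matrix <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  if (n_spectra(x) == 0L) stop("empty spectrum set")
  grid <- x$spectra[[1L]]$shifts
  same <- vapply(x$spectra, function(s) {
    length(s$shifts) == length(grid) && all(s$shifts == grid)
  }, TRUE)
  if (!all(same)) stop("spectra are not on a common grid; resample first")
  m <- t(vapply(x$spectra, function(s) s$intensities, numeric(length(grid))))
  colnames(m) <- format(grid, trim = TRUE)
  m
}

#' Subset a spectrum set
#' @param x A `spectrum_set`.
#' @param i Integer or logical index over spectra.
#' @return A `spectrum_set` with the selected spectra and metadata rows.
#' @export
subset_spectra <- function(x, i) {
  stopifnot(inherits(x, "spectrum_set"))
  spectrum_set(x$spectra[i], x$meta[i, , drop = FALSE], resampled = x$resampled)
}

same_axis <- function(a, b, tol = 1e-9) {
  length(a$shifts) == length(b$shifts) &&
    max(abs(a$shifts - b$shifts)) <= tol * max(1, max(abs(a$shifts)))
}
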