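#' Load a peak attribution table
#'
#' The packaged table merges the reference saliva band catalog (band
#' position, molecular class, assignment, matching tolerance +/- 4 cm^-1)
#' with the group in which each differential band is more abundant (COPD,
#' CTRL, or `none` for non-differential bands). User tables in the same CSV
#' format (`shift,class,assignment,enriched_group`) are accepted.
#'
#' @param path Optional path to a user CSV; default: the packaged catalog.
#' @param tolerance Matching tolerance in cm^-1 (default 4).
#' @return Data frame of class `attribution_table` with attribute
#'   `tolerance`.
#' @export
read_attribution_table <- function(path = NULL, tolerance = 4) {
  if (is.null(path)) {
    path <- system.file("extdata", "saliva_band_catalog.csv",
                        package = "salifinger")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("shift", "class", "assignment")) {
    if (!col %in% names(tab)) stop("attribution table lacks column '", col, "'")
  }
  if (!"enriched_group" %in% names(tab)) tab$enriched_group <- "none"
  if (anyDuplicated(tab$shift)) stop("attribution table shifts must be unique")
  if (tolerance <= 0) stop("tolerance must be positive")
  tab <- tab[order(tab$shift), ]
  attr(tab, "tolerance") <- tolerance
  class(tab) <- c("attribution_table", "data.frame")
  tab
}

#' Pointwise group mean and standard deviation spectrum
#'
#' @param set A resampled [spectrum_set()] (or spectra-by-grid matrix with a
#'   `labels` argument).
#' @param group Group label to average (`"COPD"` or `"CTRL"`).
#' @param labels Optional label vector when `set` is a matrix.
#' @return A list of class `mean_spectrum`: `grid`, `mean`, `sd` (sample SD,
#'   n-1 denominator), `n`, `group`.
#' @export
group_mean_sd <- function(set, group, labels = NULL) {
  if (inherits(set, "spectrum_set")) {
    m <- spectra_matrix(set)
    labels <- set$meta$group
    grid <- set$spectra[[1L]]$shifts
  } else {
    m <- as.matrix(set)
    if (is.null(labels)) stop("`labels` required when `set` is a matrix")
    grid <- as.numeric(colnames(m))
    if (anyNA(grid)) grid <- seq_len(ncol(m))
  }
  keep <- labels == group
  if (!any(keep)) stop("unknown or absent group: ", group)
  if (sum(keep) < 2L) stop("need at least 2 spectra in group ", group)
  m <- m[keep, , drop = FALSE]
  structure(list(grid = grid, mean = colMeans(m), sd = apply(m, 2, stats::sd),
                 n = nrow(m), group = group),
            class = "mean_spectrum")
}

#' Difference spectrum with error propagation
#'
#' Pointwise difference of two group mean spectra (conventionally
#' COPD - CTRL) with the propagated error `sqrt(sd_a^2 + sd_b^2)` computed
#' from the two spectral standard deviations.
#'
#' @param a,b `mean_spectrum` objects on a common grid; the difference is
#'   `a - b`.
#' @return A list of class `difference_spectrum`: `grid`, `delta`, `error`,
#'   `groups`.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "mean_spectrum"), inherits(b, "mean_spectrum"))
  if (length(a$grid) != length(b$grid) || any(a$grid != b$grid)) {
    stop("grid mismatch between the two mean spectra")
  }
  structure(list(grid = a$grid, delta = a$mean - b$mean,
                 error = sqrt(a$sd^2 + b$sd^2),
                 groups = c(a$group, b$group)),
            class = "difference_spectrum")
}

# Local maxima (strictly above both neighbours) with topographic prominence:
# height above the higher of the two bounding saddles, where each saddle is
# the minimum between the peak and the nearest higher point (or data edge).
find_peaks_core <- function(x, y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(data.frame(position = numeric(0), height = numeric(0),
                                prominence = numeric(0)))
  is_max <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
  if (length(is_max) == 0L) {
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(is_max, function(i) {
    h <- y[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      lmin <- min(lmin, y[j])
      j <- j - 1L
    }
    rmin <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) {
      rmin <- min(rmin, y[j])
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, 0)
  keep <- prom >= min_prominence
  out <- data.frame(position = x[is_max[keep]], height = y[is_max[keep]],
                    prominence = prom[keep])
  out[order(out$position), , drop = FALSE]
}

#' Detect peaks in a spectrum
#'
#' Local maxima with topographic prominence at or above `min_prominence`,
#' sorted by position. For difference spectra the search runs on +delta and
#' -delta separately, labelling each peak with the group it points to
#' (COPD for positive, CTRL for negative, under the COPD - CTRL convention).
#'
#' @param x A `raman_spectrum`, `mean_spectrum` or `difference_spectrum`.
#' @param min_prominence Minimum prominence (a.u.). For mean spectra the
#'   default is 3x the median per-point SD; otherwise 0.
#' @param ... Unused.
#' @return Data frame with `position`, `height`, `prominence` (and
#'   `direction` for difference spectra).
#' @export
detect_peaks <- function(x, min_prominence = NULL, ...) UseMethod("detect_peaks")

#' @rdname detect_peaks
#' @export
detect_peaks.raman_spectrum <- function(x, min_prominence = NULL, ...) {
  find_peaks_core(x$shifts, x$intensities, min_prominence %||% 0)
}

#' @rdname detect_peaks
#' @export
detect_peaks.mean_spectrum <- function(x, min_prominence = NULL, ...) {
  if (is.null(min_prominence)) min_prominence <- 3 * stats::median(x$sd)
  find_peaks_core(x$grid, x$mean, min_prominence)
}

#' @rdname detect_peaks
#' @export
detect_peaks.difference_spectrum <- function(x, min_prominence = NULL, ...) {
  mp <- min_prominence %||% 0
  up <- find_peaks_core(x$grid, x$delta, mp)
  dn <- find_peaks_core(x$grid, -x$delta, mp)
  if (nrow(up)) up$direction <- x$groups[1L]
  if (nrow(dn)) {
    dn$height <- -dn$height
    dn$direction <- x$groups[2L]
  }
  out <- rbind(up, dn)
  out[order(out$position), , drop = FALSE]
}

#' Attribute detected peaks to catalog bands
#'
#' Each peak is matched to the nearest catalog shift within the table's
#' tolerance (+/- 4 cm^-1 by default); ties are broken toward the lower
#' shift; peaks with no band within tolerance are reported as unassigned.
#'
#' @param peaks Data frame with a `position` column (as from
#'   [detect_peaks()]).
#' @param table An [read_attribution_table()] table.
#' @return `peaks` with added columns `ref_shift`, `class`, `assignment`
#'   (NA when unassigned).
#' @export
attribute_peaks <- function(peaks, table = read_attribution_table()) {
  stopifnot(is.data.frame(peaks), nrow(table) > 0L)
  tol <- attr(table, "tolerance") %||% 4
  ref <- rep(NA_real_, nrow(peaks))
  cls <- rep(NA_character_, nrow(peaks))
  asg <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    d <- abs(table$shift - peaks$position[i])
    ok <- which(d <= tol)
    if (length(ok)) {
      best <- ok[order(d[ok], table$shift[ok])][1L]
      ref[i] <- table$shift[best]
      cls[i] <- table$class[best]
      asg[i] <- table$assignment[best]
    }
  }
  peaks$ref_shift <- ref
  peaks$class <- cls
  peaks$assignment <- asg
  peaks
}

#' Assign differential peaks to their enriched group
#'
#' Detects peaks in the difference spectrum (both directions) and keeps those
#' whose |delta| reaches `delta_threshold` (0.005 on the normalized intensity
#' scale), assigning each to COPD when delta > 0 and CTRL when delta < 0
#' under the COPD - CTRL convention, attributed against the band catalog.
#'
#' @param diff A [difference_spectrum()] on the normalized intensity scale.
#' @param table An [read_attribution_table()] table.
#' @param delta_threshold Minimum |delta| (default 0.005).
#' @param min_prominence Peak prominence threshold (default:
#'   `delta_threshold`).
#' @return Data frame with `shift`, `delta`, `error`, `enriched_group`,
#'   `ref_shift`, `class`, `assignment`.
#' @export
assign_differential_peaks <- function(diff, table = read_attribution_table(),
                                      delta_threshold = 0.005,
                                      min_prominence = delta_threshold) {
  stopifnot(inherits(diff, "difference_spectrum"))
  pk <- detect_peaks(diff, min_prominence = min_prominence)
  if (nrow(pk) == 0L) {
    return(data.frame(shift = numeric(0), delta = numeric(0),
                      error = numeric(0), enriched_group = character(0),
                      ref_shift = numeric(0), class = character(0),
                      assignment = character(0)))
  }
  pk <- pk[abs(pk$height) >= delta_threshold, , drop = FALSE]
  pk <- attribute_peaks(pk, table)
  data.frame(shift = pk$position, delta = pk$height,
             error = diff$error[match(pk$position, diff$grid)],
             enriched_group = ifelse(pk$height > 0, diff$groups[1L],
                                     diff$groups[2L]),
             ref_shift = pk$ref_shift, class = pk$class,
             assignment = pk$assignment, stringsAsFactors = FALSE)
}
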