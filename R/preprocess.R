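#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain applied to every raw spectrum:
#' fifth-degree polynomial baseline estimated on 79 anchor points with noise
#' measured in 21-point windows, rescaling on the 1001.5 cm^-1 reference band,
#' second-degree Savitzky-Golay smoothing, extraction onto a 985-point grid at
#' 0.98 cm^-1/step, substrate removal and artifact rejection.
#'
#' @param poly_degree Baseline polynomial degree (default 5).
#' @param n_interp_points Number of baseline anchor points (default 79).
#' @param n_noise_points Window length, in points, for the local-noise
#'   estimate (default 21).
#' @param sg_degree,sg_window Savitzky-Golay polynomial degree (default 2)
#'   and odd window length in points (default 9: removes single-pixel spikes
#'   while preserving ~8 cm^-1 bands at 0.8 cm^-1/step).
#' @param ref_shift,ref_halfwidth Reference band center (1001.5 cm^-1) and
#'   half-width (4 cm^-1) of the window whose maximum is scaled to 1.
#' @param norm_mode `"height"` (divide by the window maximum, default) or
#'   `"area"` (divide by the window band area / window width).
#' @param out_start,out_step,out_n_points Extraction grid: default 985 points
#'   at 0.98 cm^-1/step starting at 400 cm^-1 (spanning 400-1364.3 cm^-1).
#' @param substrate_scale_mode `"unit"` (subtract the substrate spectrum as
#'   is, default) or `"lsq"` (non-negative least-squares scale estimated on
#'   peak-free points).
#' @param artifact_baseline_ratio_max Reject a spectrum as
#'   fluorescence-dominated when its baseline-to-peak energy ratio exceeds
#'   this (default 200; typical clean synthetic spectra sit near 10).
#' @param artifact_snr_min Reject as de-focused when the maximum
#'   baseline-corrected peak height is below this multiple of the local noise
#'   (default 10; clean spectra sit near 100).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(poly_degree = 5L, n_interp_points = 79L,
                              n_noise_points = 21L,
                              sg_degree = 2L, sg_window = 9L,
                              ref_shift = 1001.5, ref_halfwidth = 4,
                              norm_mode = c("height", "area"),
                              out_start = 400, out_step = 0.98,
                              out_n_points = 985L,
                              substrate_scale_mode = c("unit", "lsq"),
                              artifact_baseline_ratio_max = 200,
                              artifact_snr_min = 10) {
  norm_mode <- match.arg(norm_mode)
  substrate_scale_mode <- match.arg(substrate_scale_mode)
  cfg <- list(poly_degree = as.integer(poly_degree),
              n_interp_points = as.integer(n_interp_points),
              n_noise_points = as.integer(n_noise_points),
              sg_degree = as.integer(sg_degree),
              sg_window = as.integer(sg_window),
              ref_shift = ref_shift, ref_halfwidth = ref_halfwidth,
              norm_mode = norm_mode,
              out_start = out_start, out_step = out_step,
              out_n_points = as.integer(out_n_points),
              substrate_scale_mode = substrate_scale_mode,
              artifact_baseline_ratio_max = artifact_baseline_ratio_max,
              artifact_snr_min = artifact_snr_min)
  if (cfg$poly_degree < 1L) stop("poly_degree must be >= 1")
  if (cfg$sg_window %% 2L == 0L || cfg$sg_window <= cfg$sg_degree) {
    stop("sg_window must be odd and greater than sg_degree")
  }
  if (cfg$out_n_points < 2L) stop("out_n_points must be >= 2")
  if (cfg$artifact_baseline_ratio_max <= 0 || cfg$artifact_snr_min <= 0) {
    stop("artifact thresholds must be positive")
  }
  class(cfg) <- "preprocess_config"
  cfg
}

# Local noise: sd of the linearly detrended signal in consecutive windows of
# n_win points; the median over windows is robust to windows containing bands.
estimate_noise <- function(y, n_win = 21L) {
  n <- length(y)
  if (n < n_win) stop("spectrum shorter than the noise window")
  starts <- seq(1L, n - n_win + 1L, by = n_win)
  t0 <- seq_len(n_win)
  tc <- t0 - mean(t0)
  stt <- sum(tc^2)
  sds <- vapply(starts, function(s) {
    w <- y[s:(s + n_win - 1L)]
    b <- sum(tc * w) / stt
    r <- w - mean(w) - b * tc
    sqrt(sum(r^2) / (n_win - 2L))
  }, 0)
  stats::median(sds)
}

#' Fit a polynomial baseline
#'
#' Estimates the slowly varying background under the Raman bands: the local
#' noise level is measured as the median standard deviation of the linearly
#' detrended signal in consecutive `n_noise_points` windows; `n_interp_points`
#' anchor points are placed at the local minima of equal-length axis segments;
#' a degree-`poly_degree` polynomial is fitted to the anchors and anchors
#' lying more than twice the noise above the fit (i.e. on bands) are discarded
#' iteratively until none remain.
#'
#' @param spectrum A [raman_spectrum()] with at least `n_interp_points` points.
#' @param config A [preprocess_config()].
#' @return The fitted baseline as a `raman_spectrum` on the same axis.
#' @export
fit_baseline <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  x <- spectrum$shifts
  y <- spectrum$intensities
  n <- length(y)
  if (n < config$n_interp_points) {
    stop("spectrum has fewer points (", n, ") than baseline anchors (",
         config$n_interp_points, ")")
  }
  noise <- estimate_noise(y, config$n_noise_points)
  chunk <- cut(seq_len(n), config$n_interp_points, labels = FALSE)
  anchors <- vapply(split(seq_len(n), chunk),
                    function(ii) ii[which.min(y[ii])], 0L)
  xa <- x[anchors]
  ya <- y[anchors]
  tol <- 2 * noise + 1e-8 * max(diff(range(y)), .Machine$double.xmin)
  fit <- NULL
  repeat {
    fit <- stats::lm(ya ~ stats::poly(xa, config$poly_degree))
    r <- ya - stats::fitted(fit)
    drop <- r > tol
    if (!any(drop) || sum(!drop) < config$poly_degree + 2L) break
    xa <- xa[!drop]
    ya <- ya[!drop]
  }
  bl <- stats::predict(fit, newdata = data.frame(xa = x))
  raman_spectrum(x, as.numeric(bl), spectrum$meta)
}

#' Subtract a baseline from a spectrum
#'
#' Pointwise difference on a shared axis; negative values are kept.
#'
#' @param spectrum,baseline `raman_spectrum` objects on the same axis.
#' @return A `raman_spectrum`.
#' @export
subtract_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(baseline, "raman_spectrum"))
  if (!same_axis(spectrum, baseline)) stop("axis mismatch between spectrum and baseline")
  raman_spectrum(spectrum$shifts, spectrum$intensities - baseline$intensities,
                 spectrum$meta)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of degree `sg_degree` over
#' `sg_window` points; endpoints are handled by the off-center rows of the
#' projection matrix, i.e. by the polynomial fitted within the edge window.
#' A degree-2 filter reproduces constant, linear and quadratic signals
#' exactly while attenuating single-pixel spikes.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return The smoothed `raman_spectrum`.
#' @export
sg_smooth <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (config$sg_window > length(spectrum$intensities)) {
    stop("sg_window exceeds spectrum length")
  }
  y <- signal::sgolayfilt(spectrum$intensities, p = config$sg_degree,
                          n = config$sg_window)
  raman_spectrum(spectrum$shifts, y, spectrum$meta)
}

ref_window_idx <- function(shifts, config) {
  idx <- which(abs(shifts - config$ref_shift) <= config$ref_halfwidth)
  if (length(idx) == 0L) {
    stop("reference window ", config$ref_shift, " +/- ", config$ref_halfwidth,
         " cm-1 does not overlap the axis")
  }
  idx
}

#' Rescale a spectrum on the reference band
#'
#' Divides all intensities by the maximum intensity (or, in `"area"` mode,
#' the mean intensity) inside the reference window (default 1001.5 +/- 4
#' cm^-1, the phenylalanine band), so the window maximum becomes exactly 1.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return The rescaled `raman_spectrum`.
#' @export
normalize_to_reference <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  idx <- ref_window_idx(spectrum$shifts, config)
  scale <- switch(config$norm_mode,
                  height = max(spectrum$intensities[idx]),
                  area = mean(spectrum$intensities[idx]))
  if (!is.finite(scale) || scale <= 0) {
    stop("non-positive reference-band intensity; artifact candidate spectrum")
  }
  raman_spectrum(spectrum$shifts, spectrum$intensities / scale, spectrum$meta)
}

#' Resample a spectrum onto the extraction grid
#'
#' Linear interpolation onto the grid `out_start + k * out_step`,
#' `k = 0 .. out_n_points - 1` (default 985 points at 0.98 cm^-1/step).
#' The grid must lie inside the measured range.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return The resampled `raman_spectrum` of length `out_n_points`.
#' @export
resample_spectrum <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  grid <- config$out_start + (seq_len(config$out_n_points) - 1L) * config$out_step
  eps <- 1e-9 * max(abs(spectrum$shifts))
  if (grid[1L] < min(spectrum$shifts) - eps ||
      grid[length(grid)] > max(spectrum$shifts) + eps) {
    stop("extraction grid extends beyond the measured range")
  }
  y <- stats::approx(spectrum$shifts, spectrum$intensities, xout = grid,
                     rule = 2)$y
  raman_spectrum(grid, y, spectrum$meta)
}

#' Subtract the substrate contribution
#'
#' Removes the shared substrate spectrum from a spectrum on the same grid,
#' either as is (`"unit"` mode) or scaled by a non-negative least-squares
#' coefficient estimated on peak-free points (`"lsq"` mode).
#'
#' @param spectrum,substrate `raman_spectrum` objects on a common grid.
#' @param config A [preprocess_config()].
#' @param peak_free Optional logical or integer index of peak-free points
#'   used by `"lsq"` mode (default: all points).
#' @return The corrected `raman_spectrum`; the applied scale is attached as
#'   attribute `"substrate_scale"`.
#' @export
subtract_substrate <- function(spectrum, substrate,
                               config = preprocess_config(),
                               peak_free = NULL) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(substrate, "raman_spectrum"))
  if (!same_axis(spectrum, substrate)) stop("grid mismatch between spectrum and substrate")
  s <- substrate$intensities
  y <- spectrum$intensities
  scale <- 1
  if (config$substrate_scale_mode == "lsq") {
    idx <- if (is.null(peak_free)) seq_along(y) else peak_free
    denom <- sum(s[idx]^2)
    scale <- if (denom > 0) max(0, sum(s[idx] * y[idx]) / denom) else 0
  }
  out <- raman_spectrum(spectrum$shifts, y - scale * s, spectrum$meta)
  attr(out, "substrate_scale") <- scale
  out
}

#' Per-spectrum artifact statistics
#'
#' Computes the two screening statistics used for artifact rejection on a raw
#' spectrum: the baseline-to-peak energy ratio (mean squared fitted baseline
#' above its minimum, over mean squared positive baseline-corrected signal),
#' which is large for fluorescence-dominated spectra, and the peak
#' signal-to-noise ratio, which is small for z-axis de-focused spectra. The
#' peak height used in the SNR is measured after additionally detrending the
#' baseline-corrected signal with a wide running median, so smooth
#' lack-of-fit of the polynomial does not masquerade as a band.
#'
#' @param spectrum A [raman_spectrum()].
#' @param config A [preprocess_config()].
#' @return List with `baseline_ratio`, `snr`, `noise` and the fitted
#'   `baseline`.
#' @export
artifact_stats <- function(spectrum, config = preprocess_config()) {
  bl <- fit_baseline(spectrum, config)
  corr <- spectrum$intensities - bl$intensities
  noise <- estimate_noise(spectrum$intensities, config$n_noise_points)
  peak_energy <- mean(pmax(corr, 0)^2)
  baseline_energy <- mean((bl$intensities - min(bl$intensities))^2)
  kwide <- min(101L, 2L * ((length(corr) - 1L) %/% 2L) + 1L)
  peak_height <- max(corr - stats::runmed(corr, kwide))
  list(baseline_ratio = if (peak_energy > 0) baseline_energy / peak_energy else Inf,
       snr = if (noise > 0) peak_height / noise else Inf,
       noise = noise, baseline = bl)
}

#' Partition a cohort into kept and rejected (artifact) spectra
#'
#' Rejects a spectrum when its baseline-to-peak energy ratio exceeds
#' `artifact_baseline_ratio_max` (fluorescence) or its peak SNR falls below
#' `artifact_snr_min` (de-focus). The partition is exhaustive and disjoint.
#'
#' @param set A [spectrum_set()] of raw spectra.
#' @param config A [preprocess_config()].
#' @return List with `kept` and `rejected` spectrum sets and a `stats` data
#'   frame (`baseline_ratio`, `snr`, `rejected`, `reason`).
#' @export
detect_artifacts <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectrum_set"))
  n <- n_spectra(set)
  st <- data.frame(baseline_ratio = numeric(n), snr = numeric(n),
                   rejected = logical(n), reason = rep("", n),
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- artifact_stats(set$spectra[[i]], config)
    st$baseline_ratio[i] <- a$baseline_ratio
    st$snr[i] <- a$snr
    if (a$baseline_ratio > config$artifact_baseline_ratio_max) {
      st$rejected[i] <- TRUE
      st$reason[i] <- "fluorescence"
    } else if (a$snr < config$artifact_snr_min) {
      st$rejected[i] <- TRUE
      st$reason[i] <- "defocus"
    }
  }
  if (all(st$rejected)) {
    warning("artifact screening rejected every spectrum")
  }
  list(kept = subset_spectra(set, !st$rejected),
       rejected = subset_spectra(set, st$rejected),
       stats = st)
}

#' Full preprocessing chain
#'
#' Applies, per spectrum: baseline fit and subtraction, reference-band
#' rescaling, Savitzky-Golay smoothing, extraction onto the 985-point grid,
#' substrate removal (the supplied substrate spectrum is itself
#' baseline-corrected, smoothed and resampled before subtraction) and a final
#' rescale restoring the reference-band convention (window maximum exactly 1,
#' which smoothing, interpolation and substrate removal perturb slightly).
#' Artifact spectra are screened on the raw data and excluded from the output.
#'
#' @param set A [spectrum_set()] of raw spectra.
#' @param substrate Optional substrate `raman_spectrum` on the acquisition
#'   axis.
#' @param config A [preprocess_config()].
#' @return List with `processed` (resampled, normalized, artifact-free
#'   [spectrum_set()]), `rejected` (artifact set) and `counts` (named vector
#'   of per-stage spectrum counts).
#' @export
preprocess_pipeline <- function(set, substrate = NULL,
                                config = preprocess_config()) {
  stopifnot(inherits(set, "spectrum_set"))
  screened <- detect_artifacts(set, config)
  kept <- screened$kept
  sub_p <- NULL
  if (!is.null(substrate)) {
    sub_p <- resample_spectrum(
      sg_smooth(subtract_baseline(substrate, fit_baseline(substrate, config)),
                config),
      config)
  }
  out <- vector("list", n_spectra(kept))
  for (i in seq_along(out)) {
    sp <- kept$spectra[[i]]
    sp <- subtract_baseline(sp, fit_baseline(sp, config))
    sp <- normalize_to_reference(sp, config)
    sp <- sg_smooth(sp, config)
    sp <- resample_spectrum(sp, config)
    if (!is.null(sub_p)) sp <- subtract_substrate(sp, sub_p, config)
    # restore the reference-band convention exactly
    idx <- ref_window_idx(sp$shifts, config)
    sp <- raman_spectrum(sp$shifts, sp$intensities / max(sp$intensities[idx]),
                         sp$meta)
    out[[i]] <- sp
  }
  processed <- spectrum_set(out, kept$meta, resampled = TRUE)
  counts <- c(input = n_spectra(set),
              rejected_fluorescence = sum(screened$stats$reason == "fluorescence"),
              rejected_defocus = sum(screened$stats$reason == "defocus"),
              processed = n_spectra(processed))
  list(processed = processed, rejected = screened$rejected, counts = counts)
}
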