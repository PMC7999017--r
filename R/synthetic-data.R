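#' Default saliva SERS peak catalog for the synthetic generator
#'
#' Builds the generator's peak table from the packaged saliva band catalog:
#' one Gaussian band per catalog entry, with invented but realistic relative
#' amplitudes (the 1001 cm^-1 phenylalanine/tryptophan band is the strongest
#' and serves as the normalization reference) and half-widths of 3-6 cm^-1
#' (full widths 6-12 cm^-1, typical of SERS bands of biofluids).
#'
#' Group-differential bands carry a multiplier on the amplitude of the
#' enriched group. The 1001 cm^-1 reference band is deliberately kept
#' group-neutral: spectra are rescaled on that band during preprocessing, so
#' any enrichment put there would reappear, sign-flipped, on every other band.
#'
#' @param enriched_multiplier Amplitude multiplier applied to each band in the
#'   group where it is more abundant (default 1.15, a moderate effect).
#' @return Data frame with columns `center`, `width` (half-width at half
#'   maximum, cm^-1), `base_amplitude`, `copd_multiplier`, `ctrl_multiplier`,
#'   `class`, `assignment`, `enriched_group`.
#' @export
default_peak_catalog <- function(enriched_multiplier = 1.15) {
  tab <- read_attribution_table()
  amp <- c(`441` = 0.45, `471` = 0.25, `499` = 0.25, `524` = 0.5,
           `543` = 0.4, `560` = 0.25, `587` = 0.4, `621` = 0.3,
           `715` = 0.35, `746` = 0.3, `778` = 0.3, `812` = 0.25,
           `924` = 0.35, `937` = 0.3, `948` = 0.3, `962` = 0.25,
           `979` = 0.25, `1001` = 1.0, `1051` = 0.4, `1077` = 0.3,
           `1104` = 0.3, `1126` = 0.35, `1161` = 0.3, `1195` = 0.25,
           `1242` = 0.35, `1267` = 0.45, `1284` = 0.35, `1301` = 0.4,
           `1382` = 0.25, `1409` = 0.25, `1450` = 0.45, `1454` = 0.45,
           `1515` = 0.2)
  n <- nrow(tab)
  cat <- data.frame(
    center = tab$shift,
    width = rep(c(3.2, 4.0, 3.6, 4.6, 5.2, 3.0), length.out = n),
    base_amplitude = as.numeric(amp[as.character(tab$shift)]),
    copd_multiplier = 1,
    ctrl_multiplier = 1,
    class = tab$class,
    assignment = tab$assignment,
    enriched_group = tab$enriched_group,
    stringsAsFactors = FALSE
  )
  is_ref <- cat$center == 1001
  cat$copd_multiplier[cat$enriched_group == "COPD" & !is_ref] <- enriched_multiplier
  cat$ctrl_multiplier[cat$enriched_group == "CTRL"] <- enriched_multiplier
  cat
}

#' Configuration of a synthetic SERS cohort
#'
#' Describes the study conditions the generator emulates: 15 subjects per
#' group each mapped with at least 25 acquisition points, a 400-1600 cm^-1
#' axis at 0.8 cm^-1/step, Gaussian bands on a fluorescence-like random
#' fifth-degree polynomial background plus a fixed broadband substrate
#' contribution, multiplicative log-normal between-subject variability
#' (larger in CTRL, whose average spectra are the more heterogeneous),
#' per-spectrum intensity jitter, shot-like i.i.d. noise, occasional
#' cosmic-ray spikes, and a configurable fraction of artifact spectra.
#'
#' @param n_subjects_per_group Subjects per group (default 15).
#' @param spectra_per_subject Map acquisitions per subject (default 25).
#' @param axis_start,axis_end,axis_step Acquisition axis in cm^-1
#'   (default 400-1600 at 0.8).
#' @param peak_catalog Peak table as from [default_peak_catalog()].
#' @param baseline_intercept_range,baseline_coefficients_range Bounds for the
#'   random degree-5 polynomial background: the intercept and the higher-order
#'   coefficients on the axis rescaled to \[-1, 1\].
#' @param noise_sd I.i.d. Gaussian noise, in units of the 1001 cm^-1 band
#'   amplitude.
#' @param subject_effect_sd Log-scale SD of the per-subject, per-band
#'   log-normal amplitude effect; a named vector `c(COPD = ..., CTRL = ...)`
#'   or a single value for both groups.
#' @param amplitude_jitter_sd Log-scale SD of the per-spectrum global
#'   intensity jitter.
#' @param spike_rate Expected cosmic-ray spikes per spectrum (Poisson).
#' @param spike_amplitude Spike height, same units as amplitudes.
#' @param artifact_rate Fraction of spectra replaced by artifact spectra
#'   (fluorescence-dominated or z-axis de-focus).
#' @param substrate_amplitude Maximum of the shared substrate spectrum.
#' @param seed Integer seed; the same seed reproduces the cohort bit for bit.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = 15L,
                          spectra_per_subject = 25L,
                          axis_start = 400, axis_end = 1600, axis_step = 0.8,
                          peak_catalog = default_peak_catalog(),
                          baseline_intercept_range = c(0.8, 1.6),
                          baseline_coefficients_range = c(-0.25, 0.25),
                          noise_sd = 0.01,
                          subject_effect_sd = c(COPD = 0.05, CTRL = 0.10),
                          amplitude_jitter_sd = 0.05,
                          spike_rate = 0.1,
                          spike_amplitude = 5,
                          artifact_rate = 0,
                          substrate_amplitude = 0.3,
                          seed = 1L) {
  cfg <- list(n_subjects_per_group = as.integer(n_subjects_per_group),
              spectra_per_subject = as.integer(spectra_per_subject),
              axis_start = axis_start, axis_end = axis_end,
              axis_step = axis_step, peak_catalog = peak_catalog,
              baseline_intercept_range = baseline_intercept_range,
              baseline_coefficients_range = baseline_coefficients_range,
              noise_sd = noise_sd,
              subject_effect_sd = subject_effect_sd,
              amplitude_jitter_sd = amplitude_jitter_sd,
              spike_rate = spike_rate, spike_amplitude = spike_amplitude,
              artifact_rate = artifact_rate,
              substrate_amplitude = substrate_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!(cfg$axis_start < cfg$axis_end)) stop("axis_start must be < axis_end")
  if (cfg$axis_step <= 0) stop("axis_step must be positive")
  if (cfg$spectra_per_subject < 1L) stop("spectra_per_subject must be >= 1")
  if (cfg$n_subjects_per_group < 1L) stop("n_subjects_per_group must be >= 1")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stop("artifact_rate must be in [0, 1]")
  }
  pk <- cfg$peak_catalog
  if (any(pk$width <= 0)) stop("peak widths must be positive")
  if (any(pk$base_amplitude < 0) || any(pk$copd_multiplier < 0) ||
      any(pk$ctrl_multiplier < 0)) stop("amplitudes must be non-negative")
  if (any(pk$center < cfg$axis_start | pk$center > cfg$axis_end)) {
    stop("peak centers must lie within the axis range")
  }
  if (cfg$substrate_amplitude < 0) stop("substrate_amplitude must be >= 0")
  invisible(cfg)
}

cohort_axis <- function(config) {
  seq(config$axis_start, config$axis_end, by = config$axis_step)
}

group_effect_sd <- function(config, group) {
  s <- config$subject_effect_sd
  if (length(s) == 1L) return(unname(s))
  unname(s[[group]])
}

#' Generate the shared substrate spectrum
#'
#' The substrate contribution is a smooth broadband profile (a sum of four
#' wide Gaussians with seed-determined centers, widths and weights, rescaled
#' so its maximum equals `substrate_amplitude`). The exact same spectrum is
#' embedded additively in every non-artifact spectrum of the cohort, mimicking
#' the reproducible background of the metallic support.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A `raman_spectrum` on the configured axis; the drawn component
#'   parameters are attached as attribute `"components"` and the rescaling
#'   factor as `"scale"`.
#' @export
generate_substrate_spectrum <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  axis <- cohort_axis(config)
  set.seed(seed + 424243L)
  k <- 4L
  comp <- data.frame(center = stats::runif(k, config$axis_start, config$axis_end),
                     width = stats::runif(k, 120, 300),
                     weight = stats::runif(k, 0.4, 1))
  prof <- rep(0, length(axis))
  for (i in seq_len(k)) {
    prof <- prof + comp$weight[i] *
      exp(-(axis - comp$center[i])^2 / (2 * comp$width[i]^2))
  }
  scale <- if (max(prof) > 0) config$substrate_amplitude / max(prof) else 0
  sp <- raman_spectrum(axis, prof * scale, meta = list(kind = "substrate"))
  attr(sp, "components") <- comp
  attr(sp, "scale") <- scale
  sp
}

# Unit-height Gaussian band matrix: axis points x peaks. `width` is HWHM.
peak_basis <- function(axis, catalog) {
  sigma <- catalog$width / sqrt(2 * log(2))
  vapply(seq_len(nrow(catalog)), function(i) {
    exp(-(axis - catalog$center[i])^2 / (2 * sigma[i]^2))
  }, numeric(length(axis)))
}

#' Generate a synthetic SERS cohort with ground truth
#'
#' Each spectrum is the sum of the catalog's Gaussian bands (amplitude =
#' base amplitude x group multiplier x per-subject log-normal effect x
#' per-spectrum jitter), a random fifth-degree polynomial fluorescence-like
#' baseline, the shared substrate spectrum, i.i.d. Gaussian noise and
#' occasional single-point cosmic-ray spikes. Randomness is drawn from one
#' seeded stream per subject (sub-seed = seed + 100003 x group index +
#' 1009 x subject index), so extending the cohort with more subjects leaves
#' existing subjects unchanged. If `artifact_rate > 0` a fraction of spectra
#' is replaced by artifacts via [inject_artifacts()].
#'
#' @param config A [cohort_config()].
#' @return List with `set` (a [spectrum_set()]) and `truth`, a list holding
#'   the per-spectrum record table (`records`: subject, group, artifact type),
#'   the true band `amplitudes` matrix, the `baseline_coefficients` matrix
#'   (intercept and u^1..u^5 terms on the axis rescaled to \[-1, 1\]) and the
#'   `substrate` spectrum.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  axis <- cohort_axis(config)
  n_axis <- length(axis)
  u <- 2 * (axis - config$axis_start) / (config$axis_end - config$axis_start) - 1
  upow <- vapply(0:5, function(k) u^k, numeric(n_axis))
  substrate <- generate_substrate_spectrum(config)
  basis <- peak_basis(axis, config$peak_catalog)
  npk <- nrow(config$peak_catalog)
  mult <- cbind(COPD = config$peak_catalog$copd_multiplier,
                CTRL = config$peak_catalog$ctrl_multiplier)

  spectra <- list()
  rec <- list()
  amps_all <- list()
  bl_all <- list()
  idx <- 0L
  for (g in c("COPD", "CTRL")) {
    g_i <- match(g, c("COPD", "CTRL"))
    s_sd <- group_effect_sd(config, g)
    for (j in seq_len(config$n_subjects_per_group)) {
      set.seed(config$seed + 100003L * g_i + 1009L * j)
      sid <- sprintf("%s_%02d", g, j)
      subj_eff <- stats::rlnorm(npk, meanlog = -s_sd^2 / 2, sdlog = s_sd)
      for (s in seq_len(config$spectra_per_subject)) {
        idx <- idx + 1L
        jit <- stats::rlnorm(1, -config$amplitude_jitter_sd^2 / 2,
                             config$amplitude_jitter_sd)
        amps <- config$peak_catalog$base_amplitude * mult[, g] * subj_eff * jit
        coefs <- c(stats::runif(1, config$baseline_intercept_range[1],
                                config$baseline_intercept_range[2]),
                   stats::runif(5, config$baseline_coefficients_range[1],
                                config$baseline_coefficients_range[2]))
        y <- drop(basis %*% amps) + drop(upow %*% coefs) +
          substrate$intensities +
          stats::rnorm(n_axis, 0, config$noise_sd)
        nspike <- stats::rpois(1, config$spike_rate)
        if (nspike > 0) {
          at <- sample.int(n_axis, nspike)
          y[at] <- y[at] + stats::runif(nspike, 0.5, 1) * config$spike_amplitude
        }
        spectra[[idx]] <- raman_spectrum(axis, y, meta = list(
          subject_id = sid, group = g,
          map_x = (s - 1L) %% 5L, map_y = (s - 1L) %/% 5L,
          substrate = "aluminum"))
        rec[[idx]] <- data.frame(spectrum_id = idx, subject_id = sid,
                                 group = g, map_x = (s - 1L) %% 5L,
                                 map_y = (s - 1L) %/% 5L,
                                 artifact = "none", stringsAsFactors = FALSE)
        amps_all[[idx]] <- amps
        bl_all[[idx]] <- coefs
      }
    }
  }
  records <- do.call(rbind, rec)
  meta <- records[, c("spectrum_id", "subject_id", "group", "map_x", "map_y")]
  meta$artifact_flag <- FALSE
  set <- spectrum_set(spectra, meta)
  truth <- list(records = records,
                amplitudes = do.call(rbind, amps_all),
                baseline_coefficients = do.call(rbind, bl_all),
                substrate = substrate,
                catalog = config$peak_catalog)
  colnames(truth$amplitudes) <- as.character(config$peak_catalog$center)
  out <- list(set = set, truth = truth)
  if (config$artifact_rate > 0) {
    out <- inject_artifacts(set, config$artifact_rate,
                            seed = config$seed + 777L, truth = truth)
  }
  out
}

#' Replace a fraction of spectra with artifact spectra
#'
#' Emulates the two artifact types removed during preprocessing:
#' fluorescence-dominated spectra (a broad background at least ten times the
#' band amplitudes is added) and z-axis de-focus spectra (bands attenuated
#' below the noise floor, leaving only the smooth background). The number of
#' artifacts is `round(rate * n)`; flags are recorded in the ground truth.
#'
#' @param set A [spectrum_set()].
#' @param rate Fraction in \[0, 1\] of spectra to replace.
#' @param seed Integer seed for the selection and artifact shapes.
#' @param truth Optional ground-truth list to update (as from
#'   [generate_cohort()]).
#' @return List with the modified `set` and updated `truth`.
#' @export
inject_artifacts <- function(set, rate, seed = 1L, truth = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  n <- n_spectra(set)
  n_flag <- as.integer(round(rate * n))
  if (is.null(truth)) {
    truth <- list(records = data.frame(spectrum_id = seq_len(n),
                                       artifact = "none",
                                       stringsAsFactors = FALSE))
  }
  if (n_flag == 0L) return(list(set = set, truth = truth))
  set.seed(seed)
  pick <- sample.int(n, n_flag)
  type <- sample(c("fluorescence", "defocus"), n_flag, replace = TRUE)
  for (k in seq_len(n_flag)) {
    i <- pick[k]
    sp <- set$spectra[[i]]
    y <- sp$intensities
    x <- sp$shifts
    if (type[k] == "fluorescence") {
      amp <- 10 * diff(range(y))
      c0 <- stats::runif(1, min(x), max(x))
      w0 <- stats::runif(1, 250, 500)
      y <- y + amp * (0.3 + exp(-(x - c0)^2 / (2 * w0^2)))
    } else {
      bg <- stats::runmed(y, k = min(151L, 2L * (length(y) %/% 2L) - 1L))
      noise <- stats::mad(diff(y)) / sqrt(2)
      y <- bg + stats::rnorm(length(y), 0, noise)
    }
    set$spectra[[i]] <- raman_spectrum(x, y, sp$meta)
    truth$records$artifact[i] <- type[k]
    if ("artifact_flag" %in% names(set$meta)) set$meta$artifact_flag[i] <- TRUE
  }
  list(set = set, truth = truth)
}

#' Study-condition presets for the generator
#'
#' `strong_separation_config()` is the regime in which the clinical study
#' reports near-perfect classification: every differential band's group-mean
#' amplitude difference is at least five times the within-group standard
#' deviation (multiplier 1.35 against a combined within-group coefficient of
#' variation of about 6%, i.e. roughly 5-8 sigma at each band), with a 2%
#' artifact fraction. `null_cohort_config()` removes every group effect (all
#' multipliers 1) and the between-subject random effects, making spectra
#' exchangeable across group labels; any leakage-free classifier run on it
#' must perform at chance. (Subject effects have to go too: spectrum-level
#' cross-validation leaves siblings of the held-out spectrum in training, so
#' a cohort with subject-level structure is genuinely — not spuriously —
#' classifiable above chance by subject memorization even without any group
#' effect. That is a caveat of spectrum-level validation, not a bug.)
#'
#' @param seed Integer seed.
#' @param n_subjects_per_group,spectra_per_subject Cohort dimensions
#'   (defaults 15 x 16).
#' @param artifact_rate Artifact fraction (strong preset default 0.02).
#' @return A [cohort_config()].
#' @export
strong_separation_config <- function(seed = 1L, n_subjects_per_group = 15L,
                                     spectra_per_subject = 16L,
                                     artifact_rate = 0.02) {
  cohort_config(n_subjects_per_group = n_subjects_per_group,
                spectra_per_subject = spectra_per_subject,
                peak_catalog = default_peak_catalog(enriched_multiplier = 1.35),
                subject_effect_sd = c(COPD = 0.03, CTRL = 0.03),
                amplitude_jitter_sd = 0.03,
                noise_sd = 0.01,
                artifact_rate = artifact_rate,
                seed = seed)
}

#' @rdname strong_separation_config
#' @export
null_cohort_config <- function(seed = 1L, n_subjects_per_group = 15L,
                               spectra_per_subject = 16L,
                               artifact_rate = 0) {
  cohort_config(n_subjects_per_group = n_subjects_per_group,
                spectra_per_subject = spectra_per_subject,
                peak_catalog = default_peak_catalog(enriched_multiplier = 1),
                subject_effect_sd = c(COPD = 0, CTRL = 0),
                amplitude_jitter_sd = 0.03,
                noise_sd = 0.01,
                artifact_rate = artifact_rate,
                seed = seed)
}
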