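#' Read a two-column spectrum file
#'
#' Canonical on-disk format is CSV with header `wavenumber_cm-1,intensity`,
#' but the delimiter (comma, tab or semicolon) is auto-detected and the
#' header is optional, since instrument exports vary. A non-increasing axis
#' is sorted into ascending order with a warning.
#'
#' @param path Path to a spectrum file.
#' @param meta Optional metadata list attached to the spectrum.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error in ", path, ": empty file")
  sep <- detect_delimiter(lines[[1L]])
  first <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  data_lines <- if (has_header) lines[-1L] else lines
  offset <- if (has_header) 1L else 0L
  if (length(data_lines) == 0L) stop("parse error in ", path, ": no data rows")
  parts <- strsplit(data_lines, sep, fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L)) {
    stop("parse error in ", path, ": fewer than 2 columns at line ",
         which(ncols < 2L)[1L] + offset)
  }
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- is.na(x) | is.na(y)
  if (any(bad)) {
    stop("parse error in ", path, ": non-numeric row at line ",
         which(bad)[1L] + offset)
  }
  if (is.unsorted(x, strictly = TRUE)) {
    warning("non-increasing shift axis in ", path, "; sorting ascending")
    o <- order(x)
    x <- x[o]
    y <- y[o]
  }
  raman_spectrum(x, y, meta)
}

detect_delimiter <- function(line) {
  seps <- c(",", "\t", ";")
  counts <- vapply(seps, function(s) {
    length(gregexpr(s, line, fixed = TRUE)[[1L]][gregexpr(s, line, fixed = TRUE)[[1L]] > 0])
  }, 0L)
  if (all(counts == 0L)) return(",")
  seps[which.max(counts)]
}

#' Write a spectrum to a two-column CSV file
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output path.
#' @param digits Significant digits used for formatting (default 15, so a
#'   write/read round trip is exact to ~1e-15 relative).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, digits = 15L) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  df <- data.frame(
    `wavenumber_cm-1` = format(spectrum$shifts, digits = digits, trim = TRUE),
    intensity = format(spectrum$intensities, digits = digits, trim = TRUE),
    check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest and its referenced spectra
#'
#' The manifest is a CSV with columns `file`, `subject_id`, `group` (values
#' `COPD`, `CTRL` or `UNKNOWN`) and optionally `map_x`, `map_y`,
#' `artifact_flag`. File paths are resolved relative to the manifest
#' location unless `spectra_dir` is given.
#'
#' @param path Manifest CSV path.
#' @param spectra_dir Directory holding the spectrum files (default: the
#'   manifest's directory).
#' @return A [spectrum_set()] with metadata attached.
#' @export
read_manifest <- function(path, spectra_dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("file", "subject_id", "group")) {
    if (!col %in% names(man)) stop("manifest lacks required column '", col, "'")
  }
  bad_grp <- !man$group %in% c("COPD", "CTRL", "UNKNOWN")
  if (any(bad_grp)) {
    stop("unknown group label in manifest row(s) ",
         paste(which(bad_grp), collapse = ", "), ": ",
         paste(unique(man$group[bad_grp]), collapse = ", "))
  }
  paths <- file.path(spectra_dir, man$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("manifest references missing file(s) at row(s) ",
         paste(which(missing), collapse = ", "), ": ",
         paste(man$file[missing], collapse = ", "))
  }
  spectra <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    meta <- as.list(man[i, setdiff(names(man), "file"), drop = FALSE])
    spectra[[i]] <- read_spectrum(paths[i], meta = meta)
  }
  meta <- man[, setdiff(names(man), "file"), drop = FALSE]
  if (!"artifact_flag" %in% names(meta)) meta$artifact_flag <- FALSE
  spectrum_set(spectra, meta)
}

#' Write a cohort as spectrum files plus manifest (and ground truth)
#'
#' @param set A [spectrum_set()].
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list from [generate_cohort()]; written
#'   as `ground_truth.csv` (records) and `true_amplitudes.csv`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(set, dir, truth = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_spectra(set)
  files <- sprintf("spectrum_%04d.csv", seq_len(n))
  for (i in seq_len(n)) {
    write_spectrum(set$spectra[[i]], file.path(dir, files[i]))
  }
  man <- cbind(data.frame(file = files, stringsAsFactors = FALSE), set$meta)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth$records, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(truth$amplitudes),
                     file.path(dir, "true_amplitudes.csv"), row.names = FALSE)
  }
  invisible(man_path)
}
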