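#' Demographic characteristics of the printed study cohort
#'
#' Counts per group/characteristic/level of the 15 + 15 subject cohort
#' (sex, smoking habits, COPD phenotype, frequent-exacerbator status),
#' shipped as a packaged CSV. Percentages are recomputed from the counts
#' rather than stored.
#'
#' @return Data frame with columns `group`, `characteristic`, `level`,
#'   `count`, `group_n` and a derived `percent` (rounded to one decimal).
#' @export
study_demographics <- function() {
  path <- system.file("extdata", "cohort_demographics.csv",
                      package = "salifinger")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$percent <- round(100 * d$count / d$group_n, 1)
  d
}

#' Percentage of a demographic level within a group
#'
#' @param group `"COPD"` or `"CTRL"`.
#' @param characteristic Row selector, e.g. `"sex"`.
#' @param level Level within the characteristic, e.g. `"male"`.
#' @param demographics Table as from [study_demographics()].
#' @return Percentage (0-100), rounded to one decimal.
#' @export
demographic_percent <- function(group, characteristic, level,
                                demographics = study_demographics()) {
  row <- demographics[demographics$group == group &
                        demographics$characteristic == characteristic &
                        demographics$level == level, ]
  if (nrow(row) != 1L) stop("no unique demographics row for ", group, "/",
                            characteristic, "/", level)
  row$percent
}
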