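# Missing-data screen: dichotomize completion (1 = score present) per task
# and test whether completion is associated with any measured covariate or
# with the day of study. Report only — no imputation; all available data
# are analysed as-is downstream.

#' Screen missingness for systematic structure
#'
#' For every task column of the completion matrix: the completion rate, and
#' an association test against each covariate — a two-sample Welch t-test
#' for continuous covariates (completers vs non-completers), a chi-squared
#' test for categorical ones. Degenerate task columns (everyone or no one
#' completed) are reported with no test.
#'
#' @param completion A tibble: `subject_id` plus one 0/1 column per task.
#' @param covariates A tibble: `subject_id` plus covariate columns, aligned
#'   by subject.
#' @return A tibble `task`, `rate`, `covariate`, `test`, `statistic`, `p`;
#'   one row per task x covariate (plus a `none` row for degenerate tasks).
#' @export
missingness_screen <- function(completion, covariates = NULL) {
  tasks <- setdiff(names(completion), "subject_id")
  if (!is.null(covariates)) {
    joined <- left_join(completion, covariates, by = "subject_id")
    covs <- setdiff(names(covariates), "subject_id")
  } else {
    joined <- completion
    covs <- character()
  }
  purrr::map_dfr(tasks, function(task) {
    comp <- joined[[task]]
    rate <- mean(comp, na.rm = TRUE)
    if (length(unique(comp[!is.na(comp)])) < 2 || length(covs) == 0) {
      return(tibble(
        task = task, rate = rate, covariate = "none",
        test = "none", statistic = NA_real_, p = NA_real_
      ))
    }
    purrr::map_dfr(covs, function(cv) {
      x <- joined[[cv]]
      ok <- !is.na(x) & !is.na(comp)
      if (is.numeric(x)) {
        if (min(table(comp[ok])) < 2) {
          return(tibble(task = task, rate = rate, covariate = cv,
                        test = "t", statistic = NA_real_, p = NA_real_))
        }
        tt <- stats::t.test(x[ok] ~ comp[ok])
        tibble(task = task, rate = rate, covariate = cv, test = "t",
               statistic = unname(tt$statistic), p = tt$p.value)
      } else {
        ct <- suppressWarnings(
          stats::chisq.test(table(x[ok], comp[ok]))
        )
        tibble(task = task, rate = rate, covariate = cv, test = "chisq",
               statistic = unname(ct$statistic), p = ct$p.value)
      }
    })
  })
}
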