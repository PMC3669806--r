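# Unit-weighted lifestyle factor scores. The Active-Lifestyle (AL) factor
# averages standardized Positive Affect, Mini-K, Conscientiousness,
# Extraversion and Agreeableness; the Sedentary-Lifestyle (SL) factor
# averages standardized BDI, CES-D, Negative Affect, reversed Satisfaction
# with Life and Neuroticism. Openness is accepted in indicator tables but
# excluded from AL.

#' Declared indicator metadata
#'
#' Per-indicator population moments, possible score ranges and internal
#' consistencies used to calibrate the synthetic-data generator and to
#' validate indicator tables.
#'
#' @return A tibble with `indicator`, `factor`, `mean`, `sd`, `min`, `max`,
#'   `alpha` and default generator `loading` (signed: SWL loads negatively
#'   on SL before its analysis-time reversal).
#' @export
indicator_metadata <- function() {
  tibble::tribble(
    ~indicator, ~factor, ~mean,  ~sd,  ~min, ~max, ~alpha, ~loading,
    "CESD",     "SL",    38.42,  6.43,    0,   60,   0.93,     0.72,
    "BDI",      "SL",     4.49,  5.18,    0,   63,   0.90,     0.91,
    "NA",       "SL",    19.86,  6.90,   10,   50,   0.89,     0.82,
    "SWL",      "SL",    25.38,  5.86,    5,   35,   0.93,    -0.61,
    "N",        "SL",    -4.26,  8.29,  -24,   24,   0.82,     0.83,
    "C",        "AL",     7.63,  6.92,  -24,   24,   0.85,     0.74,
    "E",        "AL",     8.34,  6.81,  -24,   24,   0.80,     0.78,
    "A",        "AL",     8.43,  5.98,  -24,   24,   0.72,     0.59,
    "MK",       "AL",     1.22,  0.70,   -3,    3,   0.76,     0.67,
    "PA",       "AL",    36.81,  7.06,   10,   50,   0.93,     0.77
  )
}

#' Specification of a unit-weighted factor
#'
#' @param name Factor name (`"AL"` or `"SL"`, or any label).
#' @param indicators Ordered indicator column names.
#' @param reverse Subset of `indicators` negated after standardization.
#' @param min_present Minimum non-missing indicators required for a score
#'   (default 3).
#' @return A named list.
#' @export
factor_spec <- function(name, indicators, reverse = character(),
                        min_present = 3) {
  if (!all(reverse %in% indicators)) {
    abort("factor_spec: `reverse` must be a subset of `indicators`")
  }
  list(
    name = name, indicators = indicators, reverse = reverse,
    min_present = min_present
  )
}

#' @rdname factor_spec
#' @export
al_factor_spec <- function(min_present = 3) {
  factor_spec("AL", c("PA", "MK", "C", "E", "A"), min_present = min_present)
}

#' @rdname factor_spec
#' @export
sl_factor_spec <- function(min_present = 3) {
  factor_spec("SL", c("BDI", "CESD", "NA", "SWL", "N"),
              reverse = "SWL", min_present = min_present)
}

#' Standardize indicator columns
#'
#' z-scores each requested column over its non-missing entries (sample
#' moments, denominator n - 1). Moments come from the analysis sample
#' itself, so standardization must be re-run after any row filtering.
#'
#' @param table A per-subject indicator tibble.
#' @param cols Columns to standardize (default: all numeric columns).
#' @return The tibble with the columns replaced by their z-scores.
#' @export
standardize_columns <- function(table, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(table)[purrr::map_lgl(table, is.numeric)]
  }
  for (cl in cols) {
    x <- table[[cl]]
    if (sum(!is.na(x)) < 2) {
      abort(paste0("standardize_columns: fewer than 2 values in '", cl, "'"))
    }
    s <- sd(x, na.rm = TRUE)
    if (s == 0) {
      abort(paste0("standardize_columns: zero variance in column '", cl, "'"))
    }
    table[[cl]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Unit-weighted factor scores
#'
#' Scores each subject as the mean of the available standardized indicators,
#' negating the reverse-scored set first. Subjects with fewer than
#' `min_present` non-missing indicators get `NA`.
#'
#' @param ztable A standardized indicator tibble ([standardize_columns()]).
#' @param spec A [factor_spec()].
#' @return A numeric vector, one score per row of `ztable`.
#' @export
unit_weighted_score <- function(ztable, spec) {
  missing_ind <- setdiff(spec$indicators, names(ztable))
  if (length(missing_ind) > 0) {
    abort(paste0(
      "unit_weighted_score: unknown indicator(s): ",
      paste(missing_ind, collapse = ", ")
    ))
  }
  z <- as.matrix(ztable[, spec$indicators, drop = FALSE])
  z[, spec$indicators %in% spec$reverse] <-
    -z[, spec$indicators %in% spec$reverse]
  n_ok <- rowSums(!is.na(z))
  score <- rowMeans(z, na.rm = TRUE)
  score[n_ok < spec$min_present] <- NA_real_
  score
}

#' Score the AL and SL factors for a subject table
#'
#' Standardizes the ten indicator columns and returns per-subject AL and SL
#' composites.
#'
#' @param indicators A tibble with `subject_id` and the indicator columns
#'   named as in [indicator_metadata()].
#' @param al,sl Factor specs (defaults [al_factor_spec()],
#'   [sl_factor_spec()]).
#' @return A tibble `subject_id`, `AL`, `SL`.
#' @export
score_factors <- function(indicators, al = al_factor_spec(),
                          sl = sl_factor_spec()) {
  z <- standardize_columns(
    indicators,
    cols = intersect(union(al$indicators, sl$indicators), names(indicators))
  )
  tibble(
    subject_id = indicators$subject_id,
    AL = unit_weighted_score(z, al),
    SL = unit_weighted_score(z, sl)
  )
}

#' Cronbach's alpha
#'
#' Internal consistency of a subject-by-item score matrix:
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the total),
#' sample variances with denominator n - 1. Rows with any missing item are
#' dropped.
#'
#' @param items A numeric matrix or data frame, subjects in rows, items in
#'   columns (k >= 2 items, >= 3 complete rows).
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) {
    abort("cronbach_alpha: need >= 2 items and >= 3 complete subjects")
  }
  vt <- var(rowSums(m))
  if (vt == 0) abort("cronbach_alpha: zero total-score variance")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / vt)
}

#' Factor-indicator correlation table
#'
#' Pairwise-complete Pearson correlations between each factor score and each
#' indicator, with the per-cell n — the nomological sanity check that every
#' indicator relates to its own composite.
#'
#' @param scores A tibble from [score_factors()] (columns `AL`, `SL`).
#' @param ztable A standardized indicator tibble aligned row-for-row.
#' @param indicators Indicator columns to correlate (default: all shared
#'   with [indicator_metadata()]).
#' @return A tibble `factor`, `indicator`, `r`, `p`, `n`.
#' @export
factor_indicator_corr <- function(scores, ztable, indicators = NULL) {
  if (is.null(indicators)) {
    indicators <- intersect(indicator_metadata()$indicator, names(ztable))
  }
  grid <- tidyr::expand_grid(factor = c("AL", "SL"), indicator = indicators)
  purrr::pmap_dfr(grid, function(factor, indicator) {
    ct <- pearson_ci(scores[[factor]], ztable[[indicator]])
    tibble(factor = factor, indicator = indicator,
           r = ct$r, p = ct$p, n = ct$n)
  })
}
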