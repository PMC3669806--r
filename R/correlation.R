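# Convergent-validity correlation panels: pairwise-complete Pearson r with
# t-based p and Fisher-z confidence intervals, reported with the per-cell n.

#' Pearson correlation with p, n and Fisher-z CI
#'
#' Pairwise-complete Pearson r; two-sided p from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df; 95% CI from the Fisher z
#' transform, atanh(r) +/- z_{.975} / sqrt(n - 3).
#'
#' @param x,y Numeric vectors of equal length (missing pairs dropped).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble `r`, `p`, `n`, `ci_lo`, `ci_hi`; when fewer than
#'   4 complete pairs remain or either variable is constant, `r` is `NA` and
#'   `reason` says why.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  empty <- function(reason) {
    tibble(r = NA_real_, p = NA_real_, n = n,
           ci_lo = NA_real_, ci_hi = NA_real_, reason = reason)
  }
  if (n < 4) return(empty("fewer than 4 complete pairs"))
  if (sd(x) == 0 || sd(y) == 0) return(empty("zero variance"))
  r <- cor(x, y)
  if (abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    p <- 0
  }
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  if (abs(r) < 1) {
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  } else {
    ci <- c(r, r)
  }
  tibble(r = r, p = p, n = n, ci_lo = ci[1], ci_hi = ci[2],
         reason = NA_character_)
}

#' Convergent-validity correlation panel
#'
#' All method-pair correlations of NPV for one period, pairwise-complete,
#' with per-cell n — the bivariate convergent-validity check among Diary,
#' Google-map reconstruction and GPS measures.
#'
#' @param npv A long NPV record tibble (`subject_id`, `method`, `period`,
#'   `npv`).
#' @param period Which period to correlate: `"total4day"`, `"weekday"` or
#'   `"weekend"`.
#' @param methods Methods to include (default the three observed in `npv`).
#' @return A tibble with one row per unordered method pair: `period`,
#'   `method_a`, `method_b`, `r`, `p`, `n`, `ci_lo`, `ci_hi`.
#' @export
correlation_panel <- function(npv, period = "total4day", methods = NULL) {
  pd <- period
  wide <- npv %>%
    filter(.data$period == pd) %>%
    select("subject_id", "method", "npv") %>%
    tidyr::pivot_wider(names_from = "method", values_from = "npv")
  if (is.null(methods)) methods <- setdiff(names(wide), "subject_id")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    ct <- pearson_ci(wide[[pr[1]]], wide[[pr[2]]])
    tibble(period = pd, method_a = pr[1], method_b = pr[2]) %>%
      dplyr::bind_cols(ct[, c("r", "p", "n", "ci_lo", "ci_hi")])
  })
}
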