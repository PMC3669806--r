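# Split-plot GLM with sequential (Type-I) sums of squares.
#
# Variance is partitioned hierarchically by successive orthogonal projection
# in a declared term order: between-subjects terms (AL, SL, AL x SL, the
# subject block factor SID) first, then the within-subjects terms (Time,
# method contrasts, their interactions) and the subject-interaction error
# terms. Each tested term is compared against its own error stratum: the
# between-subjects covariates against SID, SID against the residual, Time
# and its covariate interactions against Time x SID, each method contrast
# and its covariate interactions against its own contrast x SID stratum,
# and everything else against the residual.

#' Planned orthogonal method contrasts
#'
#' C1 compares the two self-report methods directly (Diary +1, Google -1,
#' GPS 0); C2 compares the average self-report against GPS (Diary +1/2,
#' Google +1/2, GPS -1). Both are centered and mutually orthogonal.
#'
#' @return A tibble `method`, `C1`, `C2`.
#' @export
method_contrasts <- function() {
  tibble(
    method = c("Diary", "Google", "GPS"),
    C1 = c(1, -1, 0),
    C2 = c(0.5, 0.5, -1)
  )
}

#' Build the long subject x period x method table
#'
#' One row per available subject x period (weekday/weekend) x method
#' observation, with the Time code, the C1/C2 method contrast codes, and the
#' AL/SL factor scores joined in. Rows with missing NPV are omitted; rows
#' whose subject has no factor scores are retained (with `AL`/`SL` missing)
#' so correlation panels can still use them, but are dropped listwise by the
#' model-fitting functions.
#'
#' @param npv NPV records (`subject_id`, `method`, `period`, `npv`);
#'   `total4day` rows are excluded.
#' @param factors Factor scores (`subject_id`, `AL`, `SL`), or `NULL`.
#' @param time_weekday,time_weekend Numeric codes for Time (defaults -1/2
#'   and +1/2, so an intercept estimates the grand per-period mean and the
#'   Time coefficient the weekend-minus-weekday difference).
#' @return A tibble `SID`, `method`, `period`, `npv`, `Time`, `C1`, `C2`,
#'   `AL`, `SL` with attribute `n_obs`.
#' @export
build_long_table <- function(npv, factors = NULL, time_weekday = -0.5,
                             time_weekend = 0.5) {
  long <- npv %>%
    filter(.data$period %in% c("weekday", "weekend"), !is.na(.data$npv)) %>%
    mutate(Time = if_else(.data$period == "weekend",
                          time_weekend, time_weekday)) %>%
    left_join(method_contrasts(), by = "method")
  if (!is.null(factors)) {
    long <- left_join(
      long, factors[, c("subject_id", "AL", "SL")], by = "subject_id"
    )
  } else {
    long$AL <- NA_real_
    long$SL <- NA_real_
  }
  long <- long %>%
    mutate(SID = factor(.data$subject_id)) %>%
    select("SID", "subject_id", "method", "period", "npv",
           "Time", "C1", "C2", "AL", "SL")
  attr(long, "n_obs") <- nrow(long)
  long
}

#' Term order and error strata of the split-plot model
#'
#' The full model regresses NPV on the between-subjects terms AL, SL,
#' AL x SL and SID, then Time, C2, C1, the planned interactions, and the
#' subject-interaction error terms. `"AL-first"` gives causal priority to
#' AL; `"SL-first"` reverses the entry order of AL and SL (and of every
#' interaction pair involving them) so that neither construct's variance
#' share depends on an arbitrary ordering choice.
#'
#' @param order `"AL-first"` or `"SL-first"`.
#' @return A list with `terms` (character, entry order) and `strata` (named
#'   character: term -> denominator term or `"residual"`).
#' @export
splitplot_terms <- function(order = c("AL-first", "SL-first")) {
  order <- match.arg(order)
  t1 <- c(
    "AL", "SL", "AL:SL", "SID",
    "Time", "C2", "C1", "Time:C2", "Time:C1",
    "Time:AL", "Time:SL", "Time:AL:SL",
    "AL:C2", "SL:C2", "AL:SL:C2",
    "AL:C1", "SL:C1", "AL:SL:C1",
    "Time:SID", "C2:SID", "C1:SID"
  )
  if (order == "SL-first") {
    swap <- function(x) {
      x <- gsub("AL", "@", x, fixed = TRUE)
      x <- gsub("SL", "AL", x, fixed = TRUE)
      gsub("@", "SL", x, fixed = TRUE)
    }
    t1 <- swap(t1) # e.g. "AL" -> "SL", "Time:AL" -> "Time:SL"
  }
  strata <- c(
    "AL" = "SID", "SL" = "SID", "AL:SL" = "SID", "SL:AL" = "SID",
    "SID" = "residual",
    "Time" = "Time:SID", "Time:AL" = "Time:SID", "Time:SL" = "Time:SID",
    "Time:AL:SL" = "Time:SID", "Time:SL:AL" = "Time:SID",
    "C2" = "C2:SID", "AL:C2" = "C2:SID", "SL:C2" = "C2:SID",
    "AL:SL:C2" = "C2:SID", "SL:AL:C2" = "C2:SID",
    "C1" = "C1:SID", "AL:C1" = "C1:SID", "SL:C1" = "C1:SID",
    "AL:SL:C1" = "C1:SID", "SL:AL:C1" = "C1:SID",
    "Time:C2" = "residual", "Time:C1" = "residual",
    "Time:SID" = "residual", "C2:SID" = "residual", "C1:SID" = "residual"
  )
  list(terms = t1, strata = strata[t1])
}

term_type <- function(term) {
  within_vars <- c("Time", "C1", "C2")
  comps <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (any(comps %in% within_vars)) "WS" else "BS"
}

# model-matrix columns for one term: elementwise product of numeric
# components, crossed with the SID dummy block when SID participates
term_columns <- function(long, term) {
  comps <- strsplit(term, ":", fixed = TRUE)[[1]]
  num <- setdiff(comps, "SID")
  v <- rep(1, nrow(long))
  for (cm in num) {
    x <- long[[cm]]
    if (is.null(x)) abort(paste0("long table lacks column '", cm, "'"))
    v <- v * x
  }
  if ("SID" %in% comps) {
    sid <- droplevels(factor(long$SID))
    m <- stats::model.matrix(~ 0 + sid)
    m * v
  } else {
    matrix(v, ncol = 1, dimnames = list(NULL, term))
  }
}

#' Sequential (Type-I) split-plot ANOVA
#'
#' Computes sequential sums of squares by successive orthogonal projection
#' in the declared term order, with the number of degrees of freedom of each
#' term equal to the column-rank increment it contributes on the realized
#' (possibly unbalanced) design. F ratios use the declared error stratum for
#' each term; two-sided p-values come from the F distribution.
#'
#' Rows with a missing response or missing model variables are dropped
#' listwise before fitting.
#'
#' @param long A long table from [build_long_table()] (or any tibble with
#'   the columns the terms reference plus `npv`).
#' @param order Term order, `"AL-first"` or `"SL-first"`; ignored when
#'   `terms` is supplied.
#' @param terms Optional explicit term order (character vector).
#' @param strata Optional named character vector mapping each term to its
#'   denominator term or `"residual"`; required with `terms`.
#' @return A `splitplot_fit` object: a list with `terms` (per-term tibble of
#'   type, SS, NDF, DDF, F, p and effect sizes), `ss_total`, `ss_resid`,
#'   `df_resid`, `n_obs`, `order`. Use [tidy()] / [glance()] on it.
#' @export
sequential_anova <- function(long, order = "AL-first", terms = NULL,
                             strata = NULL) {
  if (is.null(terms)) {
    spec <- splitplot_terms(order)
    terms <- spec$terms
    strata <- spec$strata
  } else {
    if (is.null(strata)) abort("custom `terms` require a `strata` map")
    strata <- strata[terms]
  }
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  need <- c("npv", vars)
  keep <- complete.cases(long[, intersect(need, names(long))])
  n_dropped <- sum(!keep)
  d <- long[keep, ]
  n <- nrow(d)
  if (n < 4) abort("sequential_anova: too few complete rows")
  nsub <- length(unique(as.character(d$SID %||% seq_len(n))))

  y <- as.numeric(d$npv)
  ss_total <- sum((y - mean(y))^2)

  # orthonormal basis, seeded with the intercept
  Q <- matrix(1 / sqrt(n), nrow = n, ncol = 1)
  ss <- ndf <- stats::setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    B <- term_columns(d, tm)
    orig <- sqrt(colSums(B^2))
    # two-pass reorthogonalization for numerical stability
    R1 <- B - Q %*% crossprod(Q, B)
    R1 <- R1 - Q %*% crossprod(Q, R1)
    live <- sqrt(colSums(R1^2)) > 1e-8 * pmax(orig, 1)
    if (!any(live)) {
      ss[tm] <- 0
      ndf[tm] <- 0L
      next
    }
    dec <- qr(R1[, live, drop = FALSE])
    r <- dec$rank
    if (r == 0) {
      ss[tm] <- 0
      ndf[tm] <- 0L
      next
    }
    Qn <- qr.Q(dec)[, seq_len(r), drop = FALSE]
    # polish orthogonality against the accumulated basis
    Qn <- Qn - Q %*% crossprod(Q, Qn)
    Qn <- qr.Q(qr(Qn))[, seq_len(r), drop = FALSE]
    ss[tm] <- sum(crossprod(Qn, y)^2)
    ndf[tm] <- r
    Q <- cbind(Q, Qn)
  }
  ss_resid <- ss_total - sum(ss)
  df_resid <- n - ncol(Q)

  denom_ss <- function(dn) if (dn == "residual") ss_resid else ss[[dn]]
  denom_df <- function(dn) if (dn == "residual") df_resid else ndf[[dn]]
  tab <- purrr::map_dfr(terms, function(tm) {
    dn <- strata[[tm]]
    ddf <- denom_df(dn)
    if (is.na(ddf) || ddf <= 0) {
      abort(paste0(
        "sequential_anova: error stratum '", dn,
        "' for term '", tm, "' has no degrees of freedom"
      ))
    }
    ndf_t <- ndf[[tm]]
    ms_t <- if (ndf_t > 0) ss[[tm]] / ndf_t else NA_real_
    ms_d <- denom_ss(dn) / ddf
    fval <- if (is.na(ms_t) || ms_d <= 0) NA_real_ else ms_t / ms_d
    pval <- if (is.na(fval)) NA_real_ else pf(fval, ndf_t, ddf,
                                              lower.tail = FALSE)
    tibble(
      term = tm, type = term_type(tm), ss = ss[[tm]], ndf = ndf_t,
      denom = dn, ddf = ddf, f = fval, p = pval
    )
  })
  tab$semi_partial_r2 <- tab$ss / ss_total
  tab <- effect_sizes(tab)

  structure(
    list(
      terms = tab, ss_total = ss_total, ss_resid = ss_resid,
      df_resid = df_resid, n_obs = n, n_subjects = nsub,
      n_dropped = n_dropped, order = order
    ),
    class = "splitplot_fit"
  )
}

#' Effect-size accounting for a sequential ANOVA table
#'
#' Adds/overwrites the partial R-squared column: each term's semi-partial
#' R-squared (SS / corrected total SS) divided by the total semi-partial
#' R-squared of its between- or within-subjects stratum. Works on a fitted
#' table or on any tibble carrying `type` (`"BS"`/`"WS"`) and
#' `semi_partial_r2` columns, so published summaries can be re-accounted.
#'
#' @param tab A tibble with `type` and `semi_partial_r2`.
#' @return `tab` with `partial_r2` and attributes `bs_total`, `ws_total`
#'   and `model_r2` (= bs_total + ws_total).
#' @export
effect_sizes <- function(tab) {
  bs_total <- sum(tab$semi_partial_r2[tab$type == "BS"], na.rm = TRUE)
  ws_total <- sum(tab$semi_partial_r2[tab$type == "WS"], na.rm = TRUE)
  stratum_total <- if_else(tab$type == "BS", bs_total, ws_total)
  tab$partial_r2 <- if_else(
    stratum_total > 0, tab$semi_partial_r2 / stratum_total, NA_real_
  )
  attr(tab, "bs_total") <- bs_total
  attr(tab, "ws_total") <- ws_total
  attr(tab, "model_r2") <- bs_total + ws_total
  tab
}

#' Fit both term orders
#'
#' Fits the AL-first and SL-first models on the same data. The joint sum of
#' squares of \{AL, SL, AL x SL\} and the model R-squared are identical
#' across orders; only the split between AL and SL changes.
#'
#' @param long A long table from [build_long_table()].
#' @return A list with elements `al_first` and `sl_first`, both
#'   `splitplot_fit` objects.
#' @export
fit_both_orders <- function(long) {
  list(
    al_first = sequential_anova(long, order = "AL-first"),
    sl_first = sequential_anova(long, order = "SL-first")
  )
}

#' @exportS3Method generics::tidy
tidy.splitplot_fit <- function(x, ...) {
  x$terms
}

#' @exportS3Method generics::glance
glance.splitplot_fit <- function(x, ...) {
  ndf_model <- sum(x$terms$ndf)
  ms_model <- sum(x$terms$ss) / ndf_model
  ms_resid <- x$ss_resid / x$df_resid
  tibble(
    r_squared = attr(x$terms, "model_r2"),
    bs_r_squared = attr(x$terms, "bs_total"),
    ws_r_squared = attr(x$terms, "ws_total"),
    error_r_squared = x$ss_resid / x$ss_total,
    statistic = ms_model / ms_resid,
    ndf = ndf_model,
    ddf = x$df_resid,
    p_value = pf(ms_model / ms_resid, ndf_model, x$df_resid,
                 lower.tail = FALSE),
    n_obs = x$n_obs,
    n_subjects = x$n_subjects
  )
}

#' @export
print.splitplot_fit <- function(x, ...) {
  cat("Split-plot GLM (sequential SS), order:", x$order, "\n")
  cat("  observations:", x$n_obs, " subjects:", x$n_subjects,
      " residual df:", x$df_resid, "\n")
  g <- glance(x)
  cat(sprintf(
    "  model R^2 = %.3f (BS %.3f + WS %.3f), error R^2 = %.3f\n",
    g$r_squared, g$bs_r_squared, g$ws_r_squared, g$error_r_squared
  ))
  print(x$terms, n = nrow(x$terms))
  invisible(x)
}

#' Final parameter model: NPV on AL and Time
#'
#' Ordinary least squares of NPV on the two predictors that carry signal,
#' refining their unstandardized estimates. With Time coded -1/2 / +1/2 the
#' intercept estimates the grand per-period mean and the Time coefficient
#' the weekend-minus-weekday difference.
#'
#' @param long A long table from [build_long_table()].
#' @return A tibble `term`, `estimate`, `std_error` for Intercept, AL, Time.
#' @export
final_parameter_fit <- function(long) {
  d <- long[complete.cases(long[, c("npv", "AL", "Time")]), ]
  if (nrow(d) < 3) abort("final_parameter_fit: fewer rows than parameters")
  fit <- stats::lm(npv ~ AL + Time, data = d)
  sm <- summary(fit)$coefficients
  nm <- c("(Intercept)", "AL", "Time")
  est <- stats::coef(fit)[nm]
  se <- sm[match(nm, rownames(sm)), 2]
  # an aliased (e.g. all-zero) predictor contributes nothing: report 0
  se[is.na(est)] <- NA_real_
  est[is.na(est)] <- 0
  tibble(
    term = c("Intercept", "AL", "Time"),
    estimate = unname(est),
    std_error = unname(se)
  )
}

#' Published split-plot ANOVA summary (reference cells)
#'
#' The AL-first split-plot ANOVA summary of the original 96-participant
#' NPV validation study (NDF/DDF, F, p and effect-size columns), shipped as
#' a plain-text reference so the effect-size accounting identities —
#' partial R^2 = semi-partial R^2 / stratum total, model R^2 = BS + WS
#' semi-partial totals — can be re-derived from the printed cells.
#'
#' @return A tibble with `type`, `term`, `ndf`, `ddf`, `f`, `p`,
#'   `semi_partial_r2`, `partial_r2`.
#' @export
reference_anova_model1 <- function() {
  readr::read_csv(
    system.file("extdata", "reference_anova_model1.csv",
                package = "geovalid"),
    show_col_types = FALSE, progress = FALSE
  )
}
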