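#' Covariate-adjusted group effect (ANCOVA)
#'
#' Fits the linear model `value ~ group + covariates` and reports the
#' partial F test for the group term against the model without it. With no
#' covariates this is exactly the one-way ANOVA F. The denominator degrees
#' of freedom are `n - p` where p counts all fitted coefficients, so a
#' two-group comparison with 40 subjects and three covariates gives
#' df = (1, 35).
#'
#' @param data Data frame with one row per subject.
#' @param value Name of the response column.
#' @param group Name of the group column (2 levels).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return One-row tibble: `F`, `df1`, `df2`, `p`, `n`.
#' @export
ancova_group_effect <- function(data, value = "value", group = "group",
                                covariates = c("age", "sex", "handedness")) {
  d <- data[, c(value, group, covariates), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  terms_full <- c(group, covariates)
  if (n < length(terms_full) + 2) {
    invalid_config("too few complete observations for the requested model")
  }
  d[[group]] <- factor(d[[group]])
  if (nlevels(d[[group]]) != 2) invalid_config("group must have exactly 2 levels")
  rhs_full <- paste(terms_full, collapse = " + ")
  mm <- model.matrix(as.formula(paste("~", rhs_full)), data = d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(
      sprintf("collinear model terms: %s", paste(dropped, collapse = ", ")),
      class = "leidar_collinearity"
    )
  }
  f_full <- as.formula(paste(value, "~", rhs_full))
  rhs_null <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_null <- as.formula(paste(value, "~", rhs_null))
  fit_full <- lm(f_full, data = d)
  fit_null <- lm(f_null, data = d)
  an <- anova(fit_null, fit_full)
  tibble(
    F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
    p = an$`Pr(>F)`[2], n = n
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; monotone, idempotent,
#' never smaller than the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @return Adjusted p-values in the original order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    invalid_config("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Bayes factor for the group term (BIC approximation)
#'
#' `BF10 = exp((BIC_null - BIC_full) / 2)` comparing the covariate-only
#' model against the model with the group term, a deterministic
#' unit-information-prior approximation. Values above 1, 3 and 10 are read
#' as anecdotal, moderate and strong evidence for a group effect.
#'
#' @inheritParams ancova_group_effect
#' @return One-row tibble: `bf10`, `bic_null`, `bic_full`, `method`.
#' @export
bayes_factor_group <- function(data, value = "value", group = "group",
                               covariates = c("age", "sex", "handedness")) {
  d <- data[, c(value, group, covariates), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  d[[group]] <- factor(d[[group]])
  rhs_null <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_full <- as.formula(paste(value, "~", paste(c(group, covariates), collapse = " + ")))
  f_null <- as.formula(paste(value, "~", rhs_null))
  bic_full <- BIC(lm(f_full, data = d))
  bic_null <- BIC(lm(f_null, data = d))
  tibble(
    bf10 = exp((bic_null - bic_full) / 2),
    bic_null = bic_null, bic_full = bic_full, method = "BIC"
  )
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes both sets of ranks on the
#' covariates by least squares, and Pearson-correlates the residuals. The
#' p-value uses the t-approximation with degrees of freedom reduced by the
#' number of covariates: `df = n - 2 - n_covariates`.
#'
#' @param data Data frame.
#' @param x,y Names of the two columns to correlate.
#' @param covariates Character vector of covariate column names (typically
#'   including the group indicator).
#' @return One-row tibble: `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(data, x, y,
                             covariates = c("age", "sex", "handedness", "group")) {
  d <- data[, c(x, y, covariates), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(covariates) + 3) {
    invalid_config("too few complete observations for a partial correlation")
  }
  rx <- rank(d[[x]])
  ry <- rank(d[[y]])
  if (length(covariates)) {
    z <- model.matrix(
      as.formula(paste("~", paste(covariates, collapse = " + "))),
      data = d
    )
    rx <- lm.fit(z, rx)$residuals
    ry <- lm.fit(z, ry)$residuals
  }
  rho <- cor(rx, ry)
  df <- n - 2 - length(covariates)
  tt <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  tibble(rho = rho, p = min(2 * pt(-abs(tt), df), 1), n = n, df = df)
}

#' Full group-inference battery over the dynamic metrics
#'
#' Runs the covariate-adjusted ANCOVA, BIC Bayes factor, and group
#' summaries for every state's occupancy and lifetime (FDR-corrected within
#' each 5-state metric family) and for every directed transition. Transition
#' p-values are reported uncorrected and flagged exploratory -- with a
#' modest sample the 20 directed transitions are treated as
#' hypothesis-generating -- but an optional BH-adjusted column is included.
#'
#' @param metrics_tbl Long metrics table from [cohort_metrics()].
#' @param covariate_tbl Tibble with `subject_id`, `group`, and the
#'   covariate columns.
#' @param covariates Covariate names to adjust for (default age, sex,
#'   handedness; add `"education"` for the sensitivity analysis).
#' @return A `leida_stats` list of two tibbles: `states` (occupancy and
#'   lifetime by state: group means/SDs, `F`, `df1`, `df2`, `p`, `p_fdr`,
#'   `bf10`) and `transitions` (per directed pair, with `p_fdr_exploratory`).
#' @export
run_stats_battery <- function(metrics_tbl, covariate_tbl,
                              covariates = c("age", "sex", "handedness")) {
  needed <- c("subject_id", "group", covariates)
  stopifnot(all(needed %in% names(covariate_tbl)))
  joined <- metrics_tbl |>
    select(dplyr::any_of(c("subject_id", "metric", "state", "to_state", "value"))) |>
    left_join(covariate_tbl[, needed, drop = FALSE], by = "subject_id")
  groups <- sort(unique(as.character(joined$group)))
  one_cell <- function(d) {
    an <- ancova_group_effect(d, covariates = covariates)
    bf <- bayes_factor_group(d, covariates = covariates)
    gm <- d |>
      group_by(.data$group) |>
      summarise(mean = mean(.data$value, na.rm = TRUE),
                sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
    tibble(
      mean_1 = gm$mean[gm$group == groups[1]],
      sd_1 = gm$sd[gm$group == groups[1]],
      mean_2 = gm$mean[gm$group == groups[2]],
      sd_2 = gm$sd[gm$group == groups[2]],
      F = an$F, df1 = an$df1, df2 = an$df2, p = an$p, bf10 = bf$bf10
    )
  }
  states <- joined |>
    filter(.data$metric %in% c("occupancy", "lifetime")) |>
    group_by(.data$metric, .data$state) |>
    dplyr::group_modify(~ one_cell(.x)) |>
    ungroup() |>
    group_by(.data$metric) |>
    mutate(p_fdr = fdr_adjust(.data$p)) |>
    ungroup()
  transitions <- joined |>
    filter(.data$metric == "transition") |>
    group_by(.data$state, .data$to_state) |>
    dplyr::group_modify(~ one_cell(.x)) |>
    ungroup() |>
    mutate(p_fdr_exploratory = fdr_adjust(.data$p), exploratory = TRUE) |>
    dplyr::rename(from = "state", to = "to_state")
  structure(
    list(states = states, transitions = transitions,
         groups = groups, covariates = covariates),
    class = "leida_stats"
  )
}

#' Exploratory partial Spearman correlations with outcome measures
#'
#' Correlates each per-subject metric value with each outcome column,
#' adjusting for covariates and group, via [partial_spearman()]. Reported
#' uncorrected, as exploratory.
#'
#' @param metrics_tbl Long metrics table from [cohort_metrics()].
#' @param outcome_tbl Tibble with `subject_id` and outcome columns.
#' @param outcomes Character vector of outcome column names.
#' @param covariate_tbl Tibble with `subject_id`, `group`, covariates.
#' @param covariates Covariates to adjust for (group is added
#'   automatically).
#' @return Tibble: metric identifiers x outcome with `rho`, `p`, `n`, `df`.
#' @export
correlate_outcomes <- function(metrics_tbl, outcome_tbl, outcomes,
                               covariate_tbl,
                               covariates = c("age", "sex", "handedness")) {
  covs <- unique(c(covariates, "group"))
  wide <- metrics_tbl |>
    select(dplyr::any_of(c("subject_id", "metric", "state", "to_state", "value"))) |>
    left_join(covariate_tbl[, c("subject_id", covs), drop = FALSE],
              by = "subject_id") |>
    left_join(outcome_tbl[, c("subject_id", outcomes), drop = FALSE],
              by = "subject_id")
  cells <- wide |> dplyr::distinct(.data$metric, .data$state, .data$to_state)
  purrr::pmap(cells, function(metric, state, to_state) {
    d <- wide |>
      filter(.data$metric == !!metric, .data$state == !!state,
             (is.na(!!to_state) & is.na(.data$to_state)) |
               (!is.na(!!to_state) & .data$to_state %in% !!to_state))
    purrr::map(outcomes, function(oc) {
      ps <- partial_spearman(d, "value", oc, covariates = covs)
      mutate(ps, metric = metric, state = state, to_state = to_state,
             outcome = oc, .before = 1)
    }) |> bind_rows()
  }) |> bind_rows()
}

#' @export
print.leida_stats <- function(x, ...) {
  cat(sprintf(
    "<leida_stats> %s vs %s, covariates: %s\n  %d state-metric tests, %d transition tests\n",
    x$groups[1], x$groups[2], paste(x$covariates, collapse = ", "),
    nrow(x$states), nrow(x$transitions)
  ))
  invisible(x)
}

#' Combined tidy table of all group tests
#'
#' @param x A `leida_stats` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.leida_stats <- function(x, ...) {
  bind_rows(
    x$states |> mutate(from = .data$state, to = NA_integer_) |>
      select(-"state"),
    x$transitions |> mutate(metric = "transition")
  )
}

#' One-row summary of the group-inference battery
#'
#' Counts of tests and of FDR-significant state effects.
#'
#' @param x A `leida_stats` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.leida_stats <- function(x, ...) {
  tibble(
    n_state_tests = nrow(x$states),
    n_transition_tests = nrow(x$transitions),
    n_significant_fdr = sum(x$states$p_fdr < 0.05, na.rm = TRUE)
  )
}
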