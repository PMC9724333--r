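#' Default outcome-model adjustment sets
#'
#' Covariates significantly related to patient outcomes: ASA >= 3, age >= 75,
#' preoperative comorbidity (any of hypertension, coronary heart disease,
#' diabetes, stroke, COPD), preoperative hemoglobin, operation time >= 3 h,
#' plus — for the base population only — bleeding >= 500 mL and ICU
#' admission.
#'
#' @param population `"base"` or `"study"`.
#' @return Character vector of covariate column names (`any_comorbidity` is
#'   derived on the fly by [fit_outcome_model()]).
#' @export
outcome_covariates <- function(population = c("base", "study")) {
  population <- match.arg(population)
  common <- c("asa_ge3", "age_ge75", "any_comorbidity", "preop_hb",
              "op_time_ge3h")
  if (population == "base") c(common, "bleeding_ge500ml", "icu_admission")
  else common
}

new_effect_estimate <- function(label, or, ci_low, ci_high, p_value,
                                covariates, n, n_events, n_dropped = 0L) {
  structure(
    list(label = label, odds_ratio = or, ci_low = ci_low, ci_high = ci_high,
         p_value = p_value, covariates = covariates, n = n,
         n_events = n_events, n_dropped = n_dropped),
    class = "hb_effect"
  )
}

#' Crude odds ratio from a 2x2 table
#'
#' Closed-form cross-product odds ratio with a log-scale Wald 95% confidence
#' interval, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. Cell layout: `a` exposed
#' with event, `b` exposed without, `c` unexposed with event, `d` unexposed
#' without, so `OR = (a d)/(b c)`. Serves as the exact oracle for the
#' exposure-only logistic regression.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @param continuity If `TRUE`, add 0.5 to every cell (Haldane-Anscombe)
#'   instead of erroring on a zero cell. Default `FALSE`.
#' @param label Dataset label carried on the estimate.
#' @return An `hb_effect` (see [fit_outcome_model()]).
#' @export
#' @examples
#' crude_or(39, 623, 29, 5450)  # crude death OR
crude_or <- function(a, b, c, d, continuity = FALSE, label = "crude") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    abort("Cell counts must be nonnegative integers",
          class = "hb_effect_error")
  if (any(cells == 0)) {
    if (!continuity)
      abort(paste0("Zero cell(s) in the 2x2 table (",
                   paste(names(cells)[cells == 0], collapse = ", "),
                   "); rerun with continuity = TRUE for the 0.5 correction"),
            class = "hb_zero_cell_error")
    cells <- cells + 0.5
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  new_effect_estimate(label, unname(or), unname(exp(log(or) - z * se)),
                      unname(exp(log(or) + z * se)), unname(p),
                      covariates = character(0),
                      n = as.integer(a + b + c + d),
                      n_events = as.integer(a + c))
}

#' Adjusted odds ratio from multivariable logistic regression
#'
#' Maximum-likelihood logistic regression of the composite outcome on the
#' exposure plus an adjustment set; the reported effect is the exponentiated
#' exposure coefficient with a 95% Wald confidence interval and two-tailed
#' p-value. Complete-case: records missing any model variable are dropped
#' and counted. Matched datasets are analyzed with ordinary (unconditional)
#' logistic regression by default; `conditional = TRUE` instead conditions
#' on matched pairs via the exact conditional likelihood for 1:1 pairs
#' (discordant-pair McNemar-type estimate) and requires a `pair_id` column.
#'
#' @param data Data frame with the outcome, exposure and covariates.
#' @param outcome Logical outcome column. Default `"composite_outcome"`.
#' @param exposure Logical exposure column. Default `"transfused"`.
#' @param covariates Adjustment covariates; `"any_comorbidity"` is derived
#'   from the five comorbidity flags when absent. Default `character(0)`
#'   (crude model).
#' @param label Dataset label carried on the estimate.
#' @param conditional Condition on matched pairs (requires `pair_id`).
#' @return An `hb_effect`: odds ratio, `ci_low`, `ci_high`, `p_value`,
#'   `covariates`, `n`, `n_events`, `n_dropped`. Methods: [tidy()] (full
#'   coefficient table), [glance()] (one-row summary), `print()`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 2000, seed = 5))
#' pats <- define_composite_outcome(cohort$patients)
#' fit_outcome_model(pats, covariates = outcome_covariates("base"))
fit_outcome_model <- function(data, outcome = "composite_outcome",
                              exposure = "transfused",
                              covariates = character(0),
                              label = "unlabeled", conditional = FALSE) {
  dat <- tibble::as_tibble(data)
  if ("any_comorbidity" %in% covariates &&
      !"any_comorbidity" %in% names(dat)) {
    flags <- c("hypertension", "chd", "diabetes", "stroke", "copd")
    require_columns(dat, flags)
    dat$any_comorbidity <- Reduce(`|`, lapply(dat[flags], `%in%`, TRUE))
  }
  require_columns(dat, c(outcome, exposure, covariates))
  use <- stats::complete.cases(dat[c(outcome, exposure, covariates)])
  n_dropped <- sum(!use)
  cc <- dat[use, , drop = FALSE]
  y <- as.integer(cc[[outcome]] %in% TRUE)
  x <- as.integer(cc[[exposure]] %in% TRUE)
  if (sum(y) == 0)
    abort("No events in the dataset; the odds ratio is not estimable",
          class = "hb_effect_error")
  if (sum(1 - y) == 0)
    abort("No non-events in the dataset; the odds ratio is not estimable",
          class = "hb_effect_error")
  for (arm in c(0, 1)) {
    nm <- if (arm == 1) "exposed" else "control"
    if (sum(y[x == arm]) == 0)
      abort(sprintf(
        "No events among %s members; the odds ratio is not estimable", nm),
        class = "hb_effect_error")
    if (sum(1 - y[x == arm]) == 0)
      abort(sprintf(
        "No non-events among %s members; the odds ratio is not estimable",
        nm), class = "hb_effect_error")
  }
  if (conditional) {
    return(fit_conditional_pairs(cc, y, x, label, n_dropped))
  }
  mf <- cbind(tibble::tibble(.y = y, .exposure = x), cc[covariates])
  form <- stats::reformulate(c(".exposure", covariates), response = ".y")
  fit <- fit_logistic_checked(form, mf, context = "outcome model")
  est <- stats::coef(fit)[".exposure"]
  se <- sqrt(diag(stats::vcov(fit))[".exposure"])
  z <- stats::qnorm(0.975)
  out <- new_effect_estimate(
    label, unname(exp(est)), unname(exp(est - z * se)),
    unname(exp(est + z * se)),
    unname(2 * stats::pnorm(-abs(est / se))),
    covariates = covariates, n = nrow(cc), n_events = sum(y),
    n_dropped = n_dropped)
  out$fit <- fit
  out
}

# 1:1 matched-pair conditional logistic estimate (discordant pairs only).
fit_conditional_pairs <- function(cc, y, x, label, n_dropped) {
  require_columns(cc, "pair_id")
  d <- tibble::tibble(pair = cc$pair_id, y = y, x = x) |>
    dplyr::group_by(.data$pair) |>
    dplyr::filter(dplyr::n() == 2, sum(.data$x) == 1) |>
    dplyr::summarise(
      f = sum(.data$y[.data$x == 1]) - sum(.data$y[.data$x == 0]),
      .groups = "drop")
  n10 <- sum(d$f == 1)   # exposed member had the event, control did not
  n01 <- sum(d$f == -1)
  if (n10 == 0 || n01 == 0)
    abort("Too few discordant pairs for a conditional estimate",
          class = "hb_effect_error")
  or <- n10 / n01
  se <- sqrt(1 / n10 + 1 / n01)
  z <- stats::qnorm(0.975)
  new_effect_estimate(label, or, exp(log(or) - z * se),
                      exp(log(or) + z * se),
                      2 * stats::pnorm(-abs(log(or) / se)),
                      covariates = "conditional-on-pair",
                      n = length(y), n_events = sum(y),
                      n_dropped = n_dropped)
}

#' @export
print.hb_effect <- function(x, ...) {
  cat(sprintf("<hb_effect> %s\n", x$label))
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  n = %d, events = %d, complete-case exclusions = %d\n",
              x$n, x$n_events, x$n_dropped))
  if (length(x$covariates) > 0)
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.hb_effect <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = "exposure", estimate = log(x$odds_ratio),
                          odds_ratio = x$odds_ratio, ci_low = x$ci_low,
                          ci_high = x$ci_high, p.value = x$p_value))
  }
  co <- stats::coef(summary(x$fit))
  z <- stats::qnorm(0.975)
  est <- unname(co[, 1]); se <- unname(co[, 2])
  tibble::tibble(term = rownames(co), estimate = est,
                 std.error = se,
                 odds_ratio = exp(est),
                 ci_low = exp(est - z * se),
                 ci_high = exp(est + z * se),
                 p.value = unname(co[, 4]))
}

#' @export
glance.hb_effect <- function(x, ...) {
  tibble::tibble(label = x$label, odds_ratio = x$odds_ratio,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 p_value = x$p_value, n = x$n, n_events = x$n_events,
                 n_dropped = x$n_dropped,
                 covariates = paste(x$covariates, collapse = "+"))
}
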