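#' Default propensity-model covariate sets
#'
#' The base-population propensity model uses ASA >= 3, preoperative
#' hemoglobin, operation time >= 3 h, bleeding >= 500 mL and ICU admission;
#' the study-population model drops bleeding (the study population contains
#' no mass bleeding by construction).
#'
#' @param population `"base"` or `"study"`.
#' @return Character vector of covariate column names.
#' @export
ps_covariates <- function(population = c("base", "study")) {
  population <- match.arg(population)
  base <- c("asa_ge3", "preop_hb", "op_time_ge3h", "bleeding_ge500ml",
            "icu_admission")
  if (population == "base") base else setdiff(base, "bleeding_ge500ml")
}

#' Fit a propensity-score model
#'
#' Maximum-likelihood logistic regression of the exposure on the covariate
#' set; the propensity score is the fitted probability of transfusion.
#' Records with missing covariates are dropped (complete-case) and counted.
#' Perfect separation and non-convergence are reported as errors rather than
#' silently returning degenerate scores.
#'
#' @param data Data frame containing `patient_id`, the exposure and the
#'   covariates.
#' @param covariates Character vector of covariate columns. Default: the
#'   base-population set, see [ps_covariates()].
#' @param exposure Logical exposure column. Default `"transfused"`.
#' @return An object of class `hb_psfit`: `scores` (tibble `patient_id`,
#'   `ps`), `fit` (the `glm`), `covariates`, `exposure`, `n_dropped`
#'   (complete-case exclusions), `converged`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 1000, seed = 4))
#' psf <- fit_propensity(cohort$patients, ps_covariates("base"))
#' head(psf$scores)
fit_propensity <- function(data, covariates = ps_covariates("base"),
                           exposure = "transfused") {
  dat <- tibble::as_tibble(data)
  require_columns(dat, c("patient_id", exposure, covariates))
  use <- stats::complete.cases(dat[c(exposure, covariates)])
  n_dropped <- sum(!use)
  cc <- dat[use, , drop = FALSE]
  if (nrow(cc) == 0)
    abort("No complete cases for the propensity model",
          class = "hb_ps_error")
  y <- as.integer(cc[[exposure]] %in% TRUE)
  if (sum(y) == 0 || sum(1 - y) == 0)
    abort("Exposure is constant after complete-case filtering",
          class = "hb_ps_error")
  form <- stats::reformulate(covariates, response = ".y")
  mf <- cbind(.y = y, cc[covariates])
  fit <- fit_logistic_checked(form, mf, context = "propensity model")
  scores <- tibble::tibble(patient_id = cc$patient_id,
                           ps = as.numeric(stats::fitted(fit)))
  structure(
    list(scores = scores, fit = fit, covariates = covariates,
         exposure = exposure, n_dropped = n_dropped,
         converged = fit$converged),
    class = "hb_psfit"
  )
}

# Shared logistic fitter: flags separation and non-convergence explicitly.
# Separation is detected by diverged coefficients (|beta| > 15 on the
# log-odds scale is far outside any plausible adjusted association here);
# the accompanying glm warning is muffled because the condition is promoted
# to an error.
fit_logistic_checked <- function(formula, data, context) {
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  big <- abs(stats::coef(fit)) > 15
  big[is.na(big)] <- TRUE
  if (any(big)) {
    abort(sprintf(
      "Perfect or quasi-perfect separation in the %s (covariate set: %s)",
      context,
      paste(names(stats::coef(fit))[big], collapse = ", ")),
      class = "hb_separation_error")
  }
  if (!fit$converged)
    abort(sprintf("The %s did not converge within %d IRLS iterations",
                  context, fit$iter),
          class = "hb_convergence_error")
  fit
}

#' @export
print.hb_psfit <- function(x, ...) {
  cat("<hb_psfit>\n")
  cat(sprintf("  exposure: %s; covariates: %s\n", x$exposure,
              paste(x$covariates, collapse = ", ")))
  cat(sprintf("  %d scored, %d dropped (incomplete covariates)\n",
              nrow(x$scores), x$n_dropped))
  invisible(x)
}

#' @export
tidy.hb_psfit <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2], statistic = co[, 3],
                 p.value = co[, 4])
}

#' @export
glance.hb_psfit <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), n_dropped = x$n_dropped,
                 converged = x$converged,
                 deviance = x$fit$deviance, aic = x$fit$aic)
}

#' 1:1 nearest-neighbor propensity-score matching with a caliper
#'
#' Greedy matching without replacement: exposed members are processed one at
#' a time and matched to the nearest unmatched control by absolute
#' propensity-score difference, provided the distance is within the caliper
#' (`caliper_multiplier` times the standard deviation of the score pooled
#' over both groups, on the probability scale by default). Distance ties are
#' broken by the smallest control identifier; the processing order of the
#' exposed is random under `seed` by default, or by descending score.
#'
#' @param data Data frame with `patient_id`, the score and exposure columns.
#' @param caliper_multiplier Caliper as a multiple of the pooled score SD.
#'   Default 0.2.
#' @param seed Integer seed controlling the random processing order.
#' @param score,exposure Column names. Defaults `"ps"`, `"transfused"`.
#' @param order `"random"` (default) or `"descending"` (by exposed score).
#' @param caliper_scale `"probability"` (default; caliper and distances on
#'   the raw probability scale) or `"logit"` (both on the logit scale).
#' @return An object of class `hb_match`: `pairs` (tibble `exposed_id`,
#'   `control_id`, `delta`), `caliper`, `sd_used`, `matching_rate_exposed`,
#'   `matching_rate_control` (percent), `unmatched_exposed`,
#'   `unmatched_control`, `n_exposed`, `n_control`, and `settings`.
#' @export
#' @examples
#' d <- tibble::tibble(patient_id = letters[1:5],
#'                     ps = c(0.50, 0.30, 0.49, 0.60, 0.31),
#'                     transfused = c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' ps_match(d, caliper_multiplier = 0.5, seed = 1)
ps_match <- function(data, caliper_multiplier = 0.2, seed = 1L,
                     score = "ps", exposure = "transfused",
                     order = c("random", "descending"),
                     caliper_scale = c("probability", "logit")) {
  order <- match.arg(order)
  caliper_scale <- match.arg(caliper_scale)
  dat <- tibble::as_tibble(data)
  require_columns(dat, c("patient_id", score, exposure))
  s <- dat[[score]]
  if (anyNA(s)) abort("Scores must not be missing", class = "hb_match_error")
  exposed <- dat[[exposure]] %in% TRUE
  if (sum(exposed) == 0 || sum(!exposed) == 0)
    abort("Both exposure groups must be non-empty for matching",
          class = "hb_match_error")
  work <- if (caliper_scale == "logit") stats::qlogis(s) else s
  sd_used <- stats::sd(work)
  caliper <- caliper_multiplier * sd_used

  e_idx <- which(exposed)
  c_idx <- which(!exposed)
  e_order <- if (order == "random") {
    withr::with_seed(seed, sample(e_idx))
  } else {
    e_idx[order(-work[e_idx], dat$patient_id[e_idx])]
  }

  c_ids <- dat$patient_id[c_idx]
  c_ps <- work[c_idx]
  alive <- rep(TRUE, length(c_idx))
  pairs_e <- character(0); pairs_c <- character(0); pairs_d <- numeric(0)
  for (ei in e_order) {
    if (!any(alive)) break
    d <- abs(work[ei] - c_ps)
    d[!alive] <- Inf
    best <- min(d)
    if (best > caliper) next
    cand <- which(d == best)
    pick <- cand[order(c_ids[cand])][1]
    alive[pick] <- FALSE
    pairs_e <- c(pairs_e, dat$patient_id[ei])
    pairs_c <- c(pairs_c, c_ids[pick])
    pairs_d <- c(pairs_d, best)
  }
  pairs <- tibble::tibble(exposed_id = pairs_e, control_id = pairs_c,
                          delta = pairs_d)
  n_e <- length(e_idx); n_c <- length(c_idx)
  structure(
    list(pairs = pairs, caliper = caliper, sd_used = sd_used,
         matching_rate_exposed = 100 * nrow(pairs) / n_e,
         matching_rate_control = 100 * nrow(pairs) / n_c,
         unmatched_exposed = setdiff(dat$patient_id[e_idx], pairs$exposed_id),
         unmatched_control = c_ids[alive],
         n_exposed = n_e, n_control = n_c,
         settings = list(caliper_multiplier = caliper_multiplier,
                         seed = as.integer(seed), order = order,
                         caliper_scale = caliper_scale)),
    class = "hb_match"
  )
}

#' @export
print.hb_match <- function(x, ...) {
  cat("<hb_match>\n")
  cat(sprintf("  %d pairs; caliper %.4f (%.2f x pooled SD %.4f, %s scale)\n",
              nrow(x$pairs), x$caliper, x$settings$caliper_multiplier,
              x$sd_used, x$settings$caliper_scale))
  cat(sprintf("  matching rate: %.1f%% exposed, %.1f%% control\n",
              x$matching_rate_exposed, x$matching_rate_control))
  invisible(x)
}

#' @export
tidy.hb_match <- function(x, ...) x$pairs

#' @export
glance.hb_match <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), caliper = x$caliper,
                 sd_used = x$sd_used,
                 matching_rate_exposed = x$matching_rate_exposed,
                 matching_rate_control = x$matching_rate_control,
                 n_exposed = x$n_exposed, n_control = x$n_control)
}

#' Restrict a dataset to the members of a match result
#'
#' @param data Data frame with `patient_id`.
#' @param match An `hb_match`.
#' @return The matched subset of `data`, as a tibble.
#' @export
matched_data <- function(data, match) {
  ids <- c(match$pairs$exposed_id, match$pairs$control_id)
  dplyr::filter(tibble::as_tibble(data), .data$patient_id %in% ids)
}
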