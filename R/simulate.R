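#' Simulate a synthetic perioperative cohort
#'
#' Generates a seeded synthetic cohort of surgical admissions with baseline
#' covariates, longitudinal hemoglobin measurements, transfusion events and
#' the latent generative truth. The generator reproduces the
#' confounding-by-indication structure of transfusion practice: patients are
#' transfused *because* they are anemic, bleeding or severely ill, and those
#' same indications independently drive death and complications, so a naive
#' comparison of transfused versus non-transfused patients is biased against
#' transfusion even when its true direct effect is null.
#'
#' Time is a sequence of ordered measurement occasions (admission, preop,
#' postop day 1..k), indexed from 0. The transfusion decision is re-evaluated
#' at every occasion from the preoperative one onward as a logistic function
#' of the current hemoglobin measurement, bleeding >= 500 mL, ASA >= 3 and
#' operation time >= 3 h; the first success defines the initial transfusion,
#' so the measurement that triggered it is also the last one before it.
#' Events are recorded at half-integer occasions (strictly between two
#' measurements), and each transfusion raises all subsequent measurements by
#' `transfusion_hb_gain` g/dL. All hemoglobin values are clamped to the
#' physiologic range 3-20 g/dL.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `hb_cohort`: a list of four tibbles
#'   \describe{
#'     \item{patients}{one row per admission: demographics, comorbidity,
#'       ASA, preoperative labs, intraoperative features, ICU admission,
#'       outcome flags, plus the derived `transfused` indicator.}
#'     \item{hemoglobin}{`patient_id`, integer `occasion`, occasion `label`,
#'       `hb_gdl`.}
#'     \item{transfusions}{`patient_id`, half-integer event `occasion`,
#'       `episode` number.}
#'     \item{truth}{latent generative state per patient:
#'       `linear_predictor_outcome`, `was_confounded`,
#'       `counterfactual_outcome_prob_untransfused`.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 200, seed = 7))
#' cohort$patients
#' mean(cohort$patients$transfused)
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  m <- config$covariate_margins
  K <- length(config$measurement_schedule)

  draw <- function(name, default) {
    p <- m[[name]] %||% default
    as.logical(rbinom(n, 1, p))
  }

  # population is older surgical patients; P(age >= 75) tracks the margin
  rate <- -log(m$age_ge75 %||% 0.152) / 15
  age_years <- pmin(95L, 60L + as.integer(floor(rexp(n, rate))))
  bmi_par <- m$bmi %||% c(23.5, 3.46)

  patients <- tibble::tibble(
    patient_id      = sprintf("P%06d", seq_len(n)),
    age_years       = age_years,
    sex             = ifelse(draw("male", 0.517), "male", "female"),
    smoking         = draw("smoking", 0.10),
    bmi             = round(rnorm(n, bmi_par[1], bmi_par[2]), 1),
    hypertension    = draw("hypertension", 0.505),
    chd             = draw("chd", 0.103),
    diabetes        = draw("diabetes", 0.126),
    stroke          = draw("stroke", 0.015),
    copd            = draw("copd", 0.010),
    asa_ge3         = draw("asa_ge3", 0.228),
    albumin_lt35    = draw("albumin_lt35", 0.129),
    high_creatinine = draw("high_creatinine", 0.095),
    wbc_gt10        = draw("wbc_gt10", 0.088),
    op_time_ge3h    = draw("op_time_ge3h", 0.21),
    major_surgery   = draw("major_surgery", 0.96),
    stay_hours      = round(exp(rnorm(n, log(120), 0.8)), 1),
    high_altitude   = draw("high_altitude", 0.01)
  )
  patients$age_ge75 <- patients$age_years >= 75

  # intraoperative bleeding is concentrated in long operations
  p_bleed <- ifelse(patients$op_time_ge3h,
                    config$bleed_prob_given_long_op,
                    config$bleed_prob_short_op)
  patients$bleeding_ge500ml <- as.logical(rbinom(n, 1, p_bleed))

  p_icu <- plogis(qlogis(0.055) + 0.7 * patients$asa_ge3 +
                    0.5 * patients$op_time_ge3h)
  patients$icu_admission <- as.logical(rbinom(n, 1, p_icu))

  # hemoglobin trajectory: admission, preop, surgery drop, slow recovery
  hb <- matrix(NA_real_, n, K)
  hb[, 1] <- rnorm(n, config$hb_preop_mean, config$hb_preop_sd)
  hb[, 2] <- hb[, 1] + rnorm(n, 0, 0.3)
  drop <- pmax(0, rnorm(n, 1.8, 0.7)) +
    patients$bleeding_ge500ml * config$hb_drop_per_bleed * runif(n, 0.8, 1.2)
  hb[, 3] <- hb[, 2] - drop + rnorm(n, 0, 0.3)
  if (K > 3) {
    for (j in 4:K) hb[, j] <- hb[, j - 1] + rnorm(n, 0.15, 0.3)
  }
  hb <- pmin(pmax(hb, 3), 20)

  # sequential transfusion decisions at occasions 1..K-1 (0-based)
  tc <- config$transfusion_coefs
  s <- config$confounding_strength
  intercept <- tc$intercept +
    qlogis(config$target_transfusion_rate) - qlogis(0.108)
  first_tx_occ <- rep(NA_real_, n)
  ev_id <- character(0); ev_occ <- numeric(0)
  for (j in 2:K) {
    current <- hb[, j]
    bleed_active <- patients$bleeding_ge500ml & j >= 3
    lp <- intercept + s * (tc$hb * pmax(0, tc$hb_ref - current) +
                             tc$bleed * bleed_active +
                             tc$asa * patients$asa_ge3 +
                             tc$op_time * patients$op_time_ge3h)
    tx_now <- runif(n) < plogis(lp)
    if (any(tx_now)) {
      occ <- (j - 1) + 0.5
      ev_id <- c(ev_id, patients$patient_id[tx_now])
      ev_occ <- c(ev_occ, rep(occ, sum(tx_now)))
      first_tx_occ[tx_now & is.na(first_tx_occ)] <- occ
      if (j < K) {
        gain <- matrix(config$transfusion_hb_gain, sum(tx_now), K - j)
        hb[tx_now, (j + 1):K] <-
          pmin(hb[tx_now, (j + 1):K, drop = FALSE] + gain, 20)
      }
    }
  }
  patients$transfused <- !is.na(first_tx_occ)

  transfusions <- tibble::tibble(patient_id = ev_id, occasion = ev_occ) |>
    dplyr::arrange(.data$patient_id, .data$occasion) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(episode = dplyr::row_number()) |>
    dplyr::ungroup()

  patients$preop_hb <- round(hb[, 2], 1)

  # composite outcome from nadir anemia, bleeding, severity, age, comorbidity
  oc <- config$outcome_coefs
  nadir <- do.call(pmin, as.data.frame(hb))
  any_comorb <- patients$hypertension | patients$chd | patients$diabetes |
    patients$stroke | patients$copd
  lp_out <- oc$intercept + oc$hb * (oc$hb_ref - nadir) +
    oc$severe * pmax(0, oc$severe_ref - nadir)^2 +
    oc$bleed * patients$bleeding_ge500ml +
    oc$asa * patients$asa_ge3 +
    oc$age * patients$age_ge75 +
    oc$comorbidity * any_comorb +
    config$true_transfusion_log_or * patients$transfused
  composite <- runif(n) < plogis(lp_out)

  # split the composite into outcome groups; every event shows at least one
  isch <- composite & (runif(n) < 0.14)
  inf <- composite & (runif(n) < 0.62)
  oth <- composite & (runif(n) < 0.18)
  death <- composite & (runif(n) < 0.20)
  none <- composite & !(isch | inf | oth | death)
  inf[none] <- TRUE
  patients$complication_ischemic <- isch
  patients$complication_infection <- inf
  patients$complication_other <- oth
  patients$death <- death

  if (config$missing_op_time_rate > 0) {
    miss <- runif(n) < config$missing_op_time_rate
    patients$op_time_ge3h[miss] <- NA
  }

  hemoglobin <- tibble::tibble(
    patient_id = rep(patients$patient_id, each = K),
    occasion = rep(0:(K - 1), n),
    label = rep(config$measurement_schedule, n),
    hb_gdl = round(as.vector(t(hb)), 2)
  )

  truth <- tibble::tibble(
    patient_id = patients$patient_id,
    linear_predictor_outcome = lp_out,
    was_confounded = patients$bleeding_ge500ml | nadir < tc$hb_ref,
    counterfactual_outcome_prob_untransfused =
      plogis(lp_out - config$true_transfusion_log_or * patients$transfused)
  )

  structure(
    list(patients = patients, hemoglobin = hemoglobin,
         transfusions = transfusions, truth = truth, config = config),
    class = "hb_cohort"
  )
}

#' @export
print.hb_cohort <- function(x, ...) {
  cat("<hb_cohort>\n")
  cat(sprintf("  %d patients, %d transfused (%.1f%%)\n",
              nrow(x$patients), sum(x$patients$transfused),
              100 * mean(x$patients$transfused)))
  cat(sprintf("  %d hemoglobin measurements, %d transfusion events\n",
              nrow(x$hemoglobin), nrow(x$transfusions)))
  invisible(x)
}

#' Write / read a simulated cohort as CSV files
#'
#' `write_cohort()` writes `patients.csv`, `hemoglobin.csv`,
#' `transfusions.csv` and `truth.csv` into `dir`; `read_cohort()` reads the
#' first three (plus `truth.csv` when present) back into an `hb_cohort`-like
#' list. These are the on-disk interchange format of the pipeline: real data
#' prepared in the same column dictionary can be analyzed identically.
#'
#' @param cohort An `hb_cohort` (or list with the same tables).
#' @param dir Directory (created if needed).
#' @return `write_cohort()` the directory path, invisibly; `read_cohort()` a
#'   list of tibbles.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$patients, file.path(dir, "patients.csv"))
  readr::write_csv(cohort$hemoglobin, file.path(dir, "hemoglobin.csv"))
  readr::write_csv(cohort$transfusions, file.path(dir, "transfusions.csv"))
  if (!is.null(cohort$truth))
    readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE,
                                       progress = FALSE)
  out <- list(patients = read1("patients.csv"),
              hemoglobin = read1("hemoglobin.csv"),
              transfusions = read1("transfusions.csv"))
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) out$truth <- readr::read_csv(tf,
                                                    show_col_types = FALSE,
                                                    progress = FALSE)
  structure(out, class = "hb_cohort")
}
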