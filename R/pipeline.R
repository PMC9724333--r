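#' Default covariate roster for descriptive and balance tables
#'
#' The baseline-characteristics roster: demographics, comorbidity, ASA,
#' preoperative laboratory flags, preoperative hemoglobin, intraoperative
#' features and ICU admission. Multi-level characteristics are dichotomized
#' (age >= 75, ASA >= 3, operation time >= 3 h, bleeding >= 500 mL) before
#' balance assessment.
#'
#' @return Character vector of column names.
#' @export
default_roster <- function() {
  c("male", "age_ge75", "smoking", "bmi", "hypertension", "chd",
    "diabetes", "stroke", "copd", "asa_ge3", "albumin_lt35",
    "high_creatinine", "wbc_gt10", "preop_hb", "op_time_ge3h",
    "bleeding_ge500ml", "icu_admission")
}

# Derived analysis columns used across the pipeline.
prepare_analysis_columns <- function(patients) {
  dat <- tibble::as_tibble(patients)
  if (!"male" %in% names(dat) && "sex" %in% names(dat))
    dat$male <- dat$sex == "male"
  if (!"age_ge75" %in% names(dat) && "age_years" %in% names(dat))
    dat$age_ge75 <- dat$age_years >= 75
  flags <- c("hypertension", "chd", "diabetes", "stroke", "copd")
  if (!"any_comorbidity" %in% names(dat) && all(flags %in% names(dat)))
    dat$any_comorbidity <- Reduce(`|`, lapply(dat[flags], `%in%`, TRUE))
  dat
}

#' Analysis run configuration
#'
#' Configuration for the four-dataset workflow: either simulate a cohort
#' ([sim_config()]) or read `patients.csv`, `hemoglobin.csv` and
#' `transfusions.csv` from `input_dir`.
#'
#' @param simulate Simulate the cohort (`TRUE`) or read it from `input_dir`.
#' @param sim An [sim_config()] used when `simulate = TRUE`.
#' @param input_dir Directory with the three input CSVs when
#'   `simulate = FALSE`.
#' @param hb_window Main hemoglobin window, g/dL. Default `c(7.5, 9.5)`.
#' @param sensitivity_windows List of additional windows analyzed alongside
#'   the main one. Default `list(c(8, 10))`.
#' @param caliper_multiplier Matching caliper in pooled score SDs.
#'   Default 0.2.
#' @param ps_covariates_base,ps_covariates_study Propensity covariate sets.
#' @param outcome_covariates_base,outcome_covariates_study Adjustment sets.
#' @param roster Covariate roster for descriptive/balance tables.
#' @param seed Seed for matching order (and simulation, when `sim` carries
#'   no explicit seed change).
#' @param output_dir Directory used by [generate_report()]. Default
#'   `NULL` (report kept in memory until written).
#' @return A list of class `hb_run_config`.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(),
                       input_dir = NULL,
                       hb_window = c(7.5, 9.5),
                       sensitivity_windows = list(c(8, 10)),
                       caliper_multiplier = 0.2,
                       ps_covariates_base = ps_covariates("base"),
                       ps_covariates_study = ps_covariates("study"),
                       outcome_covariates_base = outcome_covariates("base"),
                       outcome_covariates_study = outcome_covariates("study"),
                       roster = default_roster(),
                       seed = 1L, output_dir = NULL) {
  check_window <- function(w, nm) {
    if (!is.numeric(w) || length(w) != 2 || w[1] >= w[2])
      abort(sprintf("`%s` must be c(low, high) with low < high", nm),
            class = "hb_window_error")
  }
  check_window(hb_window, "hb_window")
  for (w in sensitivity_windows) check_window(w, "sensitivity_windows")
  if (!simulate) {
    if (is.null(input_dir) || !dir.exists(input_dir))
      abort("`input_dir` must be an existing directory when simulate = FALSE",
            class = "hb_config_error")
  }
  structure(
    list(simulate = simulate, sim = sim, input_dir = input_dir,
         hb_window = hb_window, sensitivity_windows = sensitivity_windows,
         caliper_multiplier = caliper_multiplier,
         ps_covariates_base = ps_covariates_base,
         ps_covariates_study = ps_covariates_study,
         outcome_covariates_base = outcome_covariates_base,
         outcome_covariates_study = outcome_covariates_study,
         roster = roster, seed = as.integer(seed), output_dir = output_dir),
    class = "hb_run_config"
  )
}

# Diagnostics + effect for one analysis dataset. Effect failures (no events,
# separation) are recorded as "not estimable" rather than aborting the run.
analyze_dataset <- function(label, dat, roster, ps_covs, out_covs,
                            psfit = NULL, match = NULL) {
  roster <- intersect(roster, names(dat))
  balance <- balance_table(dat, roster)
  summary <- descriptive_summary(dat, roster)
  overlap <- NULL
  if (!is.null(psfit)) {
    scored <- dplyr::inner_join(dat, psfit$scores, by = "patient_id")
    overlap <- tryCatch(overlap_summary(scored),
                        error = function(e) NULL)
  }
  effect <- tryCatch(
    fit_outcome_model(dat, covariates = out_covs, label = label),
    error = function(e) structure(list(label = label,
                                       message = conditionMessage(e)),
                                  class = "hb_effect_unestimable"))
  list(label = label, n = nrow(dat),
       n_exposed = sum(dat$transfused %in% TRUE),
       members = dat[, c("patient_id", "transfused")],
       summary = summary, balance = balance, overlap = overlap,
       match = match, effect = effect,
       ps_covariates = ps_covs, outcome_covariates = out_covs)
}

#' Run the four-dataset analysis workflow
#'
#' Executes the complete design on one cohort: build the base population,
#' extract trigger values, build the study population(s), fit propensity
#' models, match within each population, and estimate the transfusion -
#' composite-outcome odds ratio in all four analysis datasets — the base
#' population before (Base Match-) and after (Base Match+) propensity-score
#' matching, and the hemoglobin-window study population before (Study
#' Match-) and after (Study Match+) matching. Sensitivity windows add
#' further Study Match-/Match+ pairs. The run is deterministic given the
#' configuration seed.
#'
#' @param config An [run_config()].
#' @return A list of class `hb_report_bundle`: `datasets` (named list, one
#'   entry per analysis dataset with descriptive summary, balance table,
#'   propensity overlap, match result and effect estimate), `base` and
#'   `study` population definitions, `triggers`, and `manifest` (seed,
#'   package version, filter accounting).
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(sim = sim_config(n_patients = 3000, seed = 11))
#' bundle <- run_four_dataset_analysis(cfg)
#' report <- generate_report(bundle)
#' report$effects
#' }
run_four_dataset_analysis <- function(config = run_config()) {
  cohort <- if (config$simulate) {
    simulate_cohort(config$sim)
  } else {
    read_cohort(config$input_dir)
  }
  patients <- prepare_analysis_columns(cohort$patients)
  if (!"transfused" %in% names(patients)) {
    patients$transfused <-
      patients$patient_id %in% cohort$transfusions$patient_id
  }
  patients <- define_composite_outcome(patients)

  base <- build_base_population(patients)
  base_ids <- base$data$patient_id
  triggers <- extract_trigger_values(
    dplyr::filter(cohort$hemoglobin, .data$patient_id %in% base_ids),
    dplyr::filter(cohort$transfusions, .data$patient_id %in% base_ids))

  datasets <- list()

  # --- base population, unmatched and matched -------------------------------
  ps_base <- fit_propensity(base$data, config$ps_covariates_base)
  base_scored <- dplyr::inner_join(base$data, ps_base$scores,
                                   by = "patient_id")
  datasets[["BaseMatchMinus"]] <- analyze_dataset(
    "BaseMatchMinus", base_scored, config$roster,
    config$ps_covariates_base, config$outcome_covariates_base,
    psfit = ps_base)
  m_base <- ps_match(base_scored, config$caliper_multiplier,
                     seed = config$seed)
  datasets[["BaseMatchPlus"]] <- analyze_dataset(
    "BaseMatchPlus", matched_data(base_scored, m_base), config$roster,
    config$ps_covariates_base, config$outcome_covariates_base,
    psfit = ps_base, match = m_base)

  # --- study population(s) --------------------------------------------------
  windows <- c(list(config$hb_window), config$sensitivity_windows)
  study_defs <- list()
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    suffix <- if (i == 1) "" else sprintf("[%g-%g]", w[1], w[2])
    study <- build_study_population(base, triggers, window = w)
    study_defs[[length(study_defs) + 1]] <- study$definition
    lab_minus <- paste0("StudyMatchMinus", suffix)
    lab_plus <- paste0("StudyMatchPlus", suffix)
    # a degenerate study population (separation, empty group) must not sink
    # the whole run: the matched dataset is then empty / not estimable
    ps_study <- tryCatch(
      fit_propensity(study$data, config$ps_covariates_study),
      error = function(e) e)
    if (inherits(ps_study, "error")) {
      datasets[[lab_minus]] <- analyze_dataset(
        lab_minus, study$data, config$roster,
        config$ps_covariates_study, config$outcome_covariates_study)
      datasets[[lab_plus]] <- analyze_dataset(
        lab_plus, study$data[0, , drop = FALSE], config$roster,
        config$ps_covariates_study, config$outcome_covariates_study)
      datasets[[lab_plus]]$effect <- structure(
        list(label = lab_plus, message = conditionMessage(ps_study)),
        class = "hb_effect_unestimable")
      next
    }
    study_scored <- dplyr::inner_join(study$data, ps_study$scores,
                                      by = "patient_id")
    datasets[[lab_minus]] <- analyze_dataset(
      lab_minus, study_scored, config$roster,
      config$ps_covariates_study, config$outcome_covariates_study,
      psfit = ps_study)
    m_study <- ps_match(study_scored, config$caliper_multiplier,
                        seed = config$seed)
    datasets[[lab_plus]] <- analyze_dataset(
      lab_plus, matched_data(study_scored, m_study), config$roster,
      config$ps_covariates_study, config$outcome_covariates_study,
      psfit = ps_study, match = m_study)
  }

  manifest <- list(
    package = "hbdesign",
    version = as.character(utils::packageVersion("hbdesign")),
    seed = config$seed,
    simulated = config$simulate,
    hb_window = config$hb_window,
    sensitivity_windows = config$sensitivity_windows,
    caliper_multiplier = config$caliper_multiplier,
    n_input = nrow(patients),
    base_exclusions = as.data.frame(base$definition$exclusions),
    study_exclusions = lapply(study_defs,
                              function(d) as.data.frame(d$exclusions)),
    n_unresolvable_triggers = sum(triggers$unresolvable),
    dataset_sizes = vapply(datasets, function(d) d$n, integer(1))
  )

  structure(
    list(datasets = datasets, base = base$definition,
         study = study_defs, triggers = triggers, manifest = manifest,
         config = config),
    class = "hb_report_bundle"
  )
}

#' @export
print.hb_report_bundle <- function(x, ...) {
  cat("<hb_report_bundle>\n")
  for (d in x$datasets) {
    est <- if (inherits(d$effect, "hb_effect"))
      sprintf("OR %.2f (%.2f-%.2f)", d$effect$odds_ratio,
              d$effect$ci_low, d$effect$ci_high)
    else "not estimable"
    cat(sprintf("  %-22s n = %5d (%4d exposed)  %s\n",
                d$label, d$n, d$n_exposed, est))
  }
  invisible(x)
}

#' Generate the analysis report
#'
#' Assembles (and optionally writes) the human-readable outputs of a
#' four-dataset run: an effect-comparison table across analysis datasets, a
#' balance-trajectory table (SMD of every roster covariate across datasets),
#' matching summaries, and the run manifest. Datasets whose effect could not
#' be estimated (for example no events after matching) are reported as
#' "not estimable" rather than failing.
#'
#' @param bundle An `hb_report_bundle` from [run_four_dataset_analysis()].
#' @param dir Output directory; when `NULL` (default), taken from the run
#'   config's `output_dir`, and when that is also `NULL` nothing is written.
#' @return A list of class `hb_report`: `effects` (tibble), `balance_trajectory`
#'   (tibble, variables x datasets), `matching` (tibble), `manifest`; plus
#'   `files` when written to disk.
#' @export
generate_report <- function(bundle, dir = NULL) {
  if (!inherits(bundle, "hb_report_bundle") || is.null(bundle$datasets) ||
      length(bundle$datasets) == 0)
    abort("Incomplete bundle: no analysis datasets present",
          class = "hb_report_error")
  needed <- c("summary", "balance", "effect")
  for (d in bundle$datasets) {
    missing <- needed[vapply(needed, function(f) is.null(d[[f]]), logical(1))]
    if (length(missing) > 0)
      abort(paste0("Incomplete bundle: dataset ", d$label,
                   " is missing stage(s): ",
                   paste(missing, collapse = ", ")),
            class = "hb_report_error")
  }

  effects <- purrr::map_dfr(bundle$datasets, function(d) {
    if (inherits(d$effect, "hb_effect")) {
      dplyr::mutate(glance(d$effect), estimable = TRUE, note = "")
    } else {
      tibble::tibble(label = d$label, odds_ratio = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     p_value = NA_real_, n = d$n, n_events = NA_integer_,
                     n_dropped = NA_integer_, covariates = "",
                     estimable = FALSE,
                     note = paste("not estimable:", d$effect$message))
    }
  })

  balance_trajectory <- purrr::map_dfr(bundle$datasets, function(d) {
    dplyr::mutate(
      dplyr::select(d$balance, "variable", "smd_percent"),
      dataset = d$label)
  }) |>
    tidyr::pivot_wider(names_from = "dataset", values_from = "smd_percent")

  matching <- purrr::map_dfr(bundle$datasets, function(d) {
    if (is.null(d$match)) return(tibble::tibble())
    dplyr::mutate(glance(d$match), label = d$label, .before = 1)
  })

  report <- structure(
    list(effects = effects, balance_trajectory = balance_trajectory,
         matching = matching, manifest = bundle$manifest),
    class = "hb_report"
  )

  dir <- dir %||% bundle$config$output_dir
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    w <- function(x, f) {
      p <- file.path(dir, f); readr::write_csv(x, p); p
    }
    files <- c(files, w(effects, "effects.csv"))
    files <- c(files, w(balance_trajectory, "balance_trajectory.csv"))
    if (nrow(matching) > 0)
      files <- c(files, w(matching, "matching.csv"))
    for (d in bundle$datasets) {
      safe <- gsub("[^A-Za-z0-9_+-]", "_", d$label)
      files <- c(files, w(d$balance, sprintf("balance_%s.csv", safe)))
      files <- c(files, w(d$summary, sprintf("summary_%s.csv", safe)))
      files <- c(files, w(d$members, sprintf("members_%s.csv", safe)))
      if (!is.null(d$match))
        files <- c(files, w(d$match$pairs, sprintf("matches_%s.csv", safe)))
    }
    mp <- file.path(dir, "manifest.json")
    jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    files <- c(files, mp)
    md <- file.path(dir, "report.md")
    writeLines(render_report_md(report), md)
    files <- c(files, md)
    report$files <- files
  }
  report
}

render_report_md <- function(report) {
  fmt_or <- function(r) {
    if (!r$estimable) return("not estimable")
    sprintf("%.2f (%.2f-%.2f), p = %.3g", r$odds_ratio, r$ci_low,
            r$ci_high, r$p_value)
  }
  lines <- c("# Transfusion-outcome analysis report", "",
             "## Effect comparison", "",
             "| dataset | n | events | OR (95% CI) |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(report$effects))) {
    r <- report$effects[i, ]
    lines <- c(lines, sprintf("| %s | %d | %s | %s |", r$label, r$n,
                              ifelse(is.na(r$n_events), "-",
                                     as.character(r$n_events)),
                              fmt_or(r)))
  }
  bt <- report$balance_trajectory
  lines <- c(lines, "", "## Balance trajectory (SMD, %)", "",
             paste0("| variable | ",
                    paste(names(bt)[-1], collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(bt)), collapse = "|"), "|"))
  for (i in seq_len(nrow(bt))) {
    vals <- vapply(as.numeric(bt[i, -1]), function(v)
      ifelse(is.na(v), "-", sprintf("%.1f", v)), character(1))
    lines <- c(lines, paste0("| ", bt$variable[i], " | ",
                             paste(vals, collapse = " | "), " |"))
  }
  lines
}

#' @export
print.hb_report <- function(x, ...) {
  cat("<hb_report>\n")
  print(x$effects[, c("label", "odds_ratio", "ci_low", "ci_high",
                      "p_value", "n", "estimable")])
  invisible(x)
}
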