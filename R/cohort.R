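#' Build the base population
#'
#' Applies the base-population inclusion criteria to a patient table:
#' major surgery (an anesthesiologist present), hospital stay of at least 24
#' hours, and residence below high altitude (patients living at 2000-5000 m
#' are excluded because the usual transfusion thresholds do not apply to
#' them). Each filter's exclusion count is recorded so the cohort flow can be
#' audited.
#'
#' @param patients Data frame of patient records; must contain
#'   `patient_id`, `major_surgery`, `stay_hours`, `high_altitude`.
#' @param min_stay_hours Minimum hospital stay, in hours. Default 24.
#' @return A list of class `hb_population`:
#'   \describe{
#'     \item{data}{tibble of retained records.}
#'     \item{definition}{an `hb_cohort_definition`: label, optional
#'       hemoglobin window, and a tibble of per-filter exclusion counts.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 300, seed = 1))
#' base <- build_base_population(cohort$patients)
#' base$definition
build_base_population <- function(patients, min_stay_hours = 24) {
  require_columns(patients,
                  c("patient_id", "major_surgery", "stay_hours",
                    "high_altitude"))
  dat <- tibble::as_tibble(patients)
  filters <- list(
    major_surgery = function(d) d$major_surgery %in% TRUE,
    stay_ge24h    = function(d) !is.na(d$stay_hours) &
                                d$stay_hours >= min_stay_hours,
    not_high_altitude = function(d) !(d$high_altitude %in% TRUE)
  )
  res <- apply_filters(dat, filters)
  definition <- new_cohort_definition("base", window = NULL,
                                      exclusions = res$log,
                                      n_input = nrow(dat),
                                      n_retained = nrow(res$data))
  structure(list(data = res$data, definition = definition),
            class = "hb_population")
}

apply_filters <- function(dat, filters) {
  log <- tibble::tibble(filter = character(0), excluded = integer(0))
  for (nm in names(filters)) {
    keep <- filters[[nm]](dat)
    log <- dplyr::bind_rows(log,
      tibble::tibble(filter = nm, excluded = sum(!keep)))
    dat <- dat[keep, , drop = FALSE]
  }
  list(data = dat, log = log)
}

new_cohort_definition <- function(label, window, exclusions, n_input,
                                  n_retained) {
  structure(
    list(label = label, hb_window = window, exclusions = exclusions,
         n_input = n_input, n_retained = n_retained),
    class = "hb_cohort_definition"
  )
}

#' @export
print.hb_cohort_definition <- function(x, ...) {
  cat(sprintf("<hb_cohort_definition> %s population\n", x$label))
  if (!is.null(x$hb_window))
    cat(sprintf("  hemoglobin window: [%.1f, %.1f] g/dL\n",
                x$hb_window[1], x$hb_window[2]))
  cat(sprintf("  input %d -> retained %d\n", x$n_input, x$n_retained))
  for (i in seq_len(nrow(x$exclusions)))
    cat(sprintf("  - %s: %d excluded\n",
                x$exclusions$filter[i], x$exclusions$excluded[i]))
  invisible(x)
}

#' @export
print.hb_population <- function(x, ...) {
  print(x$definition)
  invisible(x)
}

require_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    abort(paste0("Input table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hb_schema_error")
  invisible(df)
}

#' Extract per-patient transfusion trigger values
#'
#' The trigger value stands in for the hemoglobin level at which the
#' transfusion decision was (or was not) made: for transfused patients it is
#' the last measurement strictly before the initial transfusion; for
#' non-transfused patients it is the nadir over the whole hospital stay
#' (the preoperative measurement included). A transfused patient with no
#' measurement before the first transfusion cannot be assigned a trigger and
#' is flagged `unresolvable`; downstream cohort construction excludes and
#' counts such patients.
#'
#' If two measurements share an occasion index the lower value is kept
#' (deterministic, conservative for anemia).
#'
#' @param hb Data frame of hemoglobin measurements with columns
#'   `patient_id`, `occasion` (ordered, numeric), `hb_gdl`.
#' @param transfusions Data frame of transfusion events with `patient_id`
#'   and `occasion` (half-integer occasions lie strictly between
#'   measurements). May be empty.
#' @return A tibble with one row per patient in `hb`: `patient_id`, `value`
#'   (g/dL), `source` (`"last_pre_transfusion"` or `"stay_nadir"`),
#'   `occasion_index` of the trigger measurement, and `unresolvable`.
#' @export
#' @examples
#' hb <- tibble::tibble(patient_id = "A", occasion = 0:2,
#'                      hb_gdl = c(13.0, 8.9, 9.4))
#' tx <- tibble::tibble(patient_id = "A", occasion = 1.5)
#' extract_trigger_values(hb, tx)
extract_trigger_values <- function(hb, transfusions) {
  require_columns(hb, c("patient_id", "occasion", "hb_gdl"))
  if (nrow(hb) == 0)
    abort("No hemoglobin measurements supplied", class = "hb_trigger_error")
  if (anyNA(hb$hb_gdl) || anyNA(hb$occasion))
    abort("Hemoglobin measurements must not contain missing values",
          class = "hb_trigger_error")
  tx <- if (is.null(transfusions) || nrow(transfusions) == 0) {
    tibble::tibble(patient_id = character(0), occasion = numeric(0))
  } else {
    require_columns(transfusions, c("patient_id", "occasion"))
    tibble::as_tibble(transfusions)
  }

  first_tx <- if (nrow(tx) == 0) {
    tibble::tibble(patient_id = character(0),
                   first_tx_occasion = numeric(0))
  } else {
    tx |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(first_tx_occasion = min(.data$occasion),
                       .groups = "drop")
  }

  d <- hb |>
    tibble::as_tibble() |>
    dplyr::left_join(first_tx, by = "patient_id")

  empty_trigger <- tibble::tibble(patient_id = character(0),
                                  value = numeric(0),
                                  occasion_index = numeric(0))

  # controls: in-stay nadir (earliest occasion on value ties)
  ctrl_rows <- d |> dplyr::filter(is.na(.data$first_tx_occasion))
  ctrl <- if (nrow(ctrl_rows) == 0) empty_trigger else
    ctrl_rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      value = min(.data$hb_gdl),
      occasion_index = min(.data$occasion[.data$hb_gdl == min(.data$hb_gdl)]),
      .groups = "drop")
  ctrl <- dplyr::mutate(ctrl, source = "stay_nadir", unresolvable = FALSE)

  # transfused: last measurement strictly before the initial transfusion
  # (lower value kept if two measurements share that occasion)
  tx_pat <- d |> dplyr::filter(!is.na(.data$first_tx_occasion))
  pre_rows <- tx_pat |>
    dplyr::filter(.data$occasion < .data$first_tx_occasion)
  res_tx <- if (nrow(pre_rows) == 0) empty_trigger else
    pre_rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      value = min(.data$hb_gdl[.data$occasion == max(.data$occasion)]),
      occasion_index = max(.data$occasion),
      .groups = "drop")
  res_tx <- dplyr::mutate(res_tx, source = "last_pre_transfusion",
                          unresolvable = FALSE)
  unres_ids <- setdiff(unique(tx_pat$patient_id), res_tx$patient_id)
  unres <- tibble::tibble(patient_id = unres_ids, value = NA_real_,
                          occasion_index = NA_real_,
                          source = "last_pre_transfusion",
                          unresolvable = TRUE)

  dplyr::bind_rows(ctrl, res_tx, unres) |>
    dplyr::select("patient_id", "value", "source", "occasion_index",
                  "unresolvable") |>
    dplyr::arrange(.data$patient_id)
}

#' Build the study population
#'
#' Restricts a base population to the hemoglobin-defined study population:
#' no intraoperative bleeding >= 500 mL (the "stable" requirement), and a
#' trigger value inside the hemoglobin window of interest (default
#' 7.5-9.5 g/dL, the gray zone between restrictive and liberal transfusion
#' thresholds; bounds inclusive). The window naturally excludes severe
#' anemia left untransfused and transfusion given at hemoglobin at or above
#' 10 g/dL, the two strongest sources of bias by indication. Patients whose
#' trigger is unresolvable are excluded and counted.
#'
#' @param base An `hb_population` from [build_base_population()] (or a list
#'   with a `data` tibble).
#' @param triggers Trigger table from [extract_trigger_values()].
#' @param window Numeric `c(low, high)` hemoglobin window in g/dL,
#'   `low < high`. Default `c(7.5, 9.5)`.
#' @return An `hb_population` whose `definition` carries the window and the
#'   per-criterion exclusion counts; `data` gains `trigger_value` and
#'   `trigger_source` columns.
#' @export
build_study_population <- function(base, triggers, window = c(7.5, 9.5)) {
  if (!is.numeric(window) || length(window) != 2 || !all(is.finite(window)) ||
      window[1] >= window[2])
    abort("`window` must be c(low, high) with low < high",
          class = "hb_window_error")
  dat <- tibble::as_tibble(base$data)
  require_columns(dat, c("patient_id", "bleeding_ge500ml"))
  require_columns(triggers, c("patient_id", "value", "source",
                              "unresolvable"))
  dat <- dat |>
    dplyr::left_join(
      dplyr::select(triggers, "patient_id", trigger_value = "value",
                    trigger_source = "source", "unresolvable"),
      by = "patient_id")
  filters <- list(
    trigger_resolvable = function(d) !is.na(d$unresolvable) & !d$unresolvable,
    no_bleeding_ge500ml = function(d) !(d$bleeding_ge500ml %in% TRUE),
    trigger_in_window = function(d) !is.na(d$trigger_value) &
      d$trigger_value >= window[1] & d$trigger_value <= window[2]
  )
  res <- apply_filters(dat, filters)
  res$data$unresolvable <- NULL
  definition <- new_cohort_definition("study", window = window,
                                      exclusions = res$log,
                                      n_input = nrow(dat),
                                      n_retained = nrow(res$data))
  structure(list(data = res$data, definition = definition),
            class = "hb_population")
}

#' Define the composite adverse outcome
#'
#' Adds a logical `composite_outcome` column: death (in hospital or within 30
#' days of discharge) or any in-hospital complication group (ischemic events,
#' infection, others). The composite stabilizes estimation of these
#' low-incidence events. Missing outcome flags are treated as no event, with
#' a message reporting how many values were imputed that way.
#'
#' @param patients Data frame with `death` and `complication_*` columns.
#' @param outcome_cols Character vector of flag columns entering the
#'   composite. Defaults to `death` plus every column starting with
#'   `complication_`.
#' @return The input as a tibble with `composite_outcome` appended.
#' @export
define_composite_outcome <- function(patients, outcome_cols = NULL) {
  dat <- tibble::as_tibble(patients)
  if (is.null(outcome_cols)) {
    outcome_cols <- c("death", grep("^complication_", names(dat),
                                    value = TRUE))
  }
  require_columns(dat, "death")
  present <- intersect(outcome_cols, names(dat))
  flags <- dat[present]
  n_missing <- sum(vapply(flags, function(x) sum(is.na(x)), integer(1)))
  if (n_missing > 0)
    inform(sprintf(
      "define_composite_outcome(): %d missing outcome flag(s) treated as FALSE",
      n_missing))
  flags <- lapply(flags, function(x) x %in% TRUE)
  dat$composite_outcome <- Reduce(`|`, flags)
  dat
}

#' Descriptive summary by exposure group
#'
#' Per-group descriptive statistics in the style of a baseline
#' characteristics table: n and percent for binary variables, mean and SD
#' for continuous ones.
#'
#' @param data Data frame including the exposure column.
#' @param variables Character vector of variable names to summarize.
#' @param exposure Name of the logical exposure column. Default
#'   `"transfused"`.
#' @return A tibble with one row per variable x group: `variable`, `type`,
#'   `group` (`"exposed"`/`"control"`), `n` (group size), `count`, `pct`
#'   (percent, e.g. 15.41), `mean`, `sd`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 400, seed = 2))
#' descriptive_summary(cohort$patients, c("asa_ge3", "preop_hb"))
descriptive_summary <- function(data, variables, exposure = "transfused") {
  dat <- tibble::as_tibble(data)
  unknown <- setdiff(c(variables, exposure), names(dat))
  if (length(unknown) > 0)
    abort(paste0("Unknown variable(s): ", paste(unknown, collapse = ", ")),
          class = "hb_schema_error")
  grp <- ifelse(dat[[exposure]] %in% TRUE, "exposed", "control")
  purrr::map_dfr(variables, function(v) {
    x <- dat[[v]]
    purrr::map_dfr(c("exposed", "control"), function(g) {
      xi <- x[grp == g]
      n <- length(xi)
      if (is_binaryish(x)) {
        cnt <- sum(xi %in% TRUE)
        tibble::tibble(variable = v, type = "binary", group = g, n = n,
                       count = cnt,
                       pct = if (n > 0) 100 * cnt / n else NA_real_,
                       mean = NA_real_, sd = NA_real_)
      } else {
        tibble::tibble(variable = v, type = "continuous", group = g, n = n,
                       count = NA_integer_, pct = NA_real_,
                       mean = mean(xi, na.rm = TRUE),
                       sd = stats::sd(xi, na.rm = TRUE))
      }
    })
  })
}

is_binaryish <- function(x) {
  is.logical(x) || all(x %in% c(0, 1, NA))
}
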