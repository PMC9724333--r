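toy_patients <- function() {
  tibble::tibble(
    patient_id = paste0("p", 1:5),
    major_surgery = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    stay_hours = c(100, 10, 48, 36, 200),
    high_altitude = c(FALSE, FALSE, FALSE, FALSE, FALSE)
  )
}

test_that("base population filters retain the right records and log counts", {
  base <- build_base_population(toy_patients())
  expect_equal(nrow(base$data), 4)
  log <- base$definition$exclusions
  expect_equal(log$excluded[log$filter == "stay_ge24h"], 1)
  expect_equal(sum(log$excluded) + base$definition$n_retained,
               base$definition$n_input)

  # high-altitude residence excludes a record
  p <- toy_patients()
  p$high_altitude[1] <- TRUE
  base2 <- build_base_population(p)
  expect_false("p1" %in% base2$data$patient_id)
  expect_equal(base2$definition$exclusions$excluded[3], 1)

  # non-major surgery excluded
  p <- toy_patients()
  p$major_surgery[5] <- FALSE
  expect_false("p5" %in% build_base_population(p)$data$patient_id)
})

test_that("empty input yields an empty base population without error", {
  base <- build_base_population(toy_patients()[0, ])
  expect_equal(nrow(base$data), 0)
  expect_true(all(base$definition$exclusions$excluded == 0))
})

test_that("missing required columns raise a schema error naming them", {
  expect_error(build_base_population(tibble::tibble(patient_id = "a")),
               "major_surgery.*stay_hours|stay_hours.*major_surgery")
})

test_that("trigger extraction follows the design's two definitions", {
  hb <- tibble::tibble(patient_id = "A", occasion = 0:2,
                       hb_gdl = c(13.0, 8.9, 9.4))
  tx <- tibble::tibble(patient_id = "A", occasion = 1.5)
  tr <- extract_trigger_values(hb, tx)
  expect_equal(tr$value, 8.9)            # last measurement before first tx
  expect_equal(tr$source, "last_pre_transfusion")
  expect_equal(tr$occasion_index, 1)

  hb2 <- tibble::tibble(patient_id = "B", occasion = 0:2,
                        hb_gdl = c(12.1, 9.2, 10.4))
  tr2 <- extract_trigger_values(hb2, tx[0, ])
  expect_equal(tr2$value, 9.2)           # in-stay nadir for controls
  expect_equal(tr2$source, "stay_nadir")

  # transfusion before the first measurement is unresolvable
  tx3 <- tibble::tibble(patient_id = "A", occasion = -0.5)
  tr3 <- extract_trigger_values(hb, tx3)
  expect_true(tr3$unresolvable)
  expect_true(is.na(tr3$value))

  expect_error(extract_trigger_values(hb[0, ], tx), "measurement")
})

test_that("trigger extraction matches an exhaustive-scan oracle on random
           series", {
  withr::with_seed(42, {
    for (i in 1:60) {
      n_occ <- sample(2:6, 1)
      occ <- 0:(n_occ - 1)
      hb <- round(runif(n_occ, 5, 15), 2)
      transfused <- runif(1) < 0.5
      first_tx <- if (transfused) sample(occ, 1) + 0.5 else NA
      d <- tibble::tibble(patient_id = "X", occasion = occ, hb_gdl = hb)
      tx <- if (transfused)
        tibble::tibble(patient_id = "X", occasion = first_tx)
      else tibble::tibble(patient_id = character(0), occasion = numeric(0))
      got <- extract_trigger_values(d, tx)
      want <- oracle_trigger(occ, hb, first_tx)
      expect_equal(got$unresolvable, want$unresolvable)
      if (!want$unresolvable) {
        expect_equal(got$value, want$value)
        expect_equal(got$source, want$source)
      }
    }
  })
})

test_that("study population enforces the hemoglobin window and bleeding
           exclusion", {
  p <- tibble::tibble(
    patient_id = paste0("p", 1:6),
    major_surgery = TRUE, stay_hours = 100, high_altitude = FALSE,
    bleeding_ge500ml = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    transfused = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  )
  triggers <- tibble::tibble(
    patient_id = paste0("p", 1:6),
    value = c(9.5, 8.0, 10.2, 8.0, 7.4, NA),
    source = c("last_pre_transfusion", "stay_nadir", "last_pre_transfusion",
               "stay_nadir", "stay_nadir", "last_pre_transfusion"),
    unresolvable = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  base <- build_base_population(p)
  st <- build_study_population(base, triggers)
  # p1: boundary 9.5 retained (inclusive); p2 retained
  expect_setequal(st$data$patient_id, c("p1", "p2"))
  log <- st$definition$exclusions
  expect_equal(log$excluded[log$filter == "trigger_resolvable"], 1)
  expect_equal(log$excluded[log$filter == "no_bleeding_ge500ml"], 1)
  # p3 (transfused at 10.2 g/dL: beyond clinical standard) and p5 (7.4)
  expect_equal(log$excluded[log$filter == "trigger_in_window"], 2)
  expect_equal(sum(log$excluded) + nrow(st$data), nrow(base$data))

  expect_error(build_study_population(base, triggers, window = c(9, 8)),
               "low < high")
})

test_that("study population purity holds on simulated data", {
  co <- small_cohort(n = 4000, seed = 21)
  p <- define_composite_outcome(co$patients)
  base <- build_base_population(p)
  tr <- extract_trigger_values(co$hemoglobin, co$transfusions)
  st <- build_study_population(base, tr)
  expect_lte(nrow(st$data), nrow(base$data))
  expect_true(all(st$data$trigger_value >= 7.5 &
                    st$data$trigger_value <= 9.5))
  expect_false(any(st$data$bleeding_ge500ml))
  expect_false(any(st$data$transfused & st$data$trigger_value >= 10))
})

test_that("composite outcome is death or any complication group", {
  d <- tibble::tibble(
    patient_id = paste0("p", 1:4),
    death = c(TRUE, FALSE, FALSE, FALSE),
    complication_ischemic = c(FALSE, FALSE, FALSE, FALSE),
    complication_infection = c(FALSE, FALSE, TRUE, FALSE),  # e.g. pneumonia
    complication_other = c(FALSE, FALSE, FALSE, FALSE)
  )
  out <- define_composite_outcome(d)
  expect_equal(out$composite_outcome, c(TRUE, FALSE, TRUE, FALSE))

  # missing flags are treated as no event, with a message
  d$death[2] <- NA
  expect_message(out2 <- define_composite_outcome(d), "missing")
  expect_false(out2$composite_outcome[2])
})

test_that("descriptive summary reproduces printed group rates", {
  fx <- table1_fixture()
  s <- descriptive_summary(fx, c("complications", "death"))
  pick <- function(v, g) s$pct[s$variable == v & s$group == g]
  expect_equal(pick("complications", "exposed"), 100 * 102 / 662,
               tolerance = 1e-10)
  expect_equal(pick("complications", "control"), 100 * 226 / 5479,
               tolerance = 1e-10)
  expect_equal(pick("death", "exposed"), 100 * 39 / 662, tolerance = 1e-10)
  expect_equal(pick("death", "control"), 100 * 29 / 5479, tolerance = 1e-10)

  # identical records give SD 0 for a continuous variable
  d <- tibble::tibble(transfused = c(TRUE, TRUE, FALSE, FALSE),
                      hb = c(10, 10, 12, 12))
  s2 <- descriptive_summary(d, "hb")
  expect_equal(s2$sd, c(0, 0))

  expect_error(descriptive_summary(fx, "nope"), "nope")
})
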