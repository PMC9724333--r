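test_that("saturated single-covariate propensity model recovers stratum
           proportions", {
  # 2x2 counts: x=0 -> 10 exposed / 40 control; x=1 -> 40 exposed / 10 control
  d <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:100),
    x = rep(c(0, 1), each = 50),
    transfused = c(rep(c(TRUE, FALSE), c(10, 40)),
                   rep(c(TRUE, FALSE), c(40, 10)))
  )
  psf <- fit_propensity(d, covariates = "x")
  scores <- sort(unique(round(psf$scores$ps, 10)))
  expect_equal(scores, c(0.2, 0.8), tolerance = 1e-8)
})

test_that("propensity scores are near-constant when covariates carry no
           information", {
  co <- simulate_cohort(sim_config(n_patients = 6000, seed = 41,
                                   confounding_strength = 0))
  psf <- fit_propensity(co$patients, ps_covariates("base"))
  prev <- mean(co$patients$transfused)
  expect_lt(sd(psf$scores$ps), 0.02)
  expect_lt(abs(mean(psf$scores$ps) - prev), 0.01)
})

test_that("exposed scores stochastically dominate control scores under
           confounding", {
  co <- small_cohort(n = 6000, seed = 42)
  psf <- fit_propensity(co$patients, ps_covariates("base"))
  d <- dplyr::inner_join(co$patients, psf$scores, by = "patient_id")
  w <- stats::wilcox.test(ps ~ transfused, data = d,
                          alternative = "less")
  expect_lt(w$p.value, 1e-10)
  expect_gt(median(d$ps[d$transfused]), median(d$ps[!d$transfused]))
})

test_that("perfect separation is reported as an explicit error", {
  d <- tibble::tibble(patient_id = sprintf("p%02d", 1:40),
                      x = rep(c(0, 1), each = 20),
                      transfused = rep(c(FALSE, TRUE), each = 20))
  expect_error(fit_propensity(d, covariates = "x"),
               class = "hb_separation_error")
})

test_that("matching resolves the worked toy examples", {
  # unique nearest neighbor within caliper
  d <- tibble::tibble(patient_id = c("e1", "c1", "c2"),
                      ps = c(0.50, 0.49, 0.60),
                      transfused = c(TRUE, FALSE, FALSE))
  m <- ps_match(d, caliper_multiplier = 0.05 / sd(d$ps), seed = 1)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$control_id, "c1")
  expect_equal(m$pairs$delta, 0.01, tolerance = 1e-12)

  # caliper excludes the only candidate
  d2 <- tibble::tibble(patient_id = c("e1", "c1"),
                       ps = c(0.9, 0.1),
                       transfused = c(TRUE, FALSE))
  m2 <- ps_match(d2, caliper_multiplier = 0.05 / sd(d2$ps), seed = 1)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$matching_rate_exposed, 0)
  expect_equal(m2$matching_rate_control, 0)

  # seeded greedy order agrees with the brute-force oracle
  d3 <- tibble::tibble(patient_id = c("e1", "e2", "c1", "c2", "c3"),
                       ps = c(0.30, 0.31, 0.305, 0.32, 0.10),
                       transfused = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  caliper_mult <- 0.05 / sd(d3$ps)
  m3 <- ps_match(d3, caliper_multiplier = caliper_mult, seed = 99)
  ord <- withr::with_seed(99L, sample(which(d3$transfused)))
  want <- oracle_greedy_match(d3$patient_id, d3$ps, d3$transfused,
                              caliper_mult * sd(d3$ps), ord)
  expect_equal(as.data.frame(m3$pairs), want, tolerance = 1e-12)
})

test_that("matching invariants hold: one-to-one, within caliper, and full
           matching for identical groups", {
  co <- small_cohort(n = 3000, seed = 43)
  psf <- fit_propensity(co$patients, ps_covariates("base"))
  d <- dplyr::inner_join(co$patients, psf$scores, by = "patient_id")
  m <- ps_match(d, 0.2, seed = 5)
  ids <- c(m$pairs$exposed_id, m$pairs$control_id)
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(m$pairs$delta <= m$caliper + 1e-12))
  expect_equal(nrow(m$pairs) + length(m$unmatched_exposed), m$n_exposed)
  expect_equal(nrow(m$pairs) + length(m$unmatched_control), m$n_control)

  # matching reduces the SMD of the propensity score itself
  bt_un <- balance_table(d, "ps")
  bt_m <- balance_table(matched_data(d, m), "ps")
  expect_lte(bt_m$smd_percent, bt_un$smd_percent)

  # equal-size groups with identical score lists match completely
  d4 <- tibble::tibble(patient_id = sprintf("p%02d", 1:20),
                       ps = rep(seq(0.1, 0.9, length.out = 10), 2),
                       transfused = rep(c(TRUE, FALSE), each = 10))
  m4 <- ps_match(d4, 0.2, seed = 1)
  expect_equal(m4$matching_rate_exposed, 100)
  expect_equal(m4$matching_rate_control, 100)
  expect_true(all(m4$pairs$delta == 0))
})

test_that("descending-order and logit-scale options are deterministic and
           honour the caliper", {
  co <- small_cohort(n = 2000, seed = 44)
  psf <- fit_propensity(co$patients, ps_covariates("base"))
  d <- dplyr::inner_join(co$patients, psf$scores, by = "patient_id")
  m1 <- ps_match(d, 0.2, seed = 1, order = "descending")
  m2 <- ps_match(d, 0.2, seed = 2, order = "descending")
  expect_identical(m1$pairs, m2$pairs)  # seed-free order is reproducible
  ml <- ps_match(d, 0.2, seed = 1, caliper_scale = "logit")
  expect_equal(ml$sd_used, sd(qlogis(d$ps)))
  expect_true(all(ml$pairs$delta <= ml$caliper + 1e-12))
})

test_that("matching errors on an empty group", {
  d <- tibble::tibble(patient_id = c("a", "b"), ps = c(0.2, 0.4),
                      transfused = c(TRUE, TRUE))
  expect_error(ps_match(d, 0.2, seed = 1), "non-empty")
})
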