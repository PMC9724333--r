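test_that("crude odds ratio reproduces closed-form worked examples", {
  e <- crude_or(10, 10, 10, 10)
  expect_equal(e$odds_ratio, 1)
  expect_equal(e$p_value, 1, tolerance = 1e-12)

  # group death counts 39/662 vs 29/5479: cross-product OR
  e2 <- crude_or(39, 623, 29, 5450)
  expect_equal(e2$odds_ratio, 11.76454309, tolerance = 1e-8)
  expect_equal(e2$ci_low, 7.223993748, tolerance = 1e-8)
  expect_equal(e2$ci_high, 19.15899694, tolerance = 1e-8)
  expect_equal(e2$n, 6141L)

  expect_error(crude_or(1, 1, 1, 0), class = "hb_zero_cell_error")
  ec <- crude_or(1, 1, 1, 0, continuity = TRUE)
  expect_equal(ec$odds_ratio, (1.5 * 0.5) / (1.5 * 1.5), tolerance = 1e-12)
  expect_error(crude_or(-1, 2, 3, 4), "nonnegative")
})

test_that("exposure-only logistic regression equals the 2x2 cross-product
           oracle", {
  withr::with_seed(11, {
    for (i in 1:10) {
      a <- sample(5:40, 1); b <- sample(5:40, 1)
      c <- sample(5:40, 1); d <- sample(5:40, 1)
      dat <- tibble::tibble(
        transfused = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
        composite_outcome = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
      )
      fit <- fit_outcome_model(dat, label = "t")
      oracle <- crude_or(a, b, c, d)
      expect_equal(fit$odds_ratio, oracle$odds_ratio, tolerance = 1e-7)
      expect_equal(fit$ci_low, oracle$ci_low, tolerance = 1e-6)
      expect_equal(fit$ci_high, oracle$ci_high, tolerance = 1e-6)
    }
  })
})

test_that("randomly permuted exposure yields null-calibrated intervals", {
  co <- simulate_cohort(sim_config(n_patients = 2500, seed = 51))
  p <- define_composite_outcome(co$patients)
  covered <- withr::with_seed(52, {
    vapply(1:100, function(i) {
      p$transfused <- sample(p$transfused)
      e <- fit_outcome_model(p, label = "perm")
      e$ci_low <= 1 && e$ci_high >= 1
    }, logical(1))
  })
  expect_gte(mean(covered), 0.88)  # ~95% nominal, Monte-Carlo slack
})

test_that("a non-informative covariate barely moves the estimate", {
  co <- simulate_cohort(sim_config(n_patients = 20000, seed = 53))
  p <- define_composite_outcome(co$patients)
  p$noise <- withr::with_seed(54, rnorm(nrow(p)))
  e0 <- fit_outcome_model(p, covariates = "preop_hb", label = "a")
  e1 <- fit_outcome_model(p, covariates = c("preop_hb", "noise"),
                          label = "b")
  se <- (log(e0$ci_high) - log(e0$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(log(e1$odds_ratio) - log(e0$odds_ratio)), 3 * se)
})

test_that("degenerate outcome distributions raise errors", {
  d <- tibble::tibble(transfused = c(TRUE, FALSE, TRUE, FALSE),
                      composite_outcome = c(FALSE, FALSE, FALSE, FALSE))
  expect_error(fit_outcome_model(d, label = "x"), "No events")
  d$composite_outcome <- TRUE
  expect_error(fit_outcome_model(d, label = "x"), "non-events")
})

test_that("complete-case exclusions are counted and comorbidity is derived", {
  co <- simulate_cohort(sim_config(n_patients = 4000, seed = 55,
                                   missing_op_time_rate = 0.05))
  p <- define_composite_outcome(co$patients)
  e <- fit_outcome_model(p, covariates = outcome_covariates("base"),
                         label = "cc")
  expect_equal(e$n_dropped, sum(is.na(p$op_time_ge3h)))
  expect_equal(e$n, nrow(p) - e$n_dropped)
  expect_true("any_comorbidity" %in% e$covariates)
})

test_that("conditional pair estimate matches the discordant-pair ratio", {
  # 30 pairs: 12 discordant exposed-event, 6 discordant control-event
  pid <- rep(1:30, each = 2)
  x <- rep(c(TRUE, FALSE), 30)
  y <- rep(FALSE, 60)
  y[seq(1, 24, by = 2)] <- TRUE          # 12 pairs: exposed event only
  y[seq(26, 36, by = 2)] <- TRUE         # 6 pairs: control event only
  d <- tibble::tibble(patient_id = as.character(1:60), pair_id = pid,
                      transfused = x, composite_outcome = y)
  e <- fit_outcome_model(d, label = "cond", conditional = TRUE)
  expect_equal(e$odds_ratio, 2)
  expect_equal(e$ci_low, exp(log(2) - qnorm(0.975) * sqrt(1 / 12 + 1 / 6)),
               tolerance = 1e-10)
})

test_that("tidy and glance expose the fitted model in broom style", {
  co <- simulate_cohort(sim_config(n_patients = 3000, seed = 56))
  p <- define_composite_outcome(co$patients)
  e <- fit_outcome_model(p, covariates = "asa_ge3", label = "t")
  td <- tidy(e)
  expect_true(all(c("term", "odds_ratio", "ci_low", "ci_high") %in%
                    names(td)))
  expect_equal(td$odds_ratio[td$term == ".exposure"], e$odds_ratio)
  g <- glance(e)
  expect_equal(g$label, "t")
  expect_equal(g$n, e$n)
})
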