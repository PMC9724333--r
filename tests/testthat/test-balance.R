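test_that("SMD formulas reproduce worked examples", {
  expect_equal(smd_continuous(5, 1, 5, 4), 0)
  expect_equal(smd_continuous(0, 1, 1, 1), 100)
  # preoperative hemoglobin 11.0 vs 13.5 g/dL with SDs 2.97 / 2.255
  expect_equal(smd_continuous(11.0, 2.97^2, 13.5, 2.255^2), 94.8102005,
               tolerance = 1e-7)
  # mass bleeding 37.9% vs 2.1%: the design's signature imbalance
  expect_equal(smd_binary(0.379, 0.021), 100.0800717, tolerance = 1e-7)
  expect_equal(smd_binary(0.5, 0.5), 0)
  expect_equal(smd_binary(0.613, 0.517), 19.4557337, tolerance = 1e-7)
})

test_that("SMD is symmetric, zero iff identical, and scale invariant", {
  withr::with_seed(7, {
    for (i in 1:50) {
      m1 <- runif(1, -5, 5); m2 <- runif(1, -5, 5)
      v1 <- runif(1, 0.1, 4); v2 <- runif(1, 0.1, 4)
      expect_equal(smd_continuous(m1, v1, m2, v2),
                   smd_continuous(m2, v2, m1, v1))
      p1 <- runif(1); p2 <- runif(1)
      expect_equal(smd_binary(p1, p2), smd_binary(p2, p1))
      # common affine rescaling leaves the continuous SMD unchanged
      a <- runif(1, 0.5, 3); b <- runif(1, -2, 2)
      expect_equal(smd_continuous(a * m1 + b, a^2 * v1, a * m2 + b, a^2 * v2),
                   smd_continuous(m1, v1, m2, v2), tolerance = 1e-9)
    }
  })
  expect_equal(smd_continuous(3, 2, 3, 2), 0)
})

test_that("degenerate zero-variance cases use the documented sentinels", {
  expect_equal(smd_continuous(1, 0, 1, 0), 0)
  expect_equal(smd_continuous(1, 0, 2, 0), Inf)
  expect_equal(smd_binary(1, 1), 0)
  expect_equal(smd_binary(0, 0), 0)
  expect_error(smd_binary(1.2, 0.5), "\\[0, 1\\]")
})

test_that("balance table matches hand computation on a 4-patient dataset", {
  d <- tibble::tibble(
    transfused = c(TRUE, TRUE, FALSE, FALSE),
    hb = c(9, 11, 12, 14),
    flag = c(TRUE, FALSE, FALSE, FALSE)
  )
  bt <- balance_table(d, c("hb", "flag"))
  # continuous: means 10 vs 13, sample variances 2 and 2 -> 3/sqrt(2)*100
  expect_equal(bt$smd_percent[bt$variable == "hb"], 3 / sqrt(2) * 100,
               tolerance = 1e-9)
  # binary: p1 = .5, p2 = 0 -> .5/sqrt(.25/2)*100
  expect_equal(bt$smd_percent[bt$variable == "flag"],
               0.5 / sqrt(0.125) * 100, tolerance = 1e-9)
  expect_true(all(bt$flag_gt10))

  # groups that are copies of each other balance exactly
  d2 <- dplyr::bind_rows(dplyr::mutate(d[1:2, ], transfused = TRUE),
                         dplyr::mutate(d[1:2, ], transfused = FALSE))
  bt2 <- balance_table(d2, c("hb", "flag"))
  expect_true(all(bt2$smd_percent == 0))
})

test_that("balance rows with an empty group are marked incomputable", {
  d <- tibble::tibble(transfused = c(TRUE, TRUE), hb = c(9, 10))
  bt <- balance_table(d, "hb")
  expect_true(bt$incomputable)
  expect_true(is.na(bt$smd_percent))
})

test_that("bleeding and operation time dominate imbalance in the unmatched
           synthetic base population", {
  co <- small_cohort(n = 8000, seed = 31)
  base <- build_base_population(co$patients)
  dat <- dplyr::mutate(base$data, male = sex == "male")
  bt <- balance_table(dat, default_roster())
  top2 <- bt$variable[order(-bt$smd_percent)][1:2]
  expect_setequal(top2, c("bleeding_ge500ml", "op_time_ge3h"))
  expect_gt(max(bt$smd_percent), 100)
})

test_that("overlap summary computes common support correctly", {
  d <- tibble::tibble(ps = c(0.1, 0.4, 0.6, 0.3, 0.5, 0.9),
                      transfused = rep(c(TRUE, FALSE), each = 3))
  ov <- overlap_summary(d)
  expect_equal(ov$overlap_low, 0.3)
  expect_equal(ov$overlap_high, 0.6)
  expect_true(ov$has_overlap)

  # identical lists overlap over the full range
  d2 <- tibble::tibble(ps = rep(c(0.2, 0.5, 0.8), 2),
                       transfused = rep(c(TRUE, FALSE), each = 3))
  ov2 <- overlap_summary(d2)
  expect_equal(c(ov2$overlap_low, ov2$overlap_high), c(0.2, 0.8))

  # disjoint groups report negative width
  d3 <- tibble::tibble(ps = c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3),
                       transfused = rep(c(TRUE, FALSE), each = 3))
  ov3 <- overlap_summary(d3)
  expect_false(ov3$has_overlap)
  expect_lt(ov3$overlap_width, 0)

  expect_error(overlap_summary(
    tibble::tibble(ps = c(0.5, 0.6), transfused = c(TRUE, TRUE))),
    "non-empty")
})
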