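#' Standardized mean difference
#'
#' Scale-free measure of between-group imbalance, reported in percent.
#' For a continuous variable,
#' \deqn{SMD = |\bar x_1 - \bar x_2| / \sqrt{(s_1^2 + s_2^2)/2} \times 100\%}
#' and for a binary variable,
#' \deqn{SMD = |p_1 - p_2| / \sqrt{(p_1(1-p_1) + p_2(1-p_2))/2} \times 100\%,}
#' where \eqn{\bar x}, \eqn{s^2} and \eqn{p} are the group mean, variance and
#' proportion. A value below 10% conventionally indicates a minor difference
#' between comparison groups. Both forms are symmetric in group order.
#'
#' Degenerate cases: when both variances (or both binary variances) are zero,
#' the SMD is 0 if the means (proportions) agree and `Inf` otherwise.
#'
#' @param mean1,mean2 Group means.
#' @param var1,var2 Group variances (>= 0); for sample data use the unbiased
#'   sample variance.
#' @param p1,p2 Group proportions in \[0, 1\].
#' @return SMD in percent (nonnegative; possibly `Inf`). Vectorized.
#' @export
#' @examples
#' smd_binary(0.379, 0.021)     # ~100%: mass-bleeding imbalance
#' smd_continuous(11.0, 2.97^2, 13.5, 2.255^2)
smd_continuous <- function(mean1, var1, mean2, var2) {
  stopifnot(all(var1 >= 0, na.rm = TRUE), all(var2 >= 0, na.rm = TRUE))
  num <- abs(mean1 - mean2)
  den <- sqrt((var1 + var2) / 2)
  out <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den * 100)
  as.numeric(out)
}

#' @rdname smd_continuous
#' @export
smd_binary <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    abort("Proportions must lie in [0, 1]", class = "hb_balance_error")
  smd_continuous(p1, p1 * (1 - p1), p2, p2 * (1 - p2))
}

#' Covariate balance table
#'
#' Computes the standardized mean difference of each roster variable between
#' the exposure groups of a dataset, together with the group summaries the
#' SMD is built from. Binary variables use the `p(1-p)` variance form of the
#' SMD; continuous variables use the unbiased sample variance. Variables with
#' fewer than one usable observation in either group are marked incomputable
#' rather than dropped.
#'
#' @param data Data frame containing the roster variables and the exposure
#'   column.
#' @param variables Character vector of covariate names. Types are inferred
#'   (logical/0-1 columns are binary); override with `types`, a named
#'   character vector of `"binary"`/`"continuous"`.
#' @param exposure Logical exposure column name. Default `"transfused"`.
#' @param types Optional named character vector overriding type inference.
#' @return A tibble of class `hb_balance`, one row per variable, ordered as
#'   given: `variable`, `type`, `n1`, `n2`, `summary1`, `summary2` (mean or
#'   proportion), `sd1`, `sd2`, `smd_percent`, `flag_gt10`, `incomputable`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 1000, seed = 3))
#' balance_table(cohort$patients, c("asa_ge3", "bleeding_ge500ml", "preop_hb"))
balance_table <- function(data, variables, exposure = "transfused",
                          types = NULL) {
  dat <- tibble::as_tibble(data)
  unknown <- setdiff(c(variables, exposure), names(dat))
  if (length(unknown) > 0)
    abort(paste0("Unknown variable(s): ", paste(unknown, collapse = ", ")),
          class = "hb_schema_error")
  exposed <- dat[[exposure]] %in% TRUE

  rows <- purrr::map_dfr(variables, function(v) {
    x <- dat[[v]]
    type <- if (!is.null(types) && v %in% names(types)) types[[v]]
            else if (is_binaryish(x)) "binary" else "continuous"
    x1 <- x[exposed & !is.na(x)]
    x2 <- x[!exposed & !is.na(x)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 1 || n2 < 1) {
      return(tibble::tibble(variable = v, type = type, n1 = n1, n2 = n2,
                            summary1 = NA_real_, summary2 = NA_real_,
                            sd1 = NA_real_, sd2 = NA_real_,
                            smd_percent = NA_real_, flag_gt10 = NA,
                            incomputable = TRUE))
    }
    if (type == "binary") {
      p1 <- mean(x1 %in% TRUE); p2 <- mean(x2 %in% TRUE)
      smd <- smd_binary(p1, p2)
      tibble::tibble(variable = v, type = type, n1 = n1, n2 = n2,
                     summary1 = p1, summary2 = p2,
                     sd1 = sqrt(p1 * (1 - p1)), sd2 = sqrt(p2 * (1 - p2)),
                     smd_percent = smd, flag_gt10 = smd > 10,
                     incomputable = FALSE)
    } else {
      v1 <- if (n1 > 1) stats::var(x1) else 0
      v2 <- if (n2 > 1) stats::var(x2) else 0
      smd <- smd_continuous(mean(x1), v1, mean(x2), v2)
      tibble::tibble(variable = v, type = type, n1 = n1, n2 = n2,
                     summary1 = mean(x1), summary2 = mean(x2),
                     sd1 = sqrt(v1), sd2 = sqrt(v2),
                     smd_percent = smd, flag_gt10 = smd > 10,
                     incomputable = FALSE)
    }
  })
  class(rows) <- c("hb_balance", class(rows))
  rows
}

#' Propensity-score overlap summary
#'
#' Five-number summaries of the propensity score per exposure group plus the
#' common-support interval: `[max of group minima, min of group maxima]`. A
#' negative-width interval means the score distributions are disjoint — the
#' groups share no region of common support and matching cannot produce
#' comparable pairs.
#'
#' @param data Data frame with the score and exposure columns.
#' @param score Name of the propensity-score column (values in (0, 1)).
#'   Default `"ps"`.
#' @param exposure Logical exposure column name. Default `"transfused"`.
#' @return A list of class `hb_overlap`: `by_group` (tibble of min, q1,
#'   median, q3, max per group), `overlap_low`, `overlap_high`,
#'   `overlap_width` (possibly negative), `has_overlap`.
#' @export
overlap_summary <- function(data, score = "ps", exposure = "transfused") {
  dat <- tibble::as_tibble(data)
  require_columns(dat, c(score, exposure))
  s <- dat[[score]]
  if (any(is.na(s)) || any(s <= 0 | s >= 1))
    abort("Propensity scores must lie strictly in (0, 1)",
          class = "hb_balance_error")
  exposed <- dat[[exposure]] %in% TRUE
  if (sum(exposed) == 0 || sum(!exposed) == 0)
    abort("Both exposure groups must be non-empty",
          class = "hb_balance_error")
  fivenum_row <- function(x, g) {
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble::tibble(group = g, n = length(x), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5])
  }
  by_group <- dplyr::bind_rows(fivenum_row(s[exposed], "exposed"),
                               fivenum_row(s[!exposed], "control"))
  lo <- max(by_group$min)
  hi <- min(by_group$max)
  structure(
    list(by_group = by_group, overlap_low = lo, overlap_high = hi,
         overlap_width = hi - lo, has_overlap = hi >= lo,
         scores = tibble::tibble(ps = s,
                                 group = ifelse(exposed, "exposed",
                                                "control"))),
    class = "hb_overlap"
  )
}

#' @export
print.hb_overlap <- function(x, ...) {
  cat("<hb_overlap>\n")
  print(x$by_group)
  if (x$has_overlap) {
    cat(sprintf("  common support: [%.4f, %.4f] (width %.4f)\n",
                x$overlap_low, x$overlap_high, x$overlap_width))
  } else {
    cat("  no common support (disjoint score distributions)\n")
  }
  invisible(x)
}
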