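# Independent oracles and programmatic fixtures used across the suite.

# Brute-force greedy 1:1 caliper matcher: processes exposed rows in the
# given order; for each, scans every remaining control and takes the
# minimum-distance one within the caliper, breaking ties on the smallest
# control id. Written as a plain double loop, independent of ps_match().
oracle_greedy_match <- function(ids, ps, exposed, caliper, exposed_order) {
  ctrl <- which(!exposed)
  taken <- rep(FALSE, length(ids))
  pairs <- list()
  for (ei in exposed_order) {
    best_d <- Inf; best_j <- NA
    for (j in ctrl) {
      if (taken[j]) next
      d <- abs(ps[ei] - ps[j])
      if (d < best_d - 1e-15 ||
          (abs(d - best_d) <= 1e-15 && !is.na(best_j) &&
           ids[j] < ids[best_j])) {
        best_d <- d; best_j <- j
      }
    }
    if (!is.na(best_j) && best_d <= caliper) {
      taken[best_j] <- TRUE
      pairs[[length(pairs) + 1]] <-
        data.frame(exposed_id = ids[ei], control_id = ids[best_j],
                   delta = best_d)
    }
  }
  if (length(pairs) == 0)
    return(data.frame(exposed_id = character(0), control_id = character(0),
                      delta = numeric(0)))
  do.call(rbind, pairs)
}

# Exhaustive-scan trigger oracle for a single patient.
oracle_trigger <- function(occ, hb, first_tx = NA) {
  if (is.na(first_tx)) {
    i <- order(hb, occ)[1]
    return(list(value = hb[i], source = "stay_nadir", unresolvable = FALSE))
  }
  pre <- which(occ < first_tx)
  if (length(pre) == 0)
    return(list(value = NA, source = "last_pre_transfusion",
                unresolvable = TRUE))
  last <- pre[occ[pre] == max(occ[pre])]
  list(value = min(hb[last]), source = "last_pre_transfusion",
       unresolvable = FALSE)
}

# Baseline-characteristics fixture reconstructed from printed group counts:
# 662 transfused (102 complications, 39 deaths), 5479 non-transfused
# (226 complications, 29 deaths). Flags are assigned to leading rows of each
# group; only the group rates matter downstream.
table1_fixture <- function() {
  mk <- function(n, exposed, n_compl, n_death) {
    tibble::tibble(
      patient_id = sprintf("%s%05d", if (exposed) "T" else "C", seq_len(n)),
      transfused = exposed,
      complications = seq_len(n) <= n_compl,
      death = seq_len(n) <= n_death
    )
  }
  dplyr::bind_rows(mk(662, TRUE, 102, 39), mk(5479, FALSE, 226, 29))
}

# Small synthetic cohort shared by several test files.
small_cohort <- function(n = 4000, seed = 101) {
  simulate_cohort(sim_config(n_patients = n, seed = seed))
}
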