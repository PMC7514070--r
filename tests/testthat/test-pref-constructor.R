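test_that("the t-value matches the correlation-test statistic", {
  # oracle: exact-correlation vector pairs pushed through cor.test
  for (r in c(-0.9, -0.5, 0, 0.3, 0.5, 0.9)) {
    for (n in c(52, 102, 300)) {
      pair <- exact_cor_pair(r, n)
      oracle <- unname(cor.test(pair$x, pair$y)$statistic)
      expect_equal(t_value(r, n), oracle, tolerance = 1e-9)
    }
  }
  # the frozen reference points of the formula
  expect_equal(t_value(0, 52), 0)
  expect_equal(t_value(0.5, 52), 4.0825, tolerance = 1e-4)
  expect_equal(t_value(0.9, 102), 20.6474, tolerance = 1e-4)
  # caps and domain errors
  expect_equal(t_value(1, 100), 1e6)
  expect_equal(t_value(-1, 100), -1e6)
  expect_equal(t_value(1, 100, t_cap = 50), 50)
  expect_error(t_value(0.5, 2), "at least 3")
  expect_error(t_value(1.2, 100), "<= 1")
})

test_that("initial prefs are 150-year means with unit replication", {
  panel <- toy_param_panel(3, 40, seed = 81)
  sig <- simulate_signal_panel(panel, n_years = 400, seed = 1)
  cc <- constructor_config(5)
  prefs <- make_initial_prefs(sig, cc, seed = 2)
  expect_length(prefs, 3L)
  for (p in prefs) {
    expect_equal(pref_length(p), 150L)
    expect_equal(p$first, 400L - 150L + 1L)
    expect_equal(p$last, 400L)
    expect_true(all(pref_replication(p)[p$first:p$last] == 1L))
    expect_equal(nrow(p$members), 0L)
  }
  # psd -> 0 limit: the initial chronology equals the pmv column
  sig0 <- sig
  sig0$psd[] <- 1e-12
  prefs0 <- make_initial_prefs(sig0, cc, seed = 3)
  win <- 251:400
  expect_equal(pref_values(prefs0[[2]])[win], unname(sig0$pmv[win, 2]),
               tolerance = 1e-9)
  # identical parameters, one seed stream: sites still get independent draws
  sig_same <- sig
  sig_same$pmv[, 2] <- sig_same$pmv[, 1]
  sig_same$psd[, 2] <- sig_same$psd[, 1]
  prefs_same <- make_initial_prefs(sig_same, cc, seed = 4)
  expect_false(identical(pref_values(prefs_same[[1]]),
                         pref_values(prefs_same[[2]])))
  expect_error(
    make_initial_prefs(sig, constructor_config(5, initial_length = 401L)),
    "exceeds")
})

test_that("match_candidate picks the best reference above threshold", {
  panel <- toy_param_panel(3, 40, between_corr = 0, noise_sd = 0.05,
                           seed = 82)
  sig <- simulate_signal_panel(panel, n_years = 300, seed = 1)
  cc <- constructor_config(5)
  prefs <- make_initial_prefs(sig, cc, seed = 2)
  # candidate equal to a pref segment: r = 1, capped t, matched to it
  seg <- pref_values(prefs[[2]])[181:300]
  cand <- dendrosim:::new_pseudo_record("c1", "s2", "phs", 181L, seg)
  m <- match_candidate(cand, prefs, cc)
  expect_equal(m$pref_id, 2L)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$t, cc$t_cap)
  expect_equal(m$overlap, 120L)
  # candidate with insufficient overlap: no match
  far <- dendrosim:::new_pseudo_record("c2", "s1", "phs", 1L, rnorm(100))
  expect_true(is.na(match_candidate(far, prefs, cc)$pref_id))
  short <- dendrosim:::new_pseudo_record("c3", "s1", "phs", 102L, rnorm(98))
  expect_true(is.na(match_candidate(short, prefs, cc)$pref_id))
  # zero-variance candidate: every reference skipped
  flat <- dendrosim:::new_pseudo_record("c4", "s1", "phs", 201L, rep(1, 100))
  expect_true(is.na(match_candidate(flat, prefs, cc)$pref_id))
})

test_that("update_pref implements the mean/replication aggregation contract", {
  panel <- toy_param_panel(2, 40, seed = 83)
  sig <- simulate_signal_panel(panel, n_years = 400, seed = 1)
  cc <- constructor_config(10)
  pref <- make_initial_prefs(sig, cc, seed = 2)[[1]]
  init_vals <- pref_values(pref)
  # member fully inside the initial window: replication 2, midpoint mean
  inner <- dendrosim:::new_pseudo_record("m1", "s1", "phs", 291L,
                                         rnorm(80) + 1)
  p2 <- update_pref(pref, list(inner), run_index = 1L)
  span <- 291:370
  expect_true(all(pref_replication(p2)[span] == 2L))
  expect_equal(pref_values(p2)[span],
               (init_vals[span] + inner$values) / 2)
  expect_equal(pref_length(p2), 150L)
  # member extending 80 years before the initial window: length 150 -> 230
  early <- dendrosim:::new_pseudo_record("m2", "s1", "phs", 171L,
                                         rnorm(130))
  p3 <- update_pref(p2, list(early), run_index = 2L)
  expect_equal(pref_length(p3), 230L)
  expect_equal(p3$first, 171L)
  expect_equal(pref_values(p3)[171:250], early$values[1:80])
  # empty update is the identity; duplicate members are rejected
  expect_identical(update_pref(p3, list()), p3)
  expect_error(update_pref(p3, list(inner)), "duplicate")
})

test_that("run-1 assignments equal the brute-force one-shot scorer", {
  # 3-site orthogonal-signal toy at 200 pseudo-years, replication 5
  panel <- toy_param_panel(3, 60, between_corr = 0, noise_sd = 1, seed = 84)
  sig <- simulate_signal_panel(panel, n_years = 200, seed = 1)
  pool <- length_pool(c(50, 60, 70, 90))
  ds <- build_phs_dataset(sig, pool, target_replication = 5L, seed = 2)
  cc <- constructor_config(5)
  prefs <- make_initial_prefs(sig, cc, seed = 3)
  oracle <- brute_force_assign(ds, prefs, cc)
  res <- run_constructor(ds, prefs, cc)
  run1 <- res$trace[res$trace$run_index == 1L, ]
  got <- rep(NA_integer_, nrow(ds$meta))
  got[match(run1$record_id, ds$meta$record_id)] <- run1$pref_id
  expect_identical(got, oracle)
})

test_that("constructor runs are monotone, terminating and deterministic", {
  panel <- toy_param_panel(3, 60, between_corr = 0.3, noise_sd = 1,
                           seed = 85)
  sig <- simulate_signal_panel(panel, n_years = 250, seed = 1)
  ds <- build_phs_dataset(sig, length_pool(c(50, 70, 110)),
                          target_replication = 4L, seed = 2)
  cc <- constructor_config(5)
  prefs <- make_initial_prefs(sig, cc, seed = 3)
  res <- run_constructor(ds, prefs, cc)
  lg <- res$run_logs
  if (res$n_runs >= 2L) {
    for (p in unique(lg$pref_id)) {
      sub <- lg[lg$pref_id == p, ]
      sub <- sub[order(sub$run_index), ]
      expect_true(all(diff(sub$length) >= 0))
      expect_true(all(diff(sub$n_members) >= 0))
    }
    rem <- unique(lg[, c("run_index", "n_remaining")])
    expect_true(all(diff(rem$n_remaining[order(rem$run_index)]) <= 0))
  }
  # every executed run classified at least one candidate (termination)
  cls <- unique(lg[, c("run_index", "n_classified_run")])
  expect_true(all(cls$n_classified_run >= 1L))
  # a threshold above the cap classifies nothing
  res_none <- run_constructor(ds, prefs, constructor_config(1e6 + 1))
  expect_equal(res_none$n_runs, 0L)
  expect_equal(nrow(res_none$trace), 0L)
  expect_equal(pref_length(res_none$prefs[[1]]), 150L)
  # identical inputs give an identical classification trace
  res2 <- run_constructor(ds, prefs, cc)
  expect_identical(res$trace, res2$trace)
})

test_that("candidates identical to reference segments classify in run 1 uncontaminated", {
  panel <- toy_param_panel(3, 60, between_corr = 0, noise_sd = 0.05,
                           seed = 86)
  sig <- simulate_signal_panel(panel, n_years = 300, seed = 1)
  cc <- constructor_config(5)
  prefs <- make_initial_prefs(sig, cc, seed = 2)
  recs <- unlist(lapply(1:3, function(j) {
    v <- pref_values(prefs[[j]])
    lapply(1:3, function(k) {
      s <- 151L + (k - 1L) * 25L
      dendrosim:::new_pseudo_record(sprintf("id%d_%d", j, k),
                                    sprintf("s%d", j), "phs", s,
                                    v[s:(s + 99L)])
    })
  }), recursive = FALSE)
  ds <- dendrosim:::new_pseudo_dataset(recs, 300L, c("s1", "s2", "s3"),
                                       "phs", 1L)
  res <- run_constructor(ds, prefs, cc)
  expect_equal(res$n_runs, 1L)
  expect_equal(nrow(res$trace), 9L)
  summ <- repetition_summary(res, ds)
  expect_equal(summ$pct_generated_classified, 100)
  expect_equal(summ$pct_classified_correct, 100)
  expect_true(all(summ$per_pref$contamination_site == 0))
})

test_that("with separable signals classifications converge to 100% correct", {
  # separability limit: orthogonal signals, small noise
  set.seed(87)
  panel <- toy_param_panel(3, 60, between_corr = 0, noise_sd = 0.05)
  rep_ <- toy_repetition(panel, t_threshold = 5)
  expect_gt(rep_$summary$pct_generated_classified, 50)
  expect_equal(rep_$summary$pct_classified_correct, 100)
})
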