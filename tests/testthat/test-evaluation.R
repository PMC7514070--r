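test_that("delta_corr is zero on identical input and flags degeneracy", {
  set.seed(91)
  A <- matrix(rnorm(300), 100, 3)
  expect_equal(unname(delta_corr(A, A)), c(0, 0))
  # independent-noise matrices: differences at sampling-noise scale
  B <- matrix(rnorm(3000), 1000, 3)
  C <- matrix(rnorm(3000), 1000, 3)
  d <- delta_corr(B, C)
  expect_lt(max(abs(d)), 6 / sqrt(1000))  # generous 2/sqrt(Y)-scale envelope
  A0 <- A
  A0[, 2] <- 1
  expect_error(delta_corr(A0, A), "zero-variance")
  expect_error(delta_corr(A, matrix(1:8, 4, 2)), "column count")
})

test_that("spmv under perfect classification recovers the signal means", {
  panel <- toy_param_panel(3, 50, between_corr = 0.4, noise_sd = 0.6,
                           seed = 92)
  sig <- simulate_signal_panel(panel, n_years = 200, seed = 1)
  ds <- build_phs_dataset(sig, length_pool(c(50, 80, 100)),
                          target_replication = 40L, seed = 2)
  spmv <- spmv_from_perfect_classification(ds)
  expect_equal(dim(spmv), c(200L, 3L))
  # averaging >= 40 draws per year: spmv close to pmv
  err <- abs(spmv - sig$pmv)
  expect_lt(max(err), 6 * max(sig$psd) / sqrt(40))
  # invariance to record order
  perm <- sample(nrow(ds$meta))
  ds2 <- ds
  ds2$meta <- ds$meta[perm, ]
  ds2$values <- ds$values[perm]
  expect_equal(spmv_from_perfect_classification(ds2), spmv)
  # zero-coverage year is an error
  ds3 <- ds
  keep <- ds$meta$source_site != "s2"
  ds3$meta <- ds$meta[keep, ]
  ds3$values <- ds$values[keep]
  expect_error(spmv_from_perfect_classification(ds3), "no coverage")
})

test_that("contamination counts off-group members under each contrast", {
  meta <- data.frame(site_id = c("a", "b", "c", "d"),
                     elevation_band = c("low", "medium", "high", "low"),
                     watershed = c("w1", "w1", "w2", "w2"))
  map <- contrast_map(meta)
  mk_pref <- function(init, members) {
    p <- dendrosim:::new_pref(1L, init, 51L, rnorm(50), 100L)
    if (length(members) > 0L) {
      recs <- lapply(seq_along(members), function(i)
        dendrosim:::new_pseudo_record(paste0("m", i), members[i], "phs",
                                      31L, rnorm(40)))
      p <- update_pref(p, recs, run_index = 1L)
    }
    p
  }
  # all members on-group
  expect_equal(as.numeric(contamination(mk_pref("a", rep("a", 5)))), 0)
  # 1 of 5 off-group
  p <- mk_pref("a", c("a", "a", "a", "a", "b"))
  expect_equal(as.numeric(contamination(p, "site")), 20)
  # elevation: b is medium, a is low -> still off-group
  expect_equal(as.numeric(contamination(p, "elevation", map)), 20)
  # coarse elevation merges low+medium -> no contamination
  expect_equal(as.numeric(contamination(p, "elevation_coarse", map)), 0)
  # watershed: a and b share w1 -> no contamination
  expect_equal(as.numeric(contamination(p, "watershed", map)), 0)
  # site contrast dominates every coarsening
  set.seed(93)
  for (k in 1:20) {
    members <- sample(meta$site_id, 6, replace = TRUE)
    q <- mk_pref("a", members)
    site_c <- as.numeric(contamination(q, "site"))
    for (ctr in c("elevation", "elevation_coarse", "watershed")) {
      expect_lte(as.numeric(contamination(q, ctr, map)), site_c)
    }
  }
  # empty pref: 0 with a flag
  empty <- mk_pref("a", character(0))
  expect_equal(as.numeric(contamination(empty)), 0)
  expect_true(attr(contamination(empty), "empty"))
  expect_error(contamination(mk_pref("zz", "a"), "elevation", map),
               "unmapped")
})

# minimal hand-built repetition summaries for aggregation tests
fake_rep <- function(n_runs, conts, lengths, members, n_gen = 100L,
                     pct_cls = 50, pct_cor = 80) {
  n_pref <- length(lengths)
  logs <- do.call(rbind, lapply(seq_len(n_runs), function(r)
    data.frame(run_index = r, pref_id = seq_len(n_pref),
               init_site = paste0("s", seq_len(n_pref)),
               n_members = members, contamination = conts + r - 1,
               length = lengths + 10 * (r - 1),
               mean_replication = 2 + r * 0.5,
               n_classified_run = 5L, n_remaining = 10L)))
  structure(list(
    n_series_generated = n_gen, n_classified = round(n_gen * pct_cls / 100),
    pct_generated_classified = pct_cls, pct_classified_correct = pct_cor,
    no_classification = FALSE, n_runs_executed = n_runs,
    per_pref = data.frame(pref_id = seq_len(n_pref),
                          init_site = paste0("s", seq_len(n_pref)),
                          n_members = members,
                          length = lengths + 10 * (n_runs - 1),
                          mean_replication = 2 + n_runs * 0.5,
                          contamination_site = conts + n_runs - 1),
    run_logs = logs, contrasts = "site"), class = "repetition_summary")
}

test_that("multi-repetition aggregation obeys the fully-replicated-run rule", {
  reps <- list(fake_rep(3L, c(0, 10), c(150, 200), c(2L, 5L), pct_cls = 40),
               fake_rep(5L, c(5, 20), c(160, 220), c(3L, 6L), pct_cls = 50),
               fake_rep(7L, c(10, 30), c(170, 240), c(4L, 7L), pct_cls = 60))
  s <- summarize_repetitions(reps, n_years = 1000L)
  expect_equal(s$n_fully_replicated_runs, 3L)
  expect_equal(sort(unique(s$per_run$run_index)), 1:3)
  expect_equal(s$table1["pct_generated_classified", ],
               c(min = 40, median = 50, max = 60))
  # single repetition: min = median = max
  s1 <- summarize_repetitions(reps[1], n_years = 1000L)
  expect_true(all(s1$table1[, "min"] == s1$table1[, "max"]))
  # per-run 95th percentile with linear interpolation (type 7)
  run1 <- s$per_run[s$per_run$run_index == 1L & s$per_run$pref_id == 1L, ]
  expect_equal(run1$contamination_p95,
               as.numeric(quantile(c(0, 5, 10), 0.95, type = 7)))
})

test_that("length and attractor categories count every pref exactly once", {
  reps <- list(fake_rep(1L, rep(0, 5), c(150, 340, 700, 1000, 120),
                        c(0L, 50L, 600L, 1500L, 101L), n_gen = 2000L))
  s <- summarize_repetitions(reps, n_years = 1000L)
  lc <- s$categories[s$categories$kind == "length", ]
  ac <- s$categories[s$categories$kind == "attracted", ]
  expect_equal(sum(lc$mean_count), 5)
  expect_equal(sum(ac$mean_count), 5)
  # pref with 0 members lands in the "0" length category despite length 150
  expect_equal(lc$mean_count[lc$category == "0"], 1)
  expect_equal(lc$mean_count[lc$category == "1000"], 1)
  expect_equal(ac$mean_count[ac$category == ">1000"], 1)
  expect_equal(ac$mean_count[ac$category == "0-100"], 2)
})

test_that("contamination flags report the fraction of affected repetitions", {
  reps <- list(fake_rep(1L, c(0, 25), c(150, 200), c(2L, 5L)),
               fake_rep(1L, c(0, 5), c(150, 200), c(2L, 5L)),
               fake_rep(1L, c(30, 25), c(150, 200), c(2L, 5L)),
               fake_rep(1L, c(0, 25), c(150, 200), c(2L, 5L)))
  s <- summarize_repetitions(reps, n_years = 1000L)
  fr <- flag_contaminated(s, "site", threshold_pct = 20)
  expect_equal(unname(fr), c(0.25, 0.75))
  # monotone in the threshold
  expect_true(all(flag_contaminated(s, "site", 10) >=
                    flag_contaminated(s, "site", 20)))
  expect_error(flag_contaminated(s, "watershed"), "not available")
})

test_that("summary tables export as TSV", {
  reps <- list(fake_rep(2L, c(0, 10), c(150, 200), c(2L, 5L)))
  s <- summarize_repetitions(reps, n_years = 1000L)
  stem <- file.path(withr::local_tempdir(), "out")
  write_multirep_summary(s, stem)
  expect_true(file.exists(paste0(stem, "_summary.tsv")))
  tab <- read.delim(paste0(stem, "_per_run.tsv"))
  expect_equal(nrow(tab), 2L * 2L)
})
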