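# shared helpers for building small, fast fixtures in code

# tiny multi-site fixture spec (3 elevation blocks, 2/2/2 sites)
tiny_spec <- function(...) {
  fixture_spec(n_sites = 6L, series_per_site = c(15L, 18L),
               series_length = c(70L, 90L),
               block_sizes = c(low = 2L, medium = 2L, high = 2L), ...)
}

# random valid ring-width series with widths on the RWL 1/100 mm grid
random_rw_series <- function(id = "ser1", site = "siteA",
                             first_year = 1950L, n = 37L) {
  rw_series(id, site, first_year,
            round(stats::runif(n, 0.3, 6), 2))
}

# exact-correlation vector pair: sample cor(x, y) == r by construction
exact_cor_pair <- function(r, n) {
  u <- seq_len(n) - mean(seq_len(n))
  u <- u / sqrt(sum(u^2))
  v <- (seq_len(n))^2
  v <- v - mean(v)
  v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  list(x = u, y = r * u + sqrt(1 - r^2) * v)
}

# brute-force one-shot scorer: best pref per candidate against a FIXED set
# of reference value vectors (independent of the constructor's internals)
brute_force_assign <- function(dataset, prefs, config) {
  pv <- lapply(prefs, pref_values)
  firsts <- vapply(prefs, `[[`, integer(1), "first")
  lasts <- vapply(prefs, `[[`, integer(1), "last")
  vapply(seq_len(nrow(dataset$meta)), function(i) {
    vals <- dataset$values[[i]]
    s <- dataset$meta$start_year[i]
    e <- s + length(vals) - 1L
    best_j <- NA_integer_
    best_t <- -Inf
    for (j in seq_along(prefs)) {
      lo <- max(s, firsts[j]); hi <- min(e, lasts[j])
      n_ov <- hi - lo + 1L
      if (n_ov < config$min_overlap) next
      x <- vals[(lo - s + 1L):(hi - s + 1L)]
      y <- pv[[j]][lo:hi]
      if (sd(x) == 0 || sd(y) == 0 || anyNA(y)) next
      r <- cor(x, y)
      t <- r * sqrt(n_ov - 2) / sqrt(1 - r^2)
      if (abs(r) == 1) t <- sign(r) * config$t_cap
      if (t >= config$t_threshold && t > best_t) {
        best_t <- t
        best_j <- j
      }
    }
    best_j
  }, integer(1))
}

# one reduced-scale pipeline repetition on an analytic panel
toy_repetition <- function(panel, t_threshold = 5, n_years = 200L,
                           target_replication = 5L, pool = NULL,
                           initial_length = 150L) {
  pool <- pool %||% length_pool(c(50, 60, 70, 80, 100))
  sig <- simulate_signal_panel(panel, n_years = n_years)
  ds <- build_phs_dataset(sig, pool, target_replication = target_replication)
  cc <- constructor_config(t_threshold, initial_length = initial_length)
  prefs <- make_initial_prefs(sig, cc)
  res <- run_constructor(ds, prefs, cc)
  list(signal = sig, dataset = ds, config = cc, prefs = prefs, result = res,
       summary = repetition_summary(res, ds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
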