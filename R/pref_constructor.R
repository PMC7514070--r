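#' Configuration of the reference-chronology constructor
#'
#' @param t_threshold minimum t-value for a match; the study grid is 5, 10,
#'   15, 20, but any positive value is accepted.
#' @param min_overlap minimum overlap (years) between candidate and
#'   reference for a comparison to count (default 50; must be >= 3 for the
#'   t-value to be defined).
#' @param initial_n_series pseudo series averaged into each initial
#'   reference (default 30).
#' @param initial_length length in years of the initial references
#'   (default 150).
#' @param t_cap finite stand-in for the t-value at |r| = 1 (default 1e6);
#'   preserves ordering while avoiding infinities.
#' @return An object of class `constructor_config`.
#' @export
constructor_config <- function(t_threshold, min_overlap = 50L,
                               initial_n_series = 30L,
                               initial_length = 150L, t_cap = 1e6) {
  stopifnot(is.numeric(t_threshold), t_threshold > 0,
            min_overlap >= 3L, initial_n_series >= 1L,
            initial_length >= 1L, t_cap > 0)
  structure(list(t_threshold = t_threshold,
                 min_overlap = as.integer(min_overlap),
                 initial_n_series = as.integer(initial_n_series),
                 initial_length = as.integer(initial_length),
                 t_cap = t_cap),
            class = "constructor_config")
}

#' @export
print.constructor_config <- function(x, ...) {
  cat(sprintf(
    "<constructor_config> t >= %g, overlap >= %d, initial %d ps x %d years\n",
    x$t_threshold, x$min_overlap, x$initial_n_series, x$initial_length))
  invisible(x)
}

#' t-value of a Pearson correlation
#'
#' The crossmatching statistic: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` for a
#' correlation `r` computed over an overlap of `n` years. At `|r| = 1` the
#' statistic is capped at `+/- t_cap` to preserve ordering without
#' infinities. Vectorised over `r` and `n`.
#'
#' @param r Pearson correlation(s) in `[-1, 1]`.
#' @param n overlap length(s), `n >= 3`.
#' @param t_cap cap applied at `|r| = 1`.
#' @return Numeric vector of t-values.
#' @export
t_value <- function(r, n, t_cap = 1e6) {
  if (any(n < 3)) stop("t-value needs an overlap of at least 3 years")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  t[r == 1] <- t_cap
  t[r == -1] <- -t_cap
  pmin(pmax(t, -t_cap), t_cap)
}

new_pref <- function(pref_id, init_site, init_start, init_chron, n_years) {
  L <- length(init_chron)
  sum_v <- numeric(n_years)
  cnt <- integer(n_years)
  idx <- init_start:(init_start + L - 1L)
  sum_v[idx] <- init_chron
  cnt[idx] <- 1L
  structure(list(pref_id = as.integer(pref_id), init_site = init_site,
                 init_start = as.integer(init_start), init_chron = init_chron,
                 n_years = as.integer(n_years),
                 sum = sum_v, count = cnt,
                 first = min(idx), last = max(idx),
                 members = data.frame(record_id = character(0),
                                      run_index = integer(0),
                                      source_site = character(0),
                                      start_year = integer(0),
                                      length = integer(0),
                                      t = numeric(0), r = numeric(0),
                                      overlap = integer(0),
                                      stringsAsFactors = FALSE)),
            class = "pref")
}

#' @export
print.pref <- function(x, ...) {
  cat(sprintf(
    "<pref> #%d (init %s): %d members, years %d-%d (length %d), mean repl. %.1f\n",
    x$pref_id, x$init_site, nrow(x$members), x$first, x$last,
    pref_length(x), pref_mean_replication(x)))
  invisible(x)
}

#' Accessors for pseudo reference chronologies
#'
#' `pref_values()` returns the per-year mean chronology (NA outside
#' coverage); `pref_length()` the number of covered years;
#' `pref_replication()` the per-year contributor count (the initial
#' chronology counts as one contributor, each classified member as one
#' more); `pref_mean_replication()` its mean over covered years.
#'
#' @param pref a `pref`.
#' @return See details.
#' @export
pref_values <- function(pref) {
  v <- pref$sum / pref$count
  v[pref$count == 0L] <- NA_real_
  v
}

#' @rdname pref_values
#' @export
pref_length <- function(pref) sum(pref$count > 0L)

#' @rdname pref_values
#' @export
pref_replication <- function(pref) pref$count

#' @rdname pref_values
#' @export
pref_mean_replication <- function(pref) {
  mean(pref$count[pref$count > 0L])
}

#' Initialize one reference chronology per pseudo site
#'
#' For each site, `initial_n_series` fresh pseudo series (drawn in addition
#' to the candidate dataset) are restricted to the most recent
#' `initial_length` years of the pseudo timeline and averaged yearwise into
#' the initial chronology. The placement at the end of the timeline mimics
#' living-tree chronologies that are extended backward in time by historical
#' series. The initial chronology enters the reference mean with weight 1
#' (one chronology, not `initial_n_series` series).
#'
#' @param signal a [simulate_signal_panel()] result.
#' @param config a [constructor_config()].
#' @param seed optional integer seed.
#' @return List of `pref` objects, one per site, in `signal$site_ids` order.
#' @export
make_initial_prefs <- function(signal, config, seed = NULL) {
  stopifnot(inherits(signal, "signal_panel"),
            inherits(config, "constructor_config"))
  L <- config$initial_length
  if (L > signal$n_years) {
    stop("initial_length (", L, ") exceeds the pseudo timeline (",
         signal$n_years, ")")
  }
  set_seed_if(seed)
  win <- (signal$n_years - L + 1L):signal$n_years
  lapply(seq_along(signal$site_ids), function(j) {
    site <- signal$site_ids[j]
    draws <- matrix(rnorm(L * config$initial_n_series,
                          mean = signal$pmv[win, site],
                          sd = signal$psd[win, site]),
                    nrow = L, ncol = config$initial_n_series)
    new_pref(j, site, win[1], rowMeans(draws), signal$n_years)
  })
}

# correlation/overlap of one candidate against one pref value vector;
# returns c(r, overlap) or NULL when the overlap or variance is inadequate
.cand_pref_cor <- function(values, start_year, pref_vals, pref_first,
                           pref_last, min_overlap) {
  end_year <- start_year + length(values) - 1L
  lo <- max(start_year, pref_first)
  hi <- min(end_year, pref_last)
  n_ov <- hi - lo + 1L
  if (n_ov < min_overlap) return(NULL)
  x <- values[(lo - start_year + 1L):(hi - start_year + 1L)]
  y <- pref_vals[lo:hi]
  if (anyNA(y)) return(NULL)            # non-contiguous coverage guard
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NULL)
  c(r = stats::cor(x, y), overlap = n_ov)
}

#' Match one candidate against the current references
#'
#' Computes, for every reference overlapping the candidate by at least
#' `min_overlap` years, the Pearson correlation at the candidate's fixed
#' calendar position (dating is assumed correct, so no offset search) and
#' its t-value. The candidate is assigned to the reference with the highest
#' t-value among those reaching `t_threshold`; ties are broken by the lowest
#' reference index. References with zero variance over the overlap are
#' skipped.
#'
#' @param candidate a `pseudo_record` (phs or poc).
#' @param prefs list of `pref` objects.
#' @param config a [constructor_config()].
#' @return List with `pref_id` (or `NA` if no match), `t`, `r`, `overlap`.
#' @export
match_candidate <- function(candidate, prefs, config) {
  pv <- lapply(prefs, pref_values)
  best <- .match_one(candidate$values, candidate$start_year, pv,
                     vapply(prefs, `[[`, integer(1), "first"),
                     vapply(prefs, `[[`, integer(1), "last"),
                     config)
  best
}

.match_one <- function(values, start_year, pref_vals_list, firsts, lasts,
                       config) {
  best <- list(pref_id = NA_integer_, t = NA_real_, r = NA_real_,
               overlap = NA_integer_)
  best_t <- -Inf
  for (j in seq_along(pref_vals_list)) {
    ro <- .cand_pref_cor(values, start_year, pref_vals_list[[j]],
                         firsts[j], lasts[j], config$min_overlap)
    if (is.null(ro)) next
    t <- t_value(ro[["r"]], ro[["overlap"]], t_cap = config$t_cap)
    if (t >= config$t_threshold && t > best_t) {
      best_t <- t
      best <- list(pref_id = j, t = t, r = ro[["r"]],
                   overlap = as.integer(ro[["overlap"]]))
    }
  }
  best
}

#' Add classified members to a reference chronology
#'
#' Realises the aggregation contract: the per-year reference value is the
#' arithmetic mean of the initial chronology (where it covers the year) and
#' all member series covering the year; replication counts one per
#' contributor. Adding an empty member set is a no-op.
#'
#' @param pref a `pref`.
#' @param records list of `pseudo_record` members to add.
#' @param run_index constructor run in which they were classified.
#' @param match_stats optional data frame with one row per record and
#'   columns `t`, `r`, `overlap`.
#' @return The updated `pref`.
#' @export
update_pref <- function(pref, records, run_index = NA_integer_,
                        match_stats = NULL) {
  if (length(records) == 0L) return(pref)
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(c(pref$members$record_id, ids))) {
    stop("duplicate member record id")
  }
  for (k in seq_along(records)) {
    r <- records[[k]]
    idx <- r$start_year:(r$start_year + length(r$values) - 1L)
    if (min(idx) < 1L || max(idx) > pref$n_years) {
      stop("member '", r$record_id, "' falls outside the pseudo timeline")
    }
    pref$sum[idx] <- pref$sum[idx] + r$values
    pref$count[idx] <- pref$count[idx] + 1L
    pref$first <- min(pref$first, idx[1])
    pref$last <- max(pref$last, idx[length(idx)])
    st <- if (!is.null(match_stats)) match_stats[k, ] else
      data.frame(t = NA_real_, r = NA_real_, overlap = NA_integer_)
    pref$members <- rbind(pref$members, data.frame(
      record_id = r$record_id, run_index = as.integer(run_index),
      source_site = r$source_site, start_year = r$start_year,
      length = length(r$values), t = st$t, r = st$r,
      overlap = as.integer(st$overlap), stringsAsFactors = FALSE))
  }
  pref
}

#' Run the iterative reference-chronology constructor
#'
#' Batch (synchronous) semantics: within one run, every still-unclassified
#' candidate is matched against the references *as of the run's start*; all
#' accepted candidates are then added to their references simultaneously at
#' the run's end. Runs repeat until a run classifies zero candidates or no
#' candidates remain. A classification is final: already-classified members
#' are never re-scored. Determinism: the same dataset, references and
#' configuration give an identical classification trace.
#'
#' @param dataset a `pseudo_dataset` of candidates (phs or poc).
#' @param prefs list of `pref` objects from [make_initial_prefs()].
#' @param config a [constructor_config()].
#' @return List with `prefs` (final state), `run_logs` (data frame with one
#'   row per pref and executed run: cumulative site-level contamination in
#'   percent, length, mean replication, candidates classified in the run and
#'   remaining after it), `trace` (one row per classified candidate:
#'   `record_id`, `run_index`, `pref_id`, `t`, `r`, `overlap`) and `n_runs`
#'   (runs that classified at least one candidate).
#' @export
run_constructor <- function(dataset, prefs, config) {
  stopifnot(inherits(dataset, "pseudo_dataset"),
            inherits(config, "constructor_config"))
  n_cand <- nrow(dataset$meta)
  starts <- dataset$meta$start_year
  sources <- dataset$meta$source_site
  unclassified <- seq_len(n_cand)
  run <- 0L
  log_rows <- list()
  trace_rows <- list()
  repeat {
    if (length(unclassified) == 0L) break
    pv <- lapply(prefs, pref_values)
    firsts <- vapply(prefs, `[[`, integer(1), "first")
    lasts <- vapply(prefs, `[[`, integer(1), "last")
    assigned_pref <- integer(0)
    assigned_cand <- integer(0)
    assigned_stats <- list()
    for (i in unclassified) {
      best <- .match_one(dataset$values[[i]], starts[i], pv, firsts, lasts,
                         config)
      if (!is.na(best$pref_id)) {
        assigned_cand <- c(assigned_cand, i)
        assigned_pref <- c(assigned_pref, best$pref_id)
        assigned_stats[[length(assigned_stats) + 1L]] <-
          data.frame(t = best$t, r = best$r, overlap = best$overlap)
      }
    }
    if (length(assigned_cand) == 0L) break
    run <- run + 1L
    for (k in seq_along(assigned_cand)) {
      i <- assigned_cand[k]
      j <- assigned_pref[k]
      rec <- new_pseudo_record(dataset$meta$record_id[i], sources[i],
                               dataset$meta$kind[i], starts[i],
                               dataset$values[[i]])
      prefs[[j]] <- update_pref(prefs[[j]], list(rec), run_index = run,
                                match_stats = assigned_stats[[k]])
      trace_rows[[length(trace_rows) + 1L]] <- data.frame(
        record_id = dataset$meta$record_id[i], run_index = run,
        pref_id = j, t = assigned_stats[[k]]$t, r = assigned_stats[[k]]$r,
        overlap = assigned_stats[[k]]$overlap, stringsAsFactors = FALSE)
    }
    unclassified <- setdiff(unclassified, assigned_cand)
    for (j in seq_along(prefs)) {
      p <- prefs[[j]]
      cont <- if (nrow(p$members) == 0L) 0 else
        100 * mean(p$members$source_site != p$init_site)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        run_index = run, pref_id = j, init_site = p$init_site,
        n_members = nrow(p$members), contamination = cont,
        length = pref_length(p),
        mean_replication = pref_mean_replication(p),
        n_classified_run = length(assigned_cand),
        n_remaining = length(unclassified), stringsAsFactors = FALSE)
    }
  }
  list(prefs = prefs,
       run_logs = if (length(log_rows) > 0L) do.call(rbind, log_rows) else
         data.frame(run_index = integer(0), pref_id = integer(0),
                    init_site = character(0), n_members = integer(0),
                    contamination = numeric(0), length = integer(0),
                    mean_replication = numeric(0),
                    n_classified_run = integer(0),
                    n_remaining = integer(0)),
       trace = if (length(trace_rows) > 0L) do.call(rbind, trace_rows) else
         data.frame(record_id = character(0), run_index = integer(0),
                    pref_id = integer(0), t = numeric(0), r = numeric(0),
                    overlap = integer(0)),
       n_runs = run)
}
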