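#' Configuration of a multi-repetition simulation experiment
#'
#' One experiment = one approach (single series `phs` or object
#' chronologies `poc` at an on-site ratio), one t-value threshold, and a
#' number of independent simulation repetitions. Per repetition a fresh
#' pseudo signal panel, candidate dataset and set of initial references are
#' generated and the constructor is run to its fixpoint. Per-repetition
#' seeds are derived deterministically from the root seed, so repetitions
#' are reproducible individually and in any order.
#'
#' @param panel a [param_panel()] (estimated from data or analytic).
#' @param pool a [length_pool()].
#' @param approach `"phs"` or `"poc"`.
#' @param t_threshold t-value threshold (study grid: 5, 10, 15, 20).
#' @param osr on-site ratio for `poc` (1, 0.83 or 0.67); ignored for `phs`.
#' @param n_repetitions number of simulation repetitions (the full design
#'   uses 1000; a reduced profile is the practical default).
#' @param n_years pseudo timeline length (default 1000).
#' @param target_replication per-year coverage target (default 30).
#' @param min_overlap,initial_n_series,initial_length,t_cap constructor
#'   settings, see [constructor_config()].
#' @param seed root seed for the whole experiment.
#' @param meta optional site metadata data frame (enables elevation and
#'   watershed contrasts in the summaries).
#' @param out_dir optional directory for per-repetition JSON artifacts and
#'   the manifest; enables resuming an interrupted experiment.
#' @param label optional label used in [compare_settings()] rows; default
#'   `"<approach>_t<threshold>[_<osr>]"`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(panel, pool, approach = c("phs", "poc"),
                              t_threshold = 15, osr = 1,
                              n_repetitions = 50L, n_years = 1000L,
                              target_replication = 30L, min_overlap = 50L,
                              initial_n_series = 30L, initial_length = 150L,
                              t_cap = 1e6, seed = 1L, meta = NULL,
                              out_dir = NULL, label = NULL) {
  approach <- match.arg(approach)
  stopifnot(inherits(panel, "param_panel"), length(pool) >= 1L,
            n_repetitions >= 1L)
  label <- label %||% if (approach == "poc") {
    sprintf("poc_t%g_%g", t_threshold, osr)
  } else sprintf("phs_t%g", t_threshold)
  structure(list(panel = panel, pool = pool, approach = approach,
                 t_threshold = t_threshold, osr = osr,
                 n_repetitions = as.integer(n_repetitions),
                 n_years = as.integer(n_years),
                 target_replication = as.integer(target_replication),
                 min_overlap = as.integer(min_overlap),
                 initial_n_series = as.integer(initial_n_series),
                 initial_length = as.integer(initial_length),
                 t_cap = t_cap, seed = as.integer(seed), meta = meta,
                 out_dir = out_dir, label = label),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %s: %d reps, %d pseudo years, replication %d, seed %d\n",
    x$label, x$n_repetitions, x$n_years, x$target_replication, x$seed))
  invisible(x)
}

rep_summary_to_list <- function(s) {
  list(n_series_generated = s$n_series_generated,
       n_classified = s$n_classified,
       pct_generated_classified = s$pct_generated_classified,
       pct_classified_correct = s$pct_classified_correct,
       no_classification = s$no_classification,
       n_runs_executed = s$n_runs_executed,
       per_pref = s$per_pref, run_logs = s$run_logs,
       contrasts = s$contrasts)
}

rep_summary_from_list <- function(l) {
  l$per_pref <- as.data.frame(l$per_pref)
  l$run_logs <- as.data.frame(l$run_logs)
  l$contrasts <- unlist(l$contrasts)
  structure(l, class = "repetition_summary")
}

run_one_repetition <- function(config, rep_seed) {
  set.seed(rep_seed)
  signal <- simulate_signal_panel(config$panel, n_years = config$n_years)
  dataset <- if (config$approach == "phs") {
    build_phs_dataset(signal, config$pool,
                      target_replication = config$target_replication)
  } else {
    build_poc_dataset(signal, config$pool, osr = config$osr,
                      target_replication = config$target_replication)
  }
  cc <- constructor_config(config$t_threshold,
                           min_overlap = config$min_overlap,
                           initial_n_series = config$initial_n_series,
                           initial_length = config$initial_length,
                           t_cap = config$t_cap)
  prefs <- make_initial_prefs(signal, cc)
  res <- run_constructor(dataset, prefs, cc)
  map <- if (!is.null(config$meta)) contrast_map(config$meta) else NULL
  repetition_summary(res, dataset, map)
}

#' Run a multi-repetition experiment
#'
#' Executes `n_repetitions` independent repetitions of the pipeline
#' (signal panel, candidate dataset, initial references, constructor) and
#' aggregates them with [summarize_repetitions()]. With `out_dir` set, each
#' completed repetition is persisted as JSON and an interrupted experiment
#' resumes from the last completed repetition; a manifest records the
#' configuration and the derived seeds for exact replay.
#'
#' @param config an [experiment_config()].
#' @param verbose print a line per repetition.
#' @return List with `summary` (a `multirep_summary`), `repetitions`
#'   (per-repetition summaries), `label`, `panel_fingerprint` and `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, config$n_repetitions)
  fp <- fingerprint(log_rsd(config$panel))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest_path <- file.path(config$out_dir, "manifest.json")
    manifest <- list(label = config$label, approach = config$approach,
                     t_threshold = config$t_threshold, osr = config$osr,
                     n_repetitions = config$n_repetitions,
                     n_years = config$n_years,
                     target_replication = config$target_replication,
                     seed = config$seed, seeds = seeds,
                     panel_fingerprint = fp,
                     package_version =
                       as.character(utils::packageVersion("dendrosim")))
    if (file.exists(manifest_path)) {
      old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
      if (!identical(old$panel_fingerprint, fp) ||
          !identical(as.integer(old$seed), config$seed)) {
        stop("out_dir holds a manifest for a different experiment")
      }
      if (!identical(old$package_version, manifest$package_version)) {
        warning("resuming a manifest written by package version ",
                old$package_version)
      }
    } else {
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           digits = NA)
    }
  }
  reps <- vector("list", config$n_repetitions)
  for (i in seq_len(config$n_repetitions)) {
    rep_path <- if (!is.null(config$out_dir)) {
      file.path(config$out_dir, sprintf("rep%04d.json", i))
    } else NULL
    if (!is.null(rep_path) && file.exists(rep_path)) {
      reps[[i]] <- rep_summary_from_list(
        jsonlite::read_json(rep_path, simplifyVector = TRUE))
    } else {
      reps[[i]] <- run_one_repetition(config, seeds[i])
      if (!is.null(rep_path)) {
        jsonlite::write_json(rep_summary_to_list(reps[[i]]), rep_path,
                             auto_unbox = TRUE, digits = NA)
      }
    }
    if (verbose) {
      cat(sprintf("[%s] rep %d/%d: %.2f%% classified, %.2f%% correct, %d runs\n",
                  config$label, i, config$n_repetitions,
                  reps[[i]]$pct_generated_classified,
                  reps[[i]]$pct_classified_correct,
                  reps[[i]]$n_runs_executed))
    }
  }
  list(summary = summarize_repetitions(reps, n_years = config$n_years),
       repetitions = reps, label = config$label, panel_fingerprint = fp,
       config = config)
}

#' Combine several experiment results into one headline table
#'
#' One row per setting with the minimum/median/maximum of the four headline
#' statistics (percent classified, percent of classified correct, runs
#' executed, series generated). All experiments must share the same input
#' panel.
#'
#' @param results list of [run_experiment()] results.
#' @return Data frame, one row per setting, in input order.
#' @export
compare_settings <- function(results) {
  stopifnot(length(results) >= 1L)
  fps <- vapply(results, `[[`, character(1), "panel_fingerprint")
  if (length(unique(fps)) != 1L) {
    stop("experiments do not share the same input panel")
  }
  do.call(rbind, lapply(results, function(r) {
    t1 <- r$summary$table1
    data.frame(approach = r$label,
               classified_min = t1["pct_generated_classified", "min"],
               classified_median = t1["pct_generated_classified", "median"],
               classified_max = t1["pct_generated_classified", "max"],
               correct_min = t1["pct_classified_correct", "min"],
               correct_median = t1["pct_classified_correct", "median"],
               correct_max = t1["pct_classified_correct", "max"],
               runs_min = t1["n_runs_executed", "min"],
               runs_median = t1["n_runs_executed", "median"],
               runs_max = t1["n_runs_executed", "max"],
               generated_min = t1["n_series_generated", "min"],
               generated_median = t1["n_series_generated", "median"],
               generated_max = t1["n_series_generated", "max"],
               stringsAsFactors = FALSE)
  }))
}

#' Scaled-down reproduction of the reference summary tables
#'
#' Runs the full pipeline on a deposited real dataset: ring-width files are
#' read (one RWL file per site, or one long CSV), AR residual chronologies
#' and the parameter panel are estimated, and the requested settings are
#' each run for `n_repetitions` repetitions. Returns the per-setting
#' headline table and the spmv-vs-rmv stability range of the first
#' repetition's dataset per setting.
#'
#' @param rwl_paths character vector of RWL file paths (one site per file)
#'   or a single long-CSV path.
#' @param pool_path series-length pool file (see [read_length_pool()]).
#' @param meta_path optional site metadata CSV.
#' @param settings data frame with columns `approach`, `t_threshold`,
#'   `osr`; defaults to the four headline settings.
#' @param n_repetitions repetitions per setting (default 50; the full
#'   design used 1000).
#' @param seed root seed.
#' @param min_replication per-year replication required of the real
#'   chronologies (default 15).
#' @return List with `table` (from [compare_settings()]), `results` (per
#'   setting) and `panel`.
#' @export
reproduce_reference_summary <- function(rwl_paths, pool_path,
                                        meta_path = NULL,
                                        settings = NULL,
                                        n_repetitions = 50L, seed = 1L,
                                        min_replication = 15L) {
  settings <- settings %||% data.frame(
    approach = c("poc", "poc", "phs", "phs"),
    t_threshold = c(15, 5, 5, 10),
    osr = c(1, 1, NA, NA))
  series <- if (length(rwl_paths) == 1L &&
                grepl("\\.csv$", rwl_paths, ignore.case = TRUE)) {
    read_rw_csv(rwl_paths)
  } else {
    unlist(lapply(rwl_paths, read_rwl), recursive = FALSE)
  }
  meta <- if (!is.null(meta_path)) read_site_meta(meta_path) else NULL
  sites <- as_site_datasets(series, meta)
  panel <- build_param_panel(sites, min_replication = min_replication)
  pool <- read_length_pool(pool_path)
  results <- lapply(seq_len(nrow(settings)), function(i) {
    cfg <- experiment_config(
      panel, pool, approach = settings$approach[i],
      t_threshold = settings$t_threshold[i],
      osr = if (is.na(settings$osr[i])) 1 else settings$osr[i],
      n_repetitions = n_repetitions, seed = seed + i, meta = meta)
    run_experiment(cfg)
  })
  list(table = compare_settings(results), results = results, panel = panel)
}
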