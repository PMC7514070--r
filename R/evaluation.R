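#' Range of differences between two correlation matrices
#'
#' The columnwise Pearson correlation matrix is computed for each input and
#' the elementwise difference `cor(A) - cor(B)` taken; the minimum and
#' maximum entry (diagonal included, identically zero) are returned. Used
#' for the signal-stability metrics: the pmv-vs-rmv difference must sit at
#' machine precision, the spmv-vs-rmv difference quantifies the sampling
#' variability of finitely replicated pseudo chronologies.
#'
#' @param a,b numeric matrices with the same number of columns (sites).
#' @return Named numeric vector `c(min, max)`.
#' @export
delta_corr <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b) || ncol(a) < 2L) {
    stop("both matrices need the same column count, at least 2")
  }
  if (any(apply(a, 2L, stats::sd) == 0) ||
      any(apply(b, 2L, stats::sd) == 0)) {
    stop("zero-variance column")
  }
  d <- stats::cor(a) - stats::cor(b)
  c(min = min(d), max = max(d))
}

#' Sample pseudo mean value chronologies under perfect classification
#'
#' The hypothetical mean chronologies that would result if every pseudo
#' historical series were assigned to its true source signal: per site, the
#' yearwise mean of all records whose source is that site. Their
#' intercorrelation, compared with the real-chronology intercorrelation,
#' isolates the instability that finite per-year replication introduces
#' even with a perfect classifier.
#'
#' @param dataset a `pseudo_dataset` with full per-site coverage.
#' @return n_years x S matrix of yearly means, columns named by site.
#' @export
spmv_from_perfect_classification <- function(dataset) {
  stopifnot(inherits(dataset, "pseudo_dataset"))
  S <- length(dataset$site_ids)
  sums <- matrix(0, dataset$n_years, S,
                 dimnames = list(NULL, dataset$site_ids))
  cnts <- matrix(0L, dataset$n_years, S,
                 dimnames = list(NULL, dataset$site_ids))
  for (i in seq_len(nrow(dataset$meta))) {
    s <- dataset$meta$start_year[i]
    idx <- s:(s + dataset$meta$length[i] - 1L)
    j <- dataset$meta$source_site[i]
    sums[idx, j] <- sums[idx, j] + dataset$values[[i]]
    cnts[idx, j] <- cnts[idx, j] + 1L
  }
  if (any(cnts == 0L)) {
    bad <- which(cnts == 0L, arr.ind = TRUE)[1, ]
    stop("no coverage for site '", dataset$site_ids[bad[2]],
         "' in pseudo year ", bad[1])
  }
  sums / cnts
}

#' Contrast map: grouping of pseudo sites for contamination analysis
#'
#' Wraps a site metadata table into the four groupings used for
#' contamination: `site` (identity), `elevation` (low/medium/high band),
#' `elevation_coarse` (medium and low merged, i.e. high vs the rest) and
#' `watershed`.
#'
#' @param meta data frame with columns `site_id`, `elevation_band`,
#'   `watershed` (see [read_site_meta()]).
#' @return An object of class `contrast_map`.
#' @export
contrast_map <- function(meta) {
  need <- c("site_id", "elevation_band", "watershed")
  stopifnot(all(need %in% names(meta)))
  bad <- setdiff(unique(meta$elevation_band), c("low", "medium", "high"))
  if (length(bad) > 0L) stop("unknown elevation band(s): ",
                             paste(bad, collapse = ", "))
  df <- data.frame(site_id = meta$site_id,
                   site = meta$site_id,
                   elevation = meta$elevation_band,
                   elevation_coarse = ifelse(meta$elevation_band == "high",
                                             "high", "medium_low"),
                   watershed = meta$watershed,
                   stringsAsFactors = FALSE)
  structure(df, class = c("contrast_map", "data.frame"))
}

.map_group <- function(sites, contrast, map) {
  i <- match(sites, map$site_id)
  if (anyNA(i)) {
    stop("unmapped site(s): ",
         paste(unique(sites[is.na(i)]), collapse = ", "))
  }
  map[[contrast]][i]
}

#' Off-contrast contamination of a reference chronology
#'
#' The percentage of a reference's classified members whose source signal
#' belongs to a different contrast group than the signal that initialized
#' the reference. With the `site` contrast this is plain off-site
#' contamination; coarser contrasts (elevation, watershed) can only merge
#' groups, so their contamination is never larger. A reference with no
#' members reports 0 with attribute `empty = TRUE`.
#'
#' @param pref a `pref`.
#' @param contrast one of `"site"`, `"elevation"`, `"elevation_coarse"`,
#'   `"watershed"`.
#' @param map a [contrast_map()] (not needed for `contrast = "site"`).
#' @return Percentage in `[0, 100]`.
#' @export
contamination <- function(pref, contrast = "site", map = NULL) {
  contrast <- match.arg(contrast, c("site", "elevation",
                                    "elevation_coarse", "watershed"))
  if (nrow(pref$members) == 0L) {
    return(structure(0, empty = TRUE))
  }
  if (contrast == "site") {
    own <- pref$init_site
    grp <- pref$members$source_site
  } else {
    if (is.null(map)) stop("contrast '", contrast, "' needs a contrast_map")
    own <- .map_group(pref$init_site, contrast, map)
    grp <- .map_group(pref$members$source_site, contrast, map)
  }
  100 * mean(grp != own)
}

#' Summarise one constructor repetition
#'
#' Computes the headline per-repetition statistics: the percentage of
#' generated series that were classified, the percentage of classified
#' series that were classified correctly (to the reference initialized with
#' their source signal; for object chronologies correctness refers to the
#' nominal source site regardless of osr), the number of constructor runs
#' executed and the number of series generated, plus a per-reference table
#' of final length, mean replication and contamination under each available
#' contrast.
#'
#' @param result a [run_constructor()] result.
#' @param dataset the candidate `pseudo_dataset` given to the constructor.
#' @param map optional [contrast_map()] for off-contrast contamination.
#' @return An object of class `repetition_summary`.
#' @export
repetition_summary <- function(result, dataset, map = NULL) {
  n_gen <- nrow(dataset$meta)
  trace <- result$trace
  n_cls <- nrow(trace)
  init_sites <- vapply(result$prefs, `[[`, character(1), "init_site")
  correct <- if (n_cls == 0L) 0L else {
    src <- dataset$meta$source_site[match(trace$record_id,
                                          dataset$meta$record_id)]
    sum(src == init_sites[trace$pref_id])
  }
  contrasts <- if (is.null(map)) "site" else
    c("site", "elevation", "elevation_coarse", "watershed")
  per_pref <- do.call(rbind, lapply(result$prefs, function(p) {
    row <- data.frame(pref_id = p$pref_id, init_site = p$init_site,
                      n_members = nrow(p$members),
                      length = pref_length(p),
                      mean_replication = pref_mean_replication(p),
                      stringsAsFactors = FALSE)
    for (ctr in contrasts) {
      row[[paste0("contamination_", ctr)]] <-
        as.numeric(contamination(p, ctr, map))
    }
    row
  }))
  structure(list(
    n_series_generated = n_gen,
    n_classified = n_cls,
    pct_generated_classified = 100 * n_cls / n_gen,
    pct_classified_correct = if (n_cls == 0L) 0 else 100 * correct / n_cls,
    no_classification = n_cls == 0L,
    n_runs_executed = result$n_runs,
    per_pref = per_pref,
    run_logs = result$run_logs,
    contrasts = contrasts),
    class = "repetition_summary")
}

#' @export
print.repetition_summary <- function(x, ...) {
  cat(sprintf(
    "<repetition_summary> %d generated, %.2f%% classified, %.2f%% of those correct, %d runs\n",
    x$n_series_generated, x$pct_generated_classified,
    x$pct_classified_correct, x$n_runs_executed))
  invisible(x)
}

# length categories over the pseudo timeline: attracted-nothing, then
# thirds of the timeline, then full length
.length_category <- function(length, n_members, n_years) {
  b1 <- round(n_years / 3)
  b2 <- round(2 * n_years / 3)
  labs <- c("0", paste0("1-", b1), paste0(b1 + 1, "-", b2),
            paste0(b2 + 1, "-", n_years - 1), as.character(n_years))
  ifelse(n_members == 0L, labs[1],
         ifelse(length <= b1, labs[2],
                ifelse(length <= b2, labs[3],
                       ifelse(length < n_years, labs[4], labs[5]))))
}

.attractor_category <- function(n_members) {
  cut(n_members, breaks = c(-0.5, 100.5, 500.5, 1000.5, Inf),
      labels = c("0-100", "101-500", "501-1000", ">1000"))
}

#' Aggregate many simulation repetitions
#'
#' Produces the multi-repetition summary: minimum/median/maximum of the
#' per-repetition headline statistics; per-run 95th-percentile
#' contamination, median length and median mean replication per reference,
#' computed over *fully replicated* runs only (runs executed in every
#' repetition); mean counts of references per length category (`0` meaning
#' the reference attracted no series) and per attractor category (number of
#' series attracted); and the final per-repetition contamination per
#' reference and contrast, for [flag_contaminated()].
#'
#' @param reps list of [repetition_summary()] objects.
#' @param n_years length of the pseudo timeline (for the length
#'   categories); default taken from the longest reference seen.
#' @param probs quantile level for the per-run contamination summary
#'   (default 0.95, linear interpolation between order statistics).
#' @return An object of class `multirep_summary`.
#' @export
summarize_repetitions <- function(reps, n_years = NULL, probs = 0.95) {
  stopifnot(length(reps) >= 1L)
  n_years <- as.integer(n_years %||% max(vapply(reps, function(r)
    max(r$per_pref$length), numeric(1))))
  mmm <- function(v) c(min = min(v), median = stats::median(v), max = max(v))
  table1 <- rbind(
    pct_generated_classified = mmm(vapply(
      reps, `[[`, numeric(1), "pct_generated_classified")),
    pct_classified_correct = mmm(vapply(
      reps, `[[`, numeric(1), "pct_classified_correct")),
    n_runs_executed = mmm(vapply(
      reps, `[[`, numeric(1), "n_runs_executed")),
    n_series_generated = mmm(vapply(
      reps, `[[`, numeric(1), "n_series_generated")))
  # fully replicated runs: those executed in every repetition
  n_full <- min(vapply(reps, `[[`, numeric(1), "n_runs_executed"))
  per_run <- NULL
  if (n_full >= 1L) {
    rows <- list()
    pref_ids <- sort(unique(reps[[1]]$per_pref$pref_id))
    for (r in seq_len(n_full)) {
      for (p in pref_ids) {
        vals <- t(vapply(reps, function(rep_) {
          lg <- rep_$run_logs
          row <- lg[lg$run_index == r & lg$pref_id == p, ]
          c(row$contamination[1], row$length[1], row$mean_replication[1])
        }, numeric(3)))
        rows[[length(rows) + 1L]] <- data.frame(
          run_index = r, pref_id = p,
          contamination_p95 = as.numeric(
            stats::quantile(vals[, 1], probs, type = 7)),
          median_length = stats::median(vals[, 2]),
          median_mean_replication = stats::median(vals[, 3]))
      }
    }
    per_run <- do.call(rbind, rows)
  }
  # category means
  b1 <- round(n_years / 3); b2 <- round(2 * n_years / 3)
  len_levels <- c("0", paste0("1-", b1), paste0(b1 + 1, "-", b2),
                  paste0(b2 + 1, "-", n_years - 1), as.character(n_years))
  len_counts <- vapply(reps, function(rep_) {
    lc <- factor(.length_category(rep_$per_pref$length,
                                  rep_$per_pref$n_members, n_years),
                 levels = len_levels)
    as.numeric(table(lc))
  }, numeric(length(len_levels)))
  attr_levels <- c("0-100", "101-500", "501-1000", ">1000")
  attr_counts <- vapply(reps, function(rep_) {
    as.numeric(table(.attractor_category(rep_$per_pref$n_members)))
  }, numeric(length(attr_levels)))
  categories <- data.frame(
    category = c(len_levels, attr_levels),
    kind = c(rep("length", length(len_levels)),
             rep("attracted", length(attr_levels))),
    mean_count = c(rowMeans(len_counts), rowMeans(attr_counts)))
  # final contamination per repetition, pref and contrast
  contrasts <- reps[[1]]$contrasts
  final_cont <- lapply(stats::setNames(contrasts, contrasts), function(ctr) {
    t(vapply(reps, function(rep_)
      rep_$per_pref[[paste0("contamination_", ctr)]],
      numeric(nrow(reps[[1]]$per_pref))))
  })
  structure(list(n_repetitions = length(reps), table1 = table1,
                 per_run = per_run, categories = categories,
                 final_contamination = final_cont,
                 n_fully_replicated_runs = as.integer(n_full),
                 n_years = n_years),
            class = "multirep_summary")
}

#' @export
print.multirep_summary <- function(x, ...) {
  cat(sprintf("<multirep_summary> %d repetitions, %d fully replicated runs\n",
              x$n_repetitions, x$n_fully_replicated_runs))
  print(round(x$table1, 2))
  invisible(x)
}

#' Fraction of repetitions in which each reference was contaminated
#'
#' A repetition counts as contaminated for a reference when its final
#' off-contrast contamination exceeds `threshold_pct` (20% in the standard
#' reading of the scatterplot convention).
#'
#' @param summary a [summarize_repetitions()] result.
#' @param contrast contrast name present in the summary.
#' @param threshold_pct contamination threshold in percent.
#' @return Numeric vector, one fraction in `[0, 1]` per reference.
#' @export
flag_contaminated <- function(summary, contrast = "site",
                              threshold_pct = 20) {
  m <- summary$final_contamination[[contrast]]
  if (is.null(m)) stop("contrast '", contrast, "' not available")
  colMeans(m > threshold_pct)
}

#' Export the multi-repetition summary tables as TSV
#'
#' Writes the headline table, the per-run table and the category table to
#' `<stem>_summary.tsv`, `<stem>_per_run.tsv` and `<stem>_categories.tsv`.
#'
#' @param summary a `multirep_summary`.
#' @param stem output path stem.
#' @export
write_multirep_summary <- function(summary, stem) {
  utils::write.table(data.frame(statistic = rownames(summary$table1),
                                summary$table1),
                     paste0(stem, "_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(summary$per_run)) {
    utils::write.table(summary$per_run, paste0(stem, "_per_run.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(summary$categories, paste0(stem, "_categories.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}
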