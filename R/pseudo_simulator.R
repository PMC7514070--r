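#' Generate a covariance-preserving pseudo site-signal panel
#'
#' The heart of the simulation model. The panel's `[rmv | ln(rsd)]` matrix M
#' (Y x 2S) is summarised by its column means mu and sample covariance Sigma.
#' Sigma is decomposed via its eigenvalues, Sigma = E L E', and a standard
#' normal n_years x 2S matrix Z is pushed through X = mu + Z (E L^{1/2})'.
#' With `empirical = TRUE` (the default) Z is first column-centred, exactly
#' decorrelated by an SVD rotation and rescaled to unit SD, so the *sample*
#' covariance of X equals Sigma up to rounding error. This is what keeps the
#' intercorrelation of the pseudo signals identical to that of the real site
#' chronologies in every repetition, rather than merely equal in expectation.
#' The first S columns of X are the yearly pseudo means (`pmv`); the last S
#' columns are exponentiated into the yearly pseudo SDs (`psd`), matching the
#' log-normal model for the dispersion columns.
#'
#' @param panel a [param_panel()].
#' @param n_years length of the pseudo timeline (default 1000).
#' @param seed optional integer seed.
#' @param empirical preserve the sample covariance exactly (default `TRUE`);
#'   `FALSE` gives ordinary multivariate-normal draws.
#' @param tol relative tolerance below which negative eigenvalues of Sigma
#'   are an error rather than clamped to zero.
#' @return An object of class `signal_panel`: list with `n_years`,
#'   `site_ids`, `pmv` and `psd` (n_years x S matrices) and
#'   `source_panel_fingerprint`.
#' @export
simulate_signal_panel <- function(panel, n_years = 1000L, seed = NULL,
                                  empirical = TRUE, tol = 1e-8) {
  stopifnot(inherits(panel, "param_panel"))
  n_years <- as.integer(n_years)
  if (n_years < 1L) stop("n_years must be >= 1")
  set_seed_if(seed)
  M <- log_rsd(panel)
  mu <- colMeans(M)
  Sigma <- stats::cov(M)
  X <- rmvn_eigen(n_years, mu, Sigma, empirical = empirical, tol = tol)
  S <- length(panel$site_ids)
  pmv <- X[, seq_len(S), drop = FALSE]
  psd <- exp(X[, S + seq_len(S), drop = FALSE])
  dimnames(pmv) <- dimnames(psd) <- list(NULL, panel$site_ids)
  structure(list(n_years = n_years, site_ids = panel$site_ids,
                 pmv = pmv, psd = psd,
                 source_panel_fingerprint = fingerprint(M)),
            class = "signal_panel")
}

#' @export
print.signal_panel <- function(x, ...) {
  cat(sprintf("<signal_panel> %d pseudo sites x %d years\n",
              length(x$site_ids), x$n_years))
  invisible(x)
}

new_pseudo_record <- function(record_id, source_site, kind, start_year,
                              values, members = NULL, osr = NA_real_) {
  structure(list(record_id = record_id, source_site = source_site,
                 kind = kind, start_year = as.integer(start_year),
                 values = as.numeric(values), members = members, osr = osr),
            class = "pseudo_record")
}

#' @export
print.pseudo_record <- function(x, ...) {
  cat(sprintf("<pseudo_record> %s [%s] site %s, years %d-%d%s\n",
              x$record_id, x$kind, x$source_site, x$start_year,
              x$start_year + length(x$values) - 1L,
              if (!is.na(x$osr)) sprintf(", osr %.2f", x$osr) else ""))
  invisible(x)
}

#' Draw one full-length pseudo series from a signal panel
#'
#' The value in pseudo year t is an independent draw from
#' Normal(pmv[t, site], psd[t, site]); a pseudo series (ps) therefore
#' emulates one AR residual ring-width series spanning the whole pseudo
#' timeline.
#'
#' @param signal a [simulate_signal_panel()] result.
#' @param site site id (must be one of `signal$site_ids`).
#' @param seed optional integer seed.
#' @param record_id id for the record (default auto-generated).
#' @return A `pseudo_record` of kind `"ps"` starting in pseudo year 1.
#' @export
draw_pseudo_series <- function(signal, site, seed = NULL,
                               record_id = NULL) {
  stopifnot(inherits(signal, "signal_panel"))
  if (!site %in% signal$site_ids) stop("unknown site '", site, "'")
  set_seed_if(seed)
  vals <- rnorm(signal$n_years, mean = signal$pmv[, site],
                sd = signal$psd[, site])
  new_pseudo_record(record_id %||% paste0(site, "_ps"), site, "ps", 1L, vals)
}

#' Partition a pseudo series into pseudo historical series
#'
#' Series lengths are drawn with replacement from the length pool until the
#' drawn total reaches the series length; the series is then cut into
#' consecutive pieces starting at its first year, the final piece being
#' truncated to the remaining years. A final piece shorter than `min_length`
#' (50 years by default, the minimum usable overlap for crossmatching) is
#' discarded. The kept pieces plus any discarded tail tile the series
#' exactly, with no gaps or overlap.
#'
#' @param ps a full-length `pseudo_record` (kind `"ps"` or an averaged
#'   object series).
#' @param pool a [length_pool()].
#' @param seed optional integer seed.
#' @param min_length minimum kept partition length (years).
#' @param kind kind label for the partitions (default `"phs"`).
#' @return List of `pseudo_record` partitions carrying the parent's source
#'   site (and members/osr, for object chronologies).
#' @export
partition_series <- function(ps, pool, seed = NULL, min_length = 50L,
                             kind = "phs") {
  stopifnot(inherits(ps, "pseudo_record"), length(pool) >= 1L)
  set_seed_if(seed)
  total <- length(ps$values)
  pool <- as.integer(pool)
  lens <- integer(0)
  while (sum(lens) < total) {
    # index-based draw: sample(pool, 1) would misbehave for a 1-length pool
    lens <- c(lens, pool[sample.int(length(pool), 1L)])
  }
  out <- list()
  pos <- 1L
  for (k in seq_along(lens)) {
    len <- min(lens[k], total - pos + 1L)
    if (len >= min_length) {
      out[[length(out) + 1L]] <- new_pseudo_record(
        paste0(ps$record_id, "_p", k), ps$source_site, kind,
        ps$start_year + pos - 1L, ps$values[pos:(pos + len - 1L)],
        members = ps$members, osr = ps$osr)
    }
    pos <- pos + len
    if (pos > total) break
  }
  out
}

new_pseudo_dataset <- function(records, n_years, site_ids, kind,
                               target_replication) {
  meta <- data.frame(
    record_id = vapply(records, `[[`, character(1), "record_id"),
    source_site = vapply(records, `[[`, character(1), "source_site"),
    kind = vapply(records, `[[`, character(1), "kind"),
    start_year = vapply(records, `[[`, integer(1), "start_year"),
    length = vapply(records, function(r) length(r$values), integer(1)),
    osr = vapply(records, function(r) r$osr %||% NA_real_, numeric(1)),
    members = vapply(records, function(r)
      if (is.null(r$members)) NA_character_ else
        paste(r$members, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  structure(list(meta = meta,
                 values = lapply(records, `[[`, "values"),
                 n_years = as.integer(n_years), site_ids = site_ids,
                 kind = kind, target_replication = target_replication),
            class = "pseudo_dataset")
}

#' @export
print.pseudo_dataset <- function(x, ...) {
  cat(sprintf(
    "<pseudo_dataset> %d %s records, %d sites, %d pseudo years (target repl. %d)\n",
    nrow(x$meta), x$kind, length(x$site_ids), x$n_years,
    x$target_replication))
  invisible(x)
}

#' Per-(site, year) coverage of a pseudo dataset
#'
#' @param dataset a `pseudo_dataset`.
#' @return n_years x S integer matrix counting, per pseudo year and source
#'   site, how many records cover that year.
#' @export
dataset_coverage <- function(dataset) {
  cov <- matrix(0L, dataset$n_years, length(dataset$site_ids),
                dimnames = list(NULL, dataset$site_ids))
  for (i in seq_len(nrow(dataset$meta))) {
    s <- dataset$meta$start_year[i]
    e <- s + dataset$meta$length[i] - 1L
    j <- dataset$meta$source_site[i]
    cov[s:e, j] <- cov[s:e, j] + 1L
  }
  cov
}

#' Build a pseudo historical series (phs) dataset
#'
#' For each pseudo site, full-length pseudo series are drawn and partitioned
#' (see [partition_series()]) until every pseudo year is covered by
#' `target_replication` phs of that site. Because each pseudo series tiles
#' the whole timeline, short final partitions included, generation-time
#' coverage rises by exactly one per series and the loop draws exactly
#' `target_replication` series per site; the sub-50-year tails are then
#' discarded from the returned records (they are unusable for
#' crossmatching), so the kept-record coverage of the last few decades of
#' the timeline can fall slightly below the target.
#'
#' @param signal a [simulate_signal_panel()] result.
#' @param pool a [length_pool()].
#' @param target_replication per-year coverage target per site (default 30).
#' @param seed optional integer seed.
#' @return A `pseudo_dataset` of kind `"phs"`.
#' @export
build_phs_dataset <- function(signal, pool, target_replication = 30L,
                              seed = NULL) {
  stopifnot(inherits(signal, "signal_panel"))
  set_seed_if(seed)
  records <- list()
  for (site in signal$site_ids) {
    for (i in seq_len(target_replication)) {
      ps <- draw_pseudo_series(signal, site,
                               record_id = paste0(site, "_ps", i))
      records <- c(records, partition_series(ps, pool))
    }
  }
  new_pseudo_dataset(records, signal$n_years, signal$site_ids, "phs",
                     target_replication)
}

#' Build a pseudo object chronology (poc) dataset
#'
#' Object chronologies emulate the mean series of one historical object
#' (e.g. a roof): per object, `n_per_object` (default 6) full-length pseudo
#' series are drawn and averaged yearwise before partitioning. The on-site
#' ratio `osr` controls signal mixing: `round(osr * n_per_object)` of the
#' constituent series come from the object's nominal site, the rest from
#' off-site signals chosen uniformly at random among the other sites
#' (independently per series, so two off-site series may share a donor).
#' Partitioning and the coverage loop work exactly as for phs, with coverage
#' counted against the nominal site.
#'
#' @inheritParams build_phs_dataset
#' @param osr on-site ratio; one of 1, 5/6 (0.83) or 4/6 (0.67) unless
#'   `allow_any_osr = TRUE`.
#' @param n_per_object series averaged per object (default 6).
#' @param allow_any_osr accept any osr with integral `osr * n_per_object`.
#' @return A `pseudo_dataset` of kind `"poc"`; each record carries its six
#'   constituent source-site labels and its osr.
#' @export
build_poc_dataset <- function(signal, pool, osr = 1, n_per_object = 6L,
                              target_replication = 30L, seed = NULL,
                              allow_any_osr = FALSE) {
  stopifnot(inherits(signal, "signal_panel"))
  if (!allow_any_osr &&
      !any(abs(osr - c(1, 5 / 6, 4 / 6)) < 0.01)) {
    stop("osr must be one of 1, 0.83 (5/6) or 0.67 (4/6); ",
         "use allow_any_osr = TRUE to override")
  }
  k_on <- as.integer(round(osr * n_per_object))
  if (k_on < 1L || k_on > n_per_object) {
    stop("osr * n_per_object must round to 1..", n_per_object)
  }
  if (k_on < n_per_object && length(signal$site_ids) < 2L) {
    stop("off-site draws need at least 2 sites")
  }
  set_seed_if(seed)
  records <- list()
  for (site in signal$site_ids) {
    others <- setdiff(signal$site_ids, site)
    for (i in seq_len(target_replication)) {
      members <- c(rep(site, k_on),
                   if (k_on < n_per_object)
                     sample(others, n_per_object - k_on, replace = TRUE))
      vals <- matrix(0, signal$n_years, n_per_object)
      for (m in seq_along(members)) {
        vals[, m] <- rnorm(signal$n_years,
                           mean = signal$pmv[, members[m]],
                           sd = signal$psd[, members[m]])
      }
      obj <- new_pseudo_record(paste0(site, "_obj", i), site, "poc_full",
                               1L, rowMeans(vals),
                               members = members,
                               osr = k_on / n_per_object)
      records <- c(records, partition_series(obj, pool, kind = "poc"))
    }
  }
  new_pseudo_dataset(records, signal$n_years, signal$site_ids, "poc",
                     target_replication)
}

#' Serialize / read a pseudo dataset (long CSV + JSON sidecar)
#'
#' The CSV holds one row per record-year (`record_id`, `source_site`,
#' `kind`, `start_year`, `year`, `value`); the JSON sidecar holds per-record
#' members and osr plus dataset-level metadata.
#'
#' @param dataset a `pseudo_dataset`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
write_pseudo_dataset <- function(dataset, path) {
  m <- dataset$meta
  n <- m$length
  df <- data.frame(
    record_id = rep(m$record_id, n),
    source_site = rep(m$source_site, n),
    kind = rep(m$kind, n),
    start_year = rep(m$start_year, n),
    year = unlist(lapply(seq_len(nrow(m)), function(i)
      m$start_year[i] + seq_len(n[i]) - 1L)),
    value = unlist(dataset$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(n_years = dataset$n_years, site_ids = dataset$site_ids,
               kind = dataset$kind,
               target_replication = dataset$target_replication,
               records = m[, c("record_id", "osr", "members")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_pseudo_dataset
#' @export
read_pseudo_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  recs <- side$records
  records <- lapply(seq_len(nrow(recs)), function(i) {
    rid <- recs$record_id[i]
    rows <- df[df$record_id == rid, , drop = FALSE]
    rows <- rows[order(rows$year), , drop = FALSE]
    members <- recs$members[i]
    new_pseudo_record(rid, rows$source_site[1], rows$kind[1], rows$year[1],
                      rows$value,
                      members = if (is.na(members)) NULL else
                        strsplit(members, ",")[[1]],
                      osr = recs$osr[i])
  })
  new_pseudo_dataset(records, side$n_years, side$site_ids, side$kind,
                     side$target_replication)
}
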