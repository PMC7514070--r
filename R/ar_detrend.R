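#' Autoregressive prewhitening of a ring-width series
#'
#' Fits AR(p) models to the raw widths for p = 0..`max_order` by Yule-Walker
#' (the classic prewhitening default), selects the AIC-minimising order and
#' returns the one-step-ahead innovations. The residuals are re-centred so
#' that their mean equals the raw-series mean (residual-chronology
#' convention, which keeps series on comparable levels); the leading `p`
#' years, for which no innovation exists, are dropped, so the residual series
#' starts `p` years after the raw series.
#'
#' @param series a [rw_series()] (or any list with `series_id`, `site_id`,
#'   `first_year`, `widths`).
#' @param max_order maximum candidate AR order; the default
#'   `min(floor(10 log10 n), n - 1)` matches the standard `stats::ar()` rule.
#' @return An object of class `residual_series` with fields `series_id`,
#'   `site_id`, `first_year`, `residuals` and `ar_order`.
#' @export
ar_residuals <- function(series, max_order = NULL) {
  x <- as.numeric(series$widths)
  n <- length(x)
  if (n < 10L) stop("series '", series$series_id, "': need at least 10 rings")
  if (any(!is.finite(x))) {
    stop("series '", series$series_id, "': non-finite widths")
  }
  if (stats::var(x) == 0) {
    # degenerate constant series: nothing to whiten
    return(structure(list(series_id = series$series_id,
                          site_id = series$site_id,
                          first_year = as.integer(series$first_year),
                          residuals = rep(mean(x), n), ar_order = 0L),
                     class = "residual_series"))
  }
  max_order <- max_order %||% min(floor(10 * log10(n)), n - 1L)
  fit <- stats::ar(x, aic = TRUE, order.max = max_order,
                   method = "yule-walker")
  p <- fit$order
  res <- fit$resid                      # leading p entries are NA
  res <- res[!is.na(res)]
  res <- res - mean(res) + mean(x)      # re-centre on the raw-series mean
  structure(list(series_id = series$series_id, site_id = series$site_id,
                 first_year = as.integer(series$first_year) + p,
                 residuals = res, ar_order = as.integer(p)),
            class = "residual_series")
}

#' @export
print.residual_series <- function(x, ...) {
  cat(sprintf("<residual_series> %s (site %s), AR(%d), %d years from %d\n",
              x$series_id, x$site_id, x$ar_order, length(x$residuals),
              x$first_year))
  invisible(x)
}

#' Yearly mean/SD parameter panel of residual site chronologies
#'
#' Per site, the AR residual series are aligned by calendar year; the common
#' period is the maximal consecutive range of years in which *every* site has
#' at least `min_replication` residual values per year. Over that period the
#' panel holds, per site, the yearly sample mean (`rmv`) and yearly sample SD
#' (`rsd`, denominator n-1) of the residuals across trees. These are the
#' sufficient statistics that parameterise the sequences of yearly normal
#' distributions from which pseudo series are later sampled.
#'
#' @param site_datasets named list of [site_dataset()] objects (raw widths),
#'   or a list of lists of `residual_series` if `detrend = FALSE`.
#' @param min_replication minimum trees per year per site (default 15).
#' @param detrend if `TRUE` (default), [ar_residuals()] is applied to every
#'   series first.
#' @return An object of class `param_panel`: list with `years` (consecutive
#'   integer vector, length Y), `site_ids` (length S), `rmv` and `rsd`
#'   (Y x S matrices), and `meta` (per-site contrast attributes, if any).
#' @export
build_param_panel <- function(site_datasets, min_replication = 15L,
                              detrend = TRUE) {
  stopifnot(length(site_datasets) >= 1L)
  site_ids <- vapply(site_datasets, `[[`, character(1), "site_id")
  per_site <- lapply(site_datasets, function(sd_) {
    rs <- if (detrend) lapply(sd_$series, ar_residuals) else sd_$series
    yr_min <- min(vapply(rs, `[[`, integer(1), "first_year"))
    yr_max <- max(vapply(rs, function(r)
      r$first_year + length(r$residuals) - 1L, integer(1)))
    yrs <- yr_min:yr_max
    M <- matrix(NA_real_, nrow = length(yrs), ncol = length(rs))
    for (j in seq_along(rs)) {
      idx <- rs[[j]]$first_year - yr_min + seq_along(rs[[j]]$residuals)
      M[idx, j] <- rs[[j]]$residuals
    }
    list(years = yrs, M = M, depth = rowSums(!is.na(M)))
  })
  # per-site years meeting the replication requirement; must be contiguous
  covered <- lapply(seq_along(per_site), function(i) {
    ps <- per_site[[i]]
    ok <- ps$years[ps$depth >= min_replication]
    if (length(ok) == 0L) {
      stop("site '", site_ids[i], "': no year reaches replication ",
           min_replication, " (max depth ", max(ps$depth), ")")
    }
    if (any(diff(ok) != 1L)) {
      stop("site '", site_ids[i], "': years meeting replication ",
           min_replication, " are not contiguous")
    }
    ok
  })
  lo <- max(vapply(covered, min, integer(1)))
  hi <- min(vapply(covered, max, integer(1)))
  if (lo > hi) {
    cov_str <- paste(sprintf("%s: %d-%d", site_ids,
                             vapply(covered, min, integer(1)),
                             vapply(covered, max, integer(1))),
                     collapse = "; ")
    stop("no common period across sites (per-site coverage: ", cov_str, ")")
  }
  years <- lo:hi
  S <- length(site_ids)
  rmv <- matrix(NA_real_, length(years), S,
                dimnames = list(years, site_ids))
  rsd <- rmv
  for (i in seq_len(S)) {
    ps <- per_site[[i]]
    rows <- match(years, ps$years)
    sub <- ps$M[rows, , drop = FALSE]
    rmv[, i] <- rowMeans(sub, na.rm = TRUE)
    rsd[, i] <- apply(sub, 1L, stats::sd, na.rm = TRUE)
  }
  if (any(rsd <= 0)) stop("zero yearly SD encountered in the common period")
  meta <- lapply(site_datasets, function(sd_) sd_$meta %||% list())
  names(meta) <- site_ids
  structure(list(years = years, site_ids = unname(site_ids),
                 rmv = rmv, rsd = rsd, meta = meta),
            class = "param_panel")
}

#' Construct a parameter panel directly from matrices
#'
#' Mainly useful for tests and analytic fixtures where the yearly means and
#' SDs are specified rather than estimated from ring-width data.
#'
#' @param rmv,rsd Y x S numeric matrices of yearly means and SDs.
#' @param years integer vector of length Y (default `1:Y`).
#' @param site_ids character vector of length S (default `"s1".."sS"`).
#' @param meta optional named list of per-site contrast attributes.
#' @return A `param_panel`.
#' @export
param_panel <- function(rmv, rsd, years = NULL, site_ids = NULL,
                        meta = NULL) {
  rmv <- as.matrix(rmv); rsd <- as.matrix(rsd)
  stopifnot(all(dim(rmv) == dim(rsd)))
  if (any(rsd <= 0)) stop("all rsd entries must be positive")
  years <- as.integer(years %||% seq_len(nrow(rmv)))
  site_ids <- site_ids %||% paste0("s", seq_len(ncol(rmv)))
  stopifnot(length(years) == nrow(rmv), length(site_ids) == ncol(rmv),
            all(diff(years) == 1L))
  dimnames(rmv) <- dimnames(rsd) <- list(years, site_ids)
  meta <- meta %||% stats::setNames(vector("list", length(site_ids)),
                                    site_ids)
  structure(list(years = years, site_ids = site_ids, rmv = rmv, rsd = rsd,
                 meta = meta),
            class = "param_panel")
}

#' @export
print.param_panel <- function(x, ...) {
  cat(sprintf("<param_panel> %d sites x %d years (%d-%d)\n",
              length(x$site_ids), length(x$years),
              min(x$years), max(x$years)))
  invisible(x)
}

#' The [rmv | ln(rsd)] matrix of a parameter panel
#'
#' Yearly SDs are log-transformed (natural logarithm) before the covariance
#' matrix is taken, since a multivariate log-normal is the appropriate model
#' for the dispersion columns; means are left on their original scale.
#'
#' @param panel a [build_param_panel()] result.
#' @return Y x 2S matrix, columns named `rmv_<site>` then `rsd_<site>`
#'   (the latter holding `ln(rsd)`).
#' @export
log_rsd <- function(panel) {
  stopifnot(inherits(panel, "param_panel"))
  if (any(panel$rsd <= 0)) stop("all rsd entries must be positive")
  M <- cbind(panel$rmv, log(panel$rsd))
  colnames(M) <- c(paste0("rmv_", panel$site_ids),
                   paste0("rsd_", panel$site_ids))
  M
}

#' Export / import a parameter panel as CSV
#'
#' Wide layout: one row per year (`year` column) and columns
#' `rmv_<site>` / `rsd_<site>` on the original (not log) scale.
#'
#' @param panel a `param_panel`.
#' @param path CSV path.
#' @export
write_param_panel <- function(panel, path) {
  df <- data.frame(year = panel$years, panel$rmv, panel$rsd,
                   check.names = FALSE)
  names(df) <- c("year", paste0("rmv_", panel$site_ids),
                 paste0("rsd_", panel$site_ids))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_param_panel
#' @export
read_param_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rmv_cols <- grep("^rmv_", names(df), value = TRUE)
  rsd_cols <- grep("^rsd_", names(df), value = TRUE)
  if (length(rmv_cols) == 0L || length(rmv_cols) != length(rsd_cols)) {
    stop("panel CSV must have matching rmv_<site>/rsd_<site> columns")
  }
  sites <- sub("^rmv_", "", rmv_cols)
  years <- as.integer(df$year)
  if (any(diff(years) != 1L)) stop("panel years must be consecutive")
  rmv <- as.matrix(df[, rmv_cols, drop = FALSE])
  rsd <- as.matrix(df[, rsd_cols, drop = FALSE])
  dimnames(rmv) <- dimnames(rsd) <- list(years, sites)
  if (any(rsd <= 0)) stop("rsd entries must be positive")
  structure(list(years = years, site_ids = sites, rmv = rmv, rsd = rsd,
                 meta = stats::setNames(vector("list", length(sites)), sites)),
            class = "param_panel")
}
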