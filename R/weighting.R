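# Performance-and-independence weighting of a model ensemble. Each model
# is summarized over a latitude window by three per-cell diagnostics of
# sea surface temperature (climatological mean, linear trend, detrended
# standard deviation); distances to observations (D_i) and between models
# (S_ij) are area-weighted RMSEs of the diagnostics, combined after
# normalizing each diagnostic by its ensemble median. Weights follow
#   w_i = exp(-D_i^2 / sigma_D^2) / (1 + sum_{j != i} exp(-S_ij^2 / sigma_S^2))
# and are normalized to sum to one for ensemble averaging.

#' Climatology, trend and variability diagnostics of a field
#'
#' Per-cell time mean, least-squares linear trend (per year) and detrended
#' standard deviation over a time window.
#'
#' @param field a `forcing_field` (or any list with `values`
#'   `[time, lat, lon]`, `lat`, `lon`, `time`).
#' @param window length-2 year span; default the full series.
#' @return List of class `model_diagnostics` with matrices `clim`,
#'   `trend`, `sd` (`[lat, lon]`) plus `lat`, `lon`.
#' @export
compute_diagnostics <- function(field, window = NULL) {
  yr <- as.numeric(format(field$time, "%Y")) +
    (as.numeric(format(field$time, "%m")) - 0.5) / 12
  keep <- if (is.null(window)) seq_along(yr)
          else which(yr >= window[1] & yr < window[2] + 1)
  if (length(keep) < 120) stop("data error: window shorter than 10 years")
  v <- field$values[keep, , , drop = FALSE]
  t_c <- yr[keep] - mean(yr[keep])
  nt <- length(keep)
  nlat <- dim(v)[2]; nlon <- dim(v)[3]
  vm <- matrix(v, nt, nlat * nlon)
  clim <- colMeans(vm)
  # least-squares slope against centered time, per cell
  denom <- sum(t_c^2)
  anom <- sweep(vm, 2, clim)
  trend <- as.numeric(crossprod(t_c, anom)) / denom
  resid <- anom - outer(t_c, trend)
  sdd <- sqrt(colSums(resid^2) / (nt - 2))
  structure(list(clim = matrix(clim, nlat, nlon),
                 trend = matrix(trend, nlat, nlon),
                 sd = matrix(sdd, nlat, nlon),
                 lat = field$lat, lon = field$lon),
            class = "model_diagnostics")
}

# area-weighted RMSE between two diagnostic matrices
.aw_rmse <- function(a, b, lat) {
  w <- matrix(cos(lat * pi / 180), nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("data error: no overlapping valid cells")
  sqrt(sum(w[ok] * (a[ok] - b[ok])^2) / sum(w[ok]))
}

#' Distances of ensemble members to observations and to each other
#'
#' Computes the area-weighted RMSE of the three diagnostics between each
#' model and the observations (`D`) and between each model pair (`S`).
#' Each diagnostic's RMSEs are normalized by their ensemble median before
#' averaging the three diagnostics, so the diagnostics contribute on equal
#' footing. Multiple realizations of one model (same `model_id`) are
#' averaged before distances are computed.
#'
#' @param models list of `model_diagnostics`, named by model/realization;
#'   optionally carrying a `model_id` attribute per element (defaults to
#'   the element name stripped of a trailing `.rN` realization suffix).
#' @param obs `model_diagnostics` of the observational reference.
#' @param lat_window latitude span used for the comparison.
#' @return List of class `ensemble_distances` with `D` (named vector),
#'   `S` (symmetric matrix, zero diagonal) and `model_ids`.
#' @export
compute_distances <- function(models, obs, lat_window = c(66, 80)) {
  stopifnot(length(models) >= 1)
  ids <- vapply(seq_along(models), function(i) {
    mid <- attr(models[[i]], "model_id")
    if (!is.null(mid)) mid
    else sub("\\.r[0-9]+$", "", names(models)[i] %||% sprintf("m%d", i))
  }, character(1))

  crop <- function(d) {
    keep <- which(d$lat >= lat_window[1] & d$lat <= lat_window[2])
    if (!length(keep)) stop("configuration error: empty latitude window")
    list(clim = d$clim[keep, , drop = FALSE],
         trend = d$trend[keep, , drop = FALSE],
         sd = d$sd[keep, , drop = FALSE], lat = d$lat[keep])
  }
  obs_c <- crop(obs)
  for (m in models)
    if (!isTRUE(all.equal(m$lat, obs$lat)) ||
        !isTRUE(all.equal(m$lon, obs$lon)))
      stop("configuration error: model/observation grid mismatch")

  # average realizations of the same model
  uids <- unique(ids)
  merged <- lapply(uids, function(u) {
    grp <- lapply(models[ids == u], crop)
    list(clim = Reduce(`+`, lapply(grp, `[[`, "clim")) / length(grp),
         trend = Reduce(`+`, lapply(grp, `[[`, "trend")) / length(grp),
         sd = Reduce(`+`, lapply(grp, `[[`, "sd")) / length(grp),
         lat = grp[[1]]$lat)
  })
  names(merged) <- uids
  m_n <- length(merged)

  diag_names <- c("clim", "trend", "sd")
  d_raw <- sapply(diag_names, function(dn)
    vapply(merged, function(m)
      .aw_rmse(m[[dn]], obs_c[[dn]], m$lat), numeric(1)))
  d_raw <- matrix(d_raw, m_n, 3, dimnames = list(uids, diag_names))

  s_raw <- array(0, c(m_n, m_n, 3), dimnames = list(uids, uids, diag_names))
  if (m_n > 1)
    for (i in seq_len(m_n - 1))
      for (j in (i + 1):m_n)
        for (k in seq_along(diag_names)) {
          dn <- diag_names[k]
          s <- .aw_rmse(merged[[i]][[dn]], merged[[j]][[dn]],
                        merged[[i]]$lat)
          s_raw[i, j, k] <- s; s_raw[j, i, k] <- s
        }

  # normalize each diagnostic by its ensemble median distance-to-obs
  norm <- apply(d_raw, 2, function(x) {
    md <- median(x)
    if (md <= 0) 1 else md
  })
  d_n <- sweep(d_raw, 2, norm, "/")
  s_n <- s_raw
  for (k in 1:3) s_n[, , k] <- s_raw[, , k] / norm[k]
  structure(list(D = rowMeans(d_n),
                 S = apply(s_n, c(1, 2), mean),
                 model_ids = uids),
            class = "ensemble_distances")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Performance-and-independence ensemble weights
#'
#' `w_i = exp(-D_i^2/sigma_D^2) / (1 + sum_{j != i} exp(-S_ij^2/sigma_S^2))`,
#' normalized to sum to 1. By default the shape parameters are set to the
#' ensemble median of `D` and of the off-diagonal `S` (overridable).
#'
#' @param D nonnegative distances to observations (vector, one per model).
#' @param S symmetric inter-model distance matrix, zero diagonal.
#' @param sigma_d,sigma_s positive shape parameters; `NULL` = ensemble
#'   median default.
#' @return List of class `ensemble_weights` with `w` (normalized), `raw`,
#'   `sigma_d`, `sigma_s`.
#' @export
compute_weights <- function(D, S = NULL, sigma_d = NULL, sigma_s = NULL) {
  if (inherits(D, "ensemble_distances")) {
    S <- D$S; D <- D$D
  }
  m <- length(D)
  stopifnot(all(D >= 0))
  if (is.null(S)) S <- matrix(0, m, m)
  stopifnot(nrow(S) == m, ncol(S) == m,
            isTRUE(all.equal(S, t(S))), all(diag(S) == 0))
  if (is.null(sigma_d)) sigma_d <- max(median(D), 1e-9)
  if (is.null(sigma_s)) {
    off <- S[upper.tri(S)]
    sigma_s <- if (length(off)) max(median(off), 1e-9) else 1
  }
  if (sigma_d <= 0 || sigma_s <= 0)
    stop("parameter error: sigma must be positive")
  perf <- exp(-D^2 / sigma_d^2)
  indep <- vapply(seq_len(m), function(i)
    1 + sum(exp(-S[i, -i]^2 / sigma_s^2)), numeric(1))
  raw <- perf / indep
  structure(list(w = raw / sum(raw), raw = raw,
                 sigma_d = sigma_d, sigma_s = sigma_s, D = D),
            class = "ensemble_weights")
}

#' Weighted ensemble mean of gridded fields
#'
#' @param fields list of equally shaped arrays/matrices (or
#'   `forcing_field`s, whose `values` are used).
#' @param weights numeric weights summing to 1 (e.g.
#'   `compute_weights(...)$w`).
#' @return Array of the common shape.
#' @export
weighted_ensemble_mean <- function(fields, weights) {
  vals <- lapply(fields, function(f)
    if (inherits(f, "forcing_field")) f$values else f)
  if (length(vals) != length(weights))
    stop("configuration error: weight/field count mismatch")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("configuration error: weights must sum to 1")
  d1 <- dim(vals[[1]])
  for (v in vals)
    if (!identical(dim(v), d1))
      stop("configuration error: field shapes differ")
  Reduce(`+`, Map(function(v, w) v * w, vals, as.list(weights)))
}

#' Write a weights table
#'
#' Small delimited table (model_id, D, raw_w, w) for downstream use.
#'
#' @param wts an `ensemble_weights`.
#' @param model_ids model identifiers.
#' @param path output TSV path.
#' @return The table, invisibly.
#' @export
write_weights_table <- function(wts, model_ids, path) {
  d <- data.frame(model_id = model_ids, D = wts$D, raw_w = wts$raw,
                  w = wts$w)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
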