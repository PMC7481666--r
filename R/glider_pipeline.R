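#' Despike a sensor series by rolling median / MAD
#'
#' Flags points deviating from a centred rolling median by more than
#' \code{n_mad} times the rolling median absolute deviation (MAD, scaled by
#' 1.4826 for consistency with a Gaussian standard deviation). Flagged points
#' are replaced with the rolling median in \code{clean}; all other points
#' pass through unchanged, so the operation is idempotent.
#'
#' @param series Numeric vector, time-ordered.
#' @param window Odd integer window length, >= 3. Default 7.
#' @param n_mad Threshold in MAD units. Default 5.
#' @return List with \code{clean} (series with spikes replaced by the local
#'   median), \code{mask} (logical, TRUE at spikes) and \code{n_spikes}.
#' @examples
#' x <- c(rep(1, 10), 100, rep(1, 10))
#' despike(x)$mask
#' @export
despike <- function(series, window = 7, n_mad = 5) {
  stopifnot(is.numeric(series), window >= 3, window %% 2 == 1, n_mad > 0)
  n <- length(series)
  if (n < window) {
    warning("series shorter than window (", n, " < ", window,
            "): returned unchanged", call. = FALSE)
    return(list(clean = series, mask = rep(FALSE, n), n_spikes = 0L))
  }
  # Hampel-type filter: deviation of each point from the rolling median of
  # `window`, in units of a locally estimated MAD. The MAD is taken over a
  # wider scale window: a window-of-7 MAD is itself too noisy and trips over
  # ordinary noise in quiet deep water.
  swin <- 4L * window + 3L
  shalf <- (swin - 1L) %/% 2L
  clean <- series
  mask <- rep(FALSE, n)
  # iterate flag-and-replace to a fixed point; the converged series is
  # unchanged by a further pass, which makes despiking idempotent
  for (iter in 1:10) {
    med <- stats::runmed(clean, k = window, endrule = "median")
    dev <- abs(clean - med)
    scale <- vapply(seq_len(n), function(i) {
      idx <- max(1L, i - shalf):min(n, i + shalf)
      stats::median(abs(clean[idx] - stats::median(clean[idx])))
    }, numeric(1)) * 1.4826
    floor_scale <- 1e-12 * max(1, stats::median(abs(clean)))
    new_mask <- dev > n_mad * pmax(scale, floor_scale)
    new_mask[is.na(new_mask)] <- FALSE
    if (!any(new_mask)) break
    clean[new_mask] <- med[new_mask]
    mask <- mask | new_mask
  }
  list(clean = clean, mask = mask, n_spikes = sum(mask))
}

#' Split a sawtooth depth record into dive/climb profiles
#'
#' Detects turning points in the glider's sawtooth depth series: the travel
#' direction flips when depth has reversed by more than \code{hysteresis}
#' metres from the running extreme, which makes the segmentation robust to
#' metre-scale depth jitter. Every record is assigned to exactly one
#' profile.
#'
#' @param records data.frame of glider records with a \code{depth_m} column,
#'   time-ordered.
#' @param hysteresis Depth reversal (m) required to declare a turn. Default 5.
#' @return List of data.frames, each with attribute \code{direction}
#'   (\code{"dive"} or \code{"climb"}).
#' @export
split_profiles <- function(records, hysteresis = 5) {
  stopifnot(is.data.frame(records), "depth_m" %in% names(records))
  depth <- records$depth_m
  n <- length(depth)
  if (n == 0) return(list())
  breaks <- integer(0)
  # initial direction: first depth change beyond the hysteresis
  dir <- 0L
  extreme <- depth[1]
  for (i in seq_len(n)) {
    d <- depth[i]
    if (dir == 0L) {
      # direction unknown until depth first moves beyond the hysteresis
      if (d >= depth[1] + hysteresis) dir <- 1L
      else if (d <= depth[1] - hysteresis) dir <- -1L
      extreme <- d
      next
    }
    if (dir == 1L) {
      if (d > extreme) extreme <- d
      else if (extreme - d > hysteresis) {
        breaks <- c(breaks, i)
        dir <- -1L
        extreme <- d
      }
    } else {
      if (d < extreme) extreme <- d
      else if (d - extreme > hysteresis) {
        breaks <- c(breaks, i)
        dir <- 1L
        extreme <- d
      }
    }
  }
  starts <- c(1L, breaks)
  ends <- c(breaks - 1L, n)
  profiles <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    prof <- records[starts[k]:ends[k], , drop = FALSE]
    rownames(prof) <- NULL
    dd <- prof$depth_m[nrow(prof)] - prof$depth_m[1]
    attr(prof, "direction") <- if (dd >= 0) "dive" else "climb"
    profiles[[k]] <- prof
  }
  profiles
}

#' Chlorophyll from particulate backscattering at 700 nm
#'
#' Inverts the 700 nm backscattering power law:
#' \eqn{Chl = (b_{bp}(700) / A_{bb}(700))^{1 / B_{bb}(700)}}. This is the
#' quenching-free chlorophyll proxy used by the hybrid estimator above the
#' switching threshold.
#'
#' @param bbp700 Particulate backscattering at 700 nm, m\eqn{^{-1}},
#'   strictly positive.
#' @param coef Model coefficients.
#' @return Chlorophyll a, mg m\eqn{^{-3}}.
#' @examples
#' chl_from_bbp(bbp(700, chl = 5))  # recovers 5
#' @export
chl_from_bbp <- function(bbp700, coef = model_coefficients()) {
  if (any(!is.finite(bbp700)) || any(bbp700 <= 0)) {
    stop("bbp700 must be strictly positive", call. = FALSE)
  }
  row <- coef$bbp_table[coef$bbp_table$wavelength_nm == 700, ]
  (bbp700 / row$A_bb)^(1 / row$B_bb)
}

#' Hybrid chlorophyll estimator
#'
#' Combines the two triplet-sensor chlorophyll proxies: fluorescence-derived
#' chlorophyll is used up to the switching threshold (2 mg m\eqn{^{-3}},
#' inclusive), and above it chlorophyll is estimated from the 700 nm
#' backscattering channel, which is immune to surface fluorescence
#' quenching. The switch is hard (no blending), so a small discontinuity at
#' the threshold is expected and documented.
#'
#' @param chl_fl Fluorescence-derived chlorophyll, mg m\eqn{^{-3}}.
#' @param bbp700 Particulate backscattering at 700 nm, m\eqn{^{-1}}.
#' @param threshold Switching threshold, mg m\eqn{^{-3}}. Default 2.
#' @param coef Model coefficients.
#' @return data.frame with \code{chl} and \code{source}
#'   (\code{"fluorescence"} or \code{"backscatter"}).
#' @examples
#' hybrid_chl(chl_fl = c(0.5, 3), bbp700 = bbp(700, c(0.5, 4)))
#' @export
hybrid_chl <- function(chl_fl, bbp700, threshold = NULL,
                       coef = model_coefficients()) {
  if (is.null(threshold)) threshold <- coef$chl_switch
  if (any(!is.finite(chl_fl)) || any(chl_fl < 0)) {
    stop("chl_fl must be non-negative", call. = FALSE)
  }
  use_bb <- chl_fl > threshold
  chl <- chl_fl
  if (any(use_bb)) chl[use_bb] <- chl_from_bbp(bbp700[use_bb], coef)
  data.frame(chl = chl,
             source = ifelse(use_bb, "backscatter", "fluorescence"))
}

#' Gridded transect container
#'
#' @param along_track Along-track cell-centre coordinates, km.
#' @param depth Depth cell-centre coordinates, m (positive down).
#' @param fields Named list of matrices, dim \code{length(along_track) x
#'   length(depth)}; missing cells are \code{NA}.
#' @return Object of class \code{gridded_transect}.
#' @export
gridded_transect <- function(along_track, depth, fields = list()) {
  for (f in fields) {
    stopifnot(is.matrix(f),
              nrow(f) == length(along_track), ncol(f) == length(depth))
  }
  structure(list(along_track = along_track, depth = depth, fields = fields),
            class = "gridded_transect")
}

#' @export
print.gridded_transect <- function(x, ...) {
  dx <- if (length(x$along_track) > 1) diff(x$along_track[1:2]) else NA
  dz <- if (length(x$depth) > 1) diff(x$depth[1:2]) else NA
  cat("Gridded transect: ", length(x$along_track), " x ", length(x$depth),
      " cells (", dx, " km x ", dz, " m)\n", sep = "")
  cat("Fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

# Bilinear interpolation of a grid field at scattered (x, z); outside the
# grid hull the nearest edge value is used (only relevant for the residual
# pass of the Barnes scheme).
.bilinear <- function(xg, zg, F, x, z) {
  x <- pmin(pmax(x, xg[1]), xg[length(xg)])
  z <- pmin(pmax(z, zg[1]), zg[length(zg)])
  ix <- findInterval(x, xg, rightmost.closed = TRUE)
  iz <- findInterval(z, zg, rightmost.closed = TRUE)
  ix <- pmin(ix, length(xg) - 1L)
  iz <- pmin(iz, length(zg) - 1L)
  tx <- (x - xg[ix]) / (xg[ix + 1L] - xg[ix])
  tz <- (z - zg[iz]) / (zg[iz + 1L] - zg[iz])
  F[cbind(ix, iz)] * (1 - tx) * (1 - tz) +
    F[cbind(ix + 1L, iz)] * tx * (1 - tz) +
    F[cbind(ix, iz + 1L)] * (1 - tx) * tz +
    F[cbind(ix + 1L, iz + 1L)] * tx * tz
}

#' Barnes objective analysis onto a distance-depth grid
#'
#' Successive-correction interpolation of scattered observations onto a
#' regular along-track \eqn{\times} depth raster. Pass 1 computes
#' Gaussian-weighted means with length scales \code{radii}; each later pass
#' analyses the observation residuals with the length scales multiplied by
#' \code{gamma^(pass-1)}, sharpening the analysis while keeping it smooth.
#' Weights are \eqn{\exp(-r^2)} in scaled distance
#' \eqn{r^2 = (\Delta x / R_x)^2 + (\Delta z / R_z)^2}; cells with no
#' observation within \code{cutoff} scaled radii are flagged missing
#' (\code{NA}), never zero.
#'
#' @param x,z,value Observation coordinates (km along track, m depth) and
#'   values; equal length, \code{NA} values dropped.
#' @param along_track,depth Grid cell-centre vectors (default spacing 2 km
#'   and 5 m in the standard pipeline).
#' @param radii Length-2 first-pass influence radii \code{c(km, m)}.
#'   Default \code{c(10, 10)}.
#' @param passes Number of correction passes, >= 1. Default 2.
#' @param gamma Radius shrink factor per pass, in (0, 1]. Default 0.3.
#' @param cutoff Missing-data cutoff in scaled radii. Default 3.
#' @return Matrix \code{length(along_track) x length(depth)}.
#' @export
barnes_grid <- function(x, z, value, along_track, depth,
                        radii = c(10, 10), passes = 2, gamma = 0.3,
                        cutoff = 3) {
  stopifnot(length(x) == length(z), length(z) == length(value),
            all(radii > 0), passes >= 1, gamma > 0, gamma <= 1)
  keep <- is.finite(x) & is.finite(z) & is.finite(value)
  x <- x[keep]; z <- z[keep]; value <- value[keep]
  nx <- length(along_track); nz <- length(depth)
  G <- matrix(NA_real_, nx, nz)
  if (length(value) == 0) return(G)
  resid <- value
  analysis <- matrix(0, nx, nz)
  reachable <- matrix(FALSE, nx, nz)
  for (p in seq_len(passes)) {
    rx <- radii[1] * gamma^(p - 1)
    rz <- radii[2] * gamma^(p - 1)
    corr <- matrix(0, nx, nz)
    for (i in seq_len(nx)) {
      dx2 <- ((along_track[i] - x) / rx)^2
      for (j in seq_len(nz)) {
        r2 <- dx2 + ((depth[j] - z) / rz)^2
        if (p == 1L) {
          # reachability is judged at first-pass scales only
          if (min(r2) <= cutoff^2) reachable[i, j] <- TRUE
          else next
        } else if (!reachable[i, j]) next
        w <- exp(-r2)
        sw <- sum(w)
        if (sw > 0) corr[i, j] <- sum(w * resid) / sw
      }
    }
    analysis <- analysis + corr
    if (p < passes) {
      at_obs <- .bilinear(along_track, depth, analysis, x, z)
      resid <- value - at_obs
    }
  }
  G[reachable] <- analysis[reachable]
  G
}

#' Grid a glider deployment onto the standard transect raster
#'
#' Convenience wrapper: computes the along-track coordinate (great-circle
#' distance accumulated along the track, origin at the first record), builds
#' the 2 km \eqn{\times} 5 m grid spanning the data, and Barnes-grids the
#' requested record columns.
#'
#' @param records Glider records (data.frame with \code{lat}, \code{lon},
#'   \code{depth_m} and the requested fields).
#' @param fields Character vector of column names to grid.
#' @param spacing Grid spacing \code{c(km, m)}. Default \code{c(2, 5)}.
#' @param ... Passed to [barnes_grid()] (\code{radii}, \code{passes},
#'   \code{gamma}, \code{cutoff}).
#' @return A [gridded_transect()].
#' @export
grid_deployment <- function(records, fields, spacing = c(2, 5), ...) {
  stopifnot(all(c("lat", "lon", "depth_m") %in% names(records)),
            all(fields %in% names(records)))
  xkm <- along_track_km(records$lat, records$lon)
  # cell centres at spacing multiples, origin at the first record
  xg <- seq(0, max(xkm), by = spacing[1])
  zg <- seq(0, max(records$depth_m), by = spacing[2])
  out <- lapply(fields, function(f) {
    barnes_grid(xkm, records$depth_m, records[[f]], xg, zg, ...)
  })
  names(out) <- fields
  gridded_transect(xg, zg, out)
}

#' Along-track distance from latitude/longitude
#'
#' Great-circle (haversine) distance accumulated along the track, km,
#' starting at 0 at the first record.
#'
#' @param lat,lon Coordinates in degrees.
#' @return Numeric vector of cumulative distance, km.
#' @export
along_track_km <- function(lat, lon) {
  n <- length(lat)
  if (n < 2) return(rep(0, n))
  rad <- pi / 180
  la <- lat * rad; lo <- lon * rad
  dla <- diff(la); dlo <- diff(lo)
  h <- sin(dla / 2)^2 + cos(la[-n]) * cos(la[-1]) * sin(dlo / 2)^2
  d <- 2 * 6371 * asin(pmin(1, sqrt(h)))
  c(0, cumsum(d))
}

#' Add bio-optical IOP fields to a gridded transect
#'
#' Applies the forward bio-optical model cell-by-cell to the \code{chl} and
#' \code{salinity} fields of a gridded transect, adding one raster per
#' requested wavelength and IOP kind (\code{a_nw_<wl>}, \code{a_<wl>},
#' \code{b_<wl>}, \code{bb_<wl>}). Missing cells propagate as \code{NA};
#' backscattering at 412 nm is not produced (excluded channel).
#'
#' @param transect A [gridded_transect()] with \code{chl} and
#'   \code{salinity} fields.
#' @param wavelengths Wavelengths, nm. Default the nine model wavelengths.
#' @param temperature Deg C for the water baseline. Default 10.
#' @param coef Model coefficients.
#' @return The transect with IOP fields added.
#' @export
transect_iops <- function(transect,
                          wavelengths = c(412, 440, 488, 510, 532, 555,
                                          650, 676, 715),
                          temperature = 10, coef = model_coefficients()) {
  stopifnot(inherits(transect, "gridded_transect"),
            all(c("chl", "salinity") %in% names(transect$fields)))
  chl <- transect$fields$chl
  sal <- transect$fields$salinity
  ok <- is.finite(chl) & is.finite(sal)
  dims <- dim(chl)
  blank <- matrix(NA_real_, dims[1], dims[2])
  cv <- chl[ok]; sv <- sal[ok]
  if (!any(ok)) {
    for (wl in wavelengths) {
      for (k in c("a_nw_", "a_", "b_", if (wl != 412) "bb_")) {
        transect$fields[[paste0(k, wl)]] <- blank
      }
    }
    return(transect)
  }
  for (wl in wavelengths) {
    w <- water_iops(wl, sv, temperature)
    a_nw <- acdom(wl, sv, coef = coef) + aph(wl, cv, coef) +
      anap(wl, cv, coef)
    a_tot <- blank; b_tot <- blank; bb_tot <- blank; anw <- blank
    anw[ok] <- a_nw
    a_tot[ok] <- a_nw + w$a_w
    b_tot[ok] <- bp(wl, cv, coef) + w$b_w
    if (wl != 412) bb_tot[ok] <- bbp(wl, cv, coef) + w$bb_w
    transect$fields[[paste0("a_nw_", wl)]] <- anw
    transect$fields[[paste0("a_", wl)]] <- a_tot
    transect$fields[[paste0("b_", wl)]] <- b_tot
    if (wl != 412) transect$fields[[paste0("bb_", wl)]] <- bb_tot
  }
  transect
}
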