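#' Remote-sensing reflectance from absorption and backscattering
#'
#' Simplified semi-analytical reflectance model
#' \deqn{R_{rs} = \frac{f}{Q}\,\frac{b_b}{a}\,\frac{1 - r_F}{\eta_w^2},}
#' with the bidirectional factor \eqn{f/Q = 0.0922}, the water-side Fresnel
#' reflectance of the surface \eqn{r_F = 0.021} and the refractive index of
#' water \eqn{\eta_w = 1.34}. Raman scattering and BRDF effects are
#' deliberately not included.
#'
#' @param a Total absorption, m\eqn{^{-1}}, strictly positive.
#' @param bb Total backscattering, m\eqn{^{-1}}, non-negative.
#' @param coef Model coefficients.
#' @return Remote-sensing reflectance, sr\eqn{^{-1}}.
#' @examples
#' rrs_from_iops(a = 0.05, bb = 0.002)
#' @export
rrs_from_iops <- function(a, bb, coef = model_coefficients()) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("a must be strictly positive", call. = FALSE)
  }
  if (any(bb < 0, na.rm = TRUE)) {
    stop("bb must be non-negative", call. = FALSE)
  }
  coef$fq_ratio * (bb / a) * (1 - coef$fresnel_r) / coef$n_water^2
}

#' Surface average of a gridded field
#'
#' Per-column arithmetic mean of cells whose centre depth does not exceed
#' \code{depth_limit}. The reflectance comparison uses the mean within 2 m
#' of the surface; on the native 5 m grid (centres at 0, 5, 10, ... m) this
#' selects the single surface row. If no cell centre lies within the limit
#' (a grid whose shallowest centre is deeper), the shallowest available row
#' is used instead -- the closest gridded analogue of the 2 m criterion.
#' Columns with no finite cell are \code{NA}.
#'
#' @param transect A [gridded_transect()].
#' @param field Field name.
#' @param depth_limit Depth limit, m. Default 2.
#' @return Numeric vector, one value per along-track column.
#' @export
surface_average <- function(transect, field, depth_limit = 2) {
  stopifnot(inherits(transect, "gridded_transect"))
  if (!field %in% names(transect$fields)) {
    stop("unknown field: ", field, call. = FALSE)
  }
  F <- transect$fields[[field]]
  sel <- transect$depth <= depth_limit
  if (!any(sel)) sel <- seq_along(transect$depth) == 1L
  sub <- F[, sel, drop = FALSE]
  out <- rowMeans(sub, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Glider remote-sensing reflectance spectra
#'
#' One reflectance spectrum per along-track column, computed from the
#' surface-averaged total absorption and backscattering IOP fields of the
#' transect (see [surface_average()] and [rrs_from_iops()]).
#'
#' @param transect A [gridded_transect()] carrying \code{a_<wl>} and
#'   \code{bb_<wl>} fields (see [transect_iops()]).
#' @param wavelengths Wavelengths, nm; 412 is skipped automatically (no
#'   backscattering channel). Default the eight reflectance wavelengths.
#' @param coef Model coefficients.
#' @return data.frame in long format: \code{column} (index),
#'   \code{along_track_km}, \code{wavelength}, \code{rrs}; columns with
#'   missing surface IOPs are dropped.
#' @export
glider_rrs <- function(transect,
                       wavelengths = c(440, 488, 510, 532, 555, 650, 676,
                                       715),
                       coef = model_coefficients()) {
  wavelengths <- setdiff(wavelengths, 412)
  out <- list()
  for (wl in wavelengths) {
    af <- paste0("a_", wl); bbf <- paste0("bb_", wl)
    if (!all(c(af, bbf) %in% names(transect$fields))) {
      stop("transect lacks IOP fields for ", wl,
           " nm; run transect_iops() first", call. = FALSE)
    }
    a_s <- surface_average(transect, af)
    bb_s <- surface_average(transect, bbf)
    ok <- is.finite(a_s) & is.finite(bb_s)
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      column = which(ok),
      along_track_km = transect$along_track[ok],
      wavelength = wl,
      rrs = rrs_from_iops(a_s[ok], bb_s[ok], coef))
  }
  do.call(rbind, out)
}

#' Match glider bands to nearest satellite bands
#'
#' Pairs each glider waveband with the closest satellite waveband, with no
#' spectral interpolation; pairs farther apart than \code{tolerance} are
#' dropped.
#'
#' @param glider_wavelengths,satellite_wavelengths Band centres, nm.
#' @param tolerance Maximum band separation, nm. Default 10.
#' @return data.frame with \code{glider_nm}, \code{satellite_nm},
#'   \code{separation_nm}.
#' @examples
#' band_match(c(440, 555, 715), c(412, 443, 488, 531, 547, 667))
#' @export
band_match <- function(glider_wavelengths, satellite_wavelengths,
                       tolerance = 10) {
  stopifnot(length(glider_wavelengths) > 0,
            length(satellite_wavelengths) > 0)
  idx <- vapply(glider_wavelengths, function(w) {
    which.min(abs(satellite_wavelengths - w))
  }, integer(1))
  sep <- abs(glider_wavelengths - satellite_wavelengths[idx])
  keep <- sep <= tolerance
  data.frame(glider_nm = glider_wavelengths[keep],
             satellite_nm = satellite_wavelengths[idx[keep]],
             separation_nm = sep[keep])
}

#' Statistical comparison of two reflectance ensembles
#'
#' Distributional comparison of glider-modelled and satellite reflectance
#' spectra at their closest matching wavebands: per band, ensemble means,
#' standard deviations, 95\% confidence intervals of the mean and boxplot
#' outlier counts (beyond 1.5 IQR from the quartiles); plus a scalar
#' mean-error metric,
#' \deqn{\mathrm{ME} = \frac{100}{N}\sum_{\mathrm{bands}}
#'   \frac{|\bar{R}_{glider} - \bar{R}_{sat}|}{\bar{R}_{sat}},}
#' the band-averaged relative difference of ensemble means in percent.
#'
#' @param glider,satellite Long-format data.frames with columns
#'   \code{wavelength} and \code{rrs}, one row per spectrum sample per band.
#' @param tolerance Band-matching tolerance, nm. Default 10.
#' @return Object of class \code{rrs_comparison}: list with \code{bands}
#'   (per-band statistics data.frame) and \code{mean_error} (percent).
#' @export
compare_ensembles <- function(glider, satellite, tolerance = 10) {
  stopifnot(all(c("wavelength", "rrs") %in% names(glider)),
            all(c("wavelength", "rrs") %in% names(satellite)))
  gw <- sort(unique(glider$wavelength))
  sw <- sort(unique(satellite$wavelength))
  pairs <- band_match(gw, sw, tolerance)
  if (nrow(pairs) == 0) stop("no matched wavebands", call. = FALSE)
  stat1 <- function(x) {
    n <- length(x)
    m <- mean(x); s <- stats::sd(x)
    ci <- if (n > 1) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    out <- sum(x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
    c(mean = m, sd = s, ci_lo = m - ci, ci_hi = m + ci, n = n,
      outliers = out)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    g <- glider$rrs[glider$wavelength == pairs$glider_nm[k]]
    s <- satellite$rrs[satellite$wavelength == pairs$satellite_nm[k]]
    gs <- stat1(g); ss <- stat1(s)
    data.frame(glider_nm = pairs$glider_nm[k],
               satellite_nm = pairs$satellite_nm[k],
               glider_mean = gs["mean"], glider_sd = gs["sd"],
               glider_ci_lo = gs["ci_lo"], glider_ci_hi = gs["ci_hi"],
               glider_outliers = gs["outliers"], glider_n = gs["n"],
               satellite_mean = ss["mean"], satellite_sd = ss["sd"],
               satellite_ci_lo = ss["ci_lo"], satellite_ci_hi = ss["ci_hi"],
               satellite_outliers = ss["outliers"], satellite_n = ss["n"],
               rel_error_pct = 100 * abs(gs["mean"] - ss["mean"]) /
                 ss["mean"],
               row.names = NULL)
  })
  bands <- do.call(rbind, rows)
  n_g <- min(bands$glider_n); n_s <- min(bands$satellite_n)
  if (n_g < 2 || n_s < 2) {
    stop("need at least 2 spectra per ensemble", call. = FALSE)
  }
  structure(list(bands = bands, mean_error = mean(bands$rel_error_pct)),
            class = "rrs_comparison")
}

#' @export
print.rrs_comparison <- function(x, ...) {
  cat("Rrs ensemble comparison over", nrow(x$bands), "matched bands\n")
  print(x$bands[, c("glider_nm", "satellite_nm", "glider_mean",
                    "satellite_mean", "rel_error_pct")], row.names = FALSE)
  cat(sprintf("mean error across bands: %.1f%%\n", x$mean_error))
  invisible(x)
}
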