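# Cached pure-water absorption table, loaded once per session.
.water_env <- new.env(parent = emptyenv())

.water_absorption_table <- function() {
  if (is.null(.water_env$a_w)) {
    path <- system.file("extdata", "water_absorption_pope_fry_1997.csv",
                        package = "baroptics", mustWork = TRUE)
    .water_env$a_w <- utils::read.csv(path, comment.char = "#")
  }
  .water_env$a_w
}

#' Pure-water absorption coefficient
#'
#' Absorption by pure water, \eqn{a_w(\lambda)}, from an embedded
#' integrating-cavity literature table (Pope & Fry type, 10 nm resolution),
#' linearly interpolated between tabulated wavelengths. This is the fixed
#' baseline of the total-absorption budget.
#'
#' @param wavelength Wavelength(s) in nm; must lie within 380--750 nm.
#' @return Numeric vector of absorption coefficients in m\eqn{^{-1}}.
#' @examples
#' pure_water_absorption(c(440, 555, 676))
#' @export
pure_water_absorption <- function(wavelength) {
  tab <- .water_absorption_table()
  rng <- range(tab$wavelength_nm)
  if (any(!is.finite(wavelength)) ||
      any(wavelength < rng[1] | wavelength > rng[2])) {
    stop("wavelength must lie within [", rng[1], ", ", rng[2], "] nm",
         call. = FALSE)
  }
  stats::approx(tab$wavelength_nm, tab$a_w_m1, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Pure-seawater scattering and backscattering
#'
#' Spectral scattering by pure seawater following the classical
#' \eqn{\lambda^{-4.32}} molecular-scattering power law with a linear salinity
#' enhancement (sea salt increases density fluctuations, raising scattering by
#' roughly 30\% at oceanic salinity relative to pure water). Backscattering is
#' exactly half of total scattering: the molecular phase function is
#' fore--aft symmetric. Temperature is accepted for interface symmetry with
#' the CTD record but has a negligible published effect on \eqn{b_w} over
#' polar ocean temperatures and is not applied.
#'
#' @param wavelength Wavelength(s) in nm within 380--750 nm.
#' @param salinity Practical salinity (PSU), in \[0, 40\]. Default 35.
#' @param temperature Temperature in deg C (unused; see Details). Default 10.
#' @return A data.frame with columns \code{wavelength}, \code{b_w} and
#'   \code{bb_w} (m\eqn{^{-1}}).
#' @examples
#' pure_seawater_scattering(c(440, 550), salinity = 35)
#' @export
pure_seawater_scattering <- function(wavelength, salinity = 35,
                                     temperature = 10) {
  if (any(!is.finite(wavelength)) ||
      any(wavelength < 380 | wavelength > 750)) {
    stop("wavelength must lie within [380, 750] nm", call. = FALSE)
  }
  if (any(salinity < 0 | salinity > 40)) {
    stop("salinity must lie within [0, 40] PSU", call. = FALSE)
  }
  # Pure water b_w(500) = 0.00222 m^-1, slope -4.32 (Morel-type); salinity
  # enhancement factor 0.30 at S = 37 applied linearly in S.
  b_pure <- 0.00222 * (500 / wavelength)^4.32
  b_w <- b_pure * (1 + 0.30 * salinity / 37)
  data.frame(wavelength = wavelength, b_w = b_w, bb_w = b_w / 2)
}

#' Bundle of pure-seawater inherent optical properties
#'
#' Convenience wrapper returning absorption, scattering and backscattering of
#' (sea)water on one wavelength grid.
#'
#' @inheritParams pure_seawater_scattering
#' @return data.frame with columns \code{wavelength}, \code{a_w},
#'   \code{b_w}, \code{bb_w}.
#' @export
water_iops <- function(wavelength, salinity = 35, temperature = 10) {
  sc <- pure_seawater_scattering(wavelength, salinity, temperature)
  data.frame(wavelength = wavelength,
             a_w = pure_water_absorption(wavelength),
             b_w = sc$b_w, bb_w = sc$bb_w)
}
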