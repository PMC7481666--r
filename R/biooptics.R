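#' Bio-optical model coefficients
#'
#' Assembles every constant of the Barents Sea bio-optical model into one
#' object: the power-law tables linking particulate scattering and
#' backscattering to chlorophyll, the chlorophyll-specific phytoplankton
#' absorption coefficients, the non-algal particle (NAP) and CDOM absorption
#' parameters, the reflectance-model constants, the hybrid-estimator
#' switching threshold and the salinity validity window of the CDOM model.
#'
#' @details
#' Tables are shipped as plain-text CSV under \code{inst/extdata} with
#' provenance headers. The backscattering table has no 412 nm row: that
#' channel was excluded from the source observations for data-quality
#' reasons, and requesting 412 nm from [bbp()] is an error rather than an
#' extrapolation.
#'
#' @return An object of class \code{bio_model_coefficients}: a list with
#'   elements \code{aph_table}, \code{bp_table}, \code{bbp_table} (data
#'   frames), \code{nap_ref_coeff} (0.0124 m\eqn{^{-1}}), \code{nap_exp}
#'   (0.724), \code{nap_slope} (0.011 nm\eqn{^{-1}}), \code{cdom_sal_slope}
#'   (\eqn{-0.012} m\eqn{^{-1}} PSU\eqn{^{-1}}), \code{cdom_sal_intercept}
#'   (0.464 m\eqn{^{-1}}), \code{cdom_spectral_slope} (0.0168
#'   nm\eqn{^{-1}}), \code{fq_ratio} (0.0922), \code{fresnel_r} (0.021),
#'   \code{n_water} (1.34), \code{chl_switch} (2 mg m\eqn{^{-3}}),
#'   \code{sal_valid} (\[27, 35\] PSU) and \code{cdom_fallback} (0.04
#'   m\eqn{^{-1}}).
#' @examples
#' cf <- model_coefficients()
#' cf$bp_table
#' @export
model_coefficients <- function() {
  if (!is.null(.water_env$coefs)) return(.water_env$coefs)
  ext <- function(f) utils::read.csv(
    system.file("extdata", f, package = "baroptics", mustWork = TRUE),
    comment.char = "#")
  cf <- structure(list(
    aph_table = ext("aph_coefficients_synthetic.csv"),
    bp_table = ext("scattering_coefficients.csv"),
    bbp_table = ext("backscattering_coefficients.csv"),
    nap_ref_coeff = 0.0124,
    nap_exp = 0.724,
    nap_slope = 0.011,
    cdom_sal_slope = -0.012,
    cdom_sal_intercept = 0.464,
    cdom_spectral_slope = 0.0168,
    fq_ratio = 0.0922,
    fresnel_r = 0.021,
    n_water = 1.34,
    chl_switch = 2,
    sal_valid = c(27, 35),
    cdom_fallback = 0.04
  ), class = "bio_model_coefficients")
  .water_env$coefs <- cf
  cf
}

#' @export
print.bio_model_coefficients <- function(x, ...) {
  cat("Barents Sea bio-optical model coefficients\n")
  cat("  b_p  power-law table:", nrow(x$bp_table), "wavelengths (",
      min(x$bp_table$wavelength_nm), "-", max(x$bp_table$wavelength_nm),
      "nm )\n")
  cat("  b_bp power-law table:", nrow(x$bbp_table),
      "wavelengths (412 nm excluded)\n")
  cat("  a_NAP(440) = ", x$nap_ref_coeff, " Chl^", x$nap_exp,
      ", slope ", -x$nap_slope, " nm^-1\n", sep = "")
  cat("  a_CDOM(440) = ", x$cdom_sal_slope, " Sal + ",
      x$cdom_sal_intercept, " (valid Sal ", x$sal_valid[1], "-",
      x$sal_valid[2], "), slope ", -x$cdom_spectral_slope, " nm^-1\n",
      sep = "")
  cat("  Rrs: f/Q = ", x$fq_ratio, ", r_F = ", x$fresnel_r,
      ", n_w = ", x$n_water, "\n", sep = "")
  cat("  hybrid Chl switch at", x$chl_switch, "mg m^-3\n")
  invisible(x)
}

# Linear interpolation of a coefficient table column at `wavelength`; no
# extrapolation outside the tabulated span.
.coef_at <- function(table, column, wavelength, what) {
  rng <- range(table$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2])) {
    stop(what, ": wavelength must lie within [", rng[1], ", ", rng[2],
         "] nm", call. = FALSE)
  }
  stats::approx(table$wavelength_nm, table[[column]], xout = wavelength,
                method = "linear", ties = "ordered")$y
}

.check_chl <- function(chl) {
  if (any(!is.finite(chl)) || any(chl < 0)) {
    stop("chl must be non-negative and finite", call. = FALSE)
  }
}

#' Phytoplankton absorption
#'
#' Chlorophyll-driven phytoplankton absorption
#' \eqn{a_{ph}(\lambda, Chl) = A_{ph}(\lambda)\, Chl^{1 + B_{ph}(\lambda)}},
#' with the coefficient pair interpolated linearly between tabulated
#' wavelengths. The exponent is below one (\eqn{B_{ph}} < 0): pigment
#' packaging flattens the absorption-to-biomass relationship at high
#' chlorophyll.
#'
#' @param wavelength Wavelength(s), nm, within the coefficient table span.
#' @param chl Chlorophyll a concentration, mg m\eqn{^{-3}}, non-negative.
#' @param coef Model coefficients, see [model_coefficients()].
#' @return Absorption coefficient(s), m\eqn{^{-1}}.
#' @examples
#' aph(440, chl = 1)
#' @export
aph <- function(wavelength, chl, coef = model_coefficients()) {
  .check_chl(chl)
  A <- .coef_at(coef$aph_table, "A_ph", wavelength, "aph")
  B <- .coef_at(coef$aph_table, "B_ph", wavelength, "aph")
  A * chl^(1 + B)  # exponent in (0, 1), so chl = 0 gives 0 exactly
}

#' Non-algal particle absorption
#'
#' NAP absorption anchored at 440 nm by the power law
#' \eqn{a_{NAP}(440) = 0.0124\, Chl^{0.724}} and extended spectrally with an
#' exponential slope of \eqn{-0.011} nm\eqn{^{-1}}.
#'
#' @inheritParams aph
#' @return Absorption coefficient(s), m\eqn{^{-1}}.
#' @examples
#' anap(440, chl = 1)  # 0.0124 exactly
#' @export
anap <- function(wavelength, chl, coef = model_coefficients()) {
  .check_chl(chl)
  a440 <- coef$nap_ref_coeff * chl^coef$nap_exp
  a440 * exp(-coef$nap_slope * (wavelength - 440))
}

#' CDOM absorption from salinity
#'
#' Coloured dissolved organic matter absorption, driven by salinity on the
#' assumption that freshwater inflow is the dominant CDOM source:
#' \eqn{a_{CDOM}(440) = -0.012\, Sal + 0.464} (m\eqn{^{-1}}), extended
#' spectrally with slope \eqn{-0.0168} nm\eqn{^{-1}}.
#'
#' The linear salinity relationship is only supported by observations for
#' salinity in \[27, 35\] PSU. Outside that window the operational mode
#' substitutes the constant fallback \eqn{a_{CDOM}(440) = 0.04}
#' m\eqn{^{-1}} with a warning. \code{raw = TRUE} disables the override and
#' evaluates the regression as written (clamping any negative result to zero
#' with a warning), which is the mode used to verify the printed intercept.
#'
#' @param wavelength Wavelength(s), nm.
#' @param salinity Practical salinity, PSU, non-negative.
#' @param raw Logical; evaluate the raw regression outside its validity
#'   window instead of applying the fallback constant. Default \code{FALSE}.
#' @param coef Model coefficients, see [model_coefficients()].
#' @return Absorption coefficient(s), m\eqn{^{-1}}.
#' @examples
#' acdom(440, salinity = 34)
#' acdom(440, salinity = 0, raw = TRUE)  # regression intercept, 0.464
#' @export
acdom <- function(wavelength, salinity, raw = FALSE,
                  coef = model_coefficients()) {
  if (any(!is.finite(salinity)) || any(salinity < 0)) {
    stop("salinity must be non-negative and finite", call. = FALSE)
  }
  a440 <- coef$cdom_sal_slope * salinity + coef$cdom_sal_intercept
  if (raw) {
    if (any(a440 < 0)) {
      warning("raw CDOM regression negative at high salinity; clamped to 0",
              call. = FALSE)
      a440 <- pmax(a440, 0)
    }
  } else {
    out <- salinity < coef$sal_valid[1] | salinity > coef$sal_valid[2]
    if (any(out)) {
      warning("salinity outside [", coef$sal_valid[1], ", ",
              coef$sal_valid[2], "] PSU: using constant a_CDOM(440) = ",
              coef$cdom_fallback, " m^-1 for ", sum(out), " value(s)",
              call. = FALSE)
      a440[out] <- coef$cdom_fallback
    }
  }
  a440 * exp(-coef$cdom_spectral_slope * (wavelength - 440))
}

#' Particulate scattering from chlorophyll
#'
#' Power-law particulate scattering
#' \eqn{b_p(\lambda, Chl) = A_b(\lambda)\, Chl^{B_b(\lambda)}} with
#' coefficients fitted at nine wavelengths between 412 and 715 nm and
#' interpolated linearly in between.
#'
#' @inheritParams aph
#' @return Scattering coefficient(s), m\eqn{^{-1}}.
#' @examples
#' bp(555, chl = 1)  # table coefficient A_b(555) = 0.219
#' @export
bp <- function(wavelength, chl, coef = model_coefficients()) {
  .check_chl(chl)
  A <- .coef_at(coef$bp_table, "A_b", wavelength, "bp")
  B <- .coef_at(coef$bp_table, "B_b", wavelength, "bp")
  A * chl^B  # B > 0, so chl = 0 gives 0 exactly
}

#' Particulate backscattering from chlorophyll
#'
#' Power-law particulate backscattering
#' \eqn{b_{bp}(\lambda, Chl) = A_{bb}(\lambda)\, Chl^{B_{bb}(\lambda)}}.
#' The table covers 440--715 nm, including the 700 nm glider-triplet channel
#' (an extrapolated/interpolated row). 412 nm is deliberately not available:
#' that backscattering channel was excluded from the source data, and the
#' function refuses it rather than extrapolate.
#'
#' @inheritParams aph
#' @return Backscattering coefficient(s), m\eqn{^{-1}}.
#' @examples
#' bbp(700, chl = 5)
#' @export
bbp <- function(wavelength, chl, coef = model_coefficients()) {
  .check_chl(chl)
  if (any(wavelength == 412)) {
    stop("bbp: the 412 nm backscattering channel is excluded from the model",
         call. = FALSE)
  }
  A <- .coef_at(coef$bbp_table, "A_bb", wavelength, "bbp")
  B <- .coef_at(coef$bbp_table, "B_bb", wavelength, "bbp")
  A * chl^B  # B > 0, so chl = 0 gives 0 exactly
}

#' Bulk spectral inherent optical properties
#'
#' Assembles total absorption, scattering and backscattering as the sum of
#' their partial components:
#' \deqn{a = a_w + a_{CDOM} + a_{ph} + a_{NAP}, \quad
#'       b = b_w + b_p, \quad b_b = b_{bw} + b_{bp}.}
#' All component spectra are retained so the additivity of the bundle can be
#' checked and non-water absorption (\code{a_nw = a - a_w}) read off
#' directly.
#'
#' @param wavelengths Wavelength grid, nm, strictly ascending.
#' @param chl Chlorophyll a, mg m\eqn{^{-3}} (scalar).
#' @param salinity Practical salinity, PSU (scalar).
#' @param temperature Temperature, deg C (passed to the seawater-scattering
#'   baseline). Default 10.
#' @param raw_cdom Logical, passed to [acdom()].
#' @param coef Model coefficients.
#' @return An object of class \code{iop_bundle}: list with data.frame
#'   \code{spectra} (columns \code{wavelength}, \code{a_total},
#'   \code{b_total}, \code{bb_total}, \code{a_nw} and one column per
#'   component) plus the scalar inputs as attributes.
#' @examples
#' iops <- total_iops(c(440, 555, 676), chl = 1, salinity = 34)
#' iops$spectra
#' @export
total_iops <- function(wavelengths, chl, salinity, temperature = 10,
                       raw_cdom = FALSE, coef = model_coefficients()) {
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly ascending", call. = FALSE)
  }
  w <- water_iops(wavelengths, salinity, temperature)
  a_cdom <- acdom(wavelengths, salinity, raw = raw_cdom, coef = coef)
  a_ph <- aph(wavelengths, chl, coef)
  a_nap <- anap(wavelengths, chl, coef)
  b_p <- bp(wavelengths, chl, coef)
  # 412 nm has no backscattering row; represent it as NA rather than error
  # so a full nine-wavelength absorption/scattering bundle stays usable.
  bb_p <- rep(NA_real_, length(wavelengths))
  ok <- wavelengths != 412
  if (any(ok)) bb_p[ok] <- bbp(wavelengths[ok], chl, coef)
  spectra <- data.frame(
    wavelength = wavelengths,
    a_w = w$a_w, a_cdom = a_cdom, a_ph = a_ph, a_nap = a_nap,
    b_w = w$b_w, b_p = b_p,
    bb_w = w$bb_w, bb_p = bb_p)
  spectra$a_total <- spectra$a_w + spectra$a_cdom + spectra$a_ph +
    spectra$a_nap
  spectra$b_total <- spectra$b_w + spectra$b_p
  spectra$bb_total <- spectra$bb_w + spectra$bb_p
  spectra$a_nw <- spectra$a_total - spectra$a_w
  structure(list(spectra = spectra),
            chl = chl, salinity = salinity, temperature = temperature,
            class = "iop_bundle")
}

#' @export
print.iop_bundle <- function(x, ...) {
  cat("Bulk IOP bundle (Chl = ", attr(x, "chl"), " mg m^-3, Sal = ",
      attr(x, "salinity"), " PSU)\n", sep = "")
  print(x$spectra[, c("wavelength", "a_total", "b_total", "bb_total",
                      "a_nw")], row.names = FALSE)
  invisible(x)
}
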