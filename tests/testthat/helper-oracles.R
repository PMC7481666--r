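# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (scalar loops, no shared code with the package) so that
# agreement with the package is evidence, not tautology.

# Barnes successive-correction analysis by direct weighted sums.
barnes_oracle <- function(x, z, v, xg, zg, radii, passes = 2, gamma = 0.3,
                          cutoff = 3) {
  nx <- length(xg); nz <- length(zg)
  interp_at <- function(F, xo, zo) {
    # nearest-cell-clamped bilinear interpolation, scalar
    xo <- min(max(xo, xg[1]), xg[nx]); zo <- min(max(zo, zg[1]), zg[nz])
    i <- max(which(xg <= xo)); i <- min(i, nx - 1)
    j <- max(which(zg <= zo)); j <- min(j, nz - 1)
    tx <- (xo - xg[i]) / (xg[i + 1] - xg[i])
    tz <- (zo - zg[j]) / (zg[j + 1] - zg[j])
    F[i, j] * (1 - tx) * (1 - tz) + F[i + 1, j] * tx * (1 - tz) +
      F[i, j + 1] * (1 - tx) * tz + F[i + 1, j + 1] * tx * tz
  }
  analysis <- matrix(0, nx, nz)
  reach <- matrix(FALSE, nx, nz)
  resid <- v
  for (p in seq_len(passes)) {
    rx <- radii[1] * gamma^(p - 1); rz <- radii[2] * gamma^(p - 1)
    for (i in seq_len(nx)) for (j in seq_len(nz)) {
      sw <- 0; swv <- 0; rmin <- Inf
      for (k in seq_along(x)) {
        r2 <- ((xg[i] - x[k]) / rx)^2 + ((zg[j] - z[k]) / rz)^2
        if (r2 < rmin) rmin <- r2
        w <- exp(-r2)
        sw <- sw + w; swv <- swv + w * resid[k]
      }
      if (p == 1 && rmin <= cutoff^2) reach[i, j] <- TRUE
      if (reach[i, j] && sw > 0) {
        analysis[i, j] <- analysis[i, j] + swv / sw
      }
    }
    if (p < passes) {
      resid <- vapply(seq_along(x), function(k) {
        v[k] - interp_at(analysis, x[k], z[k])
      }, numeric(1))
    }
  }
  analysis[!reach] <- NA_real_
  analysis
}

# Log-log least squares (closed form), independent of stats::lm.
loglog_fit <- function(chl, y) {
  lx <- log(chl); ly <- log(y)
  b <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  a <- exp(mean(ly) - b * mean(lx))
  c(A = a, B = b)
}

# Small deployment used by several pipeline tests (fast: ~2400 records).
small_deployment <- function(...) {
  sc <- front_scenario(...)
  synth_glider_deployment(sc, n_profiles = 60, samples_per_profile = 40,
                          dive_depth = 120)
}
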