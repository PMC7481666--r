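#' Polar-front scenario for the synthetic-data generator
#'
#' Describes the stated world the generator emulates: a south-to-north
#' transect along 30 deg E crossing the polar front near 75.8 deg N, with
#' warm, saline Atlantic-derived water to the south, colder and fresher
#' Arctic-derived water to the north, and a surface-intensified spring bloom
#' (elevated chlorophyll and particulate backscattering) on the Arctic side.
#'
#' @param front_lat Front latitude, deg N. Default 75.8.
#' @param front_width Logistic half-width of the transition, degrees
#'   latitude. Default 0.15 (a few tens of km, a sharp shelf front).
#' @param south_ts,north_ts \code{c(temperature deg C, salinity PSU)} of the
#'   Atlantic and Arctic end members. Defaults \code{c(5, 35)} and
#'   \code{c(0.5, 34.4)}.
#' @param chl_background Deep/background chlorophyll, mg m\eqn{^{-3}}.
#'   Default 0.3.
#' @param chl_bloom_peak Surface bloom chlorophyll north of the front, mg
#'   m\eqn{^{-3}}. Default 8.
#' @param bloom_depth_scale e-folding depth of the bloom, m. Default 50.
#' @param noise Relative (lognormal) noise per optical sensor. Default 0.03.
#' @param spike_rate Probability of a spike per sample. Default 0.01.
#' @param quench_factor Multiplicative suppression of surface fluorescence
#'   during "day" records (1 = no quenching). Default 1.
#' @param quench_depth Depth above which quenching acts, m. Default 20.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return Object of class \code{front_scenario}.
#' @export
front_scenario <- function(front_lat = 75.8, front_width = 0.15,
                           south_ts = c(5, 35), north_ts = c(0.5, 34.4),
                           chl_background = 0.3, chl_bloom_peak = 8,
                           bloom_depth_scale = 50, noise = 0.03,
                           spike_rate = 0.01, quench_factor = 1,
                           quench_depth = 20, seed = 1L) {
  stopifnot(north_ts[1] < south_ts[1], north_ts[2] < south_ts[2],
            chl_bloom_peak > chl_background,
            spike_rate >= 0, spike_rate <= 1,
            noise >= 0, quench_factor > 0, quench_factor <= 1)
  structure(list(front_lat = front_lat, front_width = front_width,
                 south_ts = south_ts, north_ts = north_ts,
                 chl_background = chl_background,
                 chl_bloom_peak = chl_bloom_peak,
                 bloom_depth_scale = bloom_depth_scale, noise = noise,
                 spike_rate = spike_rate, quench_factor = quench_factor,
                 quench_depth = quench_depth, seed = as.integer(seed)),
            class = "front_scenario")
}

#' Continuous truth fields for a front scenario
#'
#' Deterministic, smooth fields: temperature and salinity follow a logistic
#' transition across the front latitude; chlorophyll rises to the bloom peak
#' north of the front and decays exponentially with depth over the bloom
#' depth scale toward the background value.
#'
#' @param scenario A [front_scenario()].
#' @return List of functions \code{temperature(lat, depth)},
#'   \code{salinity(lat, depth)}, \code{chl(lat, depth)}.
#' @export
synth_truth_fields <- function(scenario) {
  s <- scenario
  frac_north <- function(lat) stats::plogis((lat - s$front_lat) /
                                              s$front_width)
  list(
    temperature = function(lat, depth) {
      s$south_ts[1] + (s$north_ts[1] - s$south_ts[1]) * frac_north(lat)
    },
    salinity = function(lat, depth) {
      s$south_ts[2] + (s$north_ts[2] - s$south_ts[2]) * frac_north(lat)
    },
    chl = function(lat, depth) {
      bloom <- (s$chl_bloom_peak - s$chl_background) * frac_north(lat)
      s$chl_background + bloom * exp(-depth / s$bloom_depth_scale)
    }
  )
}

# Run `expr` under the scenario seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthesize a glider deployment across the front
#'
#' Samples the scenario truth fields along a sawtooth dive/climb track from
#' \code{lat_start} to \code{lat_end} along a meridian, emulating the
#' optical triplet payload: \code{chl_fl_mg_m3} is truth chlorophyll times a
#' daytime surface quenching factor times multiplicative lognormal noise;
#' \code{bbp700_m1} is the forward backscattering model at 700 nm applied to
#' truth chlorophyll, times noise; spikes are injected at
#' \code{spike_rate} as positive excursions of 10--100 local MAD. "Day" is
#' alternating 12 h blocks of the record clock. Output is byte-identical for
#' a given scenario (all randomness flows from \code{scenario$seed}).
#'
#' @param scenario A [front_scenario()].
#' @param lat_start,lat_end Track end latitudes, deg N. Defaults 75.2, 76.4.
#' @param lon Meridian, deg E. Default 30.
#' @param dive_depth Maximum depth of the sawtooth, m. Default 180.
#' @param samples_per_profile Samples in one dive or climb. Default 60.
#' @param n_profiles Number of profiles (dives + climbs). Default 240.
#' @param sample_interval_s Seconds between samples. Default 30.
#' @return List with \code{records} (glider data.frame in the standard
#'   column schema), \code{truth} (data.frame of noise-free truth values per
#'   record) and \code{spike_mask} (logical data.frame, columns
#'   \code{chl_fl_mg_m3}, \code{bbp700_m1}).
#' @export
synth_glider_deployment <- function(scenario, lat_start = 75.2,
                                    lat_end = 76.4, lon = 30,
                                    dive_depth = 180,
                                    samples_per_profile = 60,
                                    n_profiles = 240,
                                    sample_interval_s = 30) {
  fields <- synth_truth_fields(scenario)
  n <- n_profiles * samples_per_profile
  # sawtooth depth: dive then climb, linear in sample index
  one <- seq(0, dive_depth, length.out = samples_per_profile)
  depth <- rep(c(one, rev(one)), length.out = n)
  lat <- seq(lat_start, lat_end, length.out = n)
  time <- as.POSIXct("2018-04-27 00:00:00", tz = "UTC") +
    (seq_len(n) - 1) * sample_interval_s
  day <- ((as.numeric(time) %/% 43200) %% 2) == 0
  t_tru <- fields$temperature(lat, depth)
  s_tru <- fields$salinity(lat, depth)
  c_tru <- fields$chl(lat, depth)
  bbp_tru <- bbp(700, c_tru)
  .with_seed(scenario$seed, {
    lognoise <- function(x, rel) {
      if (rel <= 0) x else x * exp(stats::rnorm(length(x), 0, rel))
    }
    quench <- rep(1, n)
    quench[day & depth <= scenario$quench_depth] <- scenario$quench_factor
    chl_fl <- lognoise(c_tru * quench, scenario$noise)
    bbp700 <- lognoise(bbp_tru, scenario$noise)
    cdom_fl <- lognoise(100 * acdom(440, s_tru), scenario$noise)
    spike_mask <- data.frame(
      chl_fl_mg_m3 = stats::runif(n) < scenario$spike_rate,
      bbp700_m1 = stats::runif(n) < scenario$spike_rate)
    inject <- function(x, mask) {
      k <- sum(mask)
      if (k == 0) return(x)
      amp <- stats::runif(k, 10, 100) *
        max(stats::mad(x), 1e-6 * stats::median(abs(x)))
      x[mask] <- x[mask] + amp
      x
    }
    chl_fl <- inject(chl_fl, spike_mask$chl_fl_mg_m3)
    bbp700 <- inject(bbp700, spike_mask$bbp700_m1)
    records <- data.frame(
      time = time, lat = lat, lon = rep(lon, n), depth_m = depth,
      temp_C = t_tru, sal_psu = s_tru, chl_fl_mg_m3 = chl_fl,
      cdom_fl = cdom_fl, bbp700_m1 = bbp700)
    truth <- data.frame(temperature = t_tru, salinity = s_tru,
                        chl = c_tru, bbp700 = bbp_tru, day = day,
                        quench = quench)
    list(records = records, truth = truth, spike_mask = spike_mask)
  })
}

#' Synthesize a satellite reflectance ensemble
#'
#' Draws \code{n} pixel spectra by sampling along-track columns of the
#' glider-modelled reflectance and applying independent multiplicative
#' lognormal noise per band (\code{exp(N(0, noise_rel))}), emulating the
#' spread of an 8-day satellite composite over the study box. With
#' \code{noise_rel = 0} every drawn spectrum equals the forward-model
#' spectrum of its column.
#'
#' @param transect A [gridded_transect()] with IOP fields (see
#'   [transect_iops()]).
#' @param bands Band centres, nm. Default the eight reflectance wavelengths.
#' @param noise_rel Lognormal sigma (log scale). Default 0.15.
#' @param n Number of spectra. Default 200.
#' @param seed Integer seed.
#' @return Long-format data.frame: \code{spectrum} (id), \code{wavelength},
#'   \code{rrs}.
#' @export
synth_satellite_ensemble <- function(transect,
                                     bands = c(440, 488, 510, 532, 555,
                                               650, 676, 715),
                                     noise_rel = 0.15, n = 200,
                                     seed = 1L) {
  base <- glider_rrs(transect, bands)
  cols <- unique(base$column)
  .with_seed(seed, {
    pick <- sample(cols, n, replace = TRUE)
    out <- lapply(seq_len(n), function(i) {
      spec <- base[base$column == pick[i], ]
      noise <- if (noise_rel > 0) {
        exp(stats::rnorm(nrow(spec), 0, noise_rel))
      } else 1
      data.frame(spectrum = i, wavelength = spec$wavelength,
                 rrs = spec$rrs * noise)
    })
    do.call(rbind, out)
  })
}
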