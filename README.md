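# baroptics

Bio-optical forward modelling for the Barents Sea: convert the parameters a
standard glider payload actually measures — salinity from the CTD, and
chlorophyll fluorescence, CDOM fluorescence and particulate backscattering at
700 nm from the optical triplet sensor — into **bulk spectral inherent
optical properties** (absorption *a*, scattering *b*, backscattering *b_b*)
and **remote-sensing reflectance** spectra that can be compared
quantitatively with ocean-colour satellite observations.

The package is aimed at biological oceanographers working with autonomous
platforms (Slocum gliders, bio-Argo floats) in Arctic shelf seas, where
in-situ validation data are scarce, fluorescence quenching corrupts daytime
surface chlorophyll estimates, and persistent cloud forces statistical
rather than pixel-matched satellite comparisons.

## The model

Bulk IOPs are sums of partial IOPs, each driven by one of two "currency"
variables, chlorophyll *a* concentration (Chl, mg m⁻³) and salinity (Sal,
PSU):

    a(λ)   = a_w(λ) + a_CDOM(λ, Sal) + a_ph(λ, Chl) + a_NAP(λ, Chl)
    b(λ)   = b_w(λ) + b_p(λ, Chl)
    b_b(λ) = b_bw(λ) + b_bp(λ, Chl)

with

* `a_ph(λ, Chl) = A_ph(λ) · Chl^(1 + B_ph(λ))` — phytoplankton absorption;
* `a_NAP(λ, Chl) = 0.0124 · Chl^0.724 · exp(−0.011 (λ − 440))` — non-algal
  particles;
* `a_CDOM(λ, Sal) = (−0.012 · Sal + 0.464) · exp(−0.0168 (λ − 440))` —
  coloured dissolved organic matter, valid for Sal ∈ [27, 35] PSU (constant
  fallback 0.04 m⁻¹ outside);
* `b_p(λ, Chl) = A_b(λ) · Chl^B_b(λ)` and
  `b_bp(λ, Chl) = A_bb(λ) · Chl^B_bb(λ)` — particulate scattering and
  backscattering power laws tabulated at nine wavelengths 412–715 nm (the
  412 nm backscattering channel is excluded; a 700 nm row serves the glider
  triplet).

Chlorophyll itself comes from a **hybrid estimator**: fluorescence-derived
Chl up to 2 mg m⁻³ (inclusive), and above that the inversion of the 700 nm
backscattering power law, `Chl = (b_bp(700)/A_bb(700))^(1/B_bb(700))`, which
is immune to surface fluorescence quenching.

Reflectance uses the simplified semi-analytical model

    R_rs = (f/Q) · (b_b / a) · (1 − r_F) / η_w²,   f/Q = 0.0922,
    r_F = 0.021, η_w = 1.34,

applied to surface (within 2 m) averages of the modelled *a* and *b_b*.

Glider sawtooth time series are despiked (rolling median / MAD, a Hampel
filter iterated to a fixed point), split into dive/climb profiles, and
gridded onto a 2 km × 5 m distance–depth raster by Barnes objective
analysis (Gaussian successive correction, 2 passes, γ = 0.3).

## Worked example

```r
library(baroptics)

# forward model at the nine wavelengths
iops <- total_iops(c(412, 440, 488, 510, 532, 555, 650, 676, 715),
                   chl = 2.5, salinity = 34.3)
print(iops)

# synthetic polar-front deployment -> full pipeline -> satellite comparison
sc  <- front_scenario(seed = 42)               # front at 75.8 N, bloom north
dep <- synth_glider_deployment(sc)             # 14400 records, sawtooth
res <- run_pipeline(pipeline_config(), dep$records)
sat <- synth_satellite_ensemble(res$transect, noise_rel = 0.15, n = 200,
                                seed = 43)
compare_ensembles(res$rrs, sat)
```

Output (abridged):

```
Bulk IOP bundle (Chl = 2.5 mg m^-3, Sal = 34.3 PSU)
 wavelength   a_total   b_total    bb_total        a_nw
        440 0.2102549 0.2779725 0.005133681 0.203904877
        555 0.0991958 0.4699053 0.002675239 0.039995800
        676 0.5096697 0.3430802 0.002214663 0.055069691
...
despike: 135 chl_fl spikes, 136 bbp700 spikes masked
profiles: 240
hybrid chl: 2920 of 14400 records from backscatter
grid: 67 x 37 cells, 2479 filled
Rrs ensemble comparison over 8 matched bands
 glider_nm satellite_nm  glider_mean satellite_mean rel_error_pct
       440          440 0.0012471174   0.0012423345     0.3849885
       555          555 0.0013627443   0.0013996571     2.6372712
       715          715 0.0001375277   0.0001415848     2.8654728
mean error across bands: 1.5%
```

Reading this: total absorption at 440 nm for a moderately productive water
column is ≈0.21 m⁻¹, dominated by non-water constituents (`a_nw` ≈ 0.20);
one in five records exceeded the fluorescence threshold and took the
quenching-free backscattering route; the gridded transect is 67 columns ×
37 depth bins; and the glider-modelled reflectance ensemble agrees with the
noisy synthetic "satellite" ensemble to 1.5% in band-averaged mean error.
Glider R_rs at 440 nm of ~1.2 × 10⁻³ sr⁻¹ sits in the range typical of
spring Barents Sea observations.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli","baroptics.R",package="baroptics"))')
Rscript $CLI model --chl 1 --salinity 34 --wavelengths 440,555,676
Rscript $CLI synth --seed 1 --out glider.csv
Rscript $CLI run --glider glider.csv --out-dir out/
```

Subcommands: `model`, `synth`, `grid`, `rrs`, `compare`, `run`.

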