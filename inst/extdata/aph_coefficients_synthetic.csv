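# SYNTHETIC stand-in table: chlorophyll-specific phytoplankton absorption
# power-law coefficients, a_ph(lambda, Chl) = A_ph * Chl^(1 + B_ph).
# The model anchors on the widely cited Bricaud-type relation at 440 nm
# (a_ph(440) = 0.0654 Chl^0.728, i.e. A_ph = 0.0654, B_ph = -0.272); values at
# the other wavelengths reproduce a typical mean chlorophyll-specific
# absorption spectrum (blue peak, green/yellow trough, red peak near 676 nm,
# near-zero beyond 700 nm) because the published 2-nm table is not
# redistributable here. Exponent = 1 + B_ph.
wavelength_nm,A_ph,B_ph
412,0.0530,-0.237
440,0.0654,-0.272
488,0.0472,-0.242
510,0.0300,-0.210
532,0.0188,-0.180
555,0.0117,-0.145
650,0.0122,-0.100
676,0.0233,-0.118
715,0.0005,-0.050
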