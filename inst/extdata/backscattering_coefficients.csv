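# Particulate backscattering model coefficients,
# b_bp(lambda, Chl) = A_bb * Chl^B_bb. The 412 nm BB9 channel is excluded
# (known data-quality and drift issues); the 700 nm row is
# extrapolated/interpolated to the glider triplet wavelength. 95% CI on A_bb
# is multiplicative (a factor), on B_bb additive.
wavelength_nm,A_bb,B_bb,A_bb_ci_factor,B_bb_ci,r2,extrapolated
440,0.002,0.315,1.312,0.121,0.9243,0
488,0.001,0.766,1.555,0.198,0.9656,0
510,0.001,0.589,1.237,0.095,0.9865,0
532,0.001,0.623,1.366,0.140,0.9740,0
555,0.001,0.624,1.290,0.114,0.9827,0
650,0.001,0.568,1.128,0.054,0.9953,0
676,0.001,0.659,1.569,0.202,0.9519,0
700,0.001,0.683,1.313,0.122,0.9835,1
715,0.001,0.703,1.178,0.073,0.9835,0
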