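# Particulate scattering model coefficients, b_p(lambda, Chl) = A_b * Chl^B_b.
# Spring Barents Sea power-law fits at the nine AC-9 wavelengths; 95% CI on
# A_b is multiplicative (a factor), on B_b additive.
wavelength_nm,A_b,B_b,A_b_ci_factor,B_b_ci,r2
412,0.133,0.785,1.768,0.255,0.9457
440,0.126,0.844,2.044,0.320,0.9265
488,0.169,0.849,1.449,0.166,0.9802
510,0.165,0.851,1.451,0.167,0.9801
532,0.203,0.834,1.365,0.139,0.9855
555,0.219,0.829,1.326,0.126,0.9879
650,0.210,0.903,1.507,0.184,0.9786
676,0.152,0.886,2.311,0.375,0.9089
715,0.213,0.925,1.685,0.233,0.9671
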