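# Representative gold Auger electron lines, yield per inner-shell vacancy.
# Synthetic simplification: KLL emission is rare (high K fluorescence yield);
# L- and M-series cascades dominate.
energy_keV,yield
66.0,0.02
7.2,0.35
2.1,0.80
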