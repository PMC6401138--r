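# Gold atomic shell binding energies with fixed relative photoionization
# probabilities (renormalized among energetically allowed shells).
# Synthetic simplification assembled from standard X-ray data compilations.
binding_keV,prob
80.725,0.780
14.353,0.028
13.734,0.042
11.919,0.075
2.743,0.055
0.550,0.020
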