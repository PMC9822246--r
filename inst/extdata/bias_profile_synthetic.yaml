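# SYNTHETIC illustrative inward-turn bias profile.  The experimentally
# measured distance-binned inward-turn probabilities were published only as
# figures, never as numbers, so this file is NOT experimental data: it is a
# plausible stand-in with the qualitative shape of the measurements (chance
# level deep inside the patch, a peak at the patch border bin, elevated bias
# persisting outside, nothing beyond the 60 mm cutoff).  Edit to taste or
# supply your own profile.
# Bins are half-open [edge_i, edge_{i+1}) in mm from the nearest patch
# center; p_bias = 0 leaves the turn unbiased.
bin_edges: [0, 10, 20, 30, 40, 50, 60]
p_bias:   [0.50, 0.55, 0.80, 0.75, 0.70, 0.65]
cutoff: 60
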