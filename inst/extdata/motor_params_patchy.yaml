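# Corrected motor parameters fitted from recordings in patchy arenas, with
# separate inside-patch and outside-patch (agar surround) values.  Speeds in
# mm/s; turn and pause probabilities per second.
dt_reference: 0.5
parameters:
  - {genotype: rover,  substrate: sucrose,     region: inside,  mean_v: 0.60, sd_v: 0.27, p_turn_per_s: 0.037, p_pause_per_s: 0.039}
  - {genotype: rover,  substrate: sucrose,     region: outside, mean_v: 0.65, sd_v: 0.25, p_turn_per_s: 0.044, p_pause_per_s: 0.0014}
  - {genotype: sitter, substrate: sucrose,     region: inside,  mean_v: 0.52, sd_v: 0.28, p_turn_per_s: 0.030, p_pause_per_s: 0.088}
  - {genotype: sitter, substrate: sucrose,     region: outside, mean_v: 0.57, sd_v: 0.26, p_turn_per_s: 0.030, p_pause_per_s: 0.040}
  - {genotype: rover,  substrate: yeast,       region: inside,  mean_v: 0.37, sd_v: 0.19, p_turn_per_s: 0.039, p_pause_per_s: 0.17}
  - {genotype: rover,  substrate: yeast,       region: outside, mean_v: 0.44, sd_v: 0.20, p_turn_per_s: 0.068, p_pause_per_s: 0.023}
  - {genotype: sitter, substrate: yeast,       region: inside,  mean_v: 0.26, sd_v: 0.14, p_turn_per_s: 0.025, p_pause_per_s: 0.32}
  - {genotype: sitter, substrate: yeast,       region: outside, mean_v: 0.36, sd_v: 0.17, p_turn_per_s: 0.048, p_pause_per_s: 0.053}
  - {genotype: rover,  substrate: apple_juice, region: inside,  mean_v: 0.44, sd_v: 0.24, p_turn_per_s: 0.026, p_pause_per_s: 0.096}
  - {genotype: rover,  substrate: apple_juice, region: outside, mean_v: 0.53, sd_v: 0.26, p_turn_per_s: 0.017, p_pause_per_s: 0.076}
  - {genotype: sitter, substrate: apple_juice, region: inside,  mean_v: 0.39, sd_v: 0.21, p_turn_per_s: 0.021, p_pause_per_s: 0.13}
  - {genotype: sitter, substrate: apple_juice, region: outside, mean_v: 0.48, sd_v: 0.22, p_turn_per_s: 0.031, p_pause_per_s: 0.065}
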