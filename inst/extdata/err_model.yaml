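# Excess-relative-risk model for thyroid-cancer incidence.
# Provenance: BEIR VII (2006) committee preferred thyroid model
# (pooled-cohort analysis): ERR(D,e) = beta_sex * D * exp(gamma * e_star),
# e_star = (min(e, e_star_cap) - 30)/10. Dose in Gy.
# Latency: 5-year solid-cancer convention (package default, configurable).
beta:
  male: 0.53    # ERR per Gy
  female: 1.05  # ERR per Gy
gamma: -0.83    # per decade of exposure age
e_star_cap: .inf # exposure age where the decline stops; uncapped for thyroid,
                 # matching the continued fall of the published LAR table
latency: 5      # years
a_max: 100      # last attained age in the projection
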