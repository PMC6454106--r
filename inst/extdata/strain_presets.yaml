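# Empirically determined growth/inhibition parameter presets.
# log_ic50 is log10 of the half-inhibitory perchlorate concentration in mol/L
# (the package API carries concentrations in mM; -1.914 corresponds to 12.2 mM).
community:
  name: community
  mu_max_per_h: 0.13
  log_ic50_log10M: -1.914
  hill_slope: -1.813
bmsr:
  name: Desulfovibrio sp. BMSR
  mu_max_per_h: 0.2
  log_ic50_log10M: -2.099
  hill_slope: -1.108
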