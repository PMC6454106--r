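# Example run configuration: community preset, 50 mM perchlorate inflow
# switched on at 200 h and off at 500 h.
preset: community
volume_ml: 125
flow_ml_per_h: 2.6
k_p_pct: 40
k_a_pct: 0.5
t_end_h: 900
schedule:
  - t_start_h: 0
    inflow_perchlorate_mM: 0
  - t_start_h: 200
    inflow_perchlorate_mM: 50
  - t_start_h: 500
    inflow_perchlorate_mM: 0
noise:
  kind: multiplicative-lognormal
  sd: 0.1
  seed: 17
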