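# Demonstration scene: 40 x 40 pixel coastal gradient, 1985-2023 analysis
# span, 32-day observation cadence with cloud gaps. Events cover the three
# driver families and both change kinds.
seed: 1
scene:
  nrow: 40
  ncol: 40
  start_year: 1985
  end_year: 2023
  obs_start: 1984.0
  obs_end: 2024.25
  cadence_days: 32
  clear_prob: 0.8
  d_full: 0.3
  noise_scale: 1.0
  tide_valid_max_elev: 1.8
  events:
    - kind: abrupt            # hurricane strike, marsh flattened, recovers
      driver: extreme_weather
      onset: 2005.65
      target: open_water
      rows: [2, 9]
      cols: [19, 24]
      recovery: 4
    - kind: abrupt            # hurricane strike, no recovery
      driver: extreme_weather
      onset: 2005.65
      target: open_water
      rows: [10, 15]
      cols: [19, 24]
    - kind: gradual           # drowning under relative sea level rise
      driver: chronic_stressor
      onset: 1992.0
      target: open_water
      rows: [16, 19]
      cols: [20, 23]
      duration: 16
    - kind: gradual           # mangrove encroachment into marsh
      driver: chronic_stressor
      onset: 1995.0
      target: mangrove
      rows: [20, 23]
      cols: [20, 24]
      duration: 10
    - kind: abrupt            # restoration project: upland to marsh
      driver: human_activity
      onset: 1998.5
      target: tidal_marsh
      rows: [3, 8]
      cols: [34, 36]
    - kind: abrupt            # freeze dieback, canopy recovers
      driver: extreme_weather
      onset: 2017.7
      target: mangrove_dieback
      rows: [33, 38]
      cols: [19, 22]
      recovery: 3.5
    - kind: abrupt            # dieback that fails to recover
      driver: extreme_weather
      onset: 2017.7
      target: mangrove_dieback
      rows: [33, 38]
      cols: [23, 24]
    - kind: abrupt            # direct conversion (fill)
      driver: human_activity
      onset: 1988.3
      target: developed_barren
      rows: [17, 19]
      cols: [25, 27]
breaks:
  consecutive_required: 6
  chisq_prob: 0.99
  min_obs_init: 12
  tide_enabled: true
  order: 1
classifier:
  n_per_class: 40
  ntree: 300
trend:
  window: 10
  alpha: 0.05
estimation:
  total_n: 1200
  min_per_class: 150
  n_boot: 1000
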