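# Demo run configuration: synthetic monsoon atmosphere + synthetic
# four-country fixture regions + synthetic trap catches.
seed: 42
site:
  name: Ruili
  lat: 23.98
  lon: 97.83
  utc_offset: 8
# Peak migration nights (defaults shown explicitly for provenance)
dates:
  - 2019-04-26
  - 2019-11-02
  - 2020-05-16
  - 2020-11-15
  - 2021-05-17
  - 2021-10-11
  - 2022-04-27
  - 2022-10-28
  - 2023-04-15
  - 2023-11-11
directions: [forward, backward]
grid:
  synthetic: by_season   # spring nights get a SW monsoon field, autumn NE
  speed: 5               # m/s per component
  t_surface: 25          # deg C at ground level
trajectory:
  step: 600              # seconds between recorded positions
  altitudes_agl: [100, 200, 300, 400, 500, 600, 700, 800, 900, 1000]
  temp_threshold: 13.1   # deg C; flight not initiated below this
  temp_gate: takeoff_only
  integrator: euler
segmentation_k: 4
# Provenance metadata only: the mesoscale-model scheme that produced the
# study-grade hourly 10-km wind fields. This package consumes gridded
# fields; it never runs the mesoscale model itself.
wrf_scheme:
  grid_points: 200 x 200
  layers: 32
  map_projection: Lambert
  microphysics_scheme: Thompson
  longwave_radiation_scheme: RRTMG
  shortwave_radiation_scheme: RRTMG
  surface_layer_scheme: Monin-Obukhov
  land_water_surface_scheme: Noah
  planetary_boundary_layer_scheme: Mellor-Yamada-Janjic
  cumulus_parameterization: Tiedtke
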