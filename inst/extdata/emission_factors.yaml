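# Tier-2 emission factors and model constants. Each uncertain factor
# carries a (min, mean, max) range used by the Latin-hypercube /
# one-at-a-time uncertainty analysis; degenerate ranges contribute no
# variance. Units in comments.
ym:                      {min: 0.060, mean: 0.065, max: 0.070}   # fraction of GE to CH4
b0:                      {min: 0.18,  mean: 0.24,  max: 0.28}    # m3 CH4 / kg VS
mcf_pasture:             {min: 0.005, mean: 0.010, max: 0.020}   # unitless
mcf_heap:                {min: 0.020, mean: 0.040, max: 0.080}   # unitless
ef1:                     {min: 0.003, mean: 0.010, max: 0.030}   # kg N2O-N / kg N (soil input)
ef3_heap:                {min: 0.002, mean: 0.005, max: 0.010}   # kg N2O-N / kg N (solid storage)
ef3_pasture:             {min: 0.007, mean: 0.020, max: 0.060}   # kg N2O-N / kg N (pasture deposit)
ef4:                     {min: 0.002, mean: 0.010, max: 0.050}   # kg N2O-N / kg N volatilised
ef5:                     {min: 0.0005, mean: 0.0075, max: 0.025} # kg N2O-N / kg N leached
frac_gas:                {min: 0.10,  mean: 0.20,  max: 0.30}    # fraction of N volatilised
frac_leach:              {min: 0.10,  mean: 0.30,  max: 0.50}    # fraction of N leached
luc_ef_grass_to_crop:    {min: 60.0,  mean: 80.0,  max: 100.0}   # Mg CO2eq / ha (one-time stock change)
luc_ef_forest_to_crop:   {min: 108.8, mean: 112.7, max: 116.6}   # Mg CO2eq / ha
# concentrate_ef is a required entry with no published value; this default
# is a documented placeholder and is excluded from exact benchmark checks.
concentrate_ef:          {min: 0.20,  mean: 0.30,  max: 0.40}    # kg CO2eq / kg concentrate
gwp_ch4: 25.0      # GWP100, national-inventory convention
gwp_n2o: 298.0
# one-time conversion stock-change emissions are spread over a 20-year
# horizon (inventory convention for land-use change)
luc_amortisation_years: 20
manure_split:
  baseline: {pasture: 0.7, heap: 0.3}
  FeCo:     {pasture: 0.7, heap: 0.3}
  FoCo:     {pasture: 0.4, heap: 0.6}
  FoFeCo:   {pasture: 0.4, heap: 0.6}
ash_fraction: 0.08          # ash fraction of manure DM
urinary_energy_fraction: 0.04
milk_fat_pct: 4.0
milk_protein_pct: 3.3
n_retention_fraction: 0.02  # fraction of N intake retained in body tissue
productive_cow_fraction: 0.6
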