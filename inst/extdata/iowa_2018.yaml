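schema: ipmecon-config/1
metadata:
  name: iowa_2018
  currency: USD 2018
  yield_units: kg/ha
  description: >
    2018 Iowa soybean aphid (Aphis glycines) case study: ten-year average
    yield and 2018 market price, regional seed/pesticide cost surveys, and
    outbreak frequency from 23 insecticide-trial site-years.
yield:
  attainable_kg_ha: 3537.0
  retained_fraction:
    S: 0.873
    R: 1.0
price:
  usd_per_kg: 0.33
probabilities:
  p_outbreak: 0.435
  population:
    wild: 1.0
    resistant: 0.0
    cross_resistant: 0.0
  resistance_profiles:
    wild: []
    resistant: ["3A"]
    cross_resistant: ["3A", "1B"]
costs:
  fixed:
    tillage: 39.70
    herbicide_application: 43.61
    planting: 73.39
    early_scouting: 21.00
    harvest: 120.83
    land_rent: 548.56
  seed:
    S.H: 155.13
    S.C: 117.65
    R.C: 111.56
  seed_alternatives:
    R.C_rag1_rag2_conventional: 114.37
  herbicide:
    H: 89.70
    C: 118.61
  insecticide:
    mean: 22.88
    "1B": 21.98
    "3A": 13.83
    "4C": 61.78
  application_usd: 20.02
  scouting_usd_per_activity: 10.50
  scouting_counts:
    early: 2
    monitoring: 6
availability:
  variety_combinations: ["S.H", "S.C", "R.C"]
grammar:
  allow_standalone_monitoring: false
spray_defaults:
  first_group_I: "3A"
  rescue_group_I: "1B"
  generic_group_W: mean
grid:
  step: 0.1
sensitivity_presets:
  yield_low:
    yield_kg_ha: 3026.0
  yield_high:
    yield_kg_ha: 4035.0
  price_avg:
    price_usd_per_kg: 0.40
  price_high:
    price_usd_per_kg: 0.52
  tech_fee:
    apply_technology_fee: true
  input_scale_88:
    input_cost_factor: 0.88
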