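# Shared fixtures: the bundled Iowa 2018 configuration and small helpers.

iowa <- load_config()

table1_scenarios <- c("SHXN-W", "SHPN-W", "SHPE-W", "RCXN-W",
                      "SHXN-I", "SHPN-I", "SHPE-I", "RCXN-I")

# A configuration with every cost zeroed, for ledger edge cases.
zero_cost_config <- function() {
  cfg <- unclass(iowa)
  zero <- function(x) if (is.numeric(x)) x * 0 else if (is.list(x)) lapply(x, zero) else x
  counts <- cfg$costs$scouting_counts
  cfg$costs <- zero(cfg$costs)
  cfg$costs$scouting_counts <- counts
  validate_config(cfg)
}

# Random valid (p_o, mix) draw for property tests.
random_probability_point <- function() {
  p_o <- stats::runif(1)
  w <- stats::runif(3)
  w <- w / sum(w)
  list(p_outbreak = p_o,
       mix = population_mix(w[1], w[2], w[3]))
}

# Probability-weighted mean of the outcome tree: the brute-force counterpart
# of expected_yield_fraction().
tree_mean_fraction <- function(scenario, config, p_outbreak, mix) {
  inp <- ipmecon:::scenario_inputs(scenario, config, p_outbreak, mix)
  tree <- enumerate_outcomes(inp$scenario, inp$outbreak, inp$mix, inp$yields,
                             inp$plan)
  sum(tree$probability * tree$yield_fraction)
}
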