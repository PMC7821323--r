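# Partial-budget economics: expected application/scouting counts, expected
# variable (and optionally total) cost with an itemized audit, expected net
# revenue, and the configuration transforms used by the sensitivity analyses.

# P(first application fails) = sum of class probabilities over classes that
# survive the first application's insecticide group.
prob_first_failure <- function(plan, mix) {
  first <- plan$applications[plan$applications$role == "first", , drop = FALSE]
  if (nrow(first) == 0L) return(0)
  g <- first$group[1]
  p <- c(wild = mix$p_wild, resistant = mix$p_resistant,
         cross_resistant = mix$p_cross_resistant)
  survives <- vapply(names(p), function(cl) g %in% mix$profiles[[cl]],
                     logical(1))
  sum(p[survives])
}

#' Expected number of insecticide applications
#'
#' Prophylactic policies (P) always make the first application; the rescue
#' fires with probability `p_outbreak * P(first fails)` when enabled.
#' Threshold-based policies (T) apply only when an outbreak occurs. Policy X
#' makes none.
#'
#' @param scenario scenario code or `ipm_scenario`.
#' @param plan an `ipm_spray_plan`.
#' @param outbreak an `ipm_outbreak` or outbreak probability.
#' @param mix an `ipm_population_mix`.
#' @return expected application count (unitless).
#' @export
expected_application_count <- function(scenario, plan, outbreak, mix) {
  s <- parse_scenario(scenario)
  outbreak <- as_outbreak(outbreak)
  mix <- as_population_mix(mix)
  if (s$spray_policy == "X") return(0)
  p_rescue <- if (isTRUE(plan$rescue_enabled) &&
                  any(plan$applications$role == "rescue")) {
    outbreak$p_outbreak * prob_first_failure(plan, mix)
  } else 0
  switch(s$spray_policy,
    P = 1 + p_rescue,
    T = outbreak$p_outbreak + p_rescue
  )
}

#' Expected number of scouting activities
#'
#' Two early-season scouting passes happen in every scenario (weeds, stand,
#' seedling disease). Monitoring (M) adds six in-season passes. Efficacy
#' scouting (E) adds one pass after the first application plus a second pass
#' with the probability that a rescue application is needed.
#'
#' @inheritParams expected_application_count
#' @return expected activity count (unitless).
#' @export
expected_scouting_activities <- function(scenario, plan, outbreak, mix) {
  s <- parse_scenario(scenario)
  outbreak <- as_outbreak(outbreak)
  mix <- as_population_mix(mix)
  n <- 2
  if (s$scouting == "M") n <- n + 6
  if (s$scouting == "E" && nrow(plan$applications) >= 1L) {
    p_second <- if (isTRUE(plan$rescue_enabled)) {
      outbreak$p_outbreak * prob_first_failure(plan, mix)
    } else 0
    n <- n + 1 + p_second
  }
  n
}

# Expected count of first applications (product and application cost both
# accrue per application made).
.expected_first_count <- function(s, outbreak) {
  switch(s$spray_policy, X = 0, P = 1, T = outbreak$p_outbreak)
}

#' Itemized expected-cost audit for a scenario
#'
#' Returns the per-item cost trace behind [expected_cost()]: one row per cost
#' item with its trigger, unit cost, expected number of units, and expected
#' cost. Variable items are the herbicide product, seed, insecticide product
#' and application (weighted by expected application counts), and in-season
#' scouting beyond the two early passes. Fixed items (tillage, herbicide
#' application, planting, early scouting, harvest, land rent) are appended
#' only when `include_fixed = TRUE`.
#'
#' @param scenario scenario code or `ipm_scenario`.
#' @param config an `ipm_config`.
#' @param p_outbreak optional outbreak-probability override (defaults to the
#'   config value).
#' @param mix optional population-mix override (defaults to wild-type for -W
#'   scenarios, the config's population block for -I).
#' @param plan optional `ipm_spray_plan` override (defaults to
#'   [default_spray_plan()]).
#' @param include_fixed include fixed cost items (default `FALSE`: only
#'   variable costs enter expected net revenue).
#' @return `data.frame` with columns `item`, `trigger`, `unit_cost`,
#'   `expected_units`, `expected_cost`.
#' @export
cost_audit <- function(scenario, config, p_outbreak = NULL, mix = NULL,
                       plan = NULL, include_fixed = FALSE) {
  inp <- scenario_inputs(scenario, config, p_outbreak, mix, plan)
  s <- inp$scenario
  rows <- list()
  add <- function(item, trigger, unit, units) {
    rows[[length(rows) + 1L]] <<- data.frame(
      item = item, trigger = trigger, unit_cost = as.numeric(unit),
      expected_units = as.numeric(units),
      expected_cost = as.numeric(unit) * as.numeric(units),
      stringsAsFactors = FALSE
    )
  }

  herb <- config$costs$herbicide[[s$variety_herbicide]]
  if (is.null(herb)) {
    stop(sprintf("missing herbicide cost for trait '%s'", s$variety_herbicide),
         call. = FALSE)
  }
  add(paste0("herbicide_product_", s$variety_herbicide), "herbicide_product",
      herb, 1)

  combo <- paste(s$variety_aphid, s$variety_herbicide, sep = ".")
  seed <- config$costs$seed[[combo]]
  if (is.null(seed)) {
    stop(sprintf("missing seed cost for variety combination '%s'", combo),
         call. = FALSE)
  }
  add(paste0("seed_", combo), "seed", seed, 1)

  apps <- inp$plan$applications
  if (nrow(apps) > 0L) {
    e_first <- .expected_first_count(s, inp$outbreak)
    p_rescue <- if (isTRUE(inp$plan$rescue_enabled) &&
                    any(apps$role == "rescue")) {
      inp$outbreak$p_outbreak * prob_first_failure(inp$plan, inp$mix)
    } else 0
    for (i in seq_len(nrow(apps))) {
      units <- if (apps$role[i] == "first") e_first else p_rescue
      add(paste0("insecticide_", apps$role[i], "_", apps$group[i]),
          "per_application", apps$product_cost[i], units)
      add(paste0("application_", apps$role[i]),
          "per_application", apps$application_cost[i], units)
    }
  }

  early <- config$costs$scouting_counts$early %||% 2
  scout_units <- expected_scouting_activities(s, inp$plan, inp$outbreak,
                                              inp$mix) - early
  if (scout_units > 0) {
    add("in_season_scouting", "per_scouting_activity",
        config$costs$scouting_usd_per_activity, scout_units)
  }

  if (isTRUE(include_fixed)) {
    for (nm in names(config$costs$fixed)) {
      add(nm, "always", config$costs$fixed[[nm]], 1)
    }
  }
  do.call(rbind, rows)
}

#' Expected cost of a scenario (US$/ha)
#'
#' Sum of the [cost_audit()] items. By default only variable costs are
#' included, the convention under which expected net revenue compares
#' scenarios; `include_fixed = TRUE` adds the fixed production items for a
#' total-cost view.
#'
#' @inheritParams cost_audit
#' @return expected cost in US$/ha.
#' @examples
#' expected_cost("RCXN-W", load_config())  # 230.17
#' @export
expected_cost <- function(scenario, config, p_outbreak = NULL, mix = NULL,
                          plan = NULL, include_fixed = FALSE) {
  sum(cost_audit(scenario, config, p_outbreak, mix, plan,
                 include_fixed)$expected_cost)
}

#' Expected net revenue of a scenario (US$/ha)
#'
#' `E(R) = E(Y) * E(P) - E(C)`: expected yield times expected crop price
#' minus expected cost (yield and price treated as independent). With the
#' default `include_fixed = FALSE` this is a partial-budget comparison, not
#' whole-farm profitability.
#'
#' @inheritParams cost_audit
#' @return expected net revenue in US$/ha.
#' @examples
#' expected_net_revenue("RCXN-W", load_config())
#' @export
expected_net_revenue <- function(scenario, config, p_outbreak = NULL,
                                 mix = NULL, plan = NULL,
                                 include_fixed = FALSE) {
  inp <- scenario_inputs(scenario, config, p_outbreak, mix, plan)
  ey <- expected_yield(inp$scenario, inp$outbreak, inp$mix, inp$yields,
                       inp$plan)
  ey * config$price$usd_per_kg -
    expected_cost(scenario, config, p_outbreak, mix, plan, include_fixed)
}

#' Evaluate a scenario: yield, cost and revenue in one call
#'
#' @inheritParams cost_audit
#' @return list with `scenario`, `yield_fraction`, `expected_yield` (kg/ha),
#'   `expected_cost`, `expected_net_revenue` (US$/ha), `plan`, and the
#'   `audit` data frame.
#' @examples
#' evaluate_scenario("SHPN-W", load_config(), p_outbreak = 0.435)
#' @export
evaluate_scenario <- function(scenario, config, p_outbreak = NULL, mix = NULL,
                              plan = NULL, include_fixed = FALSE) {
  inp <- scenario_inputs(scenario, config, p_outbreak, mix, plan)
  frac <- expected_yield_fraction(inp$scenario, inp$outbreak, inp$mix,
                                  inp$yields, inp$plan)
  audit <- cost_audit(scenario, config, p_outbreak, mix, plan, include_fixed)
  ec <- sum(audit$expected_cost)
  ey <- frac * inp$yields$attainable_yield
  list(
    scenario = inp$scenario$code,
    yield_fraction = frac,
    expected_yield = ey,
    expected_cost = ec,
    expected_net_revenue = ey * config$price$usd_per_kg - ec,
    plan = inp$plan,
    audit = audit
  )
}

#' Technology fee implied by the seed cost table
#'
#' The herbicide-tolerance premium: the difference between the
#' aphid-susceptible herbicide-tolerant (`S.H`) and conventional (`S.C`) seed
#' costs. Used by the tech-fee sensitivity analysis, which asks what happens
#' if aphid-resistant varieties were marketed with the same premium.
#'
#' @param config an `ipm_config`.
#' @return fee in US$/ha.
#' @export
technology_fee <- function(config) {
  sh <- config$costs$seed[["S.H"]]
  sc <- config$costs$seed[["S.C"]]
  if (is.null(sh) || is.null(sc)) {
    stop("seed table must contain entries 'S.H' and 'S.C' to derive the technology fee",
         call. = FALSE)
  }
  as.numeric(sh) - as.numeric(sc)
}

#' Apply the technology fee to aphid-resistant seed
#'
#' Returns a copy of the configuration with the `R.C` seed cost increased by
#' [technology_fee()]; the original configuration is untouched.
#'
#' @param config an `ipm_config`.
#' @return modified `ipm_config`.
#' @export
apply_technology_fee <- function(config) {
  fee <- technology_fee(config)
  if (is.null(config$costs$seed[["R.C"]])) {
    stop("seed table must contain an 'R.C' entry to apply the technology fee",
         call. = FALSE)
  }
  config$costs$seed[["R.C"]] <- as.numeric(config$costs$seed[["R.C"]]) + fee
  config
}

#' Scale every input cost by a factor
#'
#' Multiplies all cost amounts — fixed and variable items, seed, herbicide and
#' insecticide products, application and scouting charges — by `factor`,
#' leaving probabilities, yield and price untouched. `factor = 0.88` is the
#' 12% input-cost-reduction sensitivity preset.
#'
#' @param config an `ipm_config`.
#' @param factor positive scaling factor.
#' @return modified `ipm_config`.
#' @export
apply_input_cost_scaling <- function(config, factor) {
  factor <- as.numeric(factor)
  if (length(factor) != 1L || is.na(factor) || factor <= 0) {
    stop("cost scaling factor must be a single positive number", call. = FALSE)
  }
  scale_rec <- function(x) {
    if (is.numeric(x)) return(x * factor)
    if (is.list(x)) return(lapply(x, scale_rec))
    x
  }
  keep_counts <- config$costs$scouting_counts  # counts, not dollars
  config$costs <- scale_rec(config$costs)
  config$costs$scouting_counts <- keep_counts
  config
}
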