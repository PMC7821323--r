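# Case-study configuration: loading, validation, saving.
# The bundled iowa_2018 preset carries the 2018 Iowa soybean aphid values
# (yield, price, outbreak probability, cost tables, availability rules).

.required_blocks <- c("yield", "price", "probabilities", "costs",
                      "availability")

.assert <- function(ok, path, msg) {
  if (!ok) stop(sprintf("config field '%s': %s", path, msg), call. = FALSE)
}

#' Validate a configuration list
#'
#' Checks required blocks, numeric ranges, and probability-sum constraints;
#' fills defaults (grid step 0.1, empty grammar/sensitivity blocks). Errors
#' name the offending field path or probability block.
#'
#' @param config a raw configuration list (e.g. from [yaml::read_yaml()]).
#' @return the validated configuration with class `ipm_config`.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  for (b in .required_blocks) {
    .assert(!is.null(config[[b]]), b, "block is missing")
  }
  y <- config$yield
  .assert(is.numeric(y$attainable_kg_ha) && y$attainable_kg_ha > 0,
          "yield.attainable_kg_ha", "must be a positive number")
  q <- unlist(y$retained_fraction)
  .assert(all(c("S", "R") %in% names(q)), "yield.retained_fraction",
          "must contain entries S and R")
  .assert(all(q > 0 & q <= 1), "yield.retained_fraction",
          "each q must lie in (0, 1]")
  .assert(is.numeric(config$price$usd_per_kg) && config$price$usd_per_kg > 0,
          "price.usd_per_kg", "must be a positive number")

  pr <- config$probabilities
  .assert(is.numeric(pr$p_outbreak) && pr$p_outbreak >= 0 && pr$p_outbreak <= 1,
          "probabilities.p_outbreak", "must lie in [0, 1]")
  pop <- unlist(pr$population[c("wild", "resistant", "cross_resistant")])
  .assert(length(pop) == 3L && !anyNA(pop),
          "probabilities.population",
          "must give wild, resistant and cross_resistant")
  .assert(all(pop >= 0 & pop <= 1) && abs(sum(pop) - 1) <= 1e-9,
          "probabilities.population",
          sprintf("class probabilities must sum to 1 (got %.15g)", sum(pop)))
  .assert(all(c("wild", "resistant", "cross_resistant") %in%
                names(pr$resistance_profiles)),
          "probabilities.resistance_profiles",
          "must name wild, resistant and cross_resistant")

  cost <- config$costs
  leafs <- unlist(cost[c("fixed", "seed", "herbicide", "insecticide")])
  .assert(all(unlist(c(leafs, cost$application_usd,
                       cost$scouting_usd_per_activity)) >= 0),
          "costs", "all cost amounts must be >= 0")
  avail <- unlist(config$availability$variety_combinations)
  .assert(length(avail) > 0, "availability.variety_combinations",
          "must list at least one variety combination")
  for (combo in avail) {
    .assert(!is.null(cost$seed[[combo]]), paste0("costs.seed.", combo),
            "seed cost missing for an available variety combination")
    herb <- sub("^[SR]\\.", "", combo)
    .assert(!is.null(cost$herbicide[[herb]]), paste0("costs.herbicide.", herb),
            "herbicide cost missing for an available herbicide trait")
  }

  config$grid <- config$grid %||% list()
  config$grid$step <- config$grid$step %||% 0.1
  config$grammar <- config$grammar %||% list(allow_standalone_monitoring = FALSE)
  config$sensitivity_presets <- config$sensitivity_presets %||% list()
  config$costs$scouting_counts <- config$costs$scouting_counts %||%
    list(early = 2, monitoring = 6)
  structure(config, class = "ipm_config")
}

#' Load a case-study configuration
#'
#' With no argument (or `"iowa_2018"`), loads the bundled 2018 Iowa soybean
#' aphid preset: attainable yield 3537 kg/ha, price US$0.33/kg, outbreak
#' probability 0.435, and the 2018 cost tables. Otherwise reads a YAML file.
#'
#' @param path path to a YAML configuration, or the name of a bundled preset.
#' @return an `ipm_config`.
#' @examples
#' cfg <- load_config()
#' cfg$price$usd_per_kg
#' @export
load_config <- function(path = NULL) {
  if (is.null(path) || identical(path, "iowa_2018")) {
    path <- system.file("extdata", "iowa_2018.yaml", package = "ipmecon")
  }
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: '%s'", path), call. = FALSE)
  }
  validate_config(yaml::read_yaml(path))
}

#' Save a configuration to YAML
#'
#' `load_config(save_config(cfg, path))` returns a configuration equal to
#' `cfg`.
#'
#' @param config an `ipm_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @export
print.ipm_config <- function(x, ...) {
  cat(sprintf(
    "<ipm_config %s> yield %.0f kg/ha, price %.2f US$/kg, p_outbreak %.3f\n",
    x$metadata$name %||% "(unnamed)", x$yield$attainable_kg_ha,
    x$price$usd_per_kg, x$probabilities$p_outbreak
  ))
  invisible(x)
}

# Resolve model inputs for a scenario from a config plus optional overrides.
# -W scenarios face a wild-type population by definition; -I scenarios default
# to the config's population block unless a mix is supplied.
scenario_inputs <- function(scenario, config, p_outbreak = NULL, mix = NULL,
                            plan = NULL) {
  s <- parse_scenario(scenario)
  profiles <- lapply(config$probabilities$resistance_profiles, as.character)
  if (is.null(p_outbreak)) p_outbreak <- config$probabilities$p_outbreak
  if (is.null(mix)) {
    if (s$pest_type == "W") {
      mix <- population_mix(1, 0, 0, profiles)
    } else {
      pop <- config$probabilities$population
      mix <- population_mix(pop$wild, pop$resistant, pop$cross_resistant,
                            profiles)
    }
  } else if (!inherits(mix, "ipm_population_mix")) {
    mix <- as_population_mix(c(mix, list(profiles = profiles)))
  }
  if (is.null(plan)) plan <- default_spray_plan(s, config)
  list(
    scenario = s,
    outbreak = outbreak_distribution(p_outbreak),
    mix = mix,
    yields = yield_model(config$yield$attainable_kg_ha,
                         config$yield$retained_fraction),
    plan = plan
  )
}

# Population mix along the resistance axis: p_resistant = x, p_cross fixed,
# p_wild takes the remainder.
resistance_mix <- function(p_resistant, p_cross_resistant = 0,
                           profiles = default_profiles()) {
  population_mix(1 - p_resistant - p_cross_resistant, p_resistant,
                 p_cross_resistant, profiles)
}
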