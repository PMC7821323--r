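# Scenario code algebra: parsing, validation, enumeration, default spray plans.
#
# A scenario is a five-component code such as "SHPE-I":
#   1. variety aphid trait: S (aphid-susceptible) | R (aphid-resistant)
#   2. variety herbicide trait: H (herbicide-tolerant) | C (conventional)
#   3. spray policy: X (none) | P (prophylactic) | T (threshold-based)
#   4. scouting: N (none) | E (efficacy) | M (monitoring)
#   5. pest type: W (wild-type) | I (insecticide-resistant)

.scenario_alphabets <- list(
  variety_aphid     = c("S", "R"),
  variety_herbicide = c("H", "C"),
  spray_policy      = c("X", "P", "T"),
  scouting          = c("N", "E", "M"),
  pest_type         = c("W", "I")
)

.scenario_component_labels <- c(
  "variety aphid trait", "variety herbicide trait",
  "spray policy", "scouting", "pest type"
)

new_scenario <- function(va, vh, sp, sc, pt) {
  structure(
    list(
      variety_aphid = va, variety_herbicide = vh,
      spray_policy = sp, scouting = sc, pest_type = pt,
      code = paste0(va, vh, sp, sc, "-", pt)
    ),
    class = "ipm_scenario"
  )
}

#' Parse a five-component management scenario code
#'
#' Scenario codes are four letters, a hyphen, then the pest-type letter
#' (e.g. `"SHPN-W"`: susceptible herbicide-tolerant variety, prophylactic
#' spray, no scouting, wild-type pest). Parsing is case-insensitive and only
#' checks the component alphabets; combination rules (e.g. threshold sprays
#' require monitoring) are checked by [validate_scenario()].
#'
#' @param code scenario code string, or an already-parsed `ipm_scenario`
#'   (returned unchanged).
#' @return an `ipm_scenario` object with fields `variety_aphid`,
#'   `variety_herbicide`, `spray_policy`, `scouting`, `pest_type`, `code`.
#' @examples
#' parse_scenario("SHXN-W")
#' parse_scenario("rcxn-i")$variety_aphid
#' @export
parse_scenario <- function(code) {
  if (inherits(code, "ipm_scenario")) return(code)
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stop("scenario code must be a single string", call. = FALSE)
  }
  s <- toupper(trimws(code))
  if (!grepl("^[A-Z]{4}-[A-Z]$", s)) {
    stop(sprintf(
      "scenario code '%s' must be four letters, a hyphen, then the pest-type letter (e.g. 'SHPN-W')",
      code
    ), call. = FALSE)
  }
  comp <- c(substring(s, 1:4, 1:4), substring(s, 6, 6))
  for (i in seq_along(comp)) {
    allowed <- .scenario_alphabets[[i]]
    if (!comp[i] %in% allowed) {
      stop(sprintf(
        "scenario code '%s': component %d (%s) is '%s', expected one of %s",
        code, i, .scenario_component_labels[i], comp[i],
        paste(allowed, collapse = ", ")
      ), call. = FALSE)
    }
  }
  new_scenario(comp[1], comp[2], comp[3], comp[4], comp[5])
}

#' @export
format.ipm_scenario <- function(x, ...) x$code

#' @export
print.ipm_scenario <- function(x, ...) {
  cat(sprintf(
    "<ipm_scenario %s> variety: %s/%s, spray: %s, scouting: %s, pest: %s\n",
    x$code,
    switch(x$variety_aphid, S = "aphid-susceptible", R = "aphid-resistant"),
    switch(x$variety_herbicide, H = "herbicide-tolerant", C = "conventional"),
    switch(x$spray_policy, X = "none", P = "prophylactic", T = "threshold-based"),
    switch(x$scouting, N = "none", E = "efficacy", M = "monitoring"),
    switch(x$pest_type, W = "wild-type", I = "insecticide-resistant")
  ))
  invisible(x)
}

#' @export
as.character.ipm_scenario <- function(x, ...) x$code

#' Validate a scenario against combination rules and a configuration
#'
#' Rules are data, not exceptions: the return value is a named character
#' vector of violation messages (names are rule identifiers); an empty vector
#' means the scenario is valid. Grammar rules: threshold-based sprays require
#' monitoring (`T_requires_M`); efficacy scouting only follows an application
#' (`E_requires_application`); monitoring without threshold sprays is only
#' allowed when the config's grammar flag permits it (`M_requires_T`).
#' Variety availability (e.g. aphid resistance only in conventional,
#' non-herbicide-tolerant backgrounds in 2018) comes from the config's
#' `availability$variety_combinations` table, not from hard-coded rules.
#'
#' @param scenario scenario code or `ipm_scenario`.
#' @param config an `ipm_config`, see [load_config()].
#' @return named character vector of violations; `character(0)` if valid.
#' @examples
#' cfg <- load_config()
#' validate_scenario("SHPN-W", cfg)   # valid
#' validate_scenario("SHTN-W", cfg)   # threshold spray without monitoring
#' @export
validate_scenario <- function(scenario, config) {
  s <- parse_scenario(scenario)
  v <- character(0)
  if (s$spray_policy == "T" && s$scouting != "M") {
    v <- c(v, T_requires_M =
      "threshold-based applications (T) require monitoring (M)")
  }
  if (s$scouting == "E" && s$spray_policy == "X") {
    v <- c(v, E_requires_application =
      "efficacy scouting (E) only occurs following an insecticide application")
  }
  allow_m <- isTRUE(config$grammar$allow_standalone_monitoring)
  if (s$scouting == "M" && s$spray_policy != "T" && !allow_m) {
    v <- c(v, M_requires_T =
      "monitoring (M) without threshold-based applications is not permitted by this configuration")
  }
  combo <- paste(s$variety_aphid, s$variety_herbicide, sep = ".")
  avail <- unlist(config$availability$variety_combinations)
  if (!combo %in% avail) {
    v <- c(v, variety_unavailable = sprintf(
      "variety combination %s is not available in this configuration (e.g. aphid-resistant seed unavailable with herbicide tolerance)",
      combo
    ))
  }
  v
}

#' Enumerate all valid scenario codes under a configuration
#'
#' Takes the Cartesian product of the five component alphabets and keeps the
#' codes for which [validate_scenario()] reports no violations. Output is
#' deterministic lexicographic order with no duplicates.
#'
#' @param config an `ipm_config`.
#' @param pest_type optionally restrict to `"W"` or `"I"`.
#' @return character vector of canonical scenario codes.
#' @examples
#' enumerate_scenarios(load_config(), pest_type = "W")
#' @export
enumerate_scenarios <- function(config, pest_type = NULL) {
  grid <- expand.grid(
    va = .scenario_alphabets$variety_aphid,
    vh = .scenario_alphabets$variety_herbicide,
    sp = .scenario_alphabets$spray_policy,
    sc = .scenario_alphabets$scouting,
    pt = .scenario_alphabets$pest_type,
    stringsAsFactors = FALSE
  )
  if (!is.null(pest_type)) {
    pest_type <- toupper(pest_type)
    stopifnot(all(pest_type %in% c("W", "I")))
    grid <- grid[grid$pt %in% pest_type, , drop = FALSE]
  }
  codes <- paste0(grid$va, grid$vh, grid$sp, grid$sc, "-", grid$pt)
  ok <- vapply(codes, function(cd) length(validate_scenario(cd, config)) == 0L,
               logical(1))
  sort(unique(codes[ok]))
}

#' Construct a spray plan
#'
#' A spray plan holds the ordered insecticide applications (at most two: a
#' first application and an optional rescue) with their product and
#' application costs, plus whether the rescue is enabled (it fires only when
#' efficacy scouting reveals the first application failed).
#'
#' @param applications `data.frame` with columns `role` (`"first"`,
#'   `"rescue"`), `group` (insecticide group code, e.g. `"3A"`),
#'   `product_cost`, `application_cost` (both US$/ha); or `NULL` for an empty
#'   plan.
#' @param rescue_enabled logical; whether a failed first application triggers
#'   the rescue row.
#' @return an `ipm_spray_plan`.
#' @export
spray_plan <- function(applications = NULL, rescue_enabled = FALSE) {
  if (is.null(applications)) {
    applications <- data.frame(
      role = character(0), group = character(0),
      product_cost = numeric(0), application_cost = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(applications),
            all(c("role", "group", "product_cost", "application_cost") %in%
                  names(applications)))
  if (nrow(applications) > 2L) {
    stop("a spray plan holds at most two insecticide applications",
         call. = FALSE)
  }
  if (nrow(applications) > 0L &&
      !all(applications$role %in% c("first", "rescue"))) {
    stop("application roles must be 'first' or 'rescue'", call. = FALSE)
  }
  if (sum(applications$role == "rescue") > 0L &&
      !"first" %in% applications$role) {
    stop("a rescue application requires a first application", call. = FALSE)
  }
  structure(
    list(applications = applications, rescue_enabled = isTRUE(rescue_enabled)),
    class = "ipm_spray_plan"
  )
}

#' @export
print.ipm_spray_plan <- function(x, ...) {
  if (nrow(x$applications) == 0L) {
    cat("<ipm_spray_plan> empty (no insecticide applied)\n")
  } else {
    cat(sprintf("<ipm_spray_plan> rescue_enabled: %s\n", x$rescue_enabled))
    print(x$applications, row.names = FALSE)
  }
  invisible(x)
}

.insecticide_cost <- function(config, group) {
  cost <- config$costs$insecticide[[group]]
  if (is.null(cost)) {
    stop(sprintf(
      "no insecticide product cost configured for group '%s'", group
    ), call. = FALSE)
  }
  as.numeric(cost)
}

#' Default spray plan for a scenario
#'
#' Encodes the case-study costing convention: no-spray policies get an empty
#' plan; scenarios facing insecticide-resistant pests (-I) are priced
#' class-specifically (cheapest effective product first — a pyrethroid,
#' group 3A — with an organophosphate, group 1B, as the rescue when efficacy
#' scouting is in place); wild-type (-W) scenarios are priced at the mean
#' cost across all surveyed insecticide products, since no particular class
#' is implied.
#'
#' @param scenario scenario code or `ipm_scenario`.
#' @param config an `ipm_config`.
#' @return an `ipm_spray_plan`.
#' @examples
#' cfg <- load_config()
#' default_spray_plan("SHPE-I", cfg)
#' @export
default_spray_plan <- function(scenario, config) {
  s <- parse_scenario(scenario)
  if (s$spray_policy == "X") return(spray_plan())
  app_cost <- as.numeric(config$costs$application_usd)
  if (s$pest_type == "I") {
    g_first  <- config$spray_defaults$first_group_I %||% "3A"
    g_rescue <- config$spray_defaults$rescue_group_I %||% "1B"
  } else {
    g_first <- g_rescue <- config$spray_defaults$generic_group_W %||% "mean"
  }
  rows <- data.frame(
    role = "first", group = g_first,
    product_cost = .insecticide_cost(config, g_first),
    application_cost = app_cost,
    stringsAsFactors = FALSE
  )
  rescue <- s$scouting == "E"
  if (rescue) {
    rows <- rbind(rows, data.frame(
      role = "rescue", group = g_rescue,
      product_cost = .insecticide_cost(config, g_rescue),
      application_cost = app_cost,
      stringsAsFactors = FALSE
    ))
  }
  spray_plan(rows, rescue_enabled = rescue)
}
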