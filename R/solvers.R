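# Break-even threshold solvers, probability sweeps, scenario ranking, and
# the sensitivity analyses. Expected net revenue is affine in the outbreak
# probability and in the resistant-class probability, so crossings are solved
# exactly from two endpoint evaluations and cross-checked by bisection.

.er_axis_fun <- function(scenario, config, axis, p_outbreak = NULL,
                         p_cross_resistant = 0) {
  profiles <- lapply(config$probabilities$resistance_profiles, as.character)
  if (axis == "outbreak_probability") {
    function(x) expected_net_revenue(scenario, config, p_outbreak = x)
  } else {
    p_o <- p_outbreak %||% config$probabilities$p_outbreak
    function(x) {
      expected_net_revenue(
        scenario, config, p_outbreak = p_o,
        mix = resistance_mix(x, p_cross_resistant, profiles)
      )
    }
  }
}

.breakeven <- function(a, b, config, axis, p_outbreak = NULL,
                       p_cross_resistant = 0) {
  a <- parse_scenario(a); b <- parse_scenario(b)
  fa <- .er_axis_fun(a, config, axis, p_outbreak, p_cross_resistant)
  fb <- .er_axis_fun(b, config, axis, p_outbreak, p_cross_resistant)
  hi <- if (axis == "resistance_probability") 1 - p_cross_resistant else 1
  f <- function(x) fa(x) - fb(x)
  f0 <- f(0); f1 <- f(hi)
  slope <- (f1 - f0) / hi
  diagnostic <- NA_character_
  if (abs(slope) < 1e-12) {
    crossing <- NA_real_
    diagnostic <- if (abs(f0) < 1e-9) {
      "scenarios are equal everywhere on the axis"
    } else {
      "parallel revenue lines: no crossing"
    }
    favored <- if (f0 >= 0) a$code else b$code
  } else {
    crossing <- -f0 / slope
    favored <- if (slope > 0) a$code else b$code
    if (crossing < 0 || crossing > hi) {
      diagnostic <- sprintf("crossing %.6g lies outside [0, %g]", crossing, hi)
      crossing <- NA_real_
    } else if (crossing > 0 && crossing < hi && f(0) * f(hi) < 0) {
      # independent bisection cross-check of the closed-form root
      root <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
      if (abs(root - crossing) > 1e-9) {
        stop(sprintf(
          "closed-form crossing %.12f disagrees with bisection root %.12f",
          crossing, root
        ), call. = FALSE)
      }
    }
  }
  structure(
    list(
      scenario_a = a$code, scenario_b = b$code, axis = axis,
      crossing = crossing,
      crossing_pct = if (is.na(crossing)) NA_real_ else
        round_half_up(100 * crossing),
      favored_above = favored,
      slope_difference = slope,
      diagnostic = diagnostic
    ),
    class = "ipm_breakeven"
  )
}

#' @export
print.ipm_breakeven <- function(x, ...) {
  cat(sprintf("<ipm_breakeven> %s vs %s on %s\n", x$scenario_a, x$scenario_b,
              x$axis))
  if (is.na(x$crossing)) {
    cat(sprintf("  no crossing (%s); favored: %s\n", x$diagnostic,
                x$favored_above))
  } else {
    cat(sprintf("  crossing at %.4f (%d%%); favored above: %s\n",
                x$crossing, as.integer(x$crossing_pct), x$favored_above))
  }
  invisible(x)
}

#' Break-even outbreak probability between two scenarios
#'
#' Solves `E(R)_a(p_o) = E(R)_b(p_o)` exactly (both sides are affine in the
#' outbreak probability) and verifies the root by bisection. Intended for
#' wild-type (-W) scenario comparisons, e.g. at what outbreak probability a
#' prophylactic insecticide application starts out-earning no management.
#'
#' @param a,b scenario codes or `ipm_scenario`s.
#' @param config an `ipm_config`.
#' @return an `ipm_breakeven` with fields `crossing` (probability or `NA`),
#'   `crossing_pct` (integer percent, half-up), `favored_above` (scenario
#'   with the greater revenue above the crossing), `slope_difference`,
#'   `diagnostic`.
#' @examples
#' breakeven_outbreak_probability("SHPN-W", "SHXN-W", load_config())
#' @export
breakeven_outbreak_probability <- function(a, b, config) {
  .breakeven(a, b, config, "outbreak_probability")
}

#' Break-even resistance probability between two scenarios
#'
#' Solves `E(R)_a(p_s) = E(R)_b(p_s)` along the resistant-class probability
#' axis at a fixed outbreak probability, with `p_wild = 1 - p_s - p_c`.
#'
#' @inheritParams breakeven_outbreak_probability
#' @param p_outbreak fixed outbreak probability (defaults to the config
#'   value, 0.435 in the Iowa preset).
#' @param p_cross_resistant fixed cross-resistant probability (default 0).
#' @return an `ipm_breakeven`.
#' @examples
#' breakeven_resistance_probability("SHPN-I", "SHXN-I", load_config())
#' @export
breakeven_resistance_probability <- function(a, b, config, p_outbreak = NULL,
                                             p_cross_resistant = 0) {
  .breakeven(a, b, config, "resistance_probability", p_outbreak,
             p_cross_resistant)
}

#' Probability sweep of expected yield, cost and net revenue
#'
#' Evaluates each scenario on a probability grid along the chosen axis.
#'
#' @param scenarios character vector of scenario codes.
#' @param axis `"outbreak"` (vary the outbreak probability, wild-type mix for
#'   -W scenarios) or `"resistance"` (vary the resistant-class probability at
#'   fixed outbreak probability).
#' @param config an `ipm_config`.
#' @param grid probability grid; defaults to `seq(0, 1, by = config$grid$step)`
#'   (0.1 increments in the Iowa preset).
#' @param p_outbreak fixed outbreak probability for the resistance axis.
#' @param p_cross_resistant fixed cross-resistant probability (default 0).
#' @return `data.frame` with columns `scenario`, `axis`, `axis_value`,
#'   `expected_yield`, `expected_cost`, `expected_net_revenue`, ordered by
#'   (scenario, axis_value).
#' @examples
#' sweep_scenarios(c("SHXN-W", "RCXN-W"), "outbreak", load_config())
#' @export
sweep_scenarios <- function(scenarios, axis = c("outbreak", "resistance"),
                            config, grid = NULL, p_outbreak = NULL,
                            p_cross_resistant = 0) {
  axis <- match.arg(axis)
  axis_name <- paste0(
    if (axis == "outbreak") "outbreak" else "resistance", "_probability"
  )
  if (is.null(grid)) grid <- seq(0, 1, by = config$grid$step %||% 0.1)
  if (any(grid < 0 | grid > 1)) {
    stop("sweep grid values must lie in [0, 1]", call. = FALSE)
  }
  profiles <- lapply(config$probabilities$resistance_profiles, as.character)
  scenarios <- sort(vapply(scenarios, function(s) parse_scenario(s)$code,
                           character(1)))
  rows <- lapply(scenarios, function(code) {
    per <- lapply(grid, function(x) {
      ev <- if (axis == "outbreak") {
        evaluate_scenario(code, config, p_outbreak = x)
      } else {
        evaluate_scenario(
          code, config, p_outbreak = p_outbreak,
          mix = resistance_mix(x, p_cross_resistant, profiles)
        )
      }
      data.frame(
        scenario = code, axis = axis_name, axis_value = x,
        expected_yield = ev$expected_yield,
        expected_cost = ev$expected_cost,
        expected_net_revenue = ev$expected_net_revenue,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  out[order(out$scenario, out$axis_value), , drop = FALSE]
}

#' Rank scenarios by expected net revenue
#'
#' Descending by expected net revenue; ties broken by lower expected cost,
#' then lexicographic scenario code.
#'
#' @param scenarios character vector of scenario codes.
#' @param config an `ipm_config`.
#' @param p_outbreak,mix optional probability overrides as in
#'   [evaluate_scenario()].
#' @return `data.frame` with columns `rank`, `scenario`, `expected_yield`,
#'   `expected_cost`, `expected_net_revenue`.
#' @examples
#' rank_scenarios(enumerate_scenarios(load_config(), "W"), load_config(),
#'                p_outbreak = 0.435)
#' @export
rank_scenarios <- function(scenarios, config, p_outbreak = NULL, mix = NULL) {
  evs <- lapply(scenarios, function(code) {
    ev <- evaluate_scenario(code, config, p_outbreak = p_outbreak, mix = mix)
    data.frame(
      scenario = ev$scenario, expected_yield = ev$expected_yield,
      expected_cost = ev$expected_cost,
      expected_net_revenue = ev$expected_net_revenue,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, evs)
  out <- out[order(-out$expected_net_revenue, out$expected_cost,
                   out$scenario), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Apply a named sensitivity preset to a configuration
#'
#' Exactly one factor is modified, all others held constant. Preset
#' definitions live in the config's `sensitivity_presets` block; the Iowa
#' preset ships `yield_low` (3026 kg/ha), `yield_high` (4035 kg/ha),
#' `price_avg` (US$0.40/kg), `price_high` (US$0.52/kg), `tech_fee`
#' (herbicide-tolerance premium added to aphid-resistant seed) and
#' `input_scale_88` (all input costs scaled by 0.88).
#'
#' @param config an `ipm_config`.
#' @param preset preset name.
#' @return modified `ipm_config`.
#' @export
apply_sensitivity_preset <- function(config, preset) {
  presets <- config$sensitivity_presets
  if (!preset %in% names(presets)) {
    stop(sprintf(
      "unknown sensitivity preset '%s'; available: %s",
      preset, paste(names(presets), collapse = ", ")
    ), call. = FALSE)
  }
  spec <- presets[[preset]]
  if (!is.null(spec$yield_kg_ha)) {
    config$yield$attainable_kg_ha <- as.numeric(spec$yield_kg_ha)
  } else if (!is.null(spec$price_usd_per_kg)) {
    config$price$usd_per_kg <- as.numeric(spec$price_usd_per_kg)
  } else if (isTRUE(spec$apply_technology_fee)) {
    config <- apply_technology_fee(config)
  } else if (!is.null(spec$input_cost_factor)) {
    config <- apply_input_cost_scaling(config, spec$input_cost_factor)
  } else {
    stop(sprintf("sensitivity preset '%s' modifies no recognized factor",
                 preset), call. = FALSE)
  }
  config
}

#' Run a sensitivity analysis preset
#'
#' Recomputes the case-study break-even thresholds and probability sweeps
#' under the modified configuration: the wild-type outbreak-probability
#' crossings (insecticide vs no management, resistant variety vs no
#' management) and the resistance-probability crossings at the configured
#' outbreak probability.
#'
#' @param config an `ipm_config`.
#' @param preset preset name, see [apply_sensitivity_preset()].
#' @return an `ipm_sensitivity` list with `preset`, `config` (modified),
#'   `thresholds` (data frame), and `sweeps` (list of sweep data frames
#'   `wild`, `resistance`).
#' @examples
#' sensitivity_run(load_config(), "price_avg")$thresholds
#' @export
sensitivity_run <- function(config, preset) {
  cfg <- apply_sensitivity_preset(config, preset)
  pairs_outbreak <- list(
    c("SHPN-W", "SHXN-W"), c("SHPE-W", "SHXN-W"), c("RCXN-W", "SHXN-W")
  )
  pairs_resistance <- list(
    c("SHPN-I", "SHXN-I"), c("SHPE-I", "SHXN-I"), c("SHPE-I", "SHPN-I")
  )
  th <- lapply(pairs_outbreak, function(p) {
    breakeven_outbreak_probability(p[1], p[2], cfg)
  })
  th <- c(th, lapply(pairs_resistance, function(p) {
    breakeven_resistance_probability(p[1], p[2], cfg)
  }))
  thresholds <- do.call(rbind, lapply(th, function(x) {
    data.frame(
      scenario_a = x$scenario_a, scenario_b = x$scenario_b, axis = x$axis,
      crossing = x$crossing, crossing_pct = x$crossing_pct,
      favored_above = x$favored_above, stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      preset = preset, config = cfg, thresholds = thresholds,
      sweeps = list(
        wild = sweep_scenarios(c("SHXN-W", "SHPN-W", "SHPE-W", "RCXN-W"),
                               "outbreak", cfg),
        resistance = sweep_scenarios(c("SHXN-I", "SHPN-I", "SHPE-I", "RCXN-I"),
                                     "resistance", cfg)
      )
    ),
    class = "ipm_sensitivity"
  )
}

#' @export
print.ipm_sensitivity <- function(x, ...) {
  cat(sprintf("<ipm_sensitivity preset '%s'>\n", x$preset))
  print(x$thresholds, row.names = FALSE)
  invisible(x)
}
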