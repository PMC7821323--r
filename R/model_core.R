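# Expected-yield model: probability inputs, management-effectiveness rule
# engine, expected yield fraction, and the exhaustive outcome-tree expansion.

.PROB_TOL <- 1e-12
.POP_CLASSES <- c("wild", "resistant", "cross_resistant")

#' Outbreak probability distribution
#'
#' The season either has no pest outbreak (probability `p_no_outbreak`) or an
#' outbreak (probability `p_outbreak`); the two must sum to 1.
#'
#' @param p_outbreak probability of an outbreak, in \[0, 1\].
#' @return an `ipm_outbreak` object with fields `p_no_outbreak`, `p_outbreak`.
#' @export
outbreak_distribution <- function(p_outbreak) {
  p_outbreak <- as.numeric(p_outbreak)
  if (length(p_outbreak) != 1L || is.na(p_outbreak) ||
      p_outbreak < 0 || p_outbreak > 1) {
    stop("outbreak probabilities: p_outbreak must be a single value in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(p_no_outbreak = 1 - p_outbreak, p_outbreak = p_outbreak),
    class = "ipm_outbreak"
  )
}

as_outbreak <- function(x) {
  if (inherits(x, "ipm_outbreak")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(outbreak_distribution(x))
  if (is.list(x) && all(c("p_no_outbreak", "p_outbreak") %in% names(x))) {
    ps <- as.numeric(c(x$p_no_outbreak, x$p_outbreak))
    if (any(ps < 0) || any(ps > 1) || abs(sum(ps) - 1) > .PROB_TOL) {
      stop(sprintf(
        "outbreak probabilities: p_no_outbreak + p_outbreak must equal 1 (got %.15g)",
        sum(ps)
      ), call. = FALSE)
    }
    return(structure(list(p_no_outbreak = ps[1], p_outbreak = ps[2]),
                     class = "ipm_outbreak"))
  }
  stop("cannot interpret 'outbreak' as an outbreak distribution", call. = FALSE)
}

#' Resistance profiles: which insecticide groups each pest class survives
#'
#' The default profiles mirror the soybean aphid case study: wild-type aphids
#' survive nothing, pyrethroid-resistant aphids survive group 3A, and
#' cross-resistant aphids survive groups 3A and 1B (organophosphates). The
#' sets are nested: cross-resistant superset of resistant superset of
#' wild-type (empty).
#'
#' @return named list of character vectors of insecticide group codes.
#' @export
default_profiles <- function() {
  list(
    wild = character(0),
    resistant = "3A",
    cross_resistant = c("3A", "1B")
  )
}

#' Pest population mix conditional on an outbreak
#'
#' Given that an outbreak occurs, the pest population is wild-type (all
#' insecticides work), resistant (survives one group), or cross-resistant
#' (survives two groups); the three probabilities must sum to 1.
#'
#' @param p_wild,p_resistant,p_cross_resistant class probabilities, each in
#'   \[0, 1\], summing to 1.
#' @param profiles resistance profiles, see [default_profiles()].
#' @return an `ipm_population_mix`.
#' @export
population_mix <- function(p_wild, p_resistant = 0, p_cross_resistant = 0,
                           profiles = default_profiles()) {
  ps <- as.numeric(c(p_wild, p_resistant, p_cross_resistant))
  if (length(ps) != 3L || anyNA(ps) || any(ps < 0) || any(ps > 1)) {
    stop("population mix: each class probability must be in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(ps) - 1) > .PROB_TOL) {
    stop(sprintf(
      "population mix: p_wild + p_resistant + p_cross_resistant must equal 1 (got %.15g)",
      sum(ps)
    ), call. = FALSE)
  }
  if (!all(.POP_CLASSES %in% names(profiles))) {
    stop("population mix: resistance profiles must name wild, resistant and cross_resistant",
         call. = FALSE)
  }
  structure(
    list(p_wild = ps[1], p_resistant = ps[2], p_cross_resistant = ps[3],
         profiles = lapply(profiles[.POP_CLASSES], as.character)),
    class = "ipm_population_mix"
  )
}

as_population_mix <- function(x, profiles = default_profiles()) {
  if (inherits(x, "ipm_population_mix")) return(x)
  if (is.list(x)) {
    return(population_mix(
      p_wild = x$p_wild %||% 0,
      p_resistant = x$p_resistant %||% 0,
      p_cross_resistant = x$p_cross_resistant %||% 0,
      profiles = x$profiles %||% profiles
    ))
  }
  stop("cannot interpret 'mix' as a population mix", call. = FALSE)
}

#' Yield model: attainable yield and retained fraction on damage
#'
#' `retained_fraction` (q) is the proportion of attainable yield kept when an
#' outbreak occurs and management decisions result in yield loss, by variety
#' aphid trait. In the 2018 Iowa case study q = 0.873 for aphid-susceptible
#' varieties (12.7% loss) and q = 1 for aphid-resistant varieties.
#'
#' @param attainable_yield yield in kg/ha attainable absent an outbreak (> 0).
#' @param retained_fraction named numeric vector or list with entries `S` and
#'   `R`, each in (0, 1\].
#' @return an `ipm_yield_model`.
#' @export
yield_model <- function(attainable_yield,
                        retained_fraction = c(S = 0.873, R = 1)) {
  attainable_yield <- as.numeric(attainable_yield)
  if (length(attainable_yield) != 1L || is.na(attainable_yield) ||
      attainable_yield <= 0) {
    stop("attainable_yield must be a single positive value", call. = FALSE)
  }
  q <- unlist(retained_fraction)
  if (!all(c("S", "R") %in% names(q))) {
    stop("retained_fraction must have entries for variety traits 'S' and 'R'",
         call. = FALSE)
  }
  q <- vapply(q, as.numeric, numeric(1))
  if (any(q <= 0) || any(q > 1)) {
    stop("retained fractions q must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(attainable_yield = attainable_yield, retained_fraction = as.list(q)),
    class = "ipm_yield_model"
  )
}

#' Management outcome for one pest population class
#'
#' The rule engine behind the expected-yield indicator functions. For a
#' realized population class during an outbreak the outcome is:
#' * `"no_management"` — susceptible variety and no insecticide applied;
#' * `"effective"` — aphid-resistant variety, or at least one applied
#'   insecticide whose group the class does not survive;
#' * `"ineffective"` — insecticide(s) applied but the class survives all.
#'
#' The rescue (second) application counts as applied only when the plan's
#' rescue is enabled (efficacy scouting) *and* the class survives the first
#' application's group — efficacy scouting only triggers a rescue after an
#' observed failure.
#'
#' @param scenario scenario code or `ipm_scenario`.
#' @param plan an `ipm_spray_plan` (empty iff spray policy is X).
#' @param population_class one of `"wild"`, `"resistant"`,
#'   `"cross_resistant"`.
#' @param profiles resistance profiles, see [default_profiles()].
#' @return one of `"no_management"`, `"effective"`, `"ineffective"`.
#' @examples
#' management_effectiveness("RCXN-I", spray_plan(), "cross_resistant")
#' @export
management_effectiveness <- function(scenario, plan, population_class,
                                     profiles = default_profiles()) {
  s <- parse_scenario(scenario)
  if (!population_class %in% names(profiles) ||
      !population_class %in% .POP_CLASSES) {
    stop(sprintf("unknown population class '%s'", population_class),
         call. = FALSE)
  }
  apps <- plan$applications
  if (nrow(apps) > 2L) {
    stop("a maximum of two insecticide applications is allowed", call. = FALSE)
  }
  if (s$spray_policy == "X" && nrow(apps) > 0L) {
    stop("spray policy X requires an empty spray plan", call. = FALSE)
  }
  if (s$variety_aphid == "R") return("effective")
  if (nrow(apps) == 0L) return("no_management")

  survives <- as.character(profiles[[population_class]])
  first <- apps[apps$role == "first", , drop = FALSE]
  applied <- first$group
  first_fails <- all(first$group %in% survives)
  if (isTRUE(plan$rescue_enabled) && first_fails) {
    applied <- c(applied, apps$group[apps$role == "rescue"])
  }
  if (any(!applied %in% survives)) "effective" else "ineffective"
}

.outcome_fraction <- function(outcome, q) {
  if (outcome == "effective") 1 else q
}

#' Expected yield fraction under a scenario
#'
#' The proportion of attainable yield a farmer can expect: with probability
#' `p_n` no outbreak occurs (full yield); with probability `p_o` an outbreak
#' occurs and, for each population class `t` with conditional probability
#' `p_t`, the retained fraction is 1 when management is effective and the
#' variety's q when no management occurs or management is ineffective:
#'
#' \deqn{EY = p_n + p_o \sum_t p_t \left[ I(\mathrm{effective}_t) +
#'   q\, I(\mathrm{no\ mgmt}_t \lor \mathrm{ineffective}_t) \right]}
#'
#' @param scenario scenario code or `ipm_scenario`.
#' @param outbreak an `ipm_outbreak` or a single outbreak probability.
#' @param mix an `ipm_population_mix` (or list with `p_wild` etc.).
#' @param yields an `ipm_yield_model`.
#' @param plan an `ipm_spray_plan`.
#' @return expected yield fraction in \[min q, 1\].
#' @examples
#' ym <- yield_model(3537)
#' expected_yield_fraction("SHXN-W", 1, population_mix(1), ym, spray_plan())
#' @export
expected_yield_fraction <- function(scenario, outbreak, mix, yields, plan) {
  s <- parse_scenario(scenario)
  outbreak <- as_outbreak(outbreak)
  mix <- as_population_mix(mix)
  q <- yields$retained_fraction[[s$variety_aphid]]
  p_t <- c(mix$p_wild, mix$p_resistant, mix$p_cross_resistant)
  frac <- vapply(.POP_CLASSES, function(cl) {
    .outcome_fraction(management_effectiveness(s, plan, cl, mix$profiles), q)
  }, numeric(1))
  outbreak$p_no_outbreak + outbreak$p_outbreak * sum(p_t * frac)
}

#' Expected yield (kg/ha)
#'
#' [expected_yield_fraction()] multiplied by the attainable yield.
#'
#' @inheritParams expected_yield_fraction
#' @return expected yield in kg/ha.
#' @export
expected_yield <- function(scenario, outbreak, mix, yields, plan) {
  expected_yield_fraction(scenario, outbreak, mix, yields, plan) *
    yields$attainable_yield
}

#' Exhaustive outcome-tree expansion of the expected-yield sum
#'
#' Enumerates every elementary outcome (no outbreak; outbreak with each
#' population class of nonzero probability) with its probability and yield
#' fraction. The probability-weighted mean of `yield_fraction` equals
#' [expected_yield_fraction()] exactly, making this the brute-force oracle
#' for the closed-form evaluation.
#'
#' @inheritParams expected_yield_fraction
#' @return `data.frame` with columns `label`, `probability`, `yield_fraction`.
#' @export
enumerate_outcomes <- function(scenario, outbreak, mix, yields, plan) {
  s <- parse_scenario(scenario)
  outbreak <- as_outbreak(outbreak)
  mix <- as_population_mix(mix)
  q <- yields$retained_fraction[[s$variety_aphid]]
  labels <- character(0); probs <- numeric(0); fracs <- numeric(0)
  if (outbreak$p_no_outbreak > 0) {
    labels <- "no_outbreak"; probs <- outbreak$p_no_outbreak; fracs <- 1
  }
  p_t <- c(wild = mix$p_wild, resistant = mix$p_resistant,
           cross_resistant = mix$p_cross_resistant)
  for (cl in .POP_CLASSES) {
    p <- outbreak$p_outbreak * p_t[[cl]]
    if (p > 0) {
      out <- management_effectiveness(s, plan, cl, mix$profiles)
      labels <- c(labels, paste0("outbreak_", cl, "_", out))
      probs <- c(probs, p)
      fracs <- c(fracs, .outcome_fraction(out, q))
    }
  }
  data.frame(label = labels, probability = probs, yield_fraction = fracs,
             stringsAsFactors = FALSE)
}
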