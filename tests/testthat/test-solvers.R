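# Break-even solvers, sweeps, ranking and sensitivity analyses.

test_that("wild-type spray threshold matches the closed-form oracle", {
  be <- breakeven_outbreak_probability("SHPN-W", "SHXN-W", iowa)
  # extra spray cost / value of preventable loss
  oracle <- (22.88 + 20.02) / (0.127 * 3537 * 0.33)
  expect_equal(be$crossing, oracle, tolerance = 1e-9)
  expect_equal(be$crossing_pct, 29)
  expect_equal(be$favored_above, "SHPN-W")
})

test_that("free spraying weakly dominates from the origin", {
  cfg <- iowa
  cfg$costs$insecticide$mean <- 0
  cfg$costs$application_usd <- 0
  be <- breakeven_outbreak_probability("SHPN-W", "SHXN-W", cfg)
  expect_equal(be$crossing, 0, tolerance = 1e-9)
})

test_that("wild-type threshold falls at the ten-year-high price", {
  cfg <- apply_sensitivity_preset(iowa, "price_high")
  be <- breakeven_outbreak_probability("SHPN-W", "SHXN-W", cfg)
  expect_equal(be$crossing, 42.90 / (0.127 * 3537 * 0.52), tolerance = 1e-9)
  expect_equal(round(be$crossing, 4), 0.1837)
})

test_that("resistance threshold matches the closed-form oracle at both prices", {
  be <- breakeven_resistance_probability("SHPN-I", "SHXN-I", iowa)
  oracle <- 1 - (13.83 + 20.02) / (0.435 * 0.127 * 3537 * 0.33)
  expect_equal(be$crossing, oracle, tolerance = 1e-9)
  expect_equal(be$crossing_pct, 48)
  expect_equal(be$favored_above, "SHXN-I")

  cfg40 <- apply_sensitivity_preset(iowa, "price_avg")
  be40 <- breakeven_resistance_probability("SHPN-I", "SHXN-I", cfg40)
  expect_equal(be40$crossing,
               1 - 33.85 / (0.435 * 0.127 * 3537 * 0.40), tolerance = 1e-9)
  expect_equal(be40$crossing_pct, 57)
})

test_that("no crossing is reported when spraying never pays", {
  cfg <- iowa
  cfg$price$usd_per_kg <- 0.05
  be <- breakeven_resistance_probability("SHPN-I", "SHXN-I", cfg)
  expect_true(is.na(be$crossing))
  expect_equal(be$favored_above, "SHXN-I")
})

test_that("parallel revenue lines yield a diagnostic instead of a crossing", {
  be <- breakeven_outbreak_probability("SHPN-W", "SHPE-W", iowa)
  expect_true(is.na(be$crossing))
  expect_match(be$diagnostic, "parallel")
  # SHPN-W is cheaper by one efficacy-scouting activity
  expect_equal(be$favored_above, "SHPN-W")
})

test_that("closed-form crossings equal bisection roots on randomized configs", {
  set.seed(7)
  n_checked <- 0
  for (i in seq_len(500)) {
    cfg <- iowa
    cfg$price$usd_per_kg <- stats::runif(1, 0.1, 0.6)
    cfg$yield$attainable_kg_ha <- stats::runif(1, 2000, 5000)
    cfg$costs$insecticide$mean <- stats::runif(1, 5, 60)
    cfg$costs$insecticide[["3A"]] <- stats::runif(1, 5, 60)
    cfg$costs$application_usd <- stats::runif(1, 5, 40)
    axis_outbreak <- i %% 2 == 0
    be <- if (axis_outbreak) {
      breakeven_outbreak_probability("SHPN-W", "SHXN-W", cfg)
    } else {
      breakeven_resistance_probability("SHPN-I", "SHXN-I", cfg)
    }
    if (!is.na(be$crossing) && be$crossing > 0 && be$crossing < 1) {
      f <- function(x) {
        if (axis_outbreak) {
          expected_net_revenue("SHPN-W", cfg, p_outbreak = x) -
            expected_net_revenue("SHXN-W", cfg, p_outbreak = x)
        } else {
          expected_net_revenue("SHPN-I", cfg,
                               mix = list(p_wild = 1 - x, p_resistant = x)) -
            expected_net_revenue("SHXN-I", cfg,
                                 mix = list(p_wild = 1 - x, p_resistant = x))
        }
      }
      root <- stats::uniroot(f, c(0, 1), tol = 1e-13)$root
      expect_equal(be$crossing, root, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)  # the draws must actually exercise the check
})

test_that("sweeps produce ordered grids with the expected shapes", {
  sw <- sweep_scenarios(c("SHXN-W", "SHPN-W", "RCXN-W"), "outbreak", iowa)
  expect_equal(nrow(sw), 3 * 11)
  expect_equal(unique(sw$axis), "outbreak_probability")
  expect_equal(sw, sw[order(sw$scenario, sw$axis_value), ])

  shxn <- sw[sw$scenario == "SHXN-W", ]
  expect_true(all(diff(shxn$expected_net_revenue) < 0))
  expect_equal(shxn$expected_yield[shxn$axis_value == 1], 0.873 * 3537)

  rcxn <- sw[sw$scenario == "RCXN-W", ]
  expect_equal(var(rcxn$expected_net_revenue), 0)

  swr <- sweep_scenarios("RCXN-I", "resistance", iowa)
  expect_equal(var(swr$expected_net_revenue), 0)

  # revenue columns are affine along the axis
  for (cd in unique(sw$scenario)) {
    er <- sw$expected_net_revenue[sw$scenario == cd]
    expect_true(all(abs(diff(diff(er))) < 1e-9))
  }
  expect_error(sweep_scenarios("SHXN-W", "outbreak", iowa, grid = c(-0.1, 0.5)),
               "\\[0, 1\\]")
})

test_that("scenario ranking at the high-risk outbreak probability matches component sums", {
  r <- rank_scenarios(c("SHXN-W", "SHPN-W", "SHPE-W", "RCXN-W"), iowa,
                      p_outbreak = 0.435)
  expect_equal(r$scenario, c("RCXN-W", "SHPN-W", "SHPE-W", "SHXN-W"))
  expect_equal(r$expected_net_revenue, c(937.04, 879.48, 868.98, 857.8975),
               tolerance = 1e-4)
  # with no outbreak risk, not spraying wins on cost
  r0 <- rank_scenarios(c("SHXN-W", "SHPN-W"), iowa, p_outbreak = 0)
  expect_equal(r0$scenario[1], "SHXN-W")
})

test_that("ranking tie-breaks are stable and lexicographic", {
  cfg <- zero_cost_config()
  r <- rank_scenarios(c("SHPN-W", "RCXN-W", "SHPE-W"), cfg, p_outbreak = 0)
  expect_equal(r$scenario, sort(c("SHPN-W", "RCXN-W", "SHPE-W")))
})

test_that("sensitivity presets move thresholds in the documented directions", {
  base <- breakeven_outbreak_probability("SHPN-W", "SHXN-W", iowa)$crossing
  cr <- function(preset) {
    cfg <- apply_sensitivity_preset(iowa, preset)
    breakeven_outbreak_probability("SHPN-W", "SHXN-W", cfg)$crossing
  }
  expect_gt(cr("yield_low"), base)
  expect_lt(cr("yield_high"), base)
  expect_lt(cr("price_avg"), base)
  expect_lt(cr("price_high"), cr("price_avg"))
  expect_lt(cr("input_scale_88"), base)
  expect_equal(cr("input_scale_88"), base * 0.88, tolerance = 1e-9)
})

test_that("the technology fee makes resistant varieties pay only above a low outbreak probability", {
  cfg <- apply_sensitivity_preset(iowa, "tech_fee")
  be <- breakeven_outbreak_probability("RCXN-W", "SHXN-W", cfg)
  expect_gt(be$crossing, 0.10)
  expect_lt(be$crossing, 0.25)
  expect_equal(be$favored_above, "RCXN-W")
  # without the fee, the resistant variety dominates from the origin
  be0 <- breakeven_outbreak_probability("RCXN-W", "SHXN-W", iowa)
  expect_true(is.na(be0$crossing) || be0$crossing <= 0)
})

test_that("sensitivity_run reports thresholds and sweeps for a modified config", {
  rep <- sensitivity_run(iowa, "price_avg")
  expect_s3_class(rep, "ipm_sensitivity")
  row <- rep$thresholds[rep$thresholds$scenario_a == "SHPN-I" &
                          rep$thresholds$scenario_b == "SHXN-I", ]
  expect_equal(row$crossing, 0.5669, tolerance = 1e-4)
  expect_equal(row$crossing_pct, 57)
  expect_named(rep$sweeps, c("wild", "resistance"))
  expect_error(sensitivity_run(iowa, "nope"), "available")
})
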