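# Partial-budget economics against hand-summed Iowa 2018 table values.

test_that("expected application counts follow the spray policy and failure probability", {
  ob <- 0.435
  plan_w <- default_spray_plan("SHPN-W", iowa)
  expect_equal(expected_application_count("SHPN-W", plan_w, ob,
                                          population_mix(1)), 1)
  plan_e <- default_spray_plan("SHPE-I", iowa)
  expect_equal(
    expected_application_count("SHPE-I", plan_e, ob, population_mix(0.5, 0.5)),
    1 + 0.435 * 0.5
  )
  expect_equal(
    expected_application_count("SHXN-I", spray_plan(), ob,
                               population_mix(0.5, 0.5)),
    0
  )
  # prophylactic without efficacy scouting never re-applies
  plan_n <- default_spray_plan("SHPN-I", iowa)
  expect_equal(
    expected_application_count("SHPN-I", plan_n, ob, population_mix(0, 1)),
    1
  )
})

test_that("expected scouting activities: two early passes plus policy-driven additions", {
  ob <- 0.435
  expect_equal(expected_scouting_activities("SHXN-W", spray_plan(), ob,
                                            population_mix(1)), 2)
  expect_equal(
    expected_scouting_activities("SHPN-W", default_spray_plan("SHPN-W", iowa),
                                 ob, population_mix(1)),
    2
  )
  expect_equal(
    expected_scouting_activities("SHPE-I", default_spray_plan("SHPE-I", iowa),
                                 ob, population_mix(0.5, 0.5)),
    2 + 1 + 0.2175
  )
  cfg_m <- iowa
  expect_equal(
    expected_scouting_activities("SHTM-W", default_spray_plan("SHTM-W", cfg_m),
                                 ob, population_mix(1)),
    2 + 6
  )
})

test_that("expected variable costs reproduce the table sums", {
  # conventional herbicide 118.61 + aphid-resistant seed 111.56
  expect_equal(expected_cost("RCXN-W", iowa), 230.17)
  # HT herbicide 89.70 + HT seed 155.13 + mean insecticide 22.88 + application 20.02
  expect_equal(expected_cost("SHPN-W", iowa), 287.73)
  # class-priced pyrethroid + efficacy scouting + probabilistic rescue
  expect_equal(
    expected_cost("SHPE-I", iowa, mix = list(p_wild = 0.5, p_resistant = 0.5)),
    244.83 + 13.83 + 20.02 + 10.50 + 0.2175 * (21.98 + 20.02 + 10.50),
    tolerance = 1e-12
  )
  expect_equal(expected_cost("SHPN-W", zero_cost_config()), 0)
})

test_that("fixed costs add a scenario-independent constant", {
  fixed_sum <- sum(unlist(iowa$costs$fixed))
  expect_equal(fixed_sum, 39.70 + 43.61 + 73.39 + 21.00 + 120.83 + 548.56)
  for (cd in table1_scenarios) {
    for (p_o in c(0, 0.435, 1)) {
      expect_equal(
        expected_net_revenue(cd, iowa, p_outbreak = p_o) -
          expected_net_revenue(cd, iowa, p_outbreak = p_o,
                               include_fixed = TRUE),
        fixed_sum,
        tolerance = 1e-9
      )
    }
  }
})

test_that("expected net revenue matches hand-derived values", {
  expect_equal(expected_net_revenue("RCXN-W", iowa), 937.04)
  expect_equal(expected_net_revenue("SHXN-W", iowa, p_outbreak = 0),
               3537 * 0.33 - 244.83)
  zero <- zero_cost_config()
  zero$price$usd_per_kg <- 1e-12  # price effectively zero, validation needs > 0
  expect_equal(expected_net_revenue("SHXN-W", zero, p_outbreak = 0.435), 0,
               tolerance = 1e-6)
})

test_that("doubling the crop price doubles the gross term and leaves costs unchanged", {
  cfg2 <- iowa
  cfg2$price$usd_per_kg <- 2 * iowa$price$usd_per_kg
  for (cd in c("SHXN-W", "SHPE-I")) {
    ec1 <- expected_cost(cd, iowa)
    ec2 <- expected_cost(cd, cfg2)
    expect_equal(ec1, ec2)
    gross1 <- expected_net_revenue(cd, iowa) + ec1
    gross2 <- expected_net_revenue(cd, cfg2) + ec2
    expect_equal(gross2, 2 * gross1, tolerance = 1e-12)
  }
})

test_that("the cost audit itemization sums to the expected cost", {
  for (cd in table1_scenarios) {
    for (fx in c(FALSE, TRUE)) {
      audit <- cost_audit(cd, iowa, p_outbreak = 0.435,
                          mix = if (grepl("-I$", cd))
                            list(p_wild = 0.3, p_resistant = 0.7) else NULL,
                          include_fixed = fx)
      expect_equal(sum(audit$expected_cost),
                   expected_cost(cd, iowa, p_outbreak = 0.435,
                                 mix = if (grepl("-I$", cd))
                                   list(p_wild = 0.3, p_resistant = 0.7)
                                 else NULL,
                                 include_fixed = fx),
                   tolerance = 1e-12)
      expect_equal(audit$expected_cost,
                   audit$unit_cost * audit$expected_units)
    }
  }
})

test_that("expected cost is affine in outbreak and resistance probabilities", {
  grid <- seq(0, 1, by = 0.1)
  ec_po <- vapply(grid, function(p) expected_cost("SHPE-W", iowa,
                                                  p_outbreak = p), numeric(1))
  expect_true(all(abs(diff(diff(ec_po))) < 1e-10))
  ec_ps <- vapply(grid, function(ps) {
    expected_cost("SHPE-I", iowa, mix = list(p_wild = 1 - ps,
                                             p_resistant = ps))
  }, numeric(1))
  expect_true(all(abs(diff(diff(ec_ps))) < 1e-10))
})

test_that("technology fee derives from the seed table and applies to resistant seed", {
  expect_equal(technology_fee(iowa), 155.13 - 117.65)
  cfg <- apply_technology_fee(iowa)
  expect_equal(cfg$costs$seed[["R.C"]], 111.56 + 37.48)
  # original untouched
  expect_equal(iowa$costs$seed[["R.C"]], 111.56)
  flat <- iowa
  flat$costs$seed[["S.H"]] <- flat$costs$seed[["S.C"]]
  expect_equal(technology_fee(flat), 0)
  expect_equal(apply_technology_fee(flat)$costs$seed[["R.C"]],
               flat$costs$seed[["R.C"]])
  broken <- iowa
  broken$costs$seed[["S.H"]] <- NULL
  expect_error(technology_fee(broken), "S.H")
})

test_that("input cost scaling multiplies every cost and nothing else", {
  cfg <- apply_input_cost_scaling(iowa, 0.88)
  expect_equal(cfg$costs$insecticide$mean, 22.88 * 0.88)
  expect_equal(cfg$costs$fixed$land_rent, 548.56 * 0.88)
  expect_equal(cfg$yield$attainable_kg_ha, iowa$yield$attainable_kg_ha)
  expect_equal(cfg$price$usd_per_kg, iowa$price$usd_per_kg)
  expect_equal(cfg$probabilities$p_outbreak, iowa$probabilities$p_outbreak)
  expect_equal(expected_cost("SHPN-W", cfg), 287.73 * 0.88, tolerance = 1e-12)
  ident <- apply_input_cost_scaling(iowa, 1)
  expect_equal(expected_cost("SHPE-I", ident), expected_cost("SHPE-I", iowa))
  expect_error(apply_input_cost_scaling(iowa, 0), "positive")
  expect_error(apply_input_cost_scaling(iowa, -0.5), "positive")
})

test_that("missing cost keys produce errors naming the key", {
  cfg <- iowa
  cfg$costs$seed[["R.C"]] <- NULL
  expect_error(expected_cost("RCXN-W", cfg), "R.C")
  cfg2 <- iowa
  cfg2$costs$herbicide[["C"]] <- NULL
  expect_error(expected_cost("RCXN-W", cfg2), "herbicide")
})
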