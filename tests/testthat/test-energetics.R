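tab <- load_species_table()

test_that("species table loads with parsed, balanced formulas", {
  expect_setequal(tab$name, c("oxalate", "formate", "bicarbonate", "sulfate",
                              "methane", "bisulfide", "water"))
  expect_equal(tab$formula_list[[match("oxalate", tab$name)]],
               c(C = 2L, O = 4L))
  expect_error(suppressWarnings(load_species_table(tempfile())),
               "cannot open|No such|missing")
})

test_that("reference-state identity: every species returns its formation value at 25 C, 1 bar", {
  cond <- tp_condition(25, 1)
  for (nm in tab$name) {
    expect_equal(gibbs_species(nm, cond, table = tab),
                 tab$dG_f_ref_kJ[tab$name == nm],
                 tolerance = 1e-10, label = nm)
  }
})

test_that("water model reproduces reference density and dielectric values", {
  expect_equal(density_water(25, 1), 997.047, tolerance = 1e-3)
  expect_equal(dielectric_water(25, 1), 78.4, tolerance = 1e-3)
  # density decreases monotonically with temperature above the ~4 degC
  # density maximum (which the Kell polynomial reproduces)
  expect_gt(density_water(4, 1), density_water(2, 1))
  for (P in c(1.01, 250)) {
    rho <- vapply(seq(5, 100, by = 1), density_water, 1, pressure_bar = P)
    expect_true(all(diff(rho) < 0))
  }
  # determinism
  w1 <- water_properties(50, 100); w2 <- water_properties(50, 100)
  expect_identical(w1, w2)
})

test_that("conditions are validated and sub-saturation pressure is raised to Psat", {
  expect_error(tp_condition(150, 1), "outside validated range")
  expect_error(tp_condition(-5, 1), "outside validated range")
  expect_error(tp_condition(25, 600), "outside validated range")
  expect_error(tp_condition(25, 0.5), "outside validated range")
  expect_message(cond <- tp_condition(100, 1.01), "saturation")
  expect_gt(cond$pressure_bar, 1.01)
  expect_equal(cond$nominal_pressure_bar, 1.01)
  expect_silent(tp_condition(2, 1.01))
})

test_that("reaction balance validation passes the survey reactions and catches imbalance", {
  expect_silent(validate_reaction(reaction_oxalotrophy(), tab))
  expect_silent(validate_reaction(reaction_aom_sr(), tab))

  no_water <- reaction(c(oxalate = -1, formate = 1, bicarbonate = 1),
                       label = "missing water")
  expect_error(validate_reaction(no_water, tab), "H \\+2.*O \\+1|unbalanced")

  expect_error(validate_reaction(reaction_ocp_schematic(), tab),
               "CHO.*schematic|not in the table")
})

test_that("null reactions and stoichiometric identities behave exactly", {
  cond <- tp_condition(50, 250)
  # a species minus itself cancels exactly
  dg_f <- gibbs_species("formate", cond, table = tab)
  expect_equal(dg_f - dg_f, 0)

  rx <- reaction_oxalotrophy()
  rev_rx <- reaction(-rx$stoichiometry, label = "reverse")
  scl_rx <- reaction(3 * rx$stoichiometry, label = "x3")
  dg <- delta_g_standard(rx, cond, table = tab)
  expect_equal(delta_g_standard(rev_rx, cond, table = tab), -dg)
  expect_equal(delta_g_standard(scl_rx, cond, table = tab), 3 * dg,
               tolerance = 1e-12)
})

test_that("activity corrections follow dG = dG0 + RT lnQ", {
  rx <- reaction_oxalotrophy()
  cond <- tp_condition(25, 1)

  r_unit <- delta_g(rx, cond, activity_set(), table = tab)
  expect_equal(r_unit$dG_r, r_unit$dG0_r)
  expect_equal(r_unit$lnQ, 0)

  # raising one product activity tenfold at 25 C costs RT ln 10 = 5.708 kJ
  r10 <- delta_g(rx, cond, activity_set(formate = 10), table = tab)
  expect_equal(r10$dG_r - r10$dG0_r, 8.3145 * 298.15 * log(10) / 1000,
               tolerance = 1e-9)
  expect_equal(r10$dG_r - r_unit$dG_r, 5.708, tolerance = 1e-3)

  # closed-form quotient at 100 C with the survey's activities
  cond100 <- suppressMessages(tp_condition(100, 1.01))
  r <- delta_g(rx, cond100,
               activity_set(water = 1, formate = 1e-5,
                            bicarbonate = 2e-3, oxalate = 1e-6),
               table = tab)
  expect_equal(r$lnQ, log(0.02), tolerance = 1e-12)
  expect_equal(r$dG_r - r$dG0_r, 8.3145 * 373.15 * log(0.02) / 1000,
               tolerance = 1e-9)

  expect_error(activity_set(oxalate = -1), "positive")
  expect_warning(delta_g(rx, cond, activity_set(sulfate = 2), table = tab),
                 "ignored")
})

test_that("species Gibbs surfaces are smooth in temperature", {
  # half-degree steps: increments bounded by the molar entropy scale, and
  # second differences (curvature) orders of magnitude smaller
  for (nm in c("bicarbonate", "oxalate", "methane")) {
    g <- vapply(seq(2, 100, by = 0.5), function(tc)
      gibbs_species(nm, tp_condition(tc, 250), table = tab), 1)
    expect_lt(max(abs(diff(g))), 0.1)
    expect_lt(max(abs(diff(diff(g)))), 5e-4)
  }
})

test_that("missing HKF parameters are reported by species and field", {
  tab2 <- tab
  tab2$c1[tab2$name == "formate"] <- NA
  expect_error(gibbs_species("formate", tp_condition(25, 1), table = tab2),
               "formate.*c1")
  expect_error(gibbs_species("unobtainium", tp_condition(25, 1), table = tab),
               "unknown species")
})

test_that("the default grid has the survey layout", {
  g <- default_tp_grid()
  expect_equal(nrow(g), 8L)
  expect_setequal(unique(g$temperature_C), c(2, 20, 50, 100))
  expect_setequal(unique(g$pressure_bar), c(1.01, 250))

  single <- tp_grid(list(eq2 = reaction_oxalotrophy()),
                    conditions = data.frame(temperature_C = 25,
                                            pressure_bar = 1),
                    table = tab)
  expect_equal(nrow(single), 1L)
  expect_true("dG0_eq2" %in% names(single))
})
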