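test_that("ledger totals equal hand sums on a three-reaction chain", {
  # A[e] -> A -> B -> (sink), with one NADH made by R1 and burnt by R2
  mets <- data.frame(id = c("A", "A", "B", "nad", "nadh"),
                     name = "", compartment = c("e", "c", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "At", "R1", "R2", "SINK"),
                     name = "", lb = 0, ub = 1000, gpr = "",
                     subsystem = c("exchange", "transport", "", "", "biomass"),
                     stringsAsFactors = FALSE)
  stoich <- list(
    parse_equation("-1 A[e] ->")$stoich,
    parse_equation("-1 A[e] -> 1 A[c]")$stoich,
    parse_equation("-1 A[c] + -1 nad[c] -> 1 B[c] + 1 nadh[c]")$stoich,
    parse_equation("-1 nadh[c] -> 1 nad[c]")$stoich,
    parse_equation("-1 B[c] ->")$stoich)
  chain <- metabolic_model(mets, rxns, stoich, "SINK")
  sol <- solve_pfba(chain, set_uptake(condition_spec(), "EX_A", 4))
  led <- build_ledger(chain, sol, "nadh", "c")
  expect_equal(led$produced, 4)
  expect_equal(led$consumed, 4)
  expect_setequal(led$contributions$reaction, c("R1", "R2"))
  expect_equal(led$contributions$contribution[led$contributions$reaction == "R1"], 4)
  expect_equal(led$contributions$contribution[led$contributions$reaction == "R2"], -4)
})

test_that("production equals consumption for every internal metabolite", {
  toy <- the_toy()
  sol <- solve_pfba(toy, toy_condition(5, our = 2.33, xr_ratio = 0.94))
  internal <- toy$metabolites$key[toy$metabolites$compartment != "e"]
  for (key in internal) {
    contrib <- as.numeric(toy$stoich[key, ]) * sol$fluxes
    expect_lt(abs(sum(contrib[contrib > 0]) + sum(contrib[contrib < 0])), 1e-6)
  }
  # and the ledger view agrees for the headline cofactors
  for (cf in list(c("nadh", "c"), c("nadph", "c"), c("q6h2", "m"))) {
    led <- build_ledger(toy, sol, cf[1], cf[2])
    expect_equal(led$produced, led$consumed, tolerance = 1e-6)
  }
})

test_that("ledger deltas subtract per reaction and in total", {
  toy <- the_toy()
  sol_a <- solve_pfba(toy, toy_condition(5, our = 2.33, xr_ratio = 0.94))
  sol_b <- solve_pfba(toy, toy_condition(5, our = 1.42, xr_ratio = 0.11))
  for (cf in list(c("nadph", "c"), c("q6h2", "m"))) {
    la <- build_ledger(toy, sol_a, cf[1], cf[2])
    lb <- build_ledger(toy, sol_b, cf[1], cf[2])
    d <- ledger_delta(la, lb)
    expect_equal(d$produced_change, lb$produced - la$produced, tolerance = 1e-9)
    # additivity: the signed per-reaction changes sum to the net total change
    expect_equal(sum(d$contributions$change),
                 d$produced_change - d$consumed_change, tolerance = 1e-6)
  }
  # the NADPH supply contracts as the cofactor preference shifts to NADH
  la <- build_ledger(toy, sol_a, "nadph", "c")
  lb <- build_ledger(toy, sol_b, "nadph", "c")
  expect_lt(ledger_delta(la, lb)$produced_change, 0)

  # identical conditions give an all-zero delta
  d0 <- ledger_delta(la, la)
  expect_equal(d0$produced_change, 0)
  expect_true(all(abs(d0$contributions$change) < 1e-12))
})

test_that("oxidative-PPP steps shift NADPH production by equal amounts", {
  # the two dehydrogenase steps carry the same linear oxPPP flux, so their
  # per-reaction NADPH contributions change identically between conditions;
  # in the toy the lumped oxPPP carries it all, so its contribution change
  # equals the total production change
  toy <- the_toy()
  la <- build_ledger(toy, solve_pfba(toy, toy_condition(5, our = 2.33,
                                                        xr_ratio = 0.94)),
                     "nadph", "c")
  lb <- build_ledger(toy, solve_pfba(toy, toy_condition(5, our = 1.42,
                                                        xr_ratio = 0.11)),
                     "nadph", "c")
  d <- ledger_delta(la, lb)
  oxppp <- d$contributions$change[d$contributions$reaction == "OXPPP"]
  expect_equal(oxppp, d$produced_change, tolerance = 1e-9)
})

test_that("unknown cofactors and mismatched deltas error", {
  toy <- the_toy()
  sol <- solve_pfba(toy, toy_condition(5))
  expect_error(build_ledger(toy, sol, "nadh", "x"), "unknown cofactor")
  la <- build_ledger(toy, sol, "nadh", "c")
  lb <- build_ledger(toy, sol, "nadph", "c")
  expect_error(ledger_delta(la, lb), "different cofactors")
})

test_that("shuttle fluxes aggregate their defining reactions", {
  toy <- the_toy()
  sol <- solve_pfba(toy, toy_condition(5))
  sh <- toy_shuttles()
  # single-reaction shuttle equals that reaction's flux
  expect_equal(shuttle_flux(toy, sol, sh$NADHDH), sol$fluxes[["NADHDH"]])
  # pFBA leaves the 2-step shuttle idle under the aerobic reference
  expect_equal(shuttle_flux(toy, sol, sh$GLYC3P), 0, tolerance = 1e-8)
  expect_error(shuttle_flux(toy, sol, character(0)), "empty shuttle")
  expect_error(shuttle_flux(toy, sol, c(NOPE = 1)), "unknown")
})

test_that("the NADH shuttles shrink and the GLU shuttle can absorb NADPH under downshift", {
  toy <- the_toy()
  sol_a <- solve_pfba(toy, toy_condition(5, our = 2.33, xr_ratio = 0.94))
  sol_b <- solve_pfba(toy, toy_condition(5, our = 1.42, xr_ratio = 0.11))
  sh <- toy_shuttles()
  nadh_a <- shuttle_flux(toy, sol_a, sh$NADHDH) +
    shuttle_flux(toy, sol_a, sh$GLYC3P)
  nadh_b <- shuttle_flux(toy, sol_b, sh$NADHDH) +
    shuttle_flux(toy, sol_b, sh$GLYC3P)
  expect_lt(nadh_b, nadh_a)
})

test_that("the GLU shuttle lump is a net transhydrogenase per unit flux", {
  toy <- the_toy()
  s <- reaction_stoich(toy, "GLUSH")
  expect_equal(s[["nadh[c]"]], -1)
  expect_equal(s[["nadph[c]"]], -1)
  expect_equal(s[["nadh[m]"]], 2)
  expect_equal(s[["nad[c]"]] + s[["nadp[c]"]], 2)   # carriers returned oxidised
  expect_equal(s[["nad[m]"]], -2)
})

test_that("electron accounting relates the quinol shift to the oxygen cut", {
  # the in-paper analytic case: a 1.79 mmol/gCDW/h quinol-production drop
  # against an oxygen downshift from 2.33 to 1.42 covers ~98% of the lost
  # electron-acceptor capacity
  expect_equal(electron_accounting(-1.79, 2.33, 1.42), 98.35165,
               tolerance = 1e-6)
  expect_equal(electron_accounting(-2 * 0.91, 2.33, 1.42), 100)
  expect_equal(electron_accounting(0, 2.33, 1.42), 0)
  expect_error(electron_accounting(1, 2, 2), "undefined")
})
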