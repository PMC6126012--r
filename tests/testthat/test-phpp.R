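test_that("grid cells equal independent per-cell FBA solves", {
  toy <- the_toy()
  subs <- c(2, 3.5, 5)
  o2 <- c(3, 6, 9)
  grid <- compute_phpp(toy, "EX_XYL", "EX_O2", substrate = subs, o2 = o2,
                       observables = c(ethanol = "EX_ETOH"))
  for (i in seq_along(subs)) for (j in seq_along(o2)) {
    sol <- solve_pfba(toy, toy_condition(subs[i], our = o2[j]))
    expect_equal(grid$surfaces$growth[i, j], sol$objective, tolerance = 1e-9)
    expect_equal(grid$surfaces$ethanol[i, j], sol$fluxes[["EX_ETOH"]],
                 tolerance = 1e-8)
  }
})

test_that("a zero-substrate row grows nowhere and infeasible cells stay NA", {
  toy <- the_toy()
  grid <- compute_phpp(toy, "EX_XYL", "EX_O2", substrate = c(0, 5),
                       o2 = c(0, 2, 6))
  # without carbon there is never growth: a cell is either the zero flux
  # vector (both uptakes zero) or infeasible (forced oxygen has no sink),
  # and infeasible cells are marked NA rather than zero-filled
  expect_equal(grid$surfaces$growth[1, 1], 0, tolerance = 1e-9)
  expect_false(any(grid$surfaces$growth[1, ] > 1e-9, na.rm = TRUE))
  expect_true(all(is.na(grid$surfaces$growth[1, !grid$feasible[1, ]])))
  # fixed xylose with zero oxygen cannot pay the uptake ATP cost
  expect_false(grid$feasible[2, 1])
  expect_true(is.na(grid$surfaces$growth[2, 1]))
})

test_that("xylitol secretion peaks at interior oxygen limitation", {
  toy <- the_toy()
  cond <- condition_spec()
  cond <- add_ratio_coupling(cond, "XYLR2", "XYLR1", 0.94)
  grid <- compute_phpp(toy, "EX_XYL", "EX_O2", substrate = 5,
                       o2 = seq(0, 12, by = 0.5),
                       observables = c(xylitol = "EX_XYLT"),
                       condition = cond)
  x <- grid$surfaces$xylitol[1, ]
  feas <- grid$feasible[1, ]
  peak <- which.max(ifelse(feas, x, -Inf))
  # the peak is at an oxygen-limited interior point: not the anaerobic edge
  # (infeasible for growth) and not the oxygen-excess side
  expect_gt(x[peak], 0.05)
  expect_gt(grid$o2[peak], 0)
  expect_lt(grid$o2[peak], 9)            # strictly below the LO oxygen level
  expect_false(feas[1])                  # no growth at zero oxygen
  expect_lt(max(x[grid$o2 > 9]), 1e-6)   # fully aerobic: no xylitol
})

test_that("growth along an oxygen transect rises to the LO then falls", {
  toy <- the_toy()
  grid <- compute_phpp(toy, "EX_XYL", "EX_O2", substrate = 5,
                       o2 = seq(1, 13, by = 1))
  g <- grid$surfaces$growth[1, ]
  k <- which.max(g)
  expect_true(all(diff(g[1:k]) > -1e-9))
  expect_true(all(diff(g[k:length(g)]) < 1e-9))
  # the optimum sits at the closed-form LO oxygen demand
  expect_equal(grid$o2[k], 5 * toy_closed_form(0)$lo_slope, tolerance = 0.11)
})

test_that("phase segmentation finds the expected phenotype regions", {
  toy <- the_toy()
  cond <- add_ratio_coupling(condition_spec(), "XYLR2", "XYLR1", 0.94)
  grid <- compute_phpp(toy, "EX_XYL", "EX_O2",
                       substrate = seq(1, 5, length.out = 6),
                       o2 = seq(0.5, 12, length.out = 10),
                       observables = c(co2 = "EX_CO2", ethanol = "EX_ETOH",
                                       xylitol = "EX_XYLT"),
                       condition = cond)
  phase <- segment_phases(grid)
  expect_gte(attr(phase, "n_phases"), 3)

  # a window inside the oxygen-excess region is a single phase
  sub <- compute_phpp(toy, "EX_XYL", "EX_O2", substrate = c(4.5, 5),
                      o2 = c(9.8, 10.5, 11),
                      observables = c(co2 = "EX_CO2", ethanol = "EX_ETOH",
                                      xylitol = "EX_XYLT"),
                      condition = cond)
  expect_identical(attr(segment_phases(sub), "n_phases"), 1L)
})

test_that("phase count is stable under grid refinement", {
  toy <- the_toy()
  cond <- add_ratio_coupling(condition_spec(), "XYLR2", "XYLR1", 0.94)
  obs <- c(ethanol = "EX_ETOH", xylitol = "EX_XYLT")
  g1 <- compute_phpp(toy, "EX_XYL", "EX_O2",
                     substrate = seq(2, 5, length.out = 4),
                     o2 = seq(1, 12, length.out = 8),
                     observables = obs, condition = cond)
  g2 <- compute_phpp(toy, "EX_XYL", "EX_O2",
                     substrate = seq(2, 5, length.out = 8),
                     o2 = seq(1, 12, length.out = 16),
                     observables = obs, condition = cond)
  expect_identical(attr(segment_phases(g1), "n_phases"),
                   attr(segment_phases(g2), "n_phases"))
})

test_that("the line of optimality matches the hand-derived electron balance", {
  toy <- the_toy()
  lo <- find_lo(toy, "EX_XYL", 1:5, "EX_O2")
  expect_equal(lo$slope, toy_closed_form(0)$lo_slope, tolerance = 1e-8)
  expect_lt(lo$residual, 1e-8)
  expect_gt(lo$slope, 0)

  # with the cofactor-preference coupling active the closed form shifts
  cond <- add_ratio_coupling(condition_spec(), "XYLR2", "XYLR1", 0.94)
  lo2 <- find_lo(toy, "EX_XYL", 1:5, "EX_O2", condition = cond)
  expect_equal(lo2$slope, toy_closed_form(0.94)$lo_slope, tolerance = 1e-8)
})

test_that("the LO slope is invariant to rescaling the uptake values", {
  toy <- the_toy()
  lo1 <- find_lo(toy, "EX_XYL", 1:5, "EX_O2")
  lo2 <- find_lo(toy, "EX_XYL", 2 * (1:5), "EX_O2")
  expect_equal(lo1$slope, lo2$slope, tolerance = 1e-9)
})

test_that("an infeasible LO point is reported by uptake value", {
  toy <- the_toy()
  cond <- set_bound(condition_spec(), "OXPHOS", 0, 0)  # no respiration
  expect_error(find_lo(toy, "EX_XYL", c(1, 2), "EX_O2", condition = cond),
               "infeasible LO point")
})

test_that("all active fluxes scale proportionally along the LO", {
  toy <- the_toy()
  base <- solve_pfba(toy, toy_condition(5))
  for (u in c(1, 2.5)) {
    sol <- solve_pfba(toy, toy_condition(u))
    expect_lt(max(abs(sol$fluxes - (u / 5) * base$fluxes)), 1e-6)
  }
})
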