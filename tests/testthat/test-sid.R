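sweep_endpoints <- function(our = c(2.33, 1.42), ratio = c(0.94, 0.11),
                            xylose = 5) {
  list(a = toy_condition(xylose, our = our[1], xr_ratio = ratio[1]),
       b = toy_condition(xylose, our = our[2], xr_ratio = ratio[2]))
}

test_that("sweeps interpolate every varied scalar linearly with exact endpoints", {
  ep <- sweep_endpoints()
  sweep <- design_sweep(ep$a, ep$b, n = 10)
  expect_length(sweep, 10)
  expect_equal(sweep[[1]]$bounds[["EX_O2"]], c(-2.33, -2.33))
  expect_equal(sweep[[10]]$bounds[["EX_O2"]], c(-1.42, -1.42))
  expect_equal(sweep[[1]]$couplings$ratio, 0.94)
  expect_equal(sweep[[10]]$couplings$ratio, 0.11)
  ours <- vapply(sweep, function(cc) -cc$bounds[["EX_O2"]][1], numeric(1))
  expect_equal(ours, seq(2.33, 1.42, length.out = 10), tolerance = 1e-12)

  # n = 3: the midpoint is the arithmetic mean of the endpoints
  mid <- design_sweep(ep$a, ep$b, n = 3)[[2]]
  expect_equal(mid$bounds[["EX_O2"]], c(-1.875, -1.875))
  expect_equal(mid$couplings$ratio, (0.94 + 0.11) / 2)

  # identical endpoints give n identical conditions
  same <- design_sweep(ep$a, ep$a, n = 4)
  for (cc in same) expect_equal(cc, ep$a)
})

test_that("mismatched endpoint structures are rejected", {
  ep <- sweep_endpoints()
  other <- set_bound(ep$b, "ATPM", 1, 1)
  expect_error(design_sweep(ep$a, other, 5), "different bound overrides")
  no_coupling <- toy_condition(5, our = 1.42)
  expect_error(design_sweep(ep$a, no_coupling, 5), "different couplings")
})

test_that("flux matrices hold one pFBA row per condition and abort on infeasible steps", {
  toy <- the_toy()
  ep <- sweep_endpoints()
  sweep <- design_sweep(ep$a, ep$b, n = 5)
  fm <- assemble_flux_matrix(toy, sweep)
  expect_identical(dim(fm), c(5L, nrow(toy$reactions)))
  expect_false(anyNA(fm))
  one <- solve_pfba(toy, sweep[[3]])
  expect_equal(fm[3, ], one$fluxes, tolerance = 1e-9)

  single <- assemble_flux_matrix(toy, sweep[2])
  expect_identical(nrow(single), 1L)

  bad <- design_sweep(toy_condition(5, our = 2),
                      toy_condition(5, our = 0), n = 4)
  expect_error(assemble_flux_matrix(toy, bad), "condition 4 .*infeasible")
})

test_that("bounds-only sweeps within one phase give affine flux columns", {
  toy <- the_toy()
  sweep <- design_sweep(toy_condition(5, our = 2.33, xr_ratio = 0.94),
                        toy_condition(5, our = 1.42, xr_ratio = 0.94),
                        n = 8)
  fm <- assemble_flux_matrix(toy, sweep)
  t <- seq_len(nrow(fm))
  resid <- apply(fm, 2, function(col)
    max(abs(stats::lm.fit(cbind(1, t), col)$residuals)))
  expect_lt(max(resid), 1e-6)
})

test_that("PCA explains a rank-1 matrix with a single component", {
  set.seed(7)
  X <- outer(rnorm(6), rnorm(9))
  colnames(X) <- paste0("R", 1:9)
  p <- run_pca(X, center = FALSE)
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(p$loadings[, 1]^2)), 1, tolerance = 1e-12)
})

test_that("a within-phase linear sweep is one principal component", {
  toy <- the_toy()
  sweep <- design_sweep(toy_condition(5, our = 2.33, xr_ratio = 0.94),
                        toy_condition(5, our = 1.42, xr_ratio = 0.94),
                        n = 6)
  p <- run_pca(assemble_flux_matrix(toy, sweep))
  expect_gte(p$variance_fraction[1], 0.999)
})

test_that("loadings match an independent eigendecomposition of the covariance", {
  toy <- the_toy()
  ep <- sweep_endpoints()
  fm <- assemble_flux_matrix(toy, design_sweep(ep$a, ep$b, 6))
  p <- run_pca(fm)
  ev <- eigen(stats::cov(fm), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  if (sum(v1 * p$loadings[, 1]) < 0) v1 <- -v1
  expect_lt(max(abs(p$loadings[, 1] - v1)), 1e-9)
  expect_equal(p$variance_fraction[1],
               ev$values[1] / sum(pmax(ev$values, 0)), tolerance = 1e-9)
})

test_that("a zero-variance matrix is flagged degenerate with unit fraction", {
  X <- matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- run_pca(X)
  expect_true(p$degenerate)
  expect_equal(p$variance_fraction, 1)
  expect_true(all(p$loadings == 0))
})

test_that("loading ranks are deterministic with lexicographic tie-breaks", {
  toy <- the_toy()
  ep <- sweep_endpoints()
  p <- run_pca(assemble_flux_matrix(toy, design_sweep(ep$a, ep$b, 6)))
  r1 <- rank_loadings(p, 1, 5)
  r2 <- rank_loadings(p, 1, 5)
  expect_identical(r1, r2)
  expect_true(all(diff(-abs(r1$loading)) >= -1e-15))
  # truncation beyond the reaction count
  expect_identical(nrow(rank_loadings(p, 1, 10000)), nrow(toy$reactions))
  # all-equal loadings order purely lexicographically
  X <- matrix(c(0, 1), 2, 4, dimnames = list(NULL, c("d", "b", "a", "c")))
  pt <- run_pca(X)
  expect_identical(rank_loadings(pt, 1, 4)$reaction, c("a", "b", "c", "d"))
})

test_that("response classes reproduce the oxygen-downshift motifs", {
  toy <- the_toy()
  # sweep from mild oxygen limitation into strong limitation with the
  # cofactor preference relaxing toward NADH
  sweep <- design_sweep(toy_condition(5, our = 1.0, xr_ratio = 0.94),
                        toy_condition(5, our = 1.42, xr_ratio = 0.11),
                        n = 6)
  fm <- assemble_flux_matrix(toy, sweep)
  cls <- classify_response(fm)
  expect_identical(unname(cls[["EX_XYLT"]]), "down")
  # downshift sweep at fixed preference: fermentation up, respiration down
  sweep2 <- design_sweep(toy_condition(5, our = 2.33, xr_ratio = 0.94),
                         toy_condition(5, our = 1.42, xr_ratio = 0.11),
                         n = 6)
  cls2 <- classify_response(assemble_flux_matrix(toy, sweep2))
  expect_identical(unname(cls2[["EX_ETOH"]]), "up")
  expect_identical(unname(cls2[["GLYCL"]]), "up")
  expect_identical(unname(cls2[["OXPPP"]]), "down")
  expect_identical(unname(cls2[["NADHDH"]]), "down")
  expect_identical(unname(cls2[["OXPHOS"]]), "down")
  # an all-zero column is inactive
  expect_identical(unname(cls2[["GPD"]]), "inactive")
})

test_that("classification swaps up/down when the sweep is reversed", {
  toy <- the_toy()
  ep <- sweep_endpoints()
  fwd <- classify_response(assemble_flux_matrix(toy, design_sweep(ep$a, ep$b, 5)))
  rev <- classify_response(assemble_flux_matrix(toy, design_sweep(ep$b, ep$a, 5)))
  swap <- c(up = "down", down = "up", inactive = "inactive")
  expect_identical(as.vector(swap[fwd]), as.vector(rev))
})

test_that("pinning a reaction to its own solution changes nothing", {
  toy <- the_toy()
  sweep <- design_sweep(toy_condition(5, our = 2.33, xr_ratio = 0.94),
                        toy_condition(5, our = 1.42, xr_ratio = 0.94), 4)
  fm <- assemble_flux_matrix(toy, sweep)
  pinned <- force_behavior(toy, sweep, "OXPPP", fm[, "OXPPP"])
  fm2 <- assemble_flux_matrix(toy, pinned)
  expect_equal(fm2, fm, tolerance = 1e-7)
})

test_that("forced-behavior probes surface the compensating reactions", {
  toy <- the_toy()
  # force oxidative-PPP flux proportional to oxygen uptake, well beyond what
  # the unforced optimum would use, and ask which reactions respond most
  ours <- seq(6, 9, length.out = 5)
  sweep <- lapply(ours, function(o) toy_condition(5, our = o))
  pinned <- force_behavior(toy, sweep, "OXPPP", 0.9 * ours)
  fm <- assemble_flux_matrix(toy, pinned)
  p <- run_pca(fm)
  top <- rank_loadings(p, 1, 8)$reaction
  # the NADPH forced out of the oxidative branch has to be absorbed; with
  # the NADPH-XR route saturated, the transhydrogenase-like GLU shuttle is
  # the distant reaction that compensates, and the probe surfaces it
  expect_true("GLUSH" %in% top)
  expect_identical(unname(classify_response(fm)[["GLUSH"]]), "up")
})

test_that("pinning a blocked reaction to non-zero flux errors with its step", {
  toy <- the_toy()
  sweep <- design_sweep(toy_condition(5, our = 2.33, xr_ratio = 0.94),
                        toy_condition(5, our = 1.42, xr_ratio = 0.94), 3)
  # GPD cannot carry 500 given the quinone pool and oxygen supplied
  expect_error(force_behavior(toy, sweep, "GPD", c(0, 0, 500)),
               "infeasible at sweep step 3")
})

test_that("profile length must match the sweep", {
  toy <- the_toy()
  sweep <- design_sweep(toy_condition(5, our = 2), toy_condition(5, our = 3), 4)
  expect_error(force_behavior(toy, sweep, "OXPPP", c(1, 2)), "length")
})
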