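# Fitting culture conditions to a measured ethanol yield.
#
# The measured quantity is the molar ethanol yield Y_E/S = ethanol secretion
# flux / substrate uptake flux.  The oxygen uptake rate (OUR) and the xylose
# reductase cofactor-preference ratio r (NADPH-route flux = r * NADH-route
# flux) are tuned so the model yield matches the measurement; the xylitol
# secretion predicted at the fitted point is then reported.

#' Ethanol yield of the model at one (OUR, ratio) point
#'
#' @keywords internal
#' @noRd
.yield_at <- function(model, our, ratio, substrate_id, substrate_uptake,
                      o2_id, xr_nadph, xr_nadh, ethanol_id, base_condition) {
  cond <- set_uptake(base_condition, substrate_id, substrate_uptake)
  cond <- set_uptake(cond, o2_id, our)
  cond <- add_ratio_coupling(cond, xr_nadph, xr_nadh, ratio)
  sol <- solve_pfba(model, cond)
  if (!identical(sol$status, "optimal")) return(NULL)
  list(yield = sol$fluxes[[ethanol_id]] / substrate_uptake, solution = sol)
}

#' Fit oxygen uptake and XR cofactor ratio to an ethanol yield
#'
#' Coarse grid search over (OUR, ratio), then golden-section refinement of
#' each axis around the best grid point, minimising `|Y_pred - Y_target|`.
#' Among near-equal optima the smallest OUR wins, ties broken by smaller
#' ratio.  The xylitol secretion at the fitted point is read from the
#' parsimonious representative.
#'
#' @param model a [metabolic_model()].
#' @param y_target measured molar ethanol yield (mol ethanol / mol substrate).
#' @param substrate_id,o2_id exchange reaction ids of substrate and oxygen.
#' @param substrate_uptake fixed substrate uptake (mmol/gCDW/h).
#' @param xr_nadph,xr_nadh reaction ids of the NADPH- and NADH-dependent
#'   xylose reductase routes (coupled as `v_nadph = ratio * v_nadh`).
#' @param ethanol_id,xylitol_id exchange reaction ids of ethanol and xylitol.
#' @param our_range,ratio_range search intervals.
#' @param n_grid coarse grid points per axis (default 41).
#' @param tol stop refining when the yield residual is below this.
#' @param max_refine refinement sweeps over the two axes.
#' @param base_condition extra constraints applied throughout.
#' @return A `fit_result`: `our`, `ratio`, `yield`, `xylitol`, `residual`,
#'   and `solution` (the `flux_solution` at the fitted point).
#' @export
fit_condition <- function(model, y_target, substrate_id, o2_id,
                          substrate_uptake = 5, xr_nadph, xr_nadh,
                          ethanol_id, xylitol_id,
                          our_range = c(0.1, 3), ratio_range = c(0, 1),
                          n_grid = 41, tol = 1e-4, max_refine = 3,
                          base_condition = condition_spec()) {
  stopifnot(y_target >= 0, length(our_range) == 2, length(ratio_range) == 2)
  f <- function(our, ratio) {
    y <- .yield_at(model, our, ratio, substrate_id, substrate_uptake, o2_id,
                   xr_nadph, xr_nadh, ethanol_id, base_condition)
    if (is.null(y)) NA_real_ else abs(y$yield - y_target)
  }
  ours <- seq(our_range[1], our_range[2], length.out = n_grid)
  ratios <- seq(ratio_range[1], ratio_range[2], length.out = n_grid)
  res <- outer(ours, ratios, Vectorize(f))
  if (all(is.na(res)))
    stop("no feasible point in the search ranges", call. = FALSE)
  # best residual; near-ties resolved toward smaller OUR then smaller ratio
  best <- min(res, na.rm = TRUE)
  cand <- which(res <= best + 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  i <- cand[1, 1]
  j <- cand[1, 2]

  golden <- function(fun, lo, hi, iter = 40) {
    phi <- (sqrt(5) - 1) / 2
    x1 <- hi - phi * (hi - lo)
    x2 <- lo + phi * (hi - lo)
    f1 <- fun(x1)
    f2 <- fun(x2)
    for (k in seq_len(iter)) {
      if (hi - lo < 1e-6) break
      if (is.na(f1)) f1 <- Inf
      if (is.na(f2)) f2 <- Inf
      if (f1 <= f2) {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - phi * (hi - lo); f1 <- fun(x1)
      } else {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + phi * (hi - lo); f2 <- fun(x2)
      }
    }
    if (is.na(f1)) f1 <- Inf
    if (is.na(f2)) f2 <- Inf
    if (f1 <= f2) c(x1, f1) else c(x2, f2)
  }

  our_best <- ours[i]
  ratio_best <- ratios[j]
  resid <- res[i, j]
  for (sweep in seq_len(max_refine)) {
    if (resid <= tol) break
    lo <- ours[max(i - 1, 1)]
    hi <- ours[min(i + 1, n_grid)]
    g <- golden(function(x) f(x, ratio_best), lo, hi)
    if (g[2] <= resid) { our_best <- g[1]; resid <- g[2] }
    lo <- ratios[max(j - 1, 1)]
    hi <- ratios[min(j + 1, n_grid)]
    g <- golden(function(x) f(our_best, x), lo, hi)
    if (g[2] <= resid) { ratio_best <- g[1]; resid <- g[2] }
  }

  fitted <- .yield_at(model, our_best, ratio_best, substrate_id,
                      substrate_uptake, o2_id, xr_nadph, xr_nadh, ethanol_id,
                      base_condition)
  structure(list(our = our_best, ratio = ratio_best, yield = fitted$yield,
                 xylitol = fitted$solution$fluxes[[xylitol_id]],
                 residual = abs(fitted$yield - y_target),
                 solution = fitted$solution),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: OUR %.4g mmol/gCDW/h, XR NADPH/NADH ratio %.4g\n",
              x$our, x$ratio))
  cat(sprintf("  ethanol yield %.4g (residual %.2g), xylitol secretion %.4g mmol/gCDW/h\n",
              x$yield, x$residual, x$xylitol))
  invisible(x)
}

#' Linearity check over fitted conditions
#'
#' Ordinary least squares of the XR cofactor ratio against OUR and of the
#' ethanol yield against OUR.  Near-unity R-squared values indicate the
#' conditions sit inside a single phenotype phase, where optimal responses
#' are affine in the varied constraints.
#'
#' @param points data.frame with columns `our`, `ratio`, `yield` (>= 3 rows).
#' @return A `linearity_check`: per relation `slope`, `intercept`, `r2` and a
#'   `degenerate` flag (constant response: slope 0, R-squared defined as 1).
#' @export
linearity_check <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("our", "ratio", "yield") %in% names(points)))
  if (nrow(points) < 3)
    stop("need at least 3 points for a linearity check", call. = FALSE)
  fit1 <- function(y) {
    if (stats::var(y) < 1e-24)
      return(list(slope = 0, intercept = mean(y), r2 = 1, degenerate = TRUE))
    m <- stats::lm(y ~ our, data = cbind(points, y = y))
    # summary() warns on exactly collinear inputs; R^2 = 1 is the answer
    r2 <- suppressWarnings(summary(m)$r.squared)
    list(slope = unname(stats::coef(m)[2]), intercept = unname(stats::coef(m)[1]),
         r2 = r2, degenerate = FALSE)
  }
  structure(list(ratio_vs_our = fit1(points$ratio),
                 yield_vs_our = fit1(points$yield),
                 points = points),
            class = "linearity_check")
}

#' @export
print.linearity_check <- function(x, ...) {
  cat(sprintf("ratio ~ OUR : slope %.4g, R^2 %.4f%s\n",
              x$ratio_vs_our$slope, x$ratio_vs_our$r2,
              if (x$ratio_vs_our$degenerate) " (degenerate)" else ""))
  cat(sprintf("yield ~ OUR : slope %.4g, R^2 %.4f%s\n",
              x$yield_vs_our$slope, x$yield_vs_our$r2,
              if (x$yield_vs_our$degenerate) " (degenerate)" else ""))
  invisible(x)
}
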