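# Independent oracles used across the suite.  Nothing here calls the
# package's own simplex path.

# Brute-force LP optimum by vertex enumeration of {A v = b, lb <= v <= ub}:
# every basis choice and bound assignment of the nonbasic variables is
# tried, so the value is exact for small networks.
enumerate_lp_optimum <- function(obj, A, b, lb, ub, sense = "max") {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  free <- n - m
  best <- NULL
  combs <- utils::combn(n, free)
  for (ci in seq_len(ncol(combs))) {
    fixed <- combs[, ci]
    basic <- setdiff(seq_len(n), fixed)
    B <- A[, basic, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    for (mask in 0:(2^free - 1)) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(free) - 1)))
      xf <- ifelse(at_ub, ub[fixed], lb[fixed])
      xb <- as.numeric(solve(B, b - A[, fixed, drop = FALSE] %*% xf))
      if (any(xb < lb[basic] - 1e-8) || any(xb > ub[basic] + 1e-8)) next
      x <- numeric(n)
      x[fixed] <- xf
      x[basic] <- xb
      val <- sum(obj * x)
      if (is.null(best) ||
          (sense == "max" && val > best) ||
          (sense == "min" && val < best)) best <- val
    }
  }
  best
}

# Closed-form optimum of the toy network (derived by hand from its lumped
# stoichiometry; see the methods vignette for the full derivation).  Valid
# for the default oxidative-PPP NADPH yield of 2.  `ratio` is the XR
# cofactor-preference coupling NADPH:NADH; growth and oxygen demand are per
# unit xylose uptake.
toy_closed_form <- function(ratio = 0, spec = toy_model_spec()) {
  stopifnot(spec$oxppp_nadph_yield == 2)
  rho <- ratio / (1 + ratio)
  P <- spec$atp_per_quinol
  a <- spec$uptake_atp_cost
  bG <- spec$biomass_g6p
  bA <- spec$biomass_atp
  bN <- spec$biomass_nadph
  mu <- ((2 + 12 * P) * (5 / 6 - rho / 12) - (a + 1) + P * rho) /
    ((2 + 12 * P) * (bN / 12 + bG) + bA)
  glycolysis <- 5 / 6 - rho / 12 - mu * (bN / 12 + bG)
  list(growth_per_uptake = mu,
       lo_slope = 6 * glycolysis + rho / 2)
}

# A 7-reaction branched test network small enough for vertex enumeration:
# substrate A feeds two products B and C, C via either a wasteful or an
# efficient route, and growth consumes one B plus one C.
tiny_branch_model <- function() {
  mets <- data.frame(id = c("A", "A", "B", "C"),
                     name = c("A", "A", "B", "C"),
                     compartment = c("e", "c", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "At", "RB", "RC_waste", "RC_eff", "GROWTH"),
    name = "", lb = c(0, 0, 0, 0, 0, 0), ub = c(1000, 1000, 1000, 1000, 1000, 1000),
    gpr = "", subsystem = c("exchange", "transport", "", "", "", "biomass"),
    stringsAsFactors = FALSE)
  stoich <- list(
    parse_equation("-1 A[e] ->")$stoich,
    parse_equation("-1 A[e] -> 1 A[c]")$stoich,
    parse_equation("-1 A[c] -> 1 B[c]")$stoich,
    parse_equation("-2 A[c] -> 1 C[c]")$stoich,
    parse_equation("-1 A[c] -> 1 C[c]")$stoich,
    parse_equation("-1 B[c] + -1 C[c] ->")$stoich)
  metabolic_model(mets, rxns, stoich, "GROWTH")
}

# LP matrices of a model under a condition, for handing to oracles.
lp_pieces <- function(model, condition = condition_spec()) {
  ids <- model$reactions$id
  lb <- stats::setNames(model$reactions$lb, ids)
  ub <- stats::setNames(model$reactions$ub, ids)
  for (id in names(condition$bounds)) {
    lb[id] <- condition$bounds[[id]][1]
    ub[id] <- condition$bounds[[id]][2]
  }
  lb[condition$disabled] <- 0
  ub[condition$disabled] <- 0
  A <- as.matrix(model$stoich)
  if (nrow(condition$couplings)) {
    extra <- matrix(0, nrow(condition$couplings), length(ids))
    for (i in seq_len(nrow(condition$couplings))) {
      extra[i, match(condition$couplings$rxn_a[i], ids)] <- 1
      extra[i, match(condition$couplings$rxn_b[i], ids)] <- -condition$couplings$ratio[i]
    }
    A <- rbind(A, extra)
  }
  list(A = A, b = rep(0, nrow(A)), lb = unname(lb), ub = unname(ub))
}
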