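# Flux balance analysis core.
#
# solve_fba: optimise one reaction flux subject to S v = 0, bounds and
# couplings.  solve_pfba: among the alternative optima, return the
# parsimonious representative minimising total absolute flux (the standard
# split into non-negative forward/backward parts), giving a deterministic
# solution where plain FBA is degenerate (e.g. redundant electron shuttles).

ZERO_FLUX_TOL <- 1e-6   # reported-flux zero threshold ("inactive" cutoff)

.coupling_rows <- function(model, couplings) {
  n <- nrow(model$reactions)
  if (nrow(couplings) == 0)
    return(matrix(0, 0, n))
  ids <- model$reactions$id
  A <- matrix(0, nrow(couplings), n)
  for (i in seq_len(nrow(couplings))) {
    A[i, match(couplings$rxn_a[i], ids)] <- 1
    A[i, match(couplings$rxn_b[i], ids)] <- -couplings$ratio[i]
  }
  A
}

.lp_matrices <- function(model, condition) {
  cc <- .apply_condition(model, condition)
  A <- rbind(as.matrix(model$stoich), .coupling_rows(model, cc$couplings))
  b <- rep(0, nrow(A))
  list(A = A, b = b, lb = cc$lb, ub = cc$ub)
}

.flux_solution <- function(model, v, objective, status) {
  fluxes <- if (is.null(v)) NULL else stats::setNames(v, model$reactions$id)
  obj <- if (is.null(v)) NA_real_ else unname(fluxes[objective])
  structure(list(fluxes = fluxes, objective_id = objective,
                 objective = obj, status = status),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (identical(x$status, "optimal"))
    cat(sprintf("  %s = %.6g", x$objective_id, x$objective))
  cat("\n")
  if (!is.null(x$fluxes)) {
    act <- x$fluxes[abs(x$fluxes) > ZERO_FLUX_TOL]
    cat(sprintf("  %d reactions, %d active (|v| > %g)\n",
                length(x$fluxes), length(act), ZERO_FLUX_TOL))
  }
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux through `objective` subject to
#' steady-state mass balance `S v = 0`, the model bounds as overridden by
#' `condition`, and any flux-ratio couplings.
#'
#' @param model a [metabolic_model()].
#' @param condition a [condition_spec()]; default imposes nothing beyond the
#'   model's own bounds.
#' @param objective reaction id to optimise; defaults to the model objective
#'   (biomass).
#' @param sense `"max"` (default) or `"min"`.
#' @return A `flux_solution`: named flux vector (mmol/gCDW/h; the biomass
#'   flux is a growth rate in 1/h), the objective value, and a status in
#'   `optimal`/`infeasible`.  An infeasible condition carries no flux map.
#' @export
solve_fba <- function(model, condition = condition_spec(),
                      objective = model$objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "metabolic_model"))
  if (!objective %in% model$reactions$id)
    stop("unknown objective reaction '", objective, "'", call. = FALSE)
  lp <- .lp_matrices(model, condition)
  obj <- as.numeric(model$reactions$id == objective)
  sol <- lp_solve(obj, lp$A, lp$b, lp$lb, lp$ub, sense = sense)
  .flux_solution(model, sol$x, objective, sol$status)
}

#' Parsimonious FBA
#'
#' Solves the FBA problem, then fixes the objective at its optimum and
#' minimises the total absolute flux.  The returned solution attains the same
#' objective value while selecting a deterministic, stoichiometrically
#' cheapest representative among the alternative optima.
#'
#' @inheritParams solve_fba
#' @return A `flux_solution` with an extra element `sum_abs_flux`.
#' @export
solve_pfba <- function(model, condition = condition_spec(),
                       objective = model$objective) {
  base <- solve_fba(model, condition, objective, sense = "max")
  if (!identical(base$status, "optimal")) return(base)

  lp <- .lp_matrices(model, condition)
  n <- ncol(lp$A)
  # split variables: v = p - q with p, q >= 0; the bound windows
  # p in [max(lb,0), max(ub,0)], q in [max(-ub,0), max(-lb,0)] reproduce
  # lb <= v <= ub exactly, and minimising sum(p + q) forbids overlap
  A2 <- cbind(lp$A, -lp$A)
  obj_row <- c(as.numeric(model$reactions$id == objective),
               -as.numeric(model$reactions$id == objective))
  A_eq <- rbind(A2, obj_row)
  b_eq <- c(lp$b, base$objective)
  lb2 <- c(pmax(lp$lb, 0), pmax(-lp$ub, 0))
  ub2 <- c(pmax(lp$ub, 0), pmax(-lp$lb, 0))
  sol <- lp_solve(rep(1, 2L * n), A_eq, b_eq, lb2, ub2, sense = "min")
  if (!identical(sol$status, "optimal"))
    stop("pFBA stage-2 LP unexpectedly ", sol$status, call. = FALSE)
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  out <- .flux_solution(model, v, objective, "optimal")
  out$sum_abs_flux <- sum(abs(v))
  out
}

#' Point-matching prediction error
#'
#' Relative prediction error in percent, `|pred - exp| / |exp| * 100`; when
#' the experimental value is zero the absolute error `|pred - exp|` is
#' reported instead and flagged.
#'
#' @param pred,exp numeric vectors (recycled) of predicted and experimental
#'   values.
#' @return Numeric vector of errors with attribute `absolute`, a logical
#'   vector marking entries where `exp == 0` (absolute error reported).
#' @examples
#' err_percent(1.3, 1.0)   # 30
#' err_percent(2.3, 0)     # 2.3, flagged absolute
#' @export
err_percent <- function(pred, exp) {
  n <- max(length(pred), length(exp))
  pred <- rep_len(pred, n)
  exp <- rep_len(exp, n)
  absolute <- exp == 0
  value <- ifelse(absolute, abs(pred - exp), abs(pred - exp) / abs(exp) * 100)
  attr(value, "absolute") <- absolute
  value
}

#' Maximum mass-balance residual of a solution
#'
#' @param model a `metabolic_model`.
#' @param solution an optimal `flux_solution`.
#' @return `max |S v|` over all metabolites.
#' @export
mass_balance_residual <- function(model, solution) {
  stopifnot(identical(solution$status, "optimal"))
  max(abs(as.numeric(model$stoich %*% solution$fluxes)))
}
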