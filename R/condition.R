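# Condition specifications.
#
# A condition_spec describes one in-silico experiment: bound overrides on
# named reactions (mmol/gCDW/h), linear flux-ratio couplings v_A = r * v_B
# enforced as extra LP equality rows, and reactions disabled outright.
#
# Sign convention: exchange reactions are written export-positive, so an
# uptake of 5 mmol/gCDW/h is imposed internally as lb = ub = -5, while all
# user-facing helpers and reports speak the positive-uptake convention.

#' Create a condition specification
#'
#' @param bounds named list; each element `c(lb, ub)` overrides that
#'   reaction's bounds.
#' @param couplings data.frame with columns `rxn_a`, `rxn_b`, `ratio`
#'   enforcing `v_a = ratio * v_b` (ratio >= 0).
#' @param disabled character vector of reaction ids forced to zero flux.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(bounds = list(),
                           couplings = data.frame(rxn_a = character(0),
                                                  rxn_b = character(0),
                                                  ratio = numeric(0)),
                           disabled = character(0)) {
  couplings <- as.data.frame(couplings, stringsAsFactors = FALSE)
  stopifnot(all(c("rxn_a", "rxn_b", "ratio") %in% names(couplings)))
  if (any(couplings$ratio < 0))
    stop("coupling ratios must be >= 0", call. = FALSE)
  for (b in bounds)
    if (length(b) != 2 || b[1] > b[2])
      stop("each bound override must be c(lb, ub) with lb <= ub", call. = FALSE)
  structure(list(bounds = bounds, couplings = couplings,
                 disabled = as.character(disabled)),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("condition_spec\n")
  for (id in names(x$bounds))
    cat(sprintf("  bound    %-12s [%g, %g]\n", id, x$bounds[[id]][1], x$bounds[[id]][2]))
  for (i in seq_len(nrow(x$couplings)))
    cat(sprintf("  coupling %s = %g * %s\n", x$couplings$rxn_a[i],
                x$couplings$ratio[i], x$couplings$rxn_b[i]))
  if (length(x$disabled))
    cat("  disabled", paste(x$disabled, collapse = ", "), "\n")
  invisible(x)
}

#' Override the bounds of one reaction
#'
#' @param condition a [condition_spec()].
#' @param reaction_id reaction id.
#' @param lb,ub new bounds (mmol/gCDW/h).
#' @return The updated `condition_spec`.
#' @export
set_bound <- function(condition, reaction_id, lb, ub) {
  stopifnot(inherits(condition, "condition_spec"), lb <= ub)
  condition$bounds[[reaction_id]] <- c(lb, ub)
  condition
}

#' Impose an uptake rate on an exchange reaction
#'
#' Exchange fluxes are export-positive, so a fixed uptake of `rate`
#' mmol/gCDW/h becomes `lb = ub = -rate`; with `fixed = FALSE` the uptake is
#' only capped (`lb = -rate, ub = 0`).
#'
#' @inheritParams set_bound
#' @param rate uptake rate, positive (mmol/gCDW/h).
#' @param fixed fix the uptake exactly (default) or allow any uptake up to
#'   `rate`.
#' @return The updated `condition_spec`.
#' @export
set_uptake <- function(condition, reaction_id, rate, fixed = TRUE) {
  stopifnot(rate >= 0)
  if (fixed) set_bound(condition, reaction_id, -rate, -rate)
  else set_bound(condition, reaction_id, -rate, 0)
}

#' Leave an uptake free for the solver to choose
#'
#' Sets `lb = -max_rate, ub = 0`: the solver may take up any amount (no
#' export), as when the oxygen uptake rate is left to be determined by FBA.
#'
#' @inheritParams set_bound
#' @param max_rate uptake ceiling (mmol/gCDW/h).
#' @return The updated `condition_spec`.
#' @export
free_uptake <- function(condition, reaction_id, max_rate = 1000) {
  set_bound(condition, reaction_id, -max_rate, 0)
}

#' Add a flux-ratio coupling
#'
#' Enforces `v_a = ratio * v_b` as an exact LP equality row (not a bound
#' manipulation), e.g. tying the NADPH-dependent xylose reductase flux to the
#' NADH-dependent one at a cofactor-preference ratio.
#'
#' @inheritParams set_bound
#' @param rxn_a,rxn_b reaction ids.
#' @param ratio non-negative ratio `r` in `v_a = r * v_b`.
#' @return The updated `condition_spec`.
#' @export
add_ratio_coupling <- function(condition, rxn_a, rxn_b, ratio) {
  stopifnot(inherits(condition, "condition_spec"))
  if (ratio < 0) stop("coupling ratio must be >= 0", call. = FALSE)
  condition$couplings <- rbind(condition$couplings,
                               data.frame(rxn_a = rxn_a, rxn_b = rxn_b,
                                          ratio = ratio,
                                          stringsAsFactors = FALSE))
  condition
}

#' Disable a reaction
#'
#' Forces both bounds to zero, e.g. the NADPH-dependent glutamate
#' dehydrogenase under glucose, where the gene is repressed.
#'
#' @inheritParams set_bound
#' @return The updated `condition_spec`.
#' @export
disable_reaction <- function(condition, reaction_id) {
  stopifnot(inherits(condition, "condition_spec"))
  condition$disabled <- union(condition$disabled, reaction_id)
  condition
}

# Resolve a condition against a model: effective bounds + coupling rows.
#' @keywords internal
#' @noRd
.apply_condition <- function(model, condition) {
  ids <- model$reactions$id
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  names(lb) <- names(ub) <- ids
  unknown <- setdiff(c(names(condition$bounds), condition$disabled,
                       condition$couplings$rxn_a, condition$couplings$rxn_b),
                     ids)
  if (length(unknown))
    stop("condition references unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (id in names(condition$bounds)) {
    lb[id] <- condition$bounds[[id]][1]
    ub[id] <- condition$bounds[[id]][2]
  }
  lb[condition$disabled] <- 0
  ub[condition$disabled] <- 0
  list(lb = unname(lb), ub = unname(ub), couplings = condition$couplings)
}
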