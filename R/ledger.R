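# Compartment-aware cofactor ledgers and electron accounting.
#
# For a named cofactor in a compartment, every reaction's contribution is its
# stoichiometric coefficient for the cofactor times its flux: positive
# contributions produce the cofactor, negative ones consume it.  At steady
# state an internal metabolite's produced and consumed totals match, so the
# ledger is a bookkeeping view of where the redox flux actually runs.

#' Build a cofactor production/consumption ledger
#'
#' @param model a [metabolic_model()].
#' @param solution an optimal `flux_solution`.
#' @param cofactor metabolite id (e.g. `"nadh"`, `"nadph"`, `"q6h2"`).
#' @param compartment compartment tag (e.g. `"c"`, `"m"`).
#' @param tol flux threshold below which a reaction is left out of the
#'   per-reaction listing (totals are unaffected).
#' @return A `cofactor_ledger`: `produced` and `consumed` totals
#'   (mmol/gCDW/h) and a `contributions` data.frame (`reaction`,
#'   `coefficient`, `flux`, `contribution`) over reactions that involve the
#'   cofactor and carry flux.
#' @export
build_ledger <- function(model, solution, cofactor, compartment,
                         tol = ZERO_FLUX_TOL) {
  stopifnot(inherits(model, "metabolic_model"),
            identical(solution$status, "optimal"))
  key <- paste0(cofactor, "[", compartment, "]")
  if (!key %in% rownames(model$stoich))
    stop("unknown cofactor/compartment: ", key, call. = FALSE)
  coefs <- model$stoich[key, ]
  v <- solution$fluxes[colnames(model$stoich)]
  contrib <- as.numeric(coefs) * as.numeric(v)
  produced <- sum(contrib[contrib > 0])
  consumed <- -sum(contrib[contrib < 0])
  keep <- as.numeric(coefs) != 0 & abs(as.numeric(v)) > tol
  contributions <- data.frame(reaction = colnames(model$stoich)[keep],
                              coefficient = as.numeric(coefs)[keep],
                              flux = as.numeric(v)[keep],
                              contribution = contrib[keep],
                              stringsAsFactors = FALSE)
  contributions <- contributions[order(-abs(contributions$contribution)), ]
  rownames(contributions) <- NULL
  structure(list(cofactor = cofactor, compartment = compartment,
                 produced = produced, consumed = consumed,
                 contributions = contributions),
            class = "cofactor_ledger")
}

#' @export
print.cofactor_ledger <- function(x, ...) {
  cat(sprintf("%s[%s] ledger: produced %.4g, consumed %.4g mmol/gCDW/h\n",
              x$cofactor, x$compartment, x$produced, x$consumed))
  if (nrow(x$contributions)) {
    cat(sprintf("  %d contributing reactions, largest: %s (%.4g)\n",
                nrow(x$contributions), x$contributions$reaction[1],
                x$contributions$contribution[1]))
  }
  invisible(x)
}

#' Difference between two ledgers of the same cofactor
#'
#' Per-reaction and total contribution changes, `b - a` (e.g. oxygen-limited
#' minus aerobic).
#'
#' @param a,b `cofactor_ledger`s for the same cofactor and compartment.
#' @return A `ledger_delta`: `produced_change`, `consumed_change` and a
#'   `contributions` data.frame with per-reaction `change`.
#' @export
ledger_delta <- function(a, b) {
  stopifnot(inherits(a, "cofactor_ledger"), inherits(b, "cofactor_ledger"))
  if (!identical(a$cofactor, b$cofactor) ||
      !identical(a$compartment, b$compartment))
    stop("ledgers refer to different cofactors/compartments", call. = FALSE)
  ids <- union(a$contributions$reaction, b$contributions$reaction)
  ca <- stats::setNames(rep(0, length(ids)), ids)
  cb <- ca
  ca[a$contributions$reaction] <- a$contributions$contribution
  cb[b$contributions$reaction] <- b$contributions$contribution
  d <- cb - ca
  contributions <- data.frame(reaction = ids, change = unname(d),
                              stringsAsFactors = FALSE)
  contributions <- contributions[order(-abs(contributions$change)), ]
  rownames(contributions) <- NULL
  structure(list(cofactor = a$cofactor, compartment = a$compartment,
                 produced_change = b$produced - a$produced,
                 consumed_change = b$consumed - a$consumed,
                 contributions = contributions),
            class = "ledger_delta")
}

#' @export
print.ledger_delta <- function(x, ...) {
  cat(sprintf("%s[%s] delta: produced %+.4g, consumed %+.4g mmol/gCDW/h\n",
              x$cofactor, x$compartment, x$produced_change, x$consumed_change))
  invisible(x)
}

#' Net flux through a named electron shuttle
#'
#' A shuttle is a set of reactions with declared signs; its net electron-pair
#' transfer rate is the signed sum of the member fluxes.
#'
#' @param model a [metabolic_model()].
#' @param solution an optimal `flux_solution`.
#' @param shuttle either a character vector of reaction ids (all signs +1) or
#'   a named numeric vector mapping reaction id to sign.
#' @return Net rate (mmol/gCDW/h).
#' @export
shuttle_flux <- function(model, solution, shuttle) {
  stopifnot(identical(solution$status, "optimal"))
  if (is.character(shuttle)) shuttle <- stats::setNames(rep(1, length(shuttle)), shuttle)
  if (length(shuttle) == 0)
    stop("empty shuttle definition", call. = FALSE)
  missing <- setdiff(names(shuttle), model$reactions$id)
  if (length(missing))
    stop("shuttle references unknown reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sum(shuttle * solution$fluxes[names(shuttle)])
}

#' Electron accounting of a quinol-pool shift against reduced oxygen supply
#'
#' Each mole of O2 accepts electrons from two quinol equivalents, so a drop
#' in oxygen uptake of `|OUR_a - OUR_b|` removes `2 |OUR_a - OUR_b|` of
#' quinol-oxidising capacity; the returned percentage is how much of that
#' removed capacity the observed quinol production change accounts for.
#'
#' @param delta_q6h2 change in quinol (Q6H2) production between the two
#'   conditions (mmol/gCDW/h; sign irrelevant).
#' @param our_a,our_b oxygen uptake rates of the two conditions (>= 0).
#' @return Percentage `100 |delta_q6h2| / (2 |our_a - our_b|)`.
#' @examples
#' electron_accounting(-1.79, 2.33, 1.42)  # ~98%
#' @export
electron_accounting <- function(delta_q6h2, our_a, our_b) {
  stopifnot(our_a >= 0, our_b >= 0)
  if (our_a == our_b)
    stop("electron accounting undefined: oxygen uptake rates are equal",
         call. = FALSE)
  100 * abs(delta_q6h2) / (2 * abs(our_a - our_b))
}
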