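# Phenotype phase planes and the line of optimality.

#' Compute a phenotype phase plane
#'
#' Solves one growth-maximising FBA per grid cell with both the substrate and
#' the oxygen uptake fixed, and records the requested observable fluxes from
#' the parsimonious representative.  Infeasible cells are recorded in place
#' as `NA` (never zero-filled) and the grid never aborts on them.
#'
#' @param model a [metabolic_model()].
#' @param substrate_id exchange reaction id of the carbon substrate.
#' @param o2_id exchange reaction id of oxygen.
#' @param substrate,o2 numeric vectors of uptake rates (mmol/gCDW/h) spanning
#'   the two grid axes; defaults are 50 points over \[0, 10\] substrate and
#'   \[0, 20\] oxygen.
#' @param observables named character vector of reaction ids whose fluxes are
#'   recorded as surfaces; the objective (growth) is always included.
#' @param condition base [condition_spec()] applied in every cell (e.g. a
#'   cofactor-preference coupling).
#' @param pfba use the parsimonious representative per cell (default).
#' @return A `phpp_grid`: axes, named list of `|substrate| x |o2|` surface
#'   matrices, a `feasible` logical matrix, and slots used by
#'   [segment_phases()].
#' @export
compute_phpp <- function(model, substrate_id, o2_id,
                         substrate = seq(0, 10, length.out = 50),
                         o2 = seq(0, 20, length.out = 50),
                         observables = character(0),
                         condition = condition_spec(), pfba = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  observables <- c(stats::setNames(model$objective, "growth"), observables)
  observables <- observables[!duplicated(observables)]
  surfaces <- lapply(observables, function(.)
    matrix(NA_real_, length(substrate), length(o2)))
  names(surfaces) <- names(observables)
  feasible <- matrix(FALSE, length(substrate), length(o2))
  for (i in seq_along(substrate)) {
    for (j in seq_along(o2)) {
      cond <- set_uptake(condition, substrate_id, substrate[i])
      cond <- set_uptake(cond, o2_id, o2[j])
      sol <- if (pfba) solve_pfba(model, cond) else solve_fba(model, cond)
      if (identical(sol$status, "optimal")) {
        feasible[i, j] <- TRUE
        for (k in seq_along(observables))
          surfaces[[k]][i, j] <- sol$fluxes[[observables[[k]]]]
      }
    }
  }
  structure(list(substrate = substrate, o2 = o2, surfaces = surfaces,
                 feasible = feasible, substrate_id = substrate_id,
                 o2_id = o2_id, observables = observables, phase = NULL),
            class = "phpp_grid")
}

#' @export
print.phpp_grid <- function(x, ...) {
  cat(sprintf("phpp_grid: %d x %d cells (%s x %s), %d infeasible\n",
              length(x$substrate), length(x$o2), x$substrate_id, x$o2_id,
              sum(!x$feasible)))
  cat("  surfaces:", paste(names(x$surfaces), collapse = ", "), "\n")
  if (!is.null(x$phase))
    cat("  phases:", attr(x$phase, "n_phases"), "\n")
  invisible(x)
}

#' Segment a phase plane into phenotype phases
#'
#' Cells are tagged with the sign pattern (-/0/+, zero threshold `tol`) of
#' every recorded surface; contiguous (4-neighbour) runs of one signature
#' form a phase.  Infeasible cells get label `NA`.
#'
#' @param grid a `phpp_grid` from [compute_phpp()].
#' @param tol flux zero threshold for the sign pattern.
#' @return An integer label matrix with attribute `n_phases`; the input grid
#'   with the labels attached is returned invisibly via attribute `grid`.
#' @export
segment_phases <- function(grid, tol = ZERO_FLUX_TOL) {
  stopifnot(inherits(grid, "phpp_grid"))
  ns <- length(grid$substrate)
  no <- length(grid$o2)
  sig <- matrix(NA_character_, ns, no)
  for (i in seq_len(ns)) for (j in seq_len(no)) {
    if (!grid$feasible[i, j]) next
    v <- vapply(grid$surfaces, function(s) s[i, j], numeric(1))
    sig[i, j] <- paste(ifelse(abs(v) <= tol, "0", ifelse(v > 0, "+", "-")),
                       collapse = "")
  }
  labels <- matrix(NA_integer_, ns, no)
  cur <- 0L
  for (i in seq_len(ns)) for (j in seq_len(no)) {
    if (is.na(sig[i, j]) || !is.na(labels[i, j])) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    labels[i, j] <- cur
    while (length(queue)) {
      cell <- queue[[1]]
      queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        a <- cell[1] + d[1]
        b <- cell[2] + d[2]
        if (a < 1 || a > ns || b < 1 || b > no) next
        if (is.na(sig[a, b]) || !is.na(labels[a, b])) next
        if (identical(sig[a, b], sig[cell[1], cell[2]])) {
          labels[a, b] <- cur
          queue <- c(queue, list(c(a, b)))
        }
      }
    }
  }
  attr(labels, "n_phases") <- cur
  labels
}

#' Export a phase plane as a long-form table
#'
#' @param grid a `phpp_grid`.
#' @param phase optional label matrix from [segment_phases()].
#' @return data.frame with columns `substrate`, `o2`, `observable`, `value`,
#'   `feasible` and (when given) `phase`.
#' @export
phpp_table <- function(grid, phase = NULL) {
  stopifnot(inherits(grid, "phpp_grid"))
  rows <- expand.grid(i = seq_along(grid$substrate), j = seq_along(grid$o2))
  out <- do.call(rbind, lapply(names(grid$surfaces), function(nm) {
    data.frame(substrate = grid$substrate[rows$i], o2 = grid$o2[rows$j],
               observable = nm,
               value = grid$surfaces[[nm]][cbind(rows$i, rows$j)],
               feasible = grid$feasible[cbind(rows$i, rows$j)],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(phase)) out$phase <- phase[cbind(rows$i, rows$j)]
  out
}

#' Find the line of optimality
#'
#' For each substrate uptake value the oxygen uptake is left free and read
#' from the growth-maximising (parsimonious) solution; the slope is the
#' least-squares line through the origin of oxygen vs substrate uptake, in
#' mol O2 per mol substrate.
#'
#' @param model a [metabolic_model()].
#' @param substrate_id exchange reaction id of the substrate.
#' @param uptakes >= 2 substrate uptake values (mmol/gCDW/h), all feasible.
#' @param o2_id exchange reaction id of oxygen.
#' @param condition base [condition_spec()] applied at every point.
#' @param max_o2 oxygen-uptake ceiling while the rate is left free.
#' @return A `line_of_optimality`: `slope`, a `points` data.frame
#'   (`substrate`, `o2`, `growth`) and the maximum residual about the line.
#' @export
find_lo <- function(model, substrate_id, uptakes, o2_id,
                    condition = condition_spec(), max_o2 = 1000) {
  stopifnot(length(uptakes) >= 2)
  pts <- data.frame(substrate = uptakes, o2 = NA_real_, growth = NA_real_)
  for (k in seq_along(uptakes)) {
    cond <- set_uptake(condition, substrate_id, uptakes[k])
    cond <- free_uptake(cond, o2_id, max_rate = max_o2)
    sol <- solve_pfba(model, cond)
    if (!identical(sol$status, "optimal"))
      stop("infeasible LO point at ", substrate_id, " uptake ", uptakes[k],
           call. = FALSE)
    pts$o2[k] <- -sol$fluxes[[o2_id]]
    pts$growth[k] <- sol$objective
  }
  slope <- sum(pts$o2 * pts$substrate) / sum(pts$substrate^2)
  resid <- max(abs(pts$o2 - slope * pts$substrate))
  structure(list(slope = slope, points = pts, residual = resid),
            class = "line_of_optimality")
}

#' @export
print.line_of_optimality <- function(x, ...) {
  cat(sprintf("line of optimality: %.4g mol O2 / mol substrate (%d points, max residual %.2g)\n",
              x$slope, nrow(x$points), x$residual))
  invisible(x)
}

#' Image plot of a phase-plane surface
#'
#' @param x a `phpp_grid`.
#' @param surface name of the surface to draw (default growth).
#' @param ... passed to [graphics::image()].
#' @export
plot.phpp_grid <- function(x, surface = "growth", ...) {
  z <- x$surfaces[[surface]]
  graphics::image(x$substrate, x$o2, z, xlab = paste(x$substrate_id, "uptake"),
                  ylab = paste(x$o2_id, "uptake"), main = surface, ...)
  invisible(x)
}
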