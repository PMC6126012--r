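# System-identification workflow: designed linear condition sweeps, flux
# matrices, PCA on flux distributions, loading ranking, response
# classification, and forced-behavior probes.
#
# Within one phenotype phase the optimal flux vector is affine in linearly
# varied constraints, so a single principal component captures the whole
# designed response; the PC loadings then read as per-reaction flux-change
# magnitudes.

#' Design a linear condition sweep
#'
#' Interpolates every varied scalar (bound overrides and coupling ratios)
#' linearly between two endpoint conditions: step `i` (0-based) sits at
#' `A + i/(n-1) * (B - A)`, with exact endpoints.  The two endpoints must
#' declare the same bound names, coupling pairs and disabled set.
#'
#' @param a,b endpoint [condition_spec()]s.
#' @param n number of steps (>= 3).
#' @return List of `n` `condition_spec`s.
#' @export
design_sweep <- function(a, b, n = 10) {
  stopifnot(inherits(a, "condition_spec"), inherits(b, "condition_spec"), n >= 3)
  if (!setequal(names(a$bounds), names(b$bounds)))
    stop("sweep endpoints declare different bound overrides", call. = FALSE)
  key <- function(cp) paste(cp$rxn_a, cp$rxn_b)
  if (nrow(a$couplings) != nrow(b$couplings) ||
      !identical(key(a$couplings), key(b$couplings)))
    stop("sweep endpoints declare different couplings", call. = FALSE)
  if (!setequal(a$disabled, b$disabled))
    stop("sweep endpoints declare different disabled sets", call. = FALSE)
  lapply(seq_len(n) - 1L, function(i) {
    t <- i / (n - 1)
    bounds <- lapply(names(a$bounds), function(id)
      (1 - t) * a$bounds[[id]] + t * b$bounds[[id]])
    names(bounds) <- names(a$bounds)
    cp <- a$couplings
    if (nrow(cp)) cp$ratio <- (1 - t) * a$couplings$ratio + t * b$couplings$ratio
    condition_spec(bounds = bounds, couplings = cp, disabled = a$disabled)
  })
}

#' Assemble the flux matrix of a sweep
#'
#' Row `i` is the parsimonious flux solution of condition `i`; any infeasible
#' condition aborts assembly with its index, so the matrix never contains
#' missing entries.
#'
#' @param model a [metabolic_model()].
#' @param conditions list of [condition_spec()]s (e.g. from [design_sweep()]).
#' @param pfba use parsimonious FBA per condition (default).
#' @return Numeric matrix, conditions x reactions, with reaction ids as
#'   column names and attribute `objective` (the objective reaction id).
#' @export
assemble_flux_matrix <- function(model, conditions, pfba = TRUE) {
  stopifnot(length(conditions) >= 1)
  rows <- lapply(seq_along(conditions), function(i) {
    sol <- if (pfba) solve_pfba(model, conditions[[i]])
           else solve_fba(model, conditions[[i]])
    if (!identical(sol$status, "optimal"))
      stop("condition ", i, " of the sweep is infeasible", call. = FALSE)
    sol$fluxes
  })
  fm <- do.call(rbind, rows)
  rownames(fm) <- paste0("cond", seq_along(conditions))
  attr(fm, "objective") <- model$objective
  fm
}

#' PCA of a flux matrix
#'
#' Singular value decomposition of the column-centered (not variance-scaled)
#' flux matrix: loadings stay in flux units so their magnitudes read as
#' flux-change contributions.  Explained-variance fractions come from the
#' squared singular values.  Each PC is oriented so the objective (growth)
#' loading is non-negative; when that loading is zero, the
#' largest-magnitude loading is made positive.
#'
#' @param flux_matrix conditions x reactions matrix (>= 2 rows), e.g. from
#'   [assemble_flux_matrix()].
#' @param center column-center before decomposition (default `TRUE`).
#' @param objective objective reaction id used for sign orientation; defaults
#'   to the matrix's `objective` attribute.
#' @return A `pca_result`: `loadings` (reactions x PCs, unit columns),
#'   `variance_fraction` (non-negative, descending, summing to 1), `scores`
#'   (condition coordinates) and `degenerate` (`TRUE` for a zero-variance
#'   matrix, where the fraction is defined as 1 and the loadings are zero).
#' @export
run_pca <- function(flux_matrix, center = TRUE, objective = NULL) {
  stopifnot(is.matrix(flux_matrix), nrow(flux_matrix) >= 2)
  if (is.null(objective)) objective <- attr(flux_matrix, "objective")
  X <- scale(flux_matrix, center = center, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  tot <- sum(X^2)
  k <- min(dim(flux_matrix)) - as.integer(center)
  k <- max(k, 1L)
  if (tot < 1e-24) {
    loadings <- matrix(0, ncol(flux_matrix), 1,
                       dimnames = list(colnames(flux_matrix), "PC1"))
    return(structure(list(loadings = loadings, variance_fraction = 1,
                          scores = matrix(0, nrow(flux_matrix), 1),
                          degenerate = TRUE),
                     class = "pca_result"))
  }
  sv <- svd(X, nu = k, nv = k)
  d2 <- sv$d[seq_len(k)]^2
  loadings <- sv$v
  scores <- X %*% loadings
  # fixed sign convention
  for (p in seq_len(ncol(loadings))) {
    l_obj <- if (!is.null(objective) && objective %in% colnames(flux_matrix))
      loadings[match(objective, colnames(flux_matrix)), p] else 0
    flip <- if (abs(l_obj) > 1e-12) l_obj < 0
            else loadings[which.max(abs(loadings[, p])), p] < 0
    if (flip) {
      loadings[, p] <- -loadings[, p]
      scores[, p] <- -scores[, p]
    }
  }
  dimnames(loadings) <- list(colnames(flux_matrix),
                             paste0("PC", seq_len(ncol(loadings))))
  colnames(scores) <- colnames(loadings)
  structure(list(loadings = loadings, variance_fraction = d2 / sum(sv$d^2),
                 scores = scores, degenerate = FALSE),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result\n")
  vf <- x$variance_fraction
  cat("  explained variance:",
      paste(sprintf("%s %.1f%%", names(vf) %||% paste0("PC", seq_along(vf)),
                    100 * vf), collapse = ", "), "\n")
  if (x$degenerate) cat("  (degenerate: zero-variance matrix)\n")
  invisible(x)
}

#' Rank reactions by loading magnitude
#'
#' @param pca a `pca_result`.
#' @param pc principal-component index (default 1).
#' @param k number of reactions to return; a `k` beyond the number of
#'   reactions truncates.
#' @return data.frame (`reaction`, `loading`) sorted by `|loading|`
#'   descending, ties broken lexicographically by reaction id.
#' @export
rank_loadings <- function(pca, pc = 1, k = 10) {
  stopifnot(inherits(pca, "pca_result"), k >= 1, pc <= ncol(pca$loadings))
  l <- pca$loadings[, pc]
  ord <- order(-abs(l), names(l))
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(reaction = names(l)[ord], loading = unname(l[ord]),
             stringsAsFactors = FALSE)
}

#' Classify per-reaction responses along a monotone sweep
#'
#' A reaction is `inactive` (black on a network map) when it carries no flux
#' anywhere along the sweep or its carried flux does not change; otherwise
#' it is `up` (blue) or `down` (red) by the sign of the endpoint difference
#' of the flux magnitude, so a reversible reaction running negative is
#' classified by its carried flux.  Columns whose magnitude change flips
#' sign along the sweep are still classified by the endpoints but listed in
#' the `non_monotone` attribute.
#'
#' @param flux_matrix conditions x reactions matrix from a monotone sweep.
#' @param tol zero/no-change flux threshold.
#' @return Named character vector over all reactions with values in
#'   `up`/`down`/`inactive`, attribute `non_monotone` listing flagged ids.
#' @export
classify_response <- function(flux_matrix, tol = ZERO_FLUX_TOL) {
  stopifnot(is.matrix(flux_matrix), nrow(flux_matrix) >= 2)
  mags <- abs(flux_matrix)
  delta <- mags[nrow(mags), ] - mags[1, ]
  cls <- ifelse(apply(mags, 2, max) <= tol, "inactive",
                ifelse(delta > tol, "up",
                       ifelse(delta < -tol, "down", "inactive")))
  steps <- diff(mags)
  non_mono <- vapply(seq_len(ncol(mags)), function(j) {
    s <- steps[, j]
    s <- s[abs(s) > tol]
    length(s) > 0 && min(s) < 0 && max(s) > 0
  }, logical(1))
  cls <- stats::setNames(as.character(cls), colnames(flux_matrix))
  attr(cls, "non_monotone") <- colnames(flux_matrix)[non_mono]
  cls
}

#' Pin a reaction to a flux profile along a sweep
#'
#' Returns the sweep conditions with `lb = ub = profile[i]` merged in at each
#' step — the forced-behavior probe used to ask which reactions must adjust
#' to accommodate an imposed trend (e.g. oxidative PPP flux forced
#' proportional to oxygen uptake).
#'
#' @param model a [metabolic_model()] (used for the feasibility check).
#' @param conditions list of sweep [condition_spec()]s.
#' @param reaction_id reaction to pin.
#' @param profile numeric vector, one pinned flux per step.
#' @param check solve each pinned step and error (with its index) if any is
#'   infeasible (default `TRUE`).
#' @return List of updated `condition_spec`s.
#' @export
force_behavior <- function(model, conditions, reaction_id, profile,
                           check = TRUE) {
  if (length(profile) != length(conditions))
    stop("profile length (", length(profile), ") != sweep length (",
         length(conditions), ")", call. = FALSE)
  out <- lapply(seq_along(conditions), function(i)
    set_bound(conditions[[i]], reaction_id, profile[i], profile[i]))
  if (check) {
    for (i in seq_along(out)) {
      sol <- solve_fba(model, out[[i]])
      if (!identical(sol$status, "optimal"))
        stop("pinned flux ", profile[i], " on '", reaction_id,
             "' is infeasible at sweep step ", i, call. = FALSE)
    }
  }
  out
}
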