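# The metabolic_model container.
#
# A model holds a metabolite table, a reaction table, a sparse stoichiometric
# matrix (rows = metabolite keys "id[comp]", columns = reaction ids), the
# biomass objective reaction id, the declared compartment set and the gene id
# set implied by the GPR rules.  Bounds are in mmol/gCDW/h; the objective
# reaction flux is a growth rate in 1/h.

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#'   Metabolite ids must be unique within a compartment; the global key is
#'   `id[compartment]`.
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`, `gpr`
#'   (rule string, `""` for none) and `subsystem`.
#' @param stoich named list, one named numeric vector per reaction (names are
#'   metabolite keys, negative coefficients are substrates), in the order of
#'   `reactions$id`.
#' @param objective id of the biomass (objective) reaction.
#' @param compartments declared compartment tags; defaults to those present in
#'   `metabolites`.
#' @return An object of class `metabolic_model`.
#' @seealso [load_model()], [apply_patch()], [solve_fba()]
#' @export
metabolic_model <- function(metabolites, reactions, stoich, objective,
                            compartments = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  need_m <- c("id", "name", "compartment")
  need_r <- c("id", "name", "lb", "ub", "gpr", "subsystem")
  stopifnot(all(need_m %in% names(metabolites)), all(need_r %in% names(reactions)))
  if (is.null(compartments)) compartments <- sort(unique(metabolites$compartment))

  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id(s): ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "),
         call. = FALSE)
  metabolites$key <- paste0(metabolites$id, "[", metabolites$compartment, "]")
  if (anyDuplicated(metabolites$key))
    stop("duplicate metabolite id(s) within a compartment: ",
         paste(unique(metabolites$key[duplicated(metabolites$key)]), collapse = ", "),
         call. = FALSE)
  bad_comp <- setdiff(unique(metabolites$compartment), compartments)
  if (length(bad_comp))
    stop("metabolite compartment(s) outside the declared set: ",
         paste(bad_comp, collapse = ", "), call. = FALSE)

  stopifnot(length(stoich) == nrow(reactions))
  names(stoich) <- reactions$id
  dangling <- vapply(stoich, function(s) !all(names(s) %in% metabolites$key),
                     logical(1))
  if (any(dangling))
    stop("reaction(s) reference metabolites not in the model: ",
         paste(reactions$id[dangling], collapse = ", "), call. = FALSE)
  if (any(vapply(stoich, length, integer(1)) == 0))
    stop("reaction(s) with empty stoichiometry: ",
         paste(reactions$id[vapply(stoich, length, integer(1)) == 0],
               collapse = ", "), call. = FALSE)
  if (any(reactions$lb > reactions$ub))
    stop("reaction(s) with lb > ub: ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "),
         call. = FALSE)
  if (!objective %in% reactions$id)
    stop("objective reaction '", objective, "' is not in the model", call. = FALSE)

  i <- unlist(lapply(stoich, function(s) match(names(s), metabolites$key)))
  j <- rep(seq_along(stoich), times = vapply(stoich, length, integer(1)))
  x <- unlist(stoich, use.names = FALSE)
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$key, reactions$id))

  genes <- sort(unique(unlist(lapply(reactions$gpr,
                                     function(g) gpr_genes(parse_gpr(g))))))
  structure(list(metabolites = metabolites, reactions = reactions, stoich = S,
                 objective = objective, compartments = compartments,
                 genes = genes),
            class = "metabolic_model")
}

#' Stoichiometry of one reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction id.
#' @return Named numeric vector of non-zero coefficients keyed by `met[comp]`.
#' @export
reaction_stoich <- function(model, reaction_id) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!reaction_id %in% colnames(model$stoich))
    stop("unknown reaction id '", reaction_id, "'", call. = FALSE)
  col <- model$stoich[, reaction_id]
  col[col != 0]
}

#' Is a reaction reversible?
#'
#' Reversibility is derived from the bounds: `lb < 0 < ub`.
#'
#' @inheritParams reaction_stoich
#' @return Logical.
#' @export
reaction_reversible <- function(model, reaction_id) {
  r <- model$reactions[model$reactions$id == reaction_id, ]
  if (nrow(r) == 0) stop("unknown reaction id '", reaction_id, "'", call. = FALSE)
  r$lb < 0 && r$ub > 0
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model\n")
  s <- summary(x)
  cat(sprintf("  reactions:    %d\n", s$n_reactions))
  for (comp in names(s$reactions_by_compartment))
    cat(sprintf("    %-10s %d\n", paste0(comp, ":"), s$reactions_by_compartment[[comp]]))
  cat(sprintf("    %-10s %d\n", "transport:", s$n_transport))
  cat(sprintf("  metabolites:  %d\n", s$n_metabolites))
  cat(sprintf("  genes:        %d\n", s$n_genes))
  cat(sprintf("  compartments: %s\n", paste(s$compartments, collapse = ", ")))
  cat(sprintf("  objective:    %s\n", x$objective))
  invisible(x)
}

#' Model summary counts
#'
#' Tabulates reaction/metabolite/gene counts and a per-compartment breakdown.
#' A reaction whose metabolites span more than one compartment is counted as
#' transport; a single-compartment reaction is attributed to that compartment.
#'
#' @param object a `metabolic_model`.
#' @param ... unused.
#' @return A list of counts.
#' @export
summary.metabolic_model <- function(object, ...) {
  comp_of <- function(keys) unique(sub("^.*\\[([A-Za-z0-9]+)\\]$", "\\1", keys))
  rxn_comps <- lapply(object$reactions$id,
                      function(id) comp_of(names(reaction_stoich(object, id))))
  is_transport <- vapply(rxn_comps, function(cc) length(cc) > 1, logical(1))
  by_comp <- table(factor(unlist(rxn_comps[!is_transport]),
                          levels = object$compartments))
  list(n_reactions = nrow(object$reactions),
       n_metabolites = nrow(object$metabolites),
       n_genes = length(object$genes),
       n_transport = sum(is_transport),
       reactions_by_compartment = as.list(by_comp),
       compartments = object$compartments)
}

#' Validate model invariants
#'
#' Re-checks the `metabolic_model` invariants (unique ids, consistent matrix
#' dimensions, bounds ordering, objective present, no dangling metabolites).
#' Called by the constructor; exposed for use after manual edits.
#'
#' @param model a `metabolic_model`.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  stopifnot(identical(dim(model$stoich),
                      c(nrow(model$metabolites), nrow(model$reactions))))
  stopifnot(!anyDuplicated(model$reactions$id),
            !anyDuplicated(model$metabolites$key))
  stopifnot(all(model$reactions$lb <= model$reactions$ub))
  stopifnot(model$objective %in% model$reactions$id)
  invisible(TRUE)
}
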