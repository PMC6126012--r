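# Model readers and writers.
#
# The canonical dialect is a pair of tab-separated tables in one directory:
#   metabolites.tsv: id, name, compartment
#   reactions.tsv:   id, name, equation, lb, ub, gpr, subsystem
# mirroring supplementary-table model distributions.  SBML Level 3 with the
# FBC extension is supported read-only.

#' Load a metabolic model
#'
#' @param path for `format = "tabular"`, a directory containing
#'   `metabolites.tsv` and `reactions.tsv`; for `format = "sbml"`, an SBML
#'   file (Level 3, FBC flux bounds and gene associations).
#' @param format input dialect.
#' @param objective objective reaction id; for tabular input defaults to the
#'   reaction whose id or subsystem contains "growth"/"biomass"
#'   (case-insensitive), for SBML to the active FBC objective.
#' @return A [metabolic_model()].
#' @export
load_model <- function(path, format = c("tabular", "sbml"), objective = NULL) {
  format <- match.arg(format)
  switch(format,
         tabular = read_model_tabular(path, objective = objective),
         sbml = read_model_sbml(path, objective = objective))
}

.guess_objective <- function(reactions) {
  hit <- grepl("growth|biomass", reactions$id, ignore.case = TRUE) |
    grepl("growth|biomass", reactions$subsystem, ignore.case = TRUE)
  if (sum(hit) != 1)
    stop("cannot infer the objective reaction; pass `objective=` explicitly",
         call. = FALSE)
  reactions$id[hit]
}

#' @rdname load_model
#' @export
read_model_tabular <- function(path, objective = NULL) {
  met_file <- file.path(path, "metabolites.tsv")
  rxn_file <- file.path(path, "reactions.tsv")
  if (!file.exists(met_file) || !file.exists(rxn_file))
    stop("expected metabolites.tsv and reactions.tsv under '", path, "'",
         call. = FALSE)
  mets <- utils::read.delim(met_file, stringsAsFactors = FALSE, quote = "",
                            comment.char = "", colClasses = "character")
  rxns <- utils::read.delim(rxn_file, stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  rxns$gpr[is.na(rxns$gpr)] <- ""
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  compartments <- sort(unique(mets$compartment))
  parsed <- lapply(seq_len(nrow(rxns)), function(i) {
    tryCatch(parse_equation(rxns$equation[i], compartments = compartments),
             error = function(e) stop("reaction '", rxns$id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  stoich <- lapply(parsed, `[[`, "stoich")
  reactions <- data.frame(id = rxns$id, name = rxns$name,
                          lb = as.numeric(rxns$lb), ub = as.numeric(rxns$ub),
                          gpr = rxns$gpr, subsystem = rxns$subsystem,
                          stringsAsFactors = FALSE)
  if (is.null(objective)) objective <- .guess_objective(reactions)
  metabolic_model(mets, reactions, stoich, objective,
                  compartments = compartments)
}

#' Write a model in the tabular dialect
#'
#' Writes `metabolites.tsv` and `reactions.tsv` under `path` with canonical
#' equation strings, so that `load_model(write_model_tabular(...))`
#' reproduces the model field by field.
#'
#' @param model a `metabolic_model`.
#' @param path output directory (created if missing).
#' @return Invisibly, `path`.
#' @export
write_model_tabular <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mets <- model$metabolites[, c("id", "name", "compartment")]
  eqs <- vapply(model$reactions$id, function(id) {
    r <- model$reactions[model$reactions$id == id, ]
    format_equation(reaction_stoich(model, id),
                    reversible = r$lb < 0 && r$ub > 0)
  }, character(1))
  rxns <- data.frame(id = model$reactions$id, name = model$reactions$name,
                     equation = eqs, lb = model$reactions$lb,
                     ub = model$reactions$ub, gpr = model$reactions$gpr,
                     subsystem = model$reactions$subsystem,
                     stringsAsFactors = FALSE)
  utils::write.table(mets, file.path(path, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rxns, file.path(path, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- SBML (Level 3 FBC), read-only ------------------------------------------

.sbml_gpr <- function(node) {
  # node is an <fbc:geneProductAssociation> child: geneProductRef / and / or
  name <- xml2::xml_name(node)
  if (name == "geneProductRef")
    return(list(kind = "GENE", gene = xml2::xml_attr(node, "geneProduct")))
  kids <- lapply(xml2::xml_children(node), .sbml_gpr)
  kids <- kids[!vapply(kids, is.null, logical(1))]
  if (length(kids) == 0) return(NULL)
  .gpr_node(toupper(name), kids)
}

#' @rdname load_model
#' @export
read_model_sbml <- function(path, objective = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_name <- xml2::xml_attr(sp, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  mets <- data.frame(id = sp_id, name = sp_name, compartment = sp_comp,
                     stringsAsFactors = FALSE)
  key_of <- stats::setNames(paste0(sp_id, "[", sp_comp, "]"), sp_id)

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  # gene product label lookup (fall back to the fbc id)
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(xml2::xml_attr(gps, "label"),
                              xml2::xml_attr(gps, "id"))
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]
  relabel <- function(gpr) {
    if (is.null(gpr)) return(NULL)
    if (identical(gpr$kind, "GENE")) {
      if (gpr$gene %in% names(gp_label)) gpr$gene <- unname(gp_label[gpr$gene])
      return(gpr)
    }
    gpr$children <- lapply(gpr$children, relabel)
    gpr
  }

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rx)
  stoich <- vector("list", n)
  reactions <- data.frame(id = character(n), name = character(n),
                          lb = numeric(n), ub = numeric(n),
                          gpr = character(n), subsystem = character(n),
                          stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- rx[[i]]
    id <- xml2::xml_attr(r, "id")
    nm <- xml2::xml_attr(r, "name")
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lb_ref <- xml2::xml_attr(r, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(r, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]]
          else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]]
          else 1000
    s <- numeric(0)
    for (ref in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      k <- key_of[[xml2::xml_attr(ref, "species")]]
      s[k] <- -as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      k <- key_of[[xml2::xml_attr(ref, "species")]]
      s[k] <- (if (is.null(s[k]) || is.na(s[k])) 0 else s[k]) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids) > 0)
        gpr <- gpr_to_string(relabel(.sbml_gpr(kids[[1]])))
    }
    reactions$id[i] <- id
    reactions$name[i] <- if (is.na(nm)) id else nm
    reactions$lb[i] <- lb
    reactions$ub[i] <- ub
    reactions$gpr[i] <- gpr
    stoich[[i]] <- s
  }

  if (is.null(objective)) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) objective <- xml2::xml_attr(fo, "reaction")
    if (is.null(objective) || is.na(objective))
      objective <- .guess_objective(reactions)
  }
  metabolic_model(mets, reactions, stoich, objective,
                  compartments = sort(unique(mets$compartment)))
}

# --- Refinement patches ------------------------------------------------------

#' Create a model patch
#'
#' A patch is a mechanical edit list: bound and/or stoichiometry modifications
#' of existing reactions, deletions, and additions of new reactions.  The
#' curation judgements behind a patch live outside the package; applying one
#' is purely structural.
#'
#' @param modify list of modification entries, each a list with `id` and any
#'   of `lb`, `ub`, `equation` (canonical equation string replacing the
#'   stoichiometry), `gpr`, `subsystem`.
#' @param delete character vector of reaction ids to remove.
#' @param add list of new-reaction entries, each a list with `id`, `equation`
#'   and optionally `name`, `lb`, `ub`, `gpr`, `subsystem`.
#' @return An object of class `model_patch`.
#' @export
model_patch <- function(modify = list(), delete = character(0), add = list()) {
  structure(list(modify = modify, delete = as.character(delete), add = add),
            class = "model_patch")
}

#' Read a patch from JSON
#'
#' Expects an object `{"modify": [...], "delete": [...], "add": [...]}` with
#' entries as in [model_patch()].
#'
#' @param path JSON file.
#' @return A `model_patch`.
#' @export
read_patch_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  model_patch(modify = if (is.null(p$modify)) list() else p$modify,
              delete = unlist(p$delete, use.names = FALSE) %||% character(0),
              add = if (is.null(p$add)) list() else p$add)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a refinement patch to a model
#'
#' Deletions are applied first, then modifications, then additions; the input
#' model is not mutated.  The resulting reaction count is
#' `old - length(delete) + length(add)`.
#'
#' @param model a `metabolic_model`.
#' @param patch a [model_patch()].
#' @return The patched `metabolic_model`.
#' @export
apply_patch <- function(model, patch) {
  stopifnot(inherits(model, "metabolic_model"), inherits(patch, "model_patch"))
  rxns <- model$reactions
  stoich <- lapply(rxns$id, function(id) reaction_stoich(model, id))
  names(stoich) <- rxns$id

  missing_del <- setdiff(patch$delete, rxns$id)
  if (length(missing_del))
    stop("patch deletes unknown reaction(s): ",
         paste(missing_del, collapse = ", "), call. = FALSE)
  if (model$objective %in% patch$delete)
    stop("patch would delete the objective reaction '", model$objective, "'",
         call. = FALSE)
  keep <- !rxns$id %in% patch$delete
  rxns <- rxns[keep, , drop = FALSE]
  stoich <- stoich[keep]

  for (m in patch$modify) {
    i <- match(m$id, rxns$id)
    if (is.na(i))
      stop("patch modifies unknown reaction '", m$id, "'", call. = FALSE)
    if (!is.null(m$lb)) rxns$lb[i] <- as.numeric(m$lb)
    if (!is.null(m$ub)) rxns$ub[i] <- as.numeric(m$ub)
    if (!is.null(m$equation)) {
      pe <- parse_equation(m$equation, compartments = model$compartments)
      stoich[[i]] <- pe$stoich
    }
    if (!is.null(m$gpr)) rxns$gpr[i] <- m$gpr
    if (!is.null(m$subsystem)) rxns$subsystem[i] <- m$subsystem
  }

  for (a in patch$add) {
    if (a$id %in% rxns$id)
      stop("patch adds reaction '", a$id, "' which already exists", call. = FALSE)
    pe <- parse_equation(a$equation, compartments = model$compartments)
    rxns <- rbind(rxns, data.frame(id = a$id, name = a$name %||% a$id,
                                   lb = as.numeric(a$lb %||% if (pe$reversible) -1000 else 0),
                                   ub = as.numeric(a$ub %||% 1000),
                                   gpr = a$gpr %||% "",
                                   subsystem = a$subsystem %||% "",
                                   stringsAsFactors = FALSE))
    stoich <- c(stoich, stats::setNames(list(pe$stoich), a$id))
  }

  metabolic_model(model$metabolites[, c("id", "name", "compartment")],
                  rxns, unname(stoich), model$objective,
                  compartments = model$compartments)
}
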