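# End-to-end pipeline: load/patch model -> phase plane + line of optimality
# -> designed sweep -> PCA + response classes -> cofactor ledgers -> yield
# fit -> expression comparison, with every artifact written as a TSV/JSON
# bundle carrying a provenance header.

.write_tsv <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance, con)
  utils::write.table(format(df, digits = 6, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Default pipeline configuration (toy model)
#'
#' @param seed integer seed used for the synthetic expression stage.
#' @return A nested list understood by [run_pipeline()]; set `model$path`
#'   and `model$format` to analyse a model from disk instead of the
#'   generated toy.
#' @export
pipeline_config <- function(seed = 1) {
  list(
    model = list(path = NULL, format = "tabular", patch = NULL),
    substrate_id = "EX_XYL", o2_id = "EX_O2",
    observables = c(co2 = "EX_CO2", ethanol = "EX_ETOH", xylitol = "EX_XYLT"),
    xr = list(nadph = "XYLR2", nadh = "XYLR1"),
    phpp = list(substrate = seq(0.5, 5, length.out = 10),
                o2 = seq(0, 12, length.out = 13)),
    lo_uptakes = 1:5,
    sweep = list(our = c(2.33, 1.42), ratio = c(0.94, 0.11), xylose = 5,
                 n = 10),
    ledger = list(cofactors = list(c("nadh", "c"), c("nadph", "c"),
                                   c("q6h2", "m"))),
    shuttles = NULL,   # defaults to toy_shuttles() for the toy model
    fit = list(y_target = NULL, our_range = c(0.1, 3), ratio_range = c(0, 1),
               n_grid = 21),
    expression = list(p = 0.75, n_samples = 2),
    zero_tol = ZERO_FLUX_TOL, tpm_threshold = 0.10,
    seed = seed
  )
}

#' Run the full analysis pipeline
#'
#' Sequences every stage of the workflow on one model and writes a report
#' bundle: model summary, phase-plane table, line of optimality, sweep flux
#' matrix, PCA loadings with response classes, cofactor ledgers and deltas,
#' electron accounting, a yield fit, and the flux/expression agreement
#' report (on synthetic tables when no measured ones are supplied).  Each
#' artifact starts with provenance comment lines (config hash, package
#' version, seed).  A stage failure aborts with the stage name; artifacts
#' already written are left in place.
#'
#' @param config list from [pipeline_config()], or the path of a YAML file
#'   with the same structure.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- .hash_config(config)
  ver <- tryCatch(as.character(utils::packageVersion("redoxsid")),
                  error = function(e) "dev")
  prov <- c(paste0("# redoxsid ", ver),
            paste0("# config_hash ", cfg_hash),
            paste0("# seed ", config$seed))
  stage <- function(name, fun) {
    message("[pipeline] ", name)
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list()

  res$model <- stage("model", function() {
    model <- if (is.null(config$model$path)) make_toy_model()
             else load_model(config$model$path, config$model$format)
    if (!is.null(config$model$patch))
      model <- apply_patch(model, read_patch_json(config$model$patch))
    s <- summary(model)
    .write_tsv(data.frame(quantity = c("reactions", "metabolites", "genes",
                                       "transport"),
                          count = c(s$n_reactions, s$n_metabolites,
                                    s$n_genes, s$n_transport)),
               file.path(out_dir, "model_summary.tsv"), prov)
    model
  })
  model <- res$model
  subs <- config$substrate_id
  o2 <- config$o2_id
  ratio0 <- config$sweep$ratio[1]

  res$phpp <- stage("phpp", function() {
    base <- add_ratio_coupling(condition_spec(), config$xr$nadph,
                               config$xr$nadh, ratio0)
    grid <- compute_phpp(model, subs, o2, substrate = config$phpp$substrate,
                         o2 = config$phpp$o2,
                         observables = config$observables, condition = base)
    phase <- segment_phases(grid, tol = config$zero_tol)
    .write_tsv(phpp_table(grid, phase), file.path(out_dir, "phpp.tsv"), prov)
    list(grid = grid, phase = phase)
  })

  res$lo <- stage("line_of_optimality", function() {
    lo <- find_lo(model, subs, config$lo_uptakes, o2)
    .write_tsv(cbind(lo$points, slope = lo$slope),
               file.path(out_dir, "lo.tsv"), prov)
    lo
  })

  res$sweep <- stage("sweep", function() {
    a <- toy_like_condition(config, config$sweep$our[1], config$sweep$ratio[1])
    b <- toy_like_condition(config, config$sweep$our[2], config$sweep$ratio[2])
    conditions <- design_sweep(a, b, config$sweep$n)
    fm <- assemble_flux_matrix(model, conditions)
    .write_tsv(data.frame(step = seq_len(nrow(fm)), fm, check.names = FALSE),
               file.path(out_dir, "flux_matrix.tsv"), prov)
    list(conditions = conditions, flux_matrix = fm)
  })

  res$pca <- stage("pca", function() {
    pca <- run_pca(res$sweep$flux_matrix)
    cls <- classify_response(res$sweep$flux_matrix, tol = config$zero_tol)
    .write_tsv(data.frame(reaction = rownames(pca$loadings),
                          pc1_loading = pca$loadings[, 1],
                          class = unname(cls[rownames(pca$loadings)])),
               file.path(out_dir, "pca_loadings.tsv"), prov)
    list(pca = pca, classes = cls)
  })

  res$ledgers <- stage("ledgers", function() {
    cond_a <- res$sweep$conditions[[1]]
    cond_b <- res$sweep$conditions[[length(res$sweep$conditions)]]
    sol_a <- solve_pfba(model, cond_a)
    sol_b <- solve_pfba(model, cond_b)
    out <- list()
    rows <- list()
    for (cf in config$ledger$cofactors) {
      la <- build_ledger(model, sol_a, cf[1], cf[2])
      lb <- build_ledger(model, sol_b, cf[1], cf[2])
      d <- ledger_delta(la, lb)
      out[[paste(cf, collapse = "_")]] <- list(a = la, b = lb, delta = d)
      rows[[length(rows) + 1]] <-
        data.frame(cofactor = cf[1], compartment = cf[2],
                   produced_a = la$produced, produced_b = lb$produced,
                   produced_change = d$produced_change)
    }
    .write_tsv(do.call(rbind, rows), file.path(out_dir, "ledger_summary.tsv"),
               prov)
    shuttles <- config$shuttles %||% toy_shuttles()
    sh <- do.call(rbind, lapply(names(shuttles), function(nm)
      data.frame(shuttle = nm,
                 flux_a = shuttle_flux(model, sol_a, shuttles[[nm]]),
                 flux_b = shuttle_flux(model, sol_b, shuttles[[nm]]))))
    .write_tsv(sh, file.path(out_dir, "shuttle_flux.tsv"), prov)
    q6 <- out[["q6h2_m"]]
    ea <- if (!is.null(q6))
      electron_accounting(q6$delta$produced_change, config$sweep$our[1],
                          config$sweep$our[2]) else NA_real_
    jsonlite::write_json(list(electron_accounting_pct = ea),
                         file.path(out_dir, "electron_accounting.json"),
                         auto_unbox = TRUE, digits = NA)
    c(out, list(shuttles = sh, electron_accounting_pct = ea,
                solution_a = sol_a, solution_b = sol_b))
  })

  res$fit <- stage("fit", function() {
    y_target <- config$fit$y_target
    if (is.null(y_target)) {
      # default: recover the sweep's first endpoint from its own yield
      sol <- res$ledgers$solution_a
      y_target <- sol$fluxes[[config$observables[["ethanol"]]]] /
        config$sweep$xylose
    }
    fit <- fit_condition(model, y_target, subs, o2,
                         substrate_uptake = config$sweep$xylose,
                         xr_nadph = config$xr$nadph, xr_nadh = config$xr$nadh,
                         ethanol_id = config$observables[["ethanol"]],
                         xylitol_id = config$observables[["xylitol"]],
                         our_range = config$fit$our_range,
                         ratio_range = config$fit$ratio_range,
                         n_grid = config$fit$n_grid)
    jsonlite::write_json(list(our = fit$our, ratio = fit$ratio,
                              yield = fit$yield, xylitol = fit$xylitol,
                              residual = fit$residual),
                         file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  res$expression <- stage("expression", function() {
    scope0 <- toy_scope(model)
    cls <- res$pca$classes
    fm <- res$sweep$flux_matrix
    active <- colnames(fm)[apply(abs(fm), 2, max) > config$zero_tol]
    scope <- intersect(scope0, active)
    fcalls <- flux_symbols(cls)[scope]
    set.seed(config$seed %% .Machine$integer.max)
    synth <- make_synthetic_expression(
      model, fcalls,
      synthetic_expression_spec(p = config$expression$p,
                                threshold = config$tpm_threshold),
      n_samples = config$expression$n_samples)
    aero_cols <- grep("^aerobic_", names(synth$table), value = TRUE)
    lim_cols <- grep("^limited_", names(synth$table), value = TRUE)
    e_a <- reaction_expression_profile(model, synth$table, aero_cols, scope)
    e_l <- reaction_expression_profile(model, synth$table, lim_cols, scope)
    ecalls <- expression_change(e_a, e_l, threshold = config$tpm_threshold)
    sc <- agreement_score(fcalls, ecalls, scope)
    .write_tsv(sc$table, file.path(out_dir, "expression_agreement.tsv"), prov)
    jsonlite::write_json(list(agreement_pct = sc$agreement, n = sc$n),
                         file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
    sc
  })

  invisible(res)
}

# Sweep endpoint condition from pipeline config scalars.
#' @keywords internal
#' @noRd
toy_like_condition <- function(config, our, ratio) {
  cond <- set_uptake(condition_spec(), config$substrate_id,
                     config$sweep$xylose)
  cond <- set_uptake(cond, config$o2_id, our)
  add_ratio_coupling(cond, config$xr$nadph, config$xr$nadh, ratio)
}

#' @keywords internal
#' @noRd
.hash_config <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  tmp <- tempfile()
  writeLines(txt, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
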