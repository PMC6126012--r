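# Synthetic paired expression tables with a planted agreement rate.
#
# For benchmarking the flux/transcript comparison without sequencing data:
# per scored reaction, with probability p the gene-level TPMs are drawn so
# the GPR-evaluated expression change matches the reaction's flux-change
# symbol (beyond the 10% calling threshold, in the matching direction), and
# with probability 1-p one of the other two symbols is planted instead.
# Every toy reaction owns its genes, so reaction-level fold changes can be
# realised by scaling all of a reaction's genes together, which commutes
# with both the OR-sum and the AND-min rule.

#' Synthetic-expression generator settings
#'
#' @param p planted probability that a reaction's expression change agrees
#'   with its flux call.
#' @param fold_up range of relative increase planted for `"+"` calls
#'   (drawn uniformly; must stay above the calling threshold).
#' @param fold_down range of relative decrease planted for `"-"` calls.
#' @param fold_null range of relative change planted for `"o"` calls (within
#'   the threshold).
#' @param noise_sd multiplicative log-normal noise between duplicate samples.
#' @param threshold change-calling threshold the plants must respect.
#' @return A `synthetic_expression_spec` list.
#' @export
synthetic_expression_spec <- function(p = 0.75, fold_up = c(0.2, 1.0),
                                      fold_down = c(0.2, 0.6),
                                      fold_null = c(-0.05, 0.05),
                                      noise_sd = 0.01, threshold = 0.10) {
  stopifnot(p >= 0, p <= 1, fold_up[1] > threshold, fold_down[1] > threshold,
            max(abs(fold_null)) < threshold)
  structure(list(p = p, fold_up = fold_up, fold_down = fold_down,
                 fold_null = fold_null, noise_sd = noise_sd,
                 threshold = threshold),
            class = "synthetic_expression_spec")
}

#' Generate paired aerobic/oxygen-limited expression tables
#'
#' @param model a [metabolic_model()] whose scored reactions have GPR rules
#'   with reaction-private genes (the toy model qualifies).
#' @param flux_calls named character vector of `+`/`-`/`o` symbols over the
#'   scored reactions (see [flux_symbols()]).
#' @param spec a [synthetic_expression_spec()].
#' @param n_samples duplicate samples per condition (the chemostat-style
#'   "two samples 10 min apart").
#' @return A list: `table` (data.frame: `gene`, then
#'   `aerobic_1..n`/`limited_1..n` TPM columns), `planted` (the symbol
#'   planted per reaction).  Baseline TPMs are log-uniform on \[1, 1000\].
#'   Call [set.seed()] (or `withr::with_seed()`) beforehand for
#'   reproducibility.
#' @export
make_synthetic_expression <- function(model, flux_calls,
                                      spec = synthetic_expression_spec(),
                                      n_samples = 2) {
  stopifnot(inherits(spec, "synthetic_expression_spec"), n_samples >= 1)
  rxns <- names(flux_calls)
  stopifnot(all(rxns %in% model$reactions$id))
  planted <- character(length(rxns))
  names(planted) <- rxns
  genes <- character(0)
  aerobic <- numeric(0)
  limited <- numeric(0)
  symbols <- c("+", "-", "o")
  for (r in rxns) {
    call <- flux_calls[[r]]
    agree <- stats::runif(1) < spec$p
    planted[r] <- if (agree) call else sample(setdiff(symbols, call), 1)
    fold <- switch(planted[r],
                   "+" = 1 + stats::runif(1, spec$fold_up[1], spec$fold_up[2]),
                   "-" = 1 - stats::runif(1, spec$fold_down[1], spec$fold_down[2]),
                   "o" = 1 + stats::runif(1, spec$fold_null[1], spec$fold_null[2]))
    gset <- gpr_genes(parse_gpr(model$reactions$gpr[model$reactions$id == r]))
    base <- 10^stats::runif(length(gset), 0, 3)
    genes <- c(genes, gset)
    aerobic <- c(aerobic, base)
    limited <- c(limited, base * fold)
  }
  if (anyDuplicated(genes))
    stop("scored reactions share genes; planted fold changes would collide",
         call. = FALSE)
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (k in seq_len(n_samples))
    tab[[paste0("aerobic_", k)]] <-
      aerobic * exp(stats::rnorm(length(genes), 0, spec$noise_sd))
  for (k in seq_len(n_samples))
    tab[[paste0("limited_", k)]] <-
      limited * exp(stats::rnorm(length(genes), 0, spec$noise_sd))
  list(table = tab, planted = planted)
}

#' Average a sample group and evaluate reaction expression
#'
#' Averages the TPM columns of one condition (duplicate chemostat samples)
#' and evaluates each scored reaction's GPR.
#'
#' @param model a [metabolic_model()].
#' @param table expression data.frame (`gene` plus sample columns).
#' @param columns names of the sample columns to average.
#' @param reactions reaction ids to evaluate (must have non-empty GPRs).
#' @return Named numeric vector of reaction-expression values.
#' @export
reaction_expression_profile <- function(model, table, columns, reactions) {
  stopifnot(all(columns %in% names(table)))
  expr <- rowMeans(as.matrix(table[columns]))
  names(expr) <- table$gene
  vapply(reactions, function(r) {
    gpr <- model$reactions$gpr[model$reactions$id == r]
    reaction_expression(gpr, expr)
  }, numeric(1))
}
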