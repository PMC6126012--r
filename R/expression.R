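# GPR-based reaction expression and flux/transcript agreement scoring.
#
# Reaction expression from gene expression follows the standard GPR rules:
# isozymes (OR) sum, complex subunits (AND) take the minimum.  Change calls
# use a relative threshold against the aerobic level (default 10%), and the
# agreement score is the fraction of scored reactions whose flux-change
# direction matches the expression-change direction.

#' Read a gene-expression table
#'
#' @param path TSV with a `gene` column and one numeric column per sample
#'   (TPM).
#' @return data.frame; negative values are rejected.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  stopifnot("gene" %in% names(tab))
  vals <- tab[setdiff(names(tab), "gene")]
  if (any(vapply(vals, function(x) any(x < 0, na.rm = TRUE), logical(1))))
    stop("expression values (TPM) must be >= 0", call. = FALSE)
  tab
}

.eval_gpr <- function(gpr, expr) {
  # returns list(value, present); genes absent from the table contribute 0 to
  # OR sums and are skipped inside AND minima
  if (identical(gpr$kind, "GENE")) {
    present <- gpr$gene %in% names(expr)
    return(list(value = if (present) unname(expr[[gpr$gene]]) else 0,
                present = present))
  }
  kids <- lapply(gpr$children, .eval_gpr, expr = expr)
  if (identical(gpr$kind, "OR")) {
    return(list(value = sum(vapply(kids, `[[`, numeric(1), "value")),
                present = any(vapply(kids, `[[`, logical(1), "present"))))
  }
  # AND: minimum over children with any table support
  pres <- vapply(kids, `[[`, logical(1), "present")
  if (!any(pres)) return(list(value = 0, present = FALSE))
  list(value = min(vapply(kids[pres], `[[`, numeric(1), "value")),
       present = TRUE)
}

#' Reaction expression from a GPR rule
#'
#' OR nodes (isozymes) sum their children's expression; AND nodes (complex
#' subunits) take the minimum; a gene maps to its TPM, 0 when missing from
#' the sample.  Genes entirely absent from the table are skipped inside AND
#' minima so annotation gaps do not zero out a complex.
#'
#' @param gpr GPR tree from [parse_gpr()] (or a rule string); `NULL`/empty is
#'   an error — reactions without gene association are excluded from
#'   comparison upstream.
#' @param expr named numeric vector of gene TPMs for one sample.
#' @return Numeric reaction-expression value.
#' @examples
#' reaction_expression(parse_gpr("g1 or g2"), c(g1 = 10, g2 = 5))   # 15
#' reaction_expression(parse_gpr("g1 and g2"), c(g1 = 10, g2 = 5))  # 5
#' @export
reaction_expression <- function(gpr, expr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr))
    stop("reaction has no gene association; expression undefined", call. = FALSE)
  .eval_gpr(gpr, expr)$value
}

#' Call an expression change between two conditions
#'
#' `"+"` when the relative change from the aerobic level exceeds `threshold`,
#' `"-"` when it is below `-threshold`, `"o"` otherwise.  An aerobic level of
#' zero with non-zero limited expression is called `"+"` and flagged (no
#' relative change exists); zero in both is `"o"`.
#'
#' @param aerobic,limited numeric vectors of reaction-expression values.
#' @param threshold relative-change threshold (default 0.10).
#' @return Character vector in `+`/`-`/`o` with attribute `flagged` marking
#'   zero-baseline calls.
#' @export
expression_change <- function(aerobic, limited, threshold = 0.10) {
  n <- max(length(aerobic), length(limited))
  nms <- names(aerobic) %||% names(limited)
  aerobic <- rep_len(aerobic, n)
  limited <- rep_len(limited, n)
  flagged <- aerobic == 0 & limited > 0
  rel <- ifelse(aerobic > 0, (limited - aerobic) / aerobic, 0)
  sym <- ifelse(flagged, "+",
                ifelse(rel > threshold, "+",
                       ifelse(rel < -threshold, "-", "o")))
  out <- stats::setNames(as.character(sym), nms)
  attr(out, "flagged") <- flagged
  out
}

#' Map response classes to change symbols
#'
#' Translates [classify_response()] output to `+`/`-`/`o` for comparison with
#' expression-change calls (`up` is `+`, `down` is `-`, no change is `o`).
#'
#' @param response named character vector from [classify_response()].
#' @return Named character vector of symbols.
#' @export
flux_symbols <- function(response) {
  stats::setNames(c(up = "+", down = "-", inactive = "o")[response],
                  names(response))
}

#' Flux/expression change agreement
#'
#' Fraction (in percent) of scoped reactions whose flux-change symbol equals
#' the expression-change symbol.  The scope should already exclude zero-flux
#' reactions, exchange/transport reactions and any reaction whose routes
#' cannot be told apart at the transcript level (e.g. the two cofactor routes
#' of one xylose reductase enzyme); `"o"` counts as agreement only against a
#' no-change flux call.
#'
#' @param flux_calls,expr_calls named character vectors of symbols
#'   (`+`/`-`/`o`); see [flux_symbols()] and [expression_change()].
#' @param scope character vector of reaction ids to score (non-empty; all
#'   must be present in both call sets).
#' @return A list: `agreement` (percent), `n`, and `table` (per-reaction
#'   data.frame with `reaction`, `flux`, `expression`, `agree`).
#' @export
agreement_score <- function(flux_calls, expr_calls, scope) {
  if (length(scope) == 0)
    stop("empty comparison scope", call. = FALSE)
  missing <- setdiff(scope, intersect(names(flux_calls), names(expr_calls)))
  if (length(missing))
    stop("scope reaction(s) missing from the calls: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- data.frame(reaction = scope,
                    flux = unname(flux_calls[scope]),
                    expression = unname(expr_calls[scope]),
                    stringsAsFactors = FALSE)
  tab$agree <- tab$flux == tab$expression
  list(agreement = 100 * mean(tab$agree), n = length(scope), table = tab)
}
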