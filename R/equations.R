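# Reaction-equation strings.
#
# The tabular model dialect writes reactions as signed "coef met[comp]" terms
# joined by "+", e.g. "-1 nad[c] + -1 pi[c] + -1 g3p[c] <=> 1 h[c] + 1 nadh[c]".
# Unicode minus and long arrows, as they appear in supplementary model tables,
# are normalised to ASCII before parsing.

.normalize_equation <- function(text) {
  text <- gsub("\u2212", "-", text)               # unicode minus
  text <- gsub("\u27f7|\u2194", "<=>", text)      # long left-right arrow
  text <- gsub("\u27f6|\u2192", "->", text)       # long right arrow
  text <- gsub("<->", "<=>", text, fixed = TRUE)
  text
}

# coefficient (if present) must be whitespace-separated from the metabolite,
# so ids that start with digits ("13dpg") are not mistaken for coefficients
.term_re_coef <- "^\\s*([+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?)\\s+([^][[:space:]]+)\\[([A-Za-z0-9]+)\\]\\s*$"
.term_re_bare <- "^\\s*()([^][[:space:]]+)\\[([A-Za-z0-9]+)\\]\\s*$"

.parse_side <- function(side, side_sign, compartments = NULL) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  terms <- strsplit(side, "+", fixed = TRUE)[[1]]
  terms <- terms[nzchar(trimws(terms))]
  out <- numeric(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec(.term_re_coef, tm))[[1]]
    if (length(m) == 0)
      m <- regmatches(tm, regexec(.term_re_bare, tm))[[1]]
    if (length(m) == 0)
      stop("malformed equation term: '", trimws(tm), "'", call. = FALSE)
    coef_txt <- m[2]
    met <- m[3]
    comp <- m[4]
    if (!is.null(compartments) && !comp %in% compartments)
      stop("unknown compartment tag '", comp, "' in term '", trimws(tm), "'",
           call. = FALSE)
    if (nzchar(coef_txt)) {
      coef <- as.numeric(coef_txt)
      # unsigned coefficients take the conventional side sign
      if (!grepl("^[+-]", coef_txt)) coef <- side_sign * coef
    } else {
      coef <- side_sign
    }
    key <- paste0(met, "[", comp, "]")
    out[key] <- if (key %in% names(out)) out[[key]] + coef else coef
  }
  out
}

#' Parse a reaction-equation string
#'
#' Parses equations written as signed `coef met[comp]` terms joined by `+`,
#' with `<=>` (reversible) or `->` (irreversible) separating substrates from
#' products.  Unicode minus signs and long arrows are accepted.  Coefficients
#' carrying an explicit sign are taken verbatim; unsigned coefficients are
#' negated on the substrate side, so both the signed supplementary-table style
#' and the conventional `A + B -> C` style parse to the same stoichiometry.
#'
#' @param text equation string.
#' @param compartments optional character vector of valid compartment tags;
#'   when supplied, an unknown tag is an error.
#' @return A list with elements `stoich` (named numeric vector of net
#'   coefficients keyed by `met[comp]`, negative for substrates), `reversible`
#'   (logical) and `null` (logical; `TRUE` when every net coefficient cancels,
#'   as in an identity exchange written on both sides).
#' @examples
#' parse_equation("-1 h[c] + -1 nadh[c] + -1 q6[m] -> 1 nad[c] + 1 q6h2[m]")
#' @export
parse_equation <- function(text, compartments = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  eq <- .normalize_equation(text)
  reversible <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  if (!grepl(arrow, eq, fixed = TRUE))
    stop("equation has no arrow ('<=>' or '->'): '", text, "'", call. = FALSE)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2)
    stop("equation has more than one arrow: '", text, "'", call. = FALSE)
  lhs <- .parse_side(sides[1], -1, compartments)
  rhs <- if (length(sides) == 2) .parse_side(sides[2], +1, compartments) else numeric(0)
  keys <- union(names(lhs), names(rhs))
  if (length(keys) == 0)
    stop("equation has no metabolites: '", text, "'", call. = FALSE)
  stoich <- vapply(keys, function(k) {
    (if (k %in% names(lhs)) lhs[[k]] else 0) +
      (if (k %in% names(rhs)) rhs[[k]] else 0)
  }, numeric(1))
  null <- all(abs(stoich) < 1e-12)
  stoich <- stoich[abs(stoich) >= 1e-12]
  list(stoich = stoich, reversible = reversible, null = null)
}

.fmt_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Format a stoichiometry as a canonical equation string
#'
#' Inverse of [parse_equation()] on canonical strings: substrates (negative
#' coefficients) are written with explicit negative signs on the left of the
#' arrow, products on the right, each side ordered by metabolite key.
#'
#' @param stoich named numeric vector keyed by `met[comp]`.
#' @param reversible logical; use `<=>` when `TRUE`, `->` otherwise.
#' @return A single equation string.
#' @export
format_equation <- function(stoich, reversible = FALSE) {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)))
  subs <- stoich[stoich < 0]
  prods <- stoich[stoich > 0]
  subs <- subs[order(names(subs))]
  prods <- prods[order(names(prods))]
  lhs <- paste(paste(.fmt_num(subs), names(subs)), collapse = " + ")
  rhs <- paste(paste(.fmt_num(prods), names(prods)), collapse = " + ")
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}
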