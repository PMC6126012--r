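# Gene-protein-reaction (GPR) boolean rules.
#
# A GPR is a boolean expression over gene ids with `and` (complex subunits)
# and `or` (isozymes) and parentheses.  Trees are plain lists:
#   list(kind = "GENE", gene = "g1")
#   list(kind = "AND"|"OR", children = list(...))   # always >= 2 children
# Nested nodes of the same kind are flattened.  `and` binds tighter than `or`.

.gpr_tokenize <- function(text) {
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.gpr_node <- function(kind, children) {
  if (length(children) == 1) return(children[[1]])
  flat <- list()
  for (ch in children) {
    if (is.list(ch) && identical(ch$kind, kind)) flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  list(kind = kind, children = flat)
}

#' Parse a GPR rule string into a boolean tree
#'
#' Operators `and`/`or` (case-insensitive, `&`/`|` also accepted) combine gene
#' ids; `and` binds tighter than `or`.  An empty string yields `NULL`: the
#' reaction has no gene association.
#'
#' @param text GPR rule string, e.g. `"g1 and (g2 or g3)"`.
#' @return A GPR tree (nested list with `kind` in `GENE`, `AND`, `OR`), or
#'   `NULL` for an empty rule.
#' @examples
#' parse_gpr("g1 or g2")
#' parse_gpr("g1 and (g2 or g3)")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- .gpr_tokenize(text)
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- toks[pos]
    pos <<- pos + 1L
    t
  }
  is_op <- function(t, op) !is.na(t) && tolower(t) %in% op

  parse_expr <- function() {
    terms <- list(parse_term())
    while (is_op(peek(), c("or", "|"))) {
      advance()
      terms <- c(terms, list(parse_term()))
    }
    .gpr_node("OR", terms)
  }
  parse_term <- function() {
    factors <- list(parse_factor())
    while (is_op(peek(), c("and", "&"))) {
      advance()
      factors <- c(factors, list(parse_factor()))
    }
    .gpr_node("AND", factors)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR rule: '", text, "'", call. = FALSE)
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (!identical(peek(), ")"))
        stop("unbalanced parentheses in GPR rule: '", text, "'", call. = FALSE)
      advance()
      return(node)
    }
    if (t == ")" || is_op(t, c("and", "or", "&", "|")))
      stop("unexpected token '", t, "' in GPR rule: '", text, "'", call. = FALSE)
    advance()
    list(kind = "GENE", gene = t)
  }

  tree <- parse_expr()
  if (pos <= length(toks))
    stop("trailing tokens in GPR rule: '", text, "'", call. = FALSE)
  tree
}

#' Genes referenced by a GPR tree
#'
#' @param gpr GPR tree from [parse_gpr()], or `NULL`.
#' @return Character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (identical(gpr$kind, "GENE")) return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Serialise a GPR tree back to a rule string
#'
#' @param gpr GPR tree or `NULL`.
#' @return Rule string with lower-case `and`/`or`; `""` for `NULL`.
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (identical(gpr$kind, "GENE")) return(gpr$gene)
  op <- if (identical(gpr$kind, "AND")) " and " else " or "
  parts <- vapply(gpr$children, function(ch) {
    s <- gpr_to_string(ch)
    # parenthesise a child OR under an AND to preserve precedence
    if (identical(gpr$kind, "AND") && identical(ch$kind, "OR"))
      s <- paste0("(", s, ")")
    s
  }, character(1))
  paste(parts, collapse = op)
}
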