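# Gene-protein-reaction (GPR) rules: boolean expressions over gene ids with
# "and" (complex subunits: all required) and "or" (isozymes: any suffices).
# Parsed once into a small AST, then evaluated under discrete semantics (for
# core/noncore/inactive classification) or continuous semantics (for E-Flux
# reaction scores).

#' Parse a GPR rule string
#'
#' Grammar: genes combined with `and` / `or` (case-insensitive) and
#' parentheses; `and` binds tighter than `or`.
#'
#' @param rule_text the rule, e.g. `"(g1 and g2) or g3"`.
#' @return an object of class `gpr_expression` (an AST with node kinds
#'   `gene`, `and`, `or`), carrying the source text as attribute.
#' @export
parse_gpr <- function(rule_text) {
  if (is.null(rule_text) || is.na(rule_text) || !nzchar(trimws(rule_text))) {
    abort("parse_gpr: empty rule")
  }
  toks <- gpr_tokenize(rule_text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  ast <- gpr_parse_or(state, rule_text)
  if (state$pos <= nrow(state$toks)) {
    gpr_parse_error(rule_text, state$toks[state$pos, ],
                    "unexpected trailing token")
  }
  structure(ast, class = "gpr_expression", source_text = rule_text)
}

gpr_tokenize <- function(text) {
  pattern <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) abort("parse_gpr: empty rule")
  vals <- regmatches(text, list(m))[[1]]
  type <- vapply(vals, function(v) {
    lv <- tolower(v)
    if (v == "(") "lparen"
    else if (v == ")") "rparen"
    else if (lv == "and") "and"
    else if (lv == "or") "or"
    else "gene"
  }, character(1), USE.NAMES = FALSE)
  tibble(value = vals, type = type, pos = as.integer(m))
}

gpr_parse_error <- function(text, tok, what) {
  if (is.null(tok)) {
    abort(sprintf("GPR parse error in '%s': %s at end of input", text, what))
  }
  abort(sprintf("GPR parse error in '%s': %s at position %d ('%s')",
                text, what, tok$pos, tok$value))
}

gpr_peek <- function(state) {
  if (state$pos > nrow(state$toks)) NULL else state$toks[state$pos, ]
}

# associative chains are flattened (a and (b and c) == a and b and c), which
# makes the parse -> serialise -> parse round trip structurally stable
gpr_flatten <- function(kind, children) {
  out <- list()
  for (ch in children) {
    if (identical(ch$kind, kind)) out <- c(out, ch$children) else out <- c(out, list(ch))
  }
  out
}

gpr_parse_or <- function(state, text) {
  children <- list(gpr_parse_and(state, text))
  repeat {
    tok <- gpr_peek(state)
    if (is.null(tok) || tok$type != "or") break
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_and(state, text)))
  }
  if (length(children) == 1L) return(children[[1]])
  list(kind = "or", children = gpr_flatten("or", children))
}

gpr_parse_and <- function(state, text) {
  children <- list(gpr_parse_atom(state, text))
  repeat {
    tok <- gpr_peek(state)
    if (is.null(tok) || tok$type != "and") break
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_atom(state, text)))
  }
  if (length(children) == 1L) return(children[[1]])
  list(kind = "and", children = gpr_flatten("and", children))
}

gpr_parse_atom <- function(state, text) {
  tok <- gpr_peek(state)
  if (is.null(tok)) gpr_parse_error(text, NULL, "dangling operator")
  if (tok$type == "gene") {
    state$pos <- state$pos + 1L
    return(list(kind = "gene", id = tok$value))
  }
  if (tok$type == "lparen") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state, text)
    tok2 <- gpr_peek(state)
    if (is.null(tok2) || tok2$type != "rparen") {
      gpr_parse_error(text, tok2, "unbalanced parentheses, expected ')'")
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  gpr_parse_error(text, tok, "expected gene or '('")
}

#' Serialise a GPR AST back to rule text
#'
#' @param expr a `gpr_expression` (or bare AST node).
#' @return a rule string that re-parses to a structurally equal AST.
#' @export
serialize_gpr <- function(expr) {
  node <- unclass(expr)
  wrap <- function(n, inside_and) {
    switch(n$kind,
      gene = n$id,
      and = paste(vapply(n$children, wrap, character(1), inside_and = TRUE),
                  collapse = " and "),
      or = {
        s <- paste(vapply(n$children, wrap, character(1), inside_and = FALSE),
                   collapse = " or ")
        if (inside_and) paste0("(", s, ")") else s
      }
    )
  }
  wrap(node, inside_and = FALSE)
}

#' @export
print.gpr_expression <- function(x, ...) {
  cat("<gpr> ", serialize_gpr(x), "\n", sep = "")
  invisible(x)
}

# All gene ids appearing in a rule AST
gpr_genes <- function(expr) {
  node <- unclass(expr)
  if (node$kind == "gene") return(node$id)
  unique(unlist(lapply(node$children, gpr_genes)))
}

#' Evaluate a GPR rule on discrete gene categories
#'
#' Categories follow the expressed / unknown / unexpressed convention
#' (+1 / 0 / -1). `and` takes the minimum over children (a complex is only as
#' expressed as its least-expressed subunit), `or` the maximum (any isozyme
#' suffices).
#'
#' @param expr a `gpr_expression` from [parse_gpr()].
#' @param categories named integer vector, gene -> value in `c(-1, 0, 1)`.
#' @param default_missing category assumed for genes absent from
#'   `categories` (default 0, unknown).
#' @return integer in `c(-1, 0, 1)`.
#' @export
gpr_eval_discrete <- function(expr, categories, default_missing = 0L) {
  node <- unclass(expr)
  ev <- function(n) {
    switch(n$kind,
      gene = {
        if (!n$id %in% names(categories)) default_missing
        else if (is.na(categories[[n$id]])) default_missing
        else categories[[n$id]]
      },
      and = min(vapply(n$children, ev, numeric(1))),
      or = max(vapply(n$children, ev, numeric(1)))
    )
  }
  as.integer(ev(node))
}

#' Evaluate a GPR rule on continuous gene levels
#'
#' Continuous semantics used for E-Flux reaction scoring: `and` takes the
#' minimum (complex capacity limited by scarcest subunit); `or` either the
#' sum (isozymes add capacity, the E-Flux default downstream) or the maximum,
#' per `or_mode`.
#'
#' @param expr a `gpr_expression` from [parse_gpr()].
#' @param levels named non-negative numeric vector, gene -> expression level.
#' @param or_mode `"sum"` or `"max"`.
#' @param default_missing level assumed for genes absent from `levels`
#'   (default 0).
#' @return a non-negative number.
#' @export
gpr_eval_continuous <- function(expr, levels, or_mode = c("sum", "max"),
                                default_missing = 0) {
  or_mode <- match.arg(or_mode)
  if (any(levels < 0, na.rm = TRUE)) abort("gene levels must be non-negative")
  node <- unclass(expr)
  ev <- function(n) {
    switch(n$kind,
      gene = {
        if (!n$id %in% names(levels)) default_missing
        else if (is.na(levels[[n$id]])) default_missing
        else levels[[n$id]]
      },
      and = min(vapply(n$children, ev, numeric(1))),
      or = {
        vals <- vapply(n$children, ev, numeric(1))
        if (or_mode == "sum") sum(vals) else max(vals)
      }
    )
  }
  ev(node)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
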