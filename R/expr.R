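# Boolean update-rule expressions.
#
# A rule is a recursive list over the operators AND / OR / NOT, node
# references and the constants 0/1.  The representation is deliberately
# plain (tagged lists) so rules can be serialized, inspected and compiled
# to vectorized R code for fast state-space sweeps.

#' Boolean expression constructors
#'
#' Build the recursive expression objects used as node update rules: node
#' references, the constants 0/1, and AND/OR/NOT combinations. `b_and()` and
#' `b_or()` are n-ary; with a single argument they return that argument
#' unchanged.
#'
#' @param name Node name referenced by the expression.
#' @param value Constant value, 0 or 1.
#' @param e,... Sub-expressions.
#' @return An object of class `bool_expr`.
#' @examples
#' b_and(b_var("A"), b_not(b_var("B")))   # A AND NOT B
#' @export
b_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(op = "var", name = name), class = "bool_expr")
}

#' @rdname b_var
#' @export
b_const <- function(value) {
  value <- as.integer(value)
  if (!value %in% c(0L, 1L)) stop("constant must be 0 or 1", call. = FALSE)
  structure(list(op = "const", value = value), class = "bool_expr")
}

#' @rdname b_var
#' @export
b_not <- function(e) {
  stopifnot(inherits(e, "bool_expr"))
  structure(list(op = "not", arg = e), class = "bool_expr")
}

collect_args <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !inherits(args[[1]], "bool_expr")) {
    args <- args[[1]]
  }
  if (!length(args)) stop("AND/OR need at least one argument", call. = FALSE)
  lapply(args, function(a) {
    if (!inherits(a, "bool_expr")) stop("arguments must be bool_expr objects", call. = FALSE)
    a
  })
}

#' @rdname b_var
#' @export
b_and <- function(...) {
  args <- collect_args(...)
  if (length(args) == 1L) return(args[[1]])
  structure(list(op = "and", args = args), class = "bool_expr")
}

#' @rdname b_var
#' @export
b_or <- function(...) {
  args <- collect_args(...)
  if (length(args) == 1L) return(args[[1]])
  structure(list(op = "or", args = args), class = "bool_expr")
}

#' Evaluate a Boolean expression
#'
#' @param e A `bool_expr`.
#' @param values Named integer vector of 0/1 node values; must cover every
#'   node the expression references.
#' @return 0 or 1.
#' @export
eval_expr <- function(e, values) {
  switch(e$op,
    const = e$value,
    var = {
      if (!e$name %in% names(values)) stop("unvalued node: ", e$name, call. = FALSE)
      v <- values[[e$name]]
      if (is.na(v)) stop("unvalued node: ", e$name, call. = FALSE)
      as.integer(v)
    },
    not = 1L - eval_expr(e$arg, values),
    and = {
      for (a in e$args) if (eval_expr(a, values) == 0L) return(0L)
      1L
    },
    or = {
      for (a in e$args) if (eval_expr(a, values) == 1L) return(1L)
      0L
    },
    stop("unknown operator: ", e$op, call. = FALSE)
  )
}

#' Node names referenced by an expression
#'
#' @param e A `bool_expr`.
#' @return Character vector of distinct referenced node names (possibly empty
#'   for constant rules).
#' @export
expr_refs <- function(e) {
  switch(e$op,
    const = character(0),
    var = e$name,
    not = expr_refs(e$arg),
    unique(unlist(lapply(e$args, expr_refs), use.names = FALSE))
  )
}

# Compile an expression to an R language object over `S`, a 0/1 numeric
# matrix with one column per node.  AND maps to pmin, OR to pmax, NOT to
# 1 - x, so a compiled rule evaluates simultaneously on every row of S.
expr_to_lang <- function(e, col_of) {
  switch(e$op,
    const = bquote(rep(.(as.numeric(e$value)), nrow(S))),  # keep row dimension
    var = {
      j <- col_of[[e$name]]
      if (is.null(j) || is.na(j)) stop("reference to unknown node: ", e$name, call. = FALSE)
      bquote(S[, .(j)])
    },
    not = bquote(1 - .(expr_to_lang(e$arg, col_of))),
    and = as.call(c(quote(pmin), lapply(e$args, expr_to_lang, col_of = col_of))),
    or = as.call(c(quote(pmax), lapply(e$args, expr_to_lang, col_of = col_of))),
    stop("unknown operator: ", e$op, call. = FALSE)
  )
}

#' @export
format.bool_expr <- function(x, ...) {
  switch(x$op,
    const = as.character(x$value),
    var = x$name,
    not = paste0("!", wrap_atom(x$arg)),
    and = paste(vapply(x$args, wrap_atom, character(1)), collapse = " & "),
    or = paste(vapply(x$args, wrap_atom, character(1)), collapse = " | ")
  )
}

wrap_atom <- function(e) {
  s <- format.bool_expr(e)
  if (e$op %in% c("and", "or")) paste0("(", s, ")") else s
}

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr> ", format(x), "\n", sep = "")
  invisible(x)
}
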