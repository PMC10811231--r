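# Reader/writer for the BMA-style JSON model dialect:
#   Model: { Name, Variables: [{Id, Name, RangeFrom, RangeTo, Formula}],
#            Relationships: [{FromVariable, ToVariable, Type}] }
# Formulas use a qualitative-network grammar over var(id), min(...), max(...),
# integer constants and the complement form 1 - expr (interpreted as NOT).
# Only the granularity-1 (Boolean) fragment is accepted: min -> AND,
# max -> OR, 1 - x -> NOT.  avg/ceil/floor belong to wider-range qualitative
# networks and are rejected with a clear error.

# ---- formula tokenizer + recursive-descent parser -------------------------

bma_tokenize <- function(src) {
  toks <- list()
  i <- 1L; n <- nchar(src)
  while (i <= n) {
    ch <- substr(src, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", ",", "-")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch)
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      tail <- substr(src, i, n)
      m <- regmatches(tail, regexpr("^[0-9]+", tail))
      toks[[length(toks) + 1L]] <- list(type = "int", text = m)
      i <- i + nchar(m)
    } else if (grepl("^[A-Za-z_]$", ch)) {
      tail <- substr(src, i, n)
      m <- regmatches(tail, regexpr("^[A-Za-z_][A-Za-z0-9_]*", tail))
      toks[[length(toks) + 1L]] <- list(type = "ident", text = m)
      i <- i + nchar(m)
    } else {
      stop("unexpected character '", ch, "' in formula: ", src, call. = FALSE)
    }
  }
  toks
}

# expr := INT '-' expr            (only literal 1 - x, read as NOT)
#       | INT
#       | 'var' '(' INT ')'
#       | ('min'|'max') '(' expr {',' expr} ')'
#       | '(' expr ')'
parse_bma_formula <- function(src, id_to_name) {
  toks <- bma_tokenize(src)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function(type = NULL) {
    t <- peek()
    if (is.null(t)) stop("unexpected end of formula: ", src, call. = FALSE)
    if (!is.null(type) && t$type != type) {
      stop("expected '", type, "' but found '", t$text, "' in formula: ", src, call. = FALSE)
    }
    pos <<- pos + 1L
    t
  }
  parse_expr <- function() {
    t <- peek()
    if (is.null(t)) stop("empty formula", call. = FALSE)
    if (t$type == "int") {
      take()
      v <- as.integer(t$text)
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "-") {
        if (v != 1L) stop("only the complement form 1 - expr is supported, got: ",
                          src, call. = FALSE)
        take("-")
        return(b_not(parse_expr()))
      }
      if (!v %in% c(0L, 1L)) {
        stop("constant ", v, " outside the Boolean range [0,1] in formula: ",
             src, call. = FALSE)
      }
      return(b_const(v))
    }
    if (t$type == "(") {
      take("(")
      e <- parse_expr()
      take(")")
      return(e)
    }
    if (t$type == "ident") {
      take()
      fn <- tolower(t$text)
      if (fn == "var") {
        take("(")
        id <- take("int")$text
        take(")")
        nm <- id_to_name[[id]]
        if (is.null(nm)) stop("formula references missing variable id ", id, call. = FALSE)
        return(b_var(nm))
      }
      if (fn %in% c("min", "max")) {
        take("(")
        args <- list(parse_expr())
        while (!is.null(peek()) && peek()$type == ",") {
          take(",")
          args[[length(args) + 1L]] <- parse_expr()
        }
        take(")")
        return(if (fn == "min") b_and(args) else b_or(args))
      }
      stop("unsupported function '", t$text, "' in formula: ", src,
           " (only var/min/max and 1 - expr are accepted)", call. = FALSE)
    }
    stop("unexpected token '", t$text, "' in formula: ", src, call. = FALSE)
  }
  e <- parse_expr()
  if (pos <= length(toks)) {
    stop("trailing tokens after formula: ", src, call. = FALSE)
  }
  e
}

# render a bool_expr back into the min/max/var grammar
bma_formula <- function(e, name_to_id) {
  switch(e$op,
    const = as.character(e$value),
    var = paste0("var(", name_to_id[[e$name]], ")"),
    not = paste0("1 - ", {
      s <- bma_formula(e$arg, name_to_id)
      if (e$arg$op %in% c("var", "const")) s else paste0("(", s, ")")
    }),
    and = paste0("min(", paste(vapply(e$args, bma_formula, character(1),
                                      name_to_id = name_to_id), collapse = ", "), ")"),
    or = paste0("max(", paste(vapply(e$args, bma_formula, character(1),
                                     name_to_id = name_to_id), collapse = ", "), ")")
  )
}

field <- function(rec, ...) {
  for (nm in c(...)) if (!is.null(rec[[nm]])) return(rec[[nm]])
  NULL
}

# ---- reader ---------------------------------------------------------------

#' Read a Boolean model from BMA-dialect JSON
#'
#' Accepts the JSON model dialect produced by map-to-model conversion tools:
#' a `Variables` array (integer `Id`, display `Name`, `RangeFrom`/`RangeTo`
#' bounds, a `Formula` string) and a `Relationships` array
#' (`FromVariable`, `ToVariable`, `Type` = `"Activator"`/`"Inhibitor"`).
#' Formulas in the Boolean fragment are translated (`min` to AND, `max` to
#' OR, `1 - x` to NOT). A variable with an empty formula takes a default rule
#' built from its relationships (`(OR activators) AND NOT (OR inhibitors)`),
#' or becomes an input when it has no incoming relationship. Any range other
#' than `[0, 1]` is rejected: only granularity-1 models are supported.
#'
#' @param document JSON text, or a path to a JSON file.
#' @return A `boolean_model`. Variable ids are preserved in node annotations
#'   (`bma_id`); node identity is the whitespace-trimmed display name.
#' @export
parse_bma_json <- function(document) {
  doc <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  if (!is.null(doc$Model)) doc <- doc$Model
  vars <- field(doc, "Variables", "variables")
  if (is.null(vars) || !length(vars)) stop("no variables in document", call. = FALSE)
  rels <- field(doc, "Relationships", "relationships")
  name <- field(doc, "Name", "name")
  if (is.null(name)) name <- "model"

  ids <- vapply(vars, function(v) as.character(field(v, "Id", "id")), character(1))
  nms <- vapply(vars, function(v) trimws(as.character(field(v, "Name", "name"))), character(1))
  if (anyDuplicated(ids)) stop("duplicate variable ids", call. = FALSE)
  id_to_name <- as.list(stats::setNames(nms, ids))

  for (v in vars) {
    lo <- field(v, "RangeFrom", "rangeFrom"); hi <- field(v, "RangeTo", "rangeTo")
    lo <- if (is.null(lo)) 0L else as.integer(lo)
    hi <- if (is.null(hi)) 1L else as.integer(hi)
    if (lo != 0L || hi != 1L) {
      stop("variable '", trimws(field(v, "Name", "name")), "' has range [", lo, ",", hi,
           "]; only granularity-1 (Boolean) models are supported", call. = FALSE)
    }
  }

  rel_from <- rel_to <- character(0); rel_type <- character(0)
  if (length(rels)) {
    rel_from <- vapply(rels, function(r) as.character(field(r, "FromVariable", "fromVariable")), character(1))
    rel_to <- vapply(rels, function(r) as.character(field(r, "ToVariable", "toVariable")), character(1))
    rel_type <- vapply(rels, function(r) as.character(field(r, "Type", "type")), character(1))
    missing_ref <- setdiff(c(rel_from, rel_to), ids)
    if (length(missing_ref)) {
      stop("relationship references missing variable id(s): ",
           paste(missing_ref, collapse = ", "), call. = FALSE)
    }
  }

  rules <- list()
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    nm <- nms[k]
    formula <- field(v, "Formula", "formula")
    formula <- if (is.null(formula)) "" else trimws(as.character(formula))
    incoming <- which(rel_to == ids[k])
    if (nzchar(formula)) {
      rules[[nm]] <- tryCatch(parse_bma_formula(formula, id_to_name),
        error = function(e) stop("in rule for node '", nm, "': ",
                                 conditionMessage(e), call. = FALSE))
    } else if (length(incoming)) {
      # default rule from topology: activators OR'ed, inhibitors veto
      activators <- unlist(id_to_name[rel_from[incoming][rel_type[incoming] == "Activator"]])
      inhibitors <- unlist(id_to_name[rel_from[incoming][rel_type[incoming] == "Inhibitor"]])
      act_e <- if (length(activators)) b_or(lapply(activators, b_var)) else NULL
      inh_e <- if (length(inhibitors)) b_not(b_or(lapply(inhibitors, b_var))) else NULL
      rules[[nm]] <- if (is.null(inh_e)) act_e else if (is.null(act_e)) inh_e else b_and(act_e, inh_e)
    }
    # neither formula nor incoming edges: input node, no rule
  }

  ann <- stats::setNames(lapply(seq_along(vars), function(k) list(bma_id = ids[k])), nms)
  boolean_model(nms, rules, name = name, annotations = ann)
}

# ---- writer ---------------------------------------------------------------

# sign of each regulator reference: +1 under even NOT depth, -1 under odd
ref_polarity <- function(e, depth = 0L) {
  switch(e$op,
    const = NULL,
    var = stats::setNames(list(if (depth %% 2L == 0L) 1L else -1L), e$name),
    not = ref_polarity(e$arg, depth + 1L),
    {
      out <- list()
      for (a in e$args) {
        p <- ref_polarity(a, depth)
        for (nm in names(p)) out[[nm]] <- unique(c(out[[nm]], p[[nm]]))
      }
      out
    }
  )
}

#' Write a Boolean model as BMA-dialect JSON
#'
#' Inverse of [parse_bma_json()]: emits `Variables` with integer ids and
#' `min`/`max`/`1 - x` formulas, plus `Relationships` derived from rule
#' references (sign from the NOT-parity of each reference; references seen
#' under both parities are emitted as activators). Round-tripping preserves
#' node names, the input set and every rule's truth table.
#'
#' @param model A `boolean_model`.
#' @param path Optional file path; when given, the JSON text is also written
#'   there.
#' @return JSON text, invisibly when `path` is given.
#' @export
write_bma_json <- function(model, path = NULL) {
  ids <- seq_along(model$nodes)
  name_to_id <- as.list(stats::setNames(ids, model$nodes))
  vars <- lapply(seq_along(model$nodes), function(k) {
    nm <- model$nodes[k]
    list(
      Id = ids[k], Name = nm, RangeFrom = 0L, RangeTo = 1L,
      Formula = if (nm %in% names(model$rules)) {
        bma_formula(model$rules[[nm]], name_to_id)
      } else ""
    )
  })
  rels <- list()
  rid <- 0L
  for (nm in names(model$rules)) {
    pol <- ref_polarity(model$rules[[nm]])
    for (src in names(pol)) {
      rid <- rid + 1L
      type <- if (identical(pol[[src]], -1L)) "Inhibitor" else "Activator"
      rels[[rid]] <- list(Id = rid, FromVariable = name_to_id[[src]],
                          ToVariable = name_to_id[[nm]], Type = type)
    }
  }
  doc <- list(Model = list(Name = model$name, Variables = vars, Relationships = rels))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
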