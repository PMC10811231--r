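# The boolean_model container: an ordered node set, per-node metadata and
# one update rule per non-input node.  Granularity is fixed at 1 (strictly
# Boolean); qualitative models with wider ranges are rejected at parse time.

#' Construct a Boolean model
#'
#' A model is an ordered set of uniquely named nodes plus one update rule
#' (a [b_var()]-style expression) for every node that has regulators. Nodes
#' without a rule are *inputs*: their value is clamped externally and defines
#' the environmental condition. Node kinds (`input`, `internal`, `phenotype`)
#' and phenotype classes (`cell_specific`, `signal`) are assigned by
#' [classify_nodes()]; at construction every ruled node starts as `internal`.
#'
#' @param nodes Character vector of node names (order is the state-vector
#'   order used throughout).
#' @param rules Named list of `bool_expr` rules; names must be a subset of
#'   `nodes`, every rule reference must resolve within `nodes`.
#' @param name Model name.
#' @param annotations Optional named list (per node) of free-form key/value
#'   annotation lists.
#' @return An object of class `boolean_model` with fields `nodes`, `kind`,
#'   `phenotype_class`, `rules`, `annotations`, `granularity` (always 1) and
#'   `name`.
#' @export
boolean_model <- function(nodes, rules, name = "model", annotations = NULL) {
  nodes <- as.character(nodes)
  if (!length(nodes)) stop("a model needs at least one node", call. = FALSE)
  if (anyDuplicated(nodes)) {
    stop("duplicate node names: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(nodes))) stop("empty node name", call. = FALSE)
  rules <- as.list(rules)
  if (length(rules)) {
    bad <- setdiff(names(rules), nodes)
    if (length(bad)) stop("rule for unknown node: ", paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(rules)) {
      if (!inherits(rules[[nm]], "bool_expr")) {
        stop("rule for ", nm, " is not a bool_expr", call. = FALSE)
      }
      dangling <- setdiff(expr_refs(rules[[nm]]), nodes)
      if (length(dangling)) {
        stop("rule for ", nm, " references unknown node(s): ",
             paste(dangling, collapse = ", "), call. = FALSE)
      }
    }
  }
  kind <- ifelse(nodes %in% names(rules), "internal", "input")
  names(kind) <- nodes
  pcls <- rep("none", length(nodes))
  names(pcls) <- nodes
  ann <- stats::setNames(vector("list", length(nodes)), nodes)
  if (!is.null(annotations)) ann[names(annotations)] <- annotations
  structure(
    list(name = name, nodes = nodes, kind = kind, phenotype_class = pcls,
         rules = rules, annotations = ann, granularity = 1L),
    class = "boolean_model"
  )
}

#' @export
print.boolean_model <- function(x, ...) {
  cat("<boolean_model> ", x$name, ": ", length(x$nodes), " nodes (",
      sum(x$kind == "input"), " inputs, ",
      sum(x$phenotype_class != "none"), " phenotypes), granularity 1\n", sep = "")
  invisible(x)
}

#' Model accessors
#'
#' `input_nodes()` returns the clamped environment nodes (no update rule),
#' `internal_nodes()` the ruled non-phenotype nodes, `phenotype_nodes()` the
#' readout nodes flagged by [classify_nodes()] (optionally restricted to one
#' phenotype class).
#'
#' @param model A `boolean_model`.
#' @param class Optional phenotype class filter, `"cell_specific"` or
#'   `"signal"`.
#' @return Character vector of node names.
#' @export
input_nodes <- function(model) model$nodes[model$kind == "input"]

#' @rdname input_nodes
#' @export
internal_nodes <- function(model) model$nodes[model$kind == "internal"]

#' @rdname input_nodes
#' @export
phenotype_nodes <- function(model, class = NULL) {
  keep <- model$kind == "phenotype"
  if (!is.null(class)) keep <- keep & model$phenotype_class == class
  model$nodes[keep]
}

# regulators of each ruled node, as a named list of character vectors
regulator_sets <- function(model) lapply(model$rules, expr_refs)

#' Classify nodes into inputs, internals and phenotypes
#'
#' Phenotype nodes are recognised by name suffix, following the convention of
#' disease-map derived models where cellular outcome nodes carry a cell-type
#' suffix (e.g. `"Apoptosis_M1_macrophage"`) and tissue-level readouts carry a
#' signal suffix (e.g. `"Inflammation_signal"`). Nodes without a rule are
#' inputs; everything else is internal.
#'
#' @param model A `boolean_model`.
#' @param cell_suffixes Character vector of cell-specific phenotype suffixes.
#' @param signal_suffix Single signal-phenotype suffix.
#' @return The model with `kind` and `phenotype_class` reassigned.
#' @export
classify_nodes <- function(model,
                           cell_suffixes = c("_M1_macrophage", "_M2_macrophage"),
                           signal_suffix = "_signal") {
  stopifnot(length(cell_suffixes) >= 1L, length(signal_suffix) == 1L)
  cell <- Reduce(`|`, lapply(cell_suffixes, function(s) endsWith(model$nodes, s)))
  sig <- endsWith(model$nodes, signal_suffix)
  amb <- model$nodes[cell & sig]
  if (length(amb)) {
    stop("ambiguous phenotype suffix for node(s): ",
         paste(amb, collapse = ", "), call. = FALSE)
  }
  has_rule <- model$nodes %in% names(model$rules)
  kind <- ifelse(cell | sig, "phenotype", ifelse(has_rule, "internal", "input"))
  pcls <- ifelse(cell, "cell_specific", ifelse(sig, "signal", "none"))
  model$kind <- stats::setNames(kind, model$nodes)
  model$phenotype_class <- stats::setNames(pcls, model$nodes)
  model
}

#' Restrict a model to the regulators of selected phenotypes
#'
#' Computes the ancestor closure of the given phenotype nodes over the
#' regulation graph (edges regulator -> target) and returns the induced
#' sub-model. Because the closure is taken over regulators, every retained
#' rule only references retained nodes. Inputs that fed only removed nodes
#' are removed with them; the removal report records them so a fixed default
#' value can be documented for traceability.
#'
#' @param model A `boolean_model`.
#' @param phenotype_names Nodes whose upstream regulators should be kept.
#' @return A list with `model` (the restricted `boolean_model`) and `report`
#'   (removed node/input counts and names).
#' @export
restrict_to_upstream <- function(model, phenotype_names) {
  unknown <- setdiff(phenotype_names, model$nodes)
  if (length(unknown)) {
    stop("unknown phenotype node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  regs <- regulator_sets(model)
  keep <- unique(phenotype_names)
  frontier <- keep
  while (length(frontier)) {
    parents <- unique(unlist(regs[intersect(frontier, names(regs))], use.names = FALSE))
    frontier <- setdiff(parents, keep)
    keep <- c(keep, frontier)
  }
  keep <- model$nodes[model$nodes %in% keep]   # original order
  removed <- setdiff(model$nodes, keep)
  removed_inputs <- removed[model$kind[removed] == "input"]
  sub <- boolean_model(keep, model$rules[intersect(names(model$rules), keep)],
                       name = model$name,
                       annotations = model$annotations[keep])
  sub$kind <- model$kind[keep]
  sub$phenotype_class <- model$phenotype_class[keep]
  list(
    model = sub,
    report = list(
      n_removed = length(removed),
      n_removed_inputs = length(removed_inputs),
      removed = removed,
      removed_inputs = removed_inputs,
      note = paste("inputs feeding only removed nodes were dropped;",
                   "equivalent to fixing them at a default constant")
    )
  )
}

#' Build default logical rules from a signed interaction graph
#'
#' Fixture-generation helper mirroring the common topology-based rule
#' inference: each regulated node becomes
#' `(OR of activators) AND NOT (OR of inhibitors)`; nodes with only
#' inhibitors get `NOT (OR of inhibitors)`; unregulated nodes become inputs.
#' Intended for building synthetic test models, not for reproducing any
#' particular map-conversion tool's rule set.
#'
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (`"activator"` or `"inhibitor"`).
#' @param nodes Optional character vector fixing the node set and order;
#'   defaults to the nodes mentioned in `edges`.
#' @param name Model name.
#' @return A `boolean_model`.
#' @export
infer_default_rules <- function(edges, nodes = NULL, name = "model") {
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  if (!all(edges$sign %in% c("activator", "inhibitor"))) {
    stop("sign must be 'activator' or 'inhibitor'", call. = FALSE)
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  dup <- tapply(edges$sign, key, function(s) length(unique(s)) > 1L)
  if (any(dup)) {
    bad <- sub("\r", " -> ", names(dup)[dup])
    stop("conflicting edge sign for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  edges <- edges[!duplicated(key), , drop = FALSE]
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  rules <- list()
  for (tgt in unique(edges$target)) {
    act <- edges$source[edges$target == tgt & edges$sign == "activator"]
    inh <- edges$source[edges$target == tgt & edges$sign == "inhibitor"]
    act_e <- if (length(act)) b_or(lapply(sort(act), b_var)) else NULL
    inh_e <- if (length(inh)) b_not(b_or(lapply(sort(inh), b_var))) else NULL
    rules[[tgt]] <- if (is.null(inh_e)) act_e else if (is.null(act_e)) inh_e else b_and(act_e, inh_e)
  }
  boolean_model(nodes, rules, name = name)
}

#' Summarise a model as a data frame
#'
#' @param model A `boolean_model`.
#' @return Data frame with one row per node: `node`, `kind`,
#'   `phenotype_class`, `in_degree`.
#' @export
model_summary <- function(model) {
  regs <- regulator_sets(model)
  data.frame(
    node = model$nodes,
    kind = unname(model$kind),
    phenotype_class = unname(model$phenotype_class),
    in_degree = vapply(model$nodes, function(n) {
      if (n %in% names(regs)) length(regs[[n]]) else 0L
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}

# Compile all rules into one function S -> S' over 0/1 matrices with one
# column per node (input columns are copied through; clamping is applied by
# the dynamics layer).  This is the hot path for state-space sweeps.
compile_model <- function(model) {
  col_of <- stats::setNames(seq_along(model$nodes), model$nodes)
  exprs <- vector("list", length(model$nodes))
  for (j in seq_along(model$nodes)) {
    nm <- model$nodes[j]
    exprs[[j]] <- if (nm %in% names(model$rules)) {
      expr_to_lang(model$rules[[nm]], col_of)
    } else {
      bquote(S[, .(j)])
    }
  }
  body <- as.call(c(quote(cbind), exprs))
  f <- eval(call("function", as.pairlist(alist(S = )), body), baseenv())
  function(S) {
    out <- f(S)
    colnames(out) <- model$nodes
    out
  }
}

# 32-bit FNV-1a over a string; used to fingerprint models for checkpoint
# consistency checks (not cryptographic).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(lo, b)
    # 32-bit modular multiply by the FNV prime 16777619, split to stay exact
    h <- (h * 403 + (h * 16384) %% 4294967296 * 1024) %% 4294967296
  }
  # h is a double (values may exceed .Machine$integer.max); render hex manually
  digits <- integer(8)
  for (i in 8:1) {
    digits[i] <- h %% 16
    h <- h %/% 16
  }
  paste(substring("0123456789abcdef", digits + 1, digits + 1), collapse = "")
}

model_fingerprint <- function(model) fnv1a32(write_bma_json(model))
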