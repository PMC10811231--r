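# SBML-qual reader.  Qualitative species become nodes; each transition's
# resultLevel-1 function term (MathML) becomes the target node's update rule.
# Supported MathML: <and>, <or>, <not>, <eq> of a species against 0/1, bare
# <ci> references and <cn> constants.  Species with maxLevel > 1 are rejected
# (Boolean semantics only).

#' Read a Boolean model from SBML-qual
#'
#' Parses an SBML document using the qualitative-models extension. Each
#' qualitative species becomes a node (identity = its `name` when present,
#' else its `id`); each transition contributes the update rule of its output
#' species, taken from the MathML of the function term with `resultLevel`
#' 1. Species that are the output of no transition are input nodes. Species
#' with `maxLevel` greater than 1 raise a granularity error, and MathML
#' constructs outside the AND/OR/NOT/eq fragment raise an unsupported-rule
#' error naming the node.
#'
#' @param document SBML text, or a path to an SBML file.
#' @return A `boolean_model`; species ids are kept in node annotations
#'   (`sbml_id`).
#' @export
parse_sbml_qual <- function(document) {
  doc <- xml2::read_xml(document)
  # strip namespaces: qual documents mix core, qual and MathML namespaces and
  # we match on local element names throughout
  species <- xml2::xml_find_all(doc, "//*[local-name()='qualitativeSpecies']")
  if (!length(species)) stop("no qualitative species found", call. = FALSE)

  get_attr <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) {
      # qual attributes may be namespaced (qual:id) or plain
      attrs <- xml2::xml_attrs(node)
      hits <- attrs[grepl(paste0("(^|:)", name, "$"), names(attrs))]
      v <- if (length(hits)) hits[[1]] else NA_character_
    }
    v
  }

  ids <- vapply(species, get_attr, character(1), name = "id")
  nms <- vapply(species, get_attr, character(1), name = "name")
  nms <- ifelse(is.na(nms) | !nzchar(nms), ids, trimws(nms))
  maxlev <- vapply(species, get_attr, character(1), name = "maxLevel")
  bad <- which(!is.na(maxlev) & as.integer(maxlev) > 1L)
  if (length(bad)) {
    stop("species with maxLevel > 1: ", paste(nms[bad], collapse = ", "),
         "; only granularity-1 (Boolean) models are supported", call. = FALSE)
  }
  id_to_name <- as.list(stats::setNames(nms, ids))

  mathml_to_expr <- function(node) {
    local <- xml2::xml_name(node)
    if (local == "math") {
      kids <- xml2::xml_children(node)
      if (length(kids) != 1L) stop("math element must have one child", call. = FALSE)
      return(mathml_to_expr(kids[[1]]))
    }
    if (local == "ci") {
      ref <- trimws(xml2::xml_text(node))
      nm <- id_to_name[[ref]]
      if (is.null(nm)) stop("reference to unknown species '", ref, "'", call. = FALSE)
      return(b_var(nm))
    }
    if (local == "cn") {
      v <- as.numeric(trimws(xml2::xml_text(node)))
      if (!v %in% c(0, 1)) stop("constant ", v, " outside {0,1}", call. = FALSE)
      return(b_const(v))
    }
    if (local != "apply") stop("unsupported MathML element <", local, ">", call. = FALSE)
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- kids[-1]
    switch(op,
      and = b_and(lapply(args, mathml_to_expr)),
      or = b_or(lapply(args, mathml_to_expr)),
      not = {
        if (length(args) != 1L) stop("<not> takes one argument", call. = FALSE)
        b_not(mathml_to_expr(args[[1]]))
      },
      eq = {
        if (length(args) != 2L) stop("<eq> takes two arguments", call. = FALSE)
        sub <- lapply(args, mathml_to_expr)
        ops <- vapply(sub, function(e) e$op, character(1))
        if (sum(ops == "const") != 1L || sum(ops == "var") != 1L) {
          stop("<eq> must compare a species with a 0/1 constant", call. = FALSE)
        }
        v <- sub[[which(ops == "var")]]
        k <- sub[[which(ops == "const")]]
        if (k$value == 1L) v else b_not(v)
      },
      stop("unsupported MathML operator <", op, ">", call. = FALSE)
    )
  }

  transitions <- xml2::xml_find_all(doc, "//*[local-name()='transition']")
  rules <- list()
  for (tr in transitions) {
    outs <- xml2::xml_find_all(tr, ".//*[local-name()='output']")
    if (!length(outs)) next
    out_ids <- vapply(outs, get_attr, character(1), name = "qualitativeSpecies")
    terms <- xml2::xml_find_all(tr, ".//*[local-name()='functionTerm']")
    rule <- NULL
    for (ft in terms) {
      lev <- get_attr(ft, "resultLevel")
      if (!is.na(lev) && as.integer(lev) > 1L) {
        stop("function term with resultLevel > 1 for node '",
             id_to_name[[out_ids[1]]], "'", call. = FALSE)
      }
      if (!is.na(lev) && as.integer(lev) == 1L) {
        math <- xml2::xml_find_first(ft, ".//*[local-name()='math']")
        if (inherits(math, "xml_missing")) {
          stop("function term without MathML for node '",
               id_to_name[[out_ids[1]]], "'", call. = FALSE)
        }
        rule <- tryCatch(mathml_to_expr(math),
          error = function(e) stop("in rule for node '", id_to_name[[out_ids[1]]],
                                   "': ", conditionMessage(e), call. = FALSE))
      }
    }
    if (is.null(rule)) rule <- b_const(0L)   # only a default term: constant 0
    for (oid in out_ids) {
      nm <- id_to_name[[oid]]
      if (is.null(nm)) stop("transition output references unknown species '", oid, "'",
                            call. = FALSE)
      rules[[nm]] <- rule
    }
  }

  mdl <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  model_name <- if (!inherits(mdl, "xml_missing")) {
    v <- xml2::xml_attr(mdl, "id")
    if (is.na(v)) "model" else v
  } else "model"

  ann <- stats::setNames(lapply(ids, function(i) list(sbml_id = i)), nms)
  boolean_model(nms, rules, name = model_name, annotations = ann)
}
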