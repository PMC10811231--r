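# Calibration of scanned steady states against binary expression evidence.
# Observations are discretized differential-expression calls (up = 1,
# down = 0) merged with literature-derived values; candidate steady states
# are filtered by phenotype constraints, scored with the simple matching
# coefficient S = (N00 + N11) / (N00 + N11 + N10 + N01), and the top-scoring
# states are averaged into the calibrated model state.

#' Construct an observation vector
#'
#' Binary experimentally observed values for a subset of nodes, with a
#' provenance tag per entry (`literature`, `expression`, or `both` after
#' merging).
#'
#' @param values Named 0/1 vector (names are node names).
#' @param provenance Character scalar or vector aligned with `values`.
#' @return An `observation_vector`.
#' @export
observation_vector <- function(values, provenance = "literature") {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("observation values must be named by node", call. = FALSE)
  }
  if (anyDuplicated(names(values))) {
    stop("duplicate observed node(s): ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "),
         call. = FALSE)
  }
  v <- as.integer(values)
  if (!all(v %in% c(0L, 1L))) stop("observed values must be 0 or 1", call. = FALSE)
  prov <- rep(provenance, length.out = length(v))
  if (!all(prov %in% c("literature", "expression", "both"))) {
    stop("provenance must be literature, expression or both", call. = FALSE)
  }
  structure(list(values = stats::setNames(v, names(values)),
                 provenance = stats::setNames(prov, names(values))),
            class = "observation_vector")
}

#' @export
print.observation_vector <- function(x, ...) {
  cat("<observation_vector> ", length(x$values), " observed nodes (",
      sum(x$values == 1L), " up, ", sum(x$values == 0L), " down)\n", sep = "")
  invisible(x)
}

#' @export
length.observation_vector <- function(x) length(x$values)

#' Discretize a differential-expression table
#'
#' Significant genes (adjusted p-value below `p_threshold`) are mapped to
#' Boolean observations: positive log fold-change (overexpressed in the
#' condition under study) to 1, negative to 0. Non-significant genes and
#' genes with zero log fold-change are excluded — under a strictly Boolean
#' formalism only differentially expressed molecules carry information.
#'
#' @param records Data frame with columns `gene`, `logFC`, `adjP`.
#' @param p_threshold Significance threshold on the adjusted p-value.
#' @param strict Use strict inequality `adjP < p_threshold` (the default
#'   convention); `FALSE` uses `<=`.
#' @param name_map Optional named character vector mapping gene symbols to
#'   model node names (observation name -> node name); unmapped genes keep
#'   their own name.
#' @return An `observation_vector` with provenance `"expression"`.
#' @export
discretize_deg_table <- function(records, p_threshold = 0.05, strict = TRUE,
                                 name_map = NULL) {
  records <- as.data.frame(records)
  stopifnot(all(c("gene", "logFC", "adjP") %in% names(records)))
  if (!(p_threshold > 0 && p_threshold < 1)) {
    stop("p_threshold must be in (0, 1)", call. = FALSE)
  }
  if (any(records$adjP < 0 | records$adjP > 1, na.rm = TRUE)) {
    stop("adjusted p-values must lie in [0, 1]", call. = FALSE)
  }
  sig <- if (strict) records$adjP < p_threshold else records$adjP <= p_threshold
  sig <- sig & !is.na(records$adjP) & !is.na(records$logFC) & records$logFC != 0
  kept <- records[sig, , drop = FALSE]
  gene <- as.character(kept$gene)
  if (!is.null(name_map)) {
    mapped <- name_map[gene]
    gene <- ifelse(is.na(mapped), gene, mapped)
  }
  value <- ifelse(kept$logFC > 0, 1L, 0L)
  if (anyDuplicated(gene)) {
    conf <- tapply(value, gene, function(v) length(unique(v)) > 1L)
    if (any(conf)) {
      stop("conflicting discretized values for gene(s): ",
           paste(names(conf)[conf], collapse = ", "), call. = FALSE)
    }
    keep1 <- !duplicated(gene)
    gene <- gene[keep1]; value <- value[keep1]
  }
  observation_vector(stats::setNames(value, gene), provenance = "expression")
}

#' Merge literature and expression observations
#'
#' Union of two observation vectors. Entries present in both with the same
#' value get provenance `"both"`; disagreements are resolved by `policy`
#' (the default fails loudly and lists the conflicting nodes).
#'
#' @param literature,expression `observation_vector` objects.
#' @param policy One of `"error"`, `"literature_wins"`, `"expression_wins"`.
#' @return A merged `observation_vector`.
#' @export
merge_observations <- function(literature, expression,
                               policy = c("error", "literature_wins", "expression_wins")) {
  policy <- match.arg(policy)
  stopifnot(inherits(literature, "observation_vector"),
            inherits(expression, "observation_vector"))
  shared <- intersect(names(literature$values), names(expression$values))
  disagree <- shared[literature$values[shared] != expression$values[shared]]
  if (length(disagree) && policy == "error") {
    stop("literature and expression observations disagree for node(s): ",
         paste(disagree, collapse = ", "), call. = FALSE)
  }
  vals <- c(literature$values, expression$values[setdiff(names(expression$values), shared)])
  prov <- c(literature$provenance,
            expression$provenance[setdiff(names(expression$values), shared)])
  agree <- setdiff(shared, disagree)
  prov[agree] <- "both"
  if (length(disagree)) {
    if (policy == "expression_wins") vals[disagree] <- expression$values[disagree]
    message("observation conflict(s) resolved by ", policy, ": ",
            paste(disagree, collapse = ", "))
  }
  observation_vector(vals, provenance = prov)
}

#' Filter steady states by phenotype constraints
#'
#' Keeps exactly the states whose constrained phenotype nodes carry the
#' biologically required values (e.g. Proliferation ON and Apoptosis OFF for
#' an inflammatory cell state), preserving order.
#'
#' @param states Integer matrix of steady states (columns named by node), as
#'   produced by [filter_steady()].
#' @param constraint Named 0/1 vector over phenotype nodes.
#' @return The surviving subset of `states` (possibly zero rows).
#' @export
filter_by_phenotype <- function(states, constraint) {
  if (!length(constraint)) return(states)
  unknown <- setdiff(names(constraint), colnames(states))
  if (length(unknown)) {
    stop("constraint on unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!all(constraint %in% c(0, 1))) stop("constraint values must be 0 or 1", call. = FALSE)
  sub <- states[, names(constraint), drop = FALSE]
  keep <- rowSums(sub == rep(as.integer(constraint), each = nrow(states))) == length(constraint)
  states[keep, , drop = FALSE]
}

#' Simple matching coefficient between a state and an observation
#'
#' Counts agreements and disagreements over the observed nodes that resolve
#' to state entries and returns
#' `S = (N00 + N11) / (N00 + N11 + N10 + N01)`, where `N11`/`N00` count
#' nodes that are 1/0 in both vectors and `N10`/`N01` count disagreements.
#' Observed nodes absent from the state are quarantined (excluded from the
#' counts and listed in the result) rather than raising an error.
#'
#' @param state Named 0/1 vector (a steady state).
#' @param observation An `observation_vector`, or a named 0/1 vector.
#' @return A `similarity_score`: `S`, the four counts, and `unresolved`
#'   (observed nodes not present in the state).
#' @export
similarity <- function(state, observation) {
  obs <- if (inherits(observation, "observation_vector")) observation$values else {
    if (is.null(names(observation))) stop("observation must be named", call. = FALSE)
    stats::setNames(as.integer(observation), names(observation))
  }
  common <- intersect(names(obs), names(state))
  unresolved <- setdiff(names(obs), common)
  if (!length(common)) {
    stop("no observed node resolves to a model node; nothing to compare",
         call. = FALSE)
  }
  s <- as.integer(state[common]); o <- as.integer(obs[common])
  n11 <- sum(s == 1L & o == 1L)
  n00 <- sum(s == 0L & o == 0L)
  n10 <- sum(s == 1L & o == 0L)
  n01 <- sum(s == 0L & o == 1L)
  structure(list(S = (n00 + n11) / (n00 + n11 + n10 + n01),
                 N00 = n00, N01 = n01, N10 = n10, N11 = n11,
                 unresolved = unresolved),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> S = %.4f (N00=%d N11=%d N10=%d N01=%d)\n",
              x$S, x$N00, x$N11, x$N10, x$N01))
  invisible(x)
}

#' Select the steady states with the highest similarity score
#'
#' Scores every state against the observation and returns all states tied at
#' the maximum (no secondary ordering is imposed on ties).
#'
#' @param states Integer matrix of steady states (columns named by node).
#' @param observation An `observation_vector` or named 0/1 vector.
#' @return List with `score` (the maximum S), `states` (matrix of argmax
#'   states, original order), and `scores` (per-input-state S values).
#' @export
select_top <- function(states, observation) {
  if (!nrow(states)) stop("no states to select from", call. = FALSE)
  scores <- vapply(seq_len(nrow(states)), function(i) {
    similarity(states[i, ], observation)$S
  }, numeric(1))
  best <- max(scores)
  list(score = best, states = states[scores == best, , drop = FALSE], scores = scores)
}

#' Average selected steady states into the calibrated model state
#'
#' Per-node arithmetic mean over the selected states. Nodes whose mean is
#' exactly 0 or 1 are constant across all selected states and are reported
#' as *fixed*; the remaining nodes are *unfixed* (their value is not pinned
#' down by the evidence).
#'
#' @param states Integer matrix of steady states (rows = states).
#' @param score Optional achieved similarity score to record.
#' @return A `calibrated_state`: `mean` (named numeric), `fixed`, `unfixed`
#'   (node name vectors), `n_states`, `score`.
#' @export
mean_state <- function(states, score = NA_real_) {
  if (!nrow(states)) stop("cannot average zero states", call. = FALSE)
  m <- colMeans(states)
  fixed <- names(m)[m == 0 | m == 1]
  structure(
    list(mean = m, fixed = fixed, unfixed = setdiff(names(m), fixed),
         n_states = nrow(states), score = score),
    class = "calibrated_state"
  )
}

#' @export
print.calibrated_state <- function(x, ...) {
  cat("<calibrated_state> mean over ", x$n_states, " states: ",
      length(x$fixed), " fixed, ", length(x$unfixed), " unfixed nodes\n", sep = "")
  invisible(x)
}

# round half-up to one decimal (so 96.45 -> 96.5, matching reported styles)
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Compare a calibrated state with the observation
#'
#' Per observed node: *match* when the node is fixed in the calibrated state
#' at the observed value, *mismatch* when fixed at the other value, and
#' *unfixed overlap* when the calibrated mean is fractional. The match
#' percentage (matches / observed, half-up to one decimal) counts only fixed
#' nodes as matches; unfixed overlaps are reported separately.
#'
#' @param calibrated A `calibrated_state`.
#' @param observation An `observation_vector` or named 0/1 vector.
#' @return List with `matches`, `mismatches`, `unfixed`, `unresolved` (node
#'   name vectors), `n_observed`, and `percentage`.
#' @export
match_report <- function(calibrated, observation) {
  obs <- if (inherits(observation, "observation_vector")) observation$values else observation
  resolved <- intersect(names(obs), names(calibrated$mean))
  unresolved <- setdiff(names(obs), resolved)
  m <- calibrated$mean[resolved]
  fixed <- resolved %in% calibrated$fixed
  match <- resolved[fixed & m == obs[resolved]]
  mismatch <- resolved[fixed & m != obs[resolved]]
  unfixed <- resolved[!fixed]
  n_obs <- length(resolved)
  list(
    matches = match, mismatches = mismatch, unfixed = unfixed,
    unresolved = unresolved, n_observed = n_obs,
    percentage = if (n_obs) round1_half_up(100 * length(match) / n_obs) else NA_real_
  )
}

#' Run the full calibration stage
#'
#' Convenience pipeline: phenotype-filter the steady states, score them
#' against the observation, select the top scorers and average them.
#'
#' @param states Integer matrix of steady states.
#' @param observation An `observation_vector`.
#' @param constraint Optional named phenotype constraint vector.
#' @return List with `calibrated` (a `calibrated_state`), `n_filtered`
#'   (survivors of the phenotype filter), `n_top`, `score`, and `report`
#'   (the [match_report()]).
#' @export
calibrate <- function(states, observation, constraint = NULL) {
  filtered <- if (is.null(constraint)) states else filter_by_phenotype(states, constraint)
  if (!nrow(filtered)) {
    stop("no steady state satisfies the phenotype constraint", call. = FALSE)
  }
  top <- select_top(filtered, observation)
  cal <- mean_state(top$states, score = top$score)
  list(calibrated = cal, n_filtered = nrow(filtered),
       n_top = nrow(top$states), score = top$score,
       report = match_report(cal, observation))
}

#' Write a calibrated state as TSV
#'
#' @param calibrated A `calibrated_state`.
#' @param path Optional output file.
#' @return Data frame with columns `node`, `mean`, `fixed_flag`.
#' @export
calibrated_state_table <- function(calibrated, path = NULL) {
  df <- data.frame(
    node = names(calibrated$mean),
    mean = unname(calibrated$mean),
    fixed_flag = as.integer(names(calibrated$mean) %in% calibrated$fixed),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
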