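# In-silico knockout screens.  A knockout clamps nodes at 0 (mimicking
# pharmacological inhibition); the perturbed model is simulated from the
# calibrated state and each phenotype is classified as induced (0 -> 1),
# suppressed (1 -> 0) or unchanged against its calibrated value.  The double
# screen flags a pair as synergistic when it produces a phenotype change
# that neither single knockout produces alone.

#' Clamp nodes at zero (knockout)
#'
#' Each knocked-out node's update rule is replaced by the constant 0; a
#' knocked-out input node becomes a constant-0 non-input (it no longer takes
#' part in input enumeration). All other rules are untouched. Clamping at 1
#' (over-expression) is available via `value = 1` but unused by the default
#' screens.
#'
#' @param model A `boolean_model`.
#' @param nodes Non-empty character vector of nodes to clamp.
#' @param value Clamp value, 0 (knockout, default) or 1 (over-expression).
#' @return The perturbed `boolean_model`.
#' @export
apply_knockout <- function(model, nodes, value = 0L) {
  if (!length(nodes)) stop("knockout set must be non-empty", call. = FALSE)
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, model$nodes)
  if (length(unknown)) {
    stop("knockout of unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  value <- as.integer(value)
  stopifnot(value %in% c(0L, 1L))
  for (nm in nodes) {
    model$rules[[nm]] <- b_const(value)
    if (model$kind[[nm]] == "input") model$kind[[nm]] <- "internal"
    model$annotations[[nm]] <- c(model$annotations[[nm]], list(clamped = as.character(value)))
  }
  model$name <- paste0(model$name, "_KO_", paste(nodes, collapse = "+"))
  model
}

#' Resolve a calibrated state into a concrete initial state
#'
#' Fixed nodes take their calibrated value. Unfixed nodes (fractional mean)
#' take the policy value: `"zeros"` (default) or `"ones"`; policy
#' `"as_is_threshold"` rounds the mean, and rejects means of exactly 0.5 as
#' ambiguous. The chosen policy is recorded on the returned state.
#'
#' @param calibrated A `calibrated_state`.
#' @param policy `"zeros"`, `"ones"`, or `"as_is_threshold"`.
#' @return Named 0/1 state vector with attribute `policy`.
#' @export
resolve_initial_state <- function(calibrated,
                                  policy = c("zeros", "ones", "as_is_threshold")) {
  policy <- match.arg(policy)
  m <- calibrated$mean
  out <- as.integer(round(m))
  names(out) <- names(m)
  unfixed <- calibrated$unfixed
  if (length(unfixed)) {
    out[unfixed] <- switch(policy,
      zeros = 0L,
      ones = 1L,
      as_is_threshold = {
        amb <- unfixed[m[unfixed] == 0.5]
        if (length(amb)) {
          stop("mean exactly 0.5 cannot be resolved by thresholding for node(s): ",
               paste(amb, collapse = ", "),
               "; choose policy 'zeros' or 'ones'", call. = FALSE)
        }
        as.integer(m[unfixed] > 0.5)
      }
    )
  }
  attr(out, "policy") <- policy
  out
}

classify_delta <- function(baseline, perturbed) {
  if (baseline == perturbed) "unchanged"
  else if (baseline == 0L && perturbed == 1L) "induced"
  else "suppressed"
}

#' Knock out nodes and classify the phenotype response
#'
#' Builds the knockout model, simulates it from the resolved calibrated
#' state to an attractor, and classifies each phenotype node against its
#' calibrated baseline: `induced` (0 to 1), `suppressed` (1 to 0) or
#' `unchanged`. A cyclic attractor marks the result `oscillatory` and
#' reports the value set each phenotype takes over the cycle.
#'
#' @param model The calibrated (unperturbed) `boolean_model`.
#' @param calibrated A `calibrated_state` for `model`.
#' @param nodes Knockout node set.
#' @param phenotypes Phenotype nodes to classify; defaults to all
#'   phenotype-kind nodes of the model.
#' @param policy Unfixed-node resolution policy for [resolve_initial_state()].
#' @param max_steps Simulation budget.
#' @return A `perturbation_result`: `knockout`, `status` (`"steady"` or
#'   `"oscillatory"`), `deltas` (named character vector over phenotypes),
#'   `baseline` and `perturbed` phenotype values, and the reached
#'   `attractor`.
#' @export
perturb_and_classify <- function(model, calibrated, nodes, phenotypes = NULL,
                                 policy = "zeros",
                                 max_steps = 2L * length(model$nodes) + 10L) {
  if (is.null(phenotypes)) phenotypes <- phenotype_nodes(model)
  unknown <- setdiff(phenotypes, model$nodes)
  if (length(unknown)) {
    stop("unknown phenotype node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  init <- resolve_initial_state(calibrated, policy)
  # baseline = the resolved calibrated state (equals the calibrated value on
  # every fixed node; policy-resolved on unfixed ones)
  baseline <- stats::setNames(as.integer(init[phenotypes]), phenotypes)
  ko_model <- apply_knockout(model, nodes)
  init[nodes] <- 0L
  inputs <- init[input_nodes(ko_model)]
  sim <- simulate(ko_model, init, inputs, max_steps = max_steps)
  if (sim$attractor$kind == "steady") {
    perturbed <- stats::setNames(as.integer(sim$attractor$states[1L, phenotypes]), phenotypes)
    deltas <- stats::setNames(
      mapply(classify_delta, baseline, perturbed, USE.NAMES = FALSE), phenotypes)
    status <- "steady"
    cycle_values <- NULL
  } else {
    perturbed <- stats::setNames(rep(NA_integer_, length(phenotypes)), phenotypes)
    deltas <- stats::setNames(rep("oscillatory", length(phenotypes)), phenotypes)
    status <- "oscillatory"
    cycle_values <- lapply(stats::setNames(phenotypes, phenotypes), function(p) {
      sort(unique(as.integer(sim$attractor$states[, p])))
    })
  }
  structure(
    list(knockout = nodes, status = status, deltas = deltas,
         baseline = baseline, perturbed = perturbed,
         cycle_values = cycle_values, policy = attr(init, "policy"),
         attractor = sim$attractor),
    class = "perturbation_result"
  )
}

#' @export
print.perturbation_result <- function(x, ...) {
  changed <- x$deltas[x$deltas != "unchanged"]
  cat("<perturbation_result> KO {", paste(x$knockout, collapse = ", "), "}: ",
      if (length(changed)) paste(names(changed), changed, collapse = ", ") else "no phenotype change",
      "\n", sep = "")
  invisible(x)
}

screen_row <- function(res, phenotypes) {
  c(list(target = paste(res$knockout, collapse = "+"), status = res$status),
    as.list(stats::setNames(res$deltas[phenotypes], phenotypes)))
}

#' Single-knockout screen
#'
#' Runs [perturb_and_classify()] for every target, in the given order.
#' Unresolvable target names are collected in the report and the screen
#' continues.
#'
#' @param model A classified, calibrated `boolean_model`.
#' @param calibrated Its `calibrated_state`.
#' @param targets Character vector of candidate knockout targets.
#' @param phenotypes Phenotypes to classify (default: all phenotype nodes).
#' @param policy Unfixed-node resolution policy.
#' @return A `ko_screen`: `table` (one row per resolvable target: target,
#'   status, one column per phenotype), `results` (the full
#'   `perturbation_result` objects), `hits` (targets with any phenotype
#'   change) and `unresolved` target names.
#' @export
single_ko_screen <- function(model, calibrated, targets, phenotypes = NULL,
                             policy = "zeros") {
  if (is.null(phenotypes)) phenotypes <- phenotype_nodes(model)
  targets <- as.character(targets)
  unresolved <- setdiff(targets, model$nodes)
  ok <- targets[targets %in% model$nodes]
  results <- lapply(ok, function(t) {
    perturb_and_classify(model, calibrated, t, phenotypes, policy)
  })
  names(results) <- ok
  tab <- do.call(rbind, lapply(results, function(r) {
    as.data.frame(screen_row(r, phenotypes), stringsAsFactors = FALSE,
                  check.names = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(target = character(0), status = character(0))
    for (p in phenotypes) tab[[p]] <- character(0)
  }
  rownames(tab) <- NULL
  hits <- ok[vapply(results, function(r) any(r$deltas != "unchanged"), logical(1))]
  structure(list(table = tab, results = results, hits = hits,
                 unresolved = unresolved, phenotypes = phenotypes),
            class = "ko_screen")
}

#' @export
print.ko_screen <- function(x, ...) {
  cat("<ko_screen> ", nrow(x$table), " knockouts, ", length(x$hits),
      " with a phenotype change\n", sep = "")
  invisible(x)
}

#' Double-knockout screen with synergy detection
#'
#' Tests all `C(n, 2)` unordered pairs of targets. A pair is flagged
#' *synergistic* when it produces a phenotype change (an induced or
#' suppressed label on some phenotype) that neither of its single knockouts
#' produces alone.
#'
#' @inheritParams single_ko_screen
#' @param single Optional precomputed [single_ko_screen()] over the same
#'   targets (avoids recomputation).
#' @return A `ko_screen` whose table has one row per pair plus a `synergy`
#'   logical column; `synergy_pairs` lists the flagged pairs.
#' @export
double_ko_screen <- function(model, calibrated, targets, phenotypes = NULL,
                             policy = "zeros", single = NULL) {
  if (is.null(phenotypes)) phenotypes <- phenotype_nodes(model)
  targets <- as.character(targets)
  unresolved <- setdiff(targets, model$nodes)
  ok <- unique(targets[targets %in% model$nodes])
  if (length(ok) < 2L) stop("need at least two resolvable targets", call. = FALSE)
  if (is.null(single)) {
    single <- single_ko_screen(model, calibrated, ok, phenotypes, policy)
  }
  single_changes <- lapply(single$results, function(r) {
    ch <- r$deltas[r$deltas %in% c("induced", "suppressed")]
    paste(names(ch), ch)
  })
  pairs <- utils::combn(ok, 2L)
  results <- vector("list", ncol(pairs))
  rows <- vector("list", ncol(pairs))
  synergy <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    pr <- pairs[, k]
    res <- perturb_and_classify(model, calibrated, pr, phenotypes, policy)
    ch <- res$deltas[res$deltas %in% c("induced", "suppressed")]
    pair_changes <- paste(names(ch), ch)
    alone <- unique(c(single_changes[[pr[1]]], single_changes[[pr[2]]]))
    synergy[k] <- length(setdiff(pair_changes, alone)) > 0L
    results[[k]] <- res
    rows[[k]] <- cbind(
      as.data.frame(screen_row(res, phenotypes), stringsAsFactors = FALSE,
                    check.names = FALSE),
      synergy = synergy[k]
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  hits <- tab$target[vapply(results, function(r) any(r$deltas != "unchanged"), logical(1))]
  structure(
    list(table = tab, results = results, hits = hits,
         synergy_pairs = tab$target[synergy], unresolved = unresolved,
         phenotypes = phenotypes, single = single),
    class = "ko_screen"
  )
}

#' Number of unordered knockout pairs
#'
#' Counts `C(n, 2)` without materializing the pairs, for screen planning.
#'
#' @param n_targets Number of targets.
#' @return `n_targets * (n_targets - 1) / 2`.
#' @export
n_ko_pairs <- function(n_targets) {
  stopifnot(n_targets >= 0)
  n_targets * (n_targets - 1) / 2
}

#' Write a knockout screen table as TSV
#'
#' @param screen A `ko_screen`.
#' @param path Optional output file.
#' @return The screen's data frame.
#' @export
screen_table <- function(screen, path = NULL) {
  if (!is.null(path)) {
    utils::write.table(screen$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(screen$table))
  }
  screen$table
}
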