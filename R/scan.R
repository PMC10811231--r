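# Exhaustive scan over free-input combinations.  The combination index is a
# stable contract: free inputs are sorted lexicographically (C locale) and
# bit j of index i (bit 0 first) gives the value of the j-th free input, so
# published scans can be referenced by index.  Results are keyed by index,
# which makes the aggregate independent of worker count and scheduling, and
# lets interrupted scans resume from checkpoints bit-identically.

#' Enumerate free-input combinations
#'
#' Splits the model's inputs into fixed (given in `fixed`, typically from
#' experimentally observed expression) and free inputs, and defines the
#' deterministic combination order: free inputs sorted lexicographically,
#' combination index `i` assigning bit `j` of `i` to the `j`-th free input.
#' The enumeration is lazy — `2^|free|` can be counted without materializing
#' any valuation.
#'
#' @param model A `boolean_model`.
#' @param fixed Named 0/1 vector clamping a subset of inputs.
#' @return An `input_enumeration`: `fixed`, `free` (sorted), and
#'   `n_combinations` (= `2^|free|`, as a double so counts above 2^31 are
#'   representable).
#' @export
enumerate_input_combinations <- function(model, fixed = NULL) {
  ins <- input_nodes(model)
  fixed <- if (is.null(fixed)) stats::setNames(integer(0), character(0)) else fixed
  bad <- setdiff(names(fixed), ins)
  if (length(bad)) {
    stop("fixed assignment for non-input node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(fixed) && !all(fixed %in% c(0, 1))) {
    stop("fixed input values must be 0 or 1", call. = FALSE)
  }
  free <- sort(setdiff(ins, names(fixed)), method = "radix")
  structure(
    list(fixed = stats::setNames(as.integer(fixed), names(fixed)),
         free = free, n_combinations = 2^length(free)),
    class = "input_enumeration"
  )
}

#' @export
print.input_enumeration <- function(x, ...) {
  cat("<input_enumeration> ", length(x$fixed), " fixed, ", length(x$free),
      " free inputs: ", format(x$n_combinations, big.mark = ","),
      " combinations\n", sep = "")
  invisible(x)
}

#' Input valuation for one combination index
#'
#' @param enum An `input_enumeration`.
#' @param i Combination index, 0-based, below `enum$n_combinations`.
#' @return Named 0/1 vector valuing every input (fixed plus decoded free
#'   bits).
#' @export
combination_inputs <- function(enum, i) {
  if (i < 0 || i >= enum$n_combinations) stop("combination index out of range", call. = FALSE)
  bits <- integer(length(enum$free))
  if (length(bits)) bits <- (i %/% 2^(seq_along(enum$free) - 1)) %% 2
  c(enum$fixed, stats::setNames(as.integer(bits), enum$free))
}

#' Scan every input combination for its attractor
#'
#' Runs [prove_stability()] for each of the `2^|free|` input combinations of
#' [enumerate_input_combinations()]. Records are keyed by combination index,
#' so the aggregate result is identical for any worker count; with a
#' checkpoint directory, completed blocks are persisted and an interrupted
#' scan resumes with bit-identical final output.
#'
#' @param model A `boolean_model`.
#' @param fixed Named 0/1 vector clamping a subset of inputs.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param checkpoint_every Combinations per checkpoint block.
#' @param checkpoint_dir Optional directory for resumable checkpoints; its
#'   metadata records a model fingerprint, and resuming against a different
#'   model or fixed assignment is an error.
#' @param search_budget Passed to [prove_stability()].
#' @param max_combinations Guard against accidental full-scale scans; scans
#'   larger than this require `allow_large = TRUE`.
#' @param allow_large Override the guard.
#' @return A `scan_result`: per-combination `status` and witness kind, a
#'   steady-state matrix (NA rows for non-steady records), and counters.
#' @export
scan <- function(model, fixed = NULL, workers = 1L, checkpoint_every = 1024L,
                 checkpoint_dir = NULL, search_budget = 2L^16,
                 max_combinations = 2^24, allow_large = FALSE) {
  stopifnot(workers >= 1L, checkpoint_every >= 1L)
  enum <- enumerate_input_combinations(model, fixed)
  n <- enum$n_combinations
  if (n > max_combinations && !allow_large) {
    stop("scan of ", format(n, big.mark = ","), " combinations exceeds the guard (",
         format(max_combinations, big.mark = ","),
         "); set allow_large = TRUE to run it anyway", call. = FALSE)
  }
  fp <- model_fingerprint(model)

  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    meta_path <- file.path(checkpoint_dir, "meta.json")
    meta <- list(fingerprint = fp,
                 fixed = as.list(enum$fixed), free = enum$free,
                 checkpoint_every = checkpoint_every)
    if (file.exists(meta_path)) {
      old <- jsonlite::fromJSON(meta_path, simplifyVector = FALSE)
      same <- identical(old$fingerprint, fp) &&
        identical(unlist(old$fixed), unlist(meta$fixed)) &&
        identical(unlist(old$free), enum$free) &&
        identical(as.integer(old$checkpoint_every), as.integer(checkpoint_every))
      if (!same) {
        stop("checkpoint directory belongs to a different scan ",
             "(model fingerprint or configuration mismatch)", call. = FALSE)
      }
    } else {
      jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
    }
  }

  one <- function(i) {
    r <- prove_stability(model, combination_inputs(enum, i), search_budget = search_budget)
    detail <- if (r$status == "stable") "steady"
      else if (r$status == "not_stable") r$witness$kind
      else "inconclusive"
    state <- if (r$status == "stable") r$steady_state else
      stats::setNames(rep(NA_integer_, length(model$nodes)), model$nodes)
    list(index = i, status = r$status, detail = detail, state = state)
  }

  run_block <- function(indices) {
    recs <- if (workers > 1L) {
      parallel::mclapply(indices, one, mc.cores = workers)
    } else {
      lapply(indices, one)
    }
    recs
  }

  block_df <- function(recs) {
    states <- do.call(rbind, lapply(recs, `[[`, "state"))
    df <- data.frame(
      combination_index = vapply(recs, `[[`, numeric(1), "index"),
      status = vapply(recs, `[[`, character(1), "status"),
      detail = vapply(recs, `[[`, character(1), "detail"),
      stringsAsFactors = FALSE
    )
    cbind(df, as.data.frame(states))
  }

  starts <- seq(0, n - 1, by = checkpoint_every)
  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    idx <- starts[b]:min(starts[b] + checkpoint_every - 1, n - 1)
    ck <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("block_%012.0f.tsv", starts[b]))
    }
    if (!is.null(ck) && file.exists(ck)) {
      blocks[[b]] <- utils::read.table(ck, header = TRUE, sep = "\t",
                                       check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      df <- block_df(run_block(idx))
      if (!is.null(ck)) {
        utils::write.table(df, ck, sep = "\t", quote = FALSE, row.names = FALSE)
        df <- utils::read.table(ck, header = TRUE, sep = "\t",
                                check.names = FALSE, stringsAsFactors = FALSE)
      }
      blocks[[b]] <- df
    }
  }
  records <- do.call(rbind, blocks)
  records <- records[order(records$combination_index), , drop = FALSE]
  rownames(records) <- NULL

  counters <- c(
    stable = sum(records$status == "stable"),
    cycle = sum(records$detail == "cycle"),
    multiple_fixed_points = sum(records$detail == "multiple_fixed_points"),
    inconclusive = sum(records$status == "inconclusive")
  )
  structure(
    list(model_name = model$name, fingerprint = fp, fixed = enum$fixed,
         free = enum$free, nodes = model$nodes, records = records,
         counters = counters),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> ", x$model_name, ": ", nrow(x$records), " combinations (",
      x$counters[["stable"]], " stable, ", x$counters[["cycle"]], " cyclic, ",
      x$counters[["multiple_fixed_points"]], " multistable, ",
      x$counters[["inconclusive"]], " inconclusive)\n", sep = "")
  invisible(x)
}

#' Serialize a scan result as TSV text
#'
#' One row per combination: `combination_index`, `status`, `detail`, then one
#' column per node (steady-state values; NA for non-steady records). The
#' serialization is the determinism contract: scans of the same model with
#' any worker count, and resumed scans, produce identical text.
#'
#' @param scan_result A `scan_result`.
#' @param path Optional output file (written verbatim).
#' @return Character scalar of TSV text.
#' @export
scan_tsv <- function(scan_result, path = NULL) {
  lines <- utils::capture.output(
    utils::write.table(scan_result$records, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  txt
}

#' Keep the steady states of a scan
#'
#' @param scan_result A `scan_result`.
#' @return List with `states` (integer matrix of steady states, rows named
#'   by combination index, combination order preserved) and `report`
#'   (discard counts by reason).
#' @export
filter_steady <- function(scan_result) {
  rec <- scan_result$records
  keep <- rec$status == "stable"
  states <- as.matrix(rec[keep, scan_result$nodes, drop = FALSE])
  storage.mode(states) <- "integer"
  rownames(states) <- format(rec$combination_index[keep], scientific = FALSE, trim = TRUE)
  list(
    states = states,
    report = list(
      n_kept = sum(keep),
      n_discarded = sum(!keep),
      n_cyclic = sum(rec$detail == "cycle"),
      n_multiple_fixed_points = sum(rec$detail == "multiple_fixed_points"),
      n_inconclusive = sum(rec$status == "inconclusive")
    )
  )
}
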