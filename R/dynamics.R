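# Synchronous update semantics and the two-phase stability proof:
# phase 1 narrows every node's reachable value set by iterating the image of
# its rule over its regulators' sets (all-singleton = proof of a unique
# steady state); phase 2 searches the residual reduced space exhaustively
# for fixed points and cycles, falling back to seeded simulation when the
# residual space exceeds the search budget.

# documented base seed for the deterministic pseudo-random stream that picks
# fallback simulation start states
.fallback_stream_seed <- 20240126

# simple 31-bit LCG so fallback seeds never touch R's global RNG state
lcg_stream <- function(seed) {
  state <- seed %% 2147483647
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 1103515245 + 12345) %% 2147483648
      out[i] <- state
    }
    out
  }
}

check_inputs <- function(model, inputs) {
  ins <- input_nodes(model)
  if (length(ins)) {
    missing <- setdiff(ins, names(inputs))
    if (length(missing)) {
      stop("incomplete input assignment; unvalued input(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  vals <- as.integer(inputs[ins])
  if (length(vals) && !all(vals %in% c(0L, 1L))) {
    stop("input values must be 0 or 1", call. = FALSE)
  }
  stats::setNames(vals, ins)
}

as_state <- function(model, state) {
  if (is.null(names(state))) {
    if (length(state) != length(model$nodes)) {
      stop("state length ", length(state), " does not match node count ",
           length(model$nodes), call. = FALSE)
    }
    state <- stats::setNames(as.integer(state), model$nodes)
  } else {
    missing <- setdiff(model$nodes, names(state))
    if (length(missing)) {
      stop("state is missing node(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    state <- stats::setNames(as.integer(state[model$nodes]), model$nodes)
  }
  if (!all(state %in% c(0L, 1L))) stop("state values must be 0 or 1", call. = FALSE)
  state
}

#' Synchronous update step
#'
#' Applies every update rule simultaneously to the current state: each ruled
#' node takes its rule's value evaluated on the *previous* state, and each
#' input node keeps its clamped value from `inputs`.
#'
#' @param model A `boolean_model`.
#' @param state Current state: 0/1 vector aligned to `model$nodes` (named or
#'   positional).
#' @param inputs Named 0/1 vector valuing every input node.
#' @return The successor state (named integer vector).
#' @export
sync_step <- function(model, state, inputs) {
  state <- as_state(model, state)
  ivals <- check_inputs(model, inputs)
  nxt <- state
  for (nm in names(model$rules)) nxt[[nm]] <- eval_expr(model$rules[[nm]], state)
  nxt[names(ivals)] <- ivals
  nxt
}

new_attractor <- function(kind, states, input_assignment) {
  structure(list(kind = kind, states = states, input_assignment = input_assignment),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat("<attractor> ", x$kind,
      if (x$kind == "cyclic") paste0(" (length ", nrow(x$states), ")"), "\n", sep = "")
  invisible(x)
}

#' Simulate synchronous dynamics to an attractor
#'
#' Iterates [sync_step()] from `initial_state`, recording every visited
#' state, until a state repeats. A repeat of the immediately preceding state
#' is a steady state; otherwise the segment between the first and second
#' occurrence is a cyclic attractor. The full trajectory is returned for
#' time-course plots.
#'
#' @param model A `boolean_model`.
#' @param initial_state Starting state (input-node entries are overridden by
#'   `inputs` from step 1 on; step 0 records `initial_state` with inputs
#'   clamped).
#' @param inputs Named 0/1 vector valuing every input node.
#' @param max_steps Step budget; exceeding it without a repeat raises a
#'   nontermination error (cannot happen when `max_steps` is at least the
#'   state-space size, but the guard is kept).
#' @return List with `trajectory` (matrix, one row per step starting at step
#'   0) and `attractor` (an `attractor` object).
#' @export
simulate <- function(model, initial_state, inputs, max_steps = 2L * length(model$nodes) + 10L) {
  stopifnot(max_steps >= 1L)
  state <- as_state(model, initial_state)
  ivals <- check_inputs(model, inputs)
  state[names(ivals)] <- ivals
  traj <- matrix(NA_integer_, nrow = max_steps + 1L, ncol = length(model$nodes),
                 dimnames = list(NULL, model$nodes))
  traj[1L, ] <- state
  seen <- new.env(parent = emptyenv())
  assign(paste(state, collapse = ""), 1L, envir = seen)
  for (step in seq_len(max_steps)) {
    state <- sync_step(model, state, ivals)
    traj[step + 1L, ] <- state
    key <- paste(state, collapse = "")
    first <- get0(key, envir = seen)
    if (!is.null(first)) {
      traj <- traj[seq_len(step + 1L), , drop = FALSE]
      rownames(traj) <- paste0("step", 0L:step)
      if (first == step) {  # repeated the immediately preceding state
        att <- new_attractor("steady", traj[step + 1L, , drop = FALSE], ivals)
      } else {
        cyc <- traj[first:step, , drop = FALSE]
        att <- new_attractor("cyclic", cyc, ivals)
      }
      return(list(trajectory = traj, attractor = att))
    }
    assign(key, step + 1L, envir = seen)
  }
  stop("no repeated state within ", max_steps, " steps (nontermination guard)",
       call. = FALSE)
}

#' Export a trajectory in long TSV form
#'
#' @param sim Result of [simulate()].
#' @param path Optional file path to write a TSV (`step`, `node`, `value`).
#' @return The long-format data frame, invisibly when written to `path`.
#' @export
trajectory_table <- function(sim, path = NULL) {
  traj <- sim$trajectory
  df <- data.frame(
    step = rep(seq_len(nrow(traj)) - 1L, times = ncol(traj)),
    node = rep(colnames(traj), each = nrow(traj)),
    value = as.vector(traj),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Reduce each node's range to its reachable value set
#'
#' Starting from `{0,1}` for every ruled node and the clamped singleton for
#' every input, repeatedly replaces each node's set by the image of its rule
#' over the product of its regulators' current sets, until a fixpoint. The
#' result is a conservative superset of each node's long-run value set; if
#' every set is a singleton the model has a unique steady state under these
#' inputs and cannot cycle.
#'
#' @param model A `boolean_model`.
#' @param inputs Named 0/1 vector valuing every input node.
#' @param max_enum Skip image computation (keeping the previous, conservative
#'   set) for rules whose unresolved regulators exceed this count.
#' @return Named list mapping each node to an integer vector of possible
#'   values (`0`, `1`, or both).
#' @export
range_reduction <- function(model, inputs, max_enum = 16L) {
  ivals <- check_inputs(model, inputs)
  sets <- stats::setNames(rep(list(c(0L, 1L)), length(model$nodes)), model$nodes)
  for (nm in names(ivals)) sets[[nm]] <- ivals[[nm]]
  regs <- regulator_sets(model)
  repeat {
    changed <- FALSE
    for (nm in names(model$rules)) {
      rs <- regs[[nm]]
      free <- rs[vapply(rs, function(r) length(sets[[r]]) > 1L, logical(1))]
      if (length(free) > max_enum) next
      base <- stats::setNames(vapply(rs, function(r) sets[[r]][1L], integer(1)), rs)
      img <- integer(0)
      for (i in 0L:(2L^length(free) - 1L)) {
        vals <- base
        if (length(free)) {
          bits <- bitwAnd(i %/% 2L^(seq_along(free) - 1L), 1L)
          vals[free] <- ifelse(bits == 1L,
                               vapply(free, function(r) sets[[r]][2L], integer(1)),
                               vapply(free, function(r) sets[[r]][1L], integer(1)))
        }
        img <- unique(c(img, eval_expr(model$rules[[nm]], vals)))
        if (length(img) == 2L) break
      }
      img <- sort(img)
      if (!identical(img, sets[[nm]])) {
        sets[[nm]] <- img
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sets
}

# all cycles and fixed points of a functional graph given by successor
# indices (1-based).  Returns fixed-point indices and cycles (index vectors,
# length >= 2).
functional_graph_cycles <- function(nxt) {
  m <- length(nxt)
  color <- integer(m)           # 0 = unvisited, 1 = on current path, 2 = done
  pos_on_path <- integer(m)
  path <- integer(m)
  fixed <- which(nxt == seq_len(m))
  cycles <- list()
  for (v in seq_len(m)) {
    if (color[v] != 0L) next
    len <- 0L
    u <- v
    while (color[u] == 0L) {
      color[u] <- 1L
      len <- len + 1L
      path[len] <- u
      pos_on_path[u] <- len
      u <- nxt[u]
    }
    if (color[u] == 1L) {       # closed a new cycle on the current path
      cyc <- path[pos_on_path[u]:len]
      if (length(cyc) >= 2L) cycles[[length(cycles) + 1L]] <- cyc
    }
    color[path[seq_len(len)]] <- 2L
  }
  list(fixed_points = fixed, cycles = cycles)
}

# Build the 2^k x n state matrix spanning `bits_of` (little-endian bit j ->
# bits_of[j]) with all other columns held at `base`.
reduced_space_matrix <- function(base, bits_of, sets) {
  m <- 2L^length(bits_of)
  S <- matrix(rep(base, each = m), nrow = m, dimnames = list(NULL, names(base)))
  idx <- 0:(m - 1)
  for (j in seq_along(bits_of)) {
    nm <- bits_of[j]
    bit <- (idx %/% 2^(j - 1)) %% 2
    S[, nm] <- ifelse(bit == 1, sets[[nm]][2L], sets[[nm]][1L])
  }
  S
}

new_stability_result <- function(status, steady_state = NULL, witness = NULL,
                                 reduced_ranges = NULL) {
  structure(list(status = status, steady_state = steady_state,
                 witness = witness, reduced_ranges = reduced_ranges),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result> ", x$status, sep = "")
  if (!is.null(x$witness)) cat(" (witness: ", x$witness$kind, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Prove or refute stability under one input assignment
#'
#' Two-phase proof under the synchronous scheduler. Phase 1,
#' [range_reduction()]: if every node's set collapses to a singleton the
#' unique steady state is returned (`status = "stable"`). Phase 2: the
#' residual space spanned by unresolved nodes is searched for fixed points
#' and cycles — exhaustively when its size is within `search_budget`
#' (verdicts are then exact: stable iff exactly one fixed point and no
#' cycle), otherwise by simulation from a deterministic set of seed states;
#' simulation can refute stability (a cycle or a second fixed point is a
#' witness) but never prove it, so the result is `"inconclusive"` when no
#' witness is found.
#'
#' @param model A `boolean_model`.
#' @param inputs Named 0/1 vector valuing every input node.
#' @param search_budget Maximum residual-space size searched exhaustively.
#' @param n_sim_seeds Number of seeded fallback simulations.
#' @return A `stability_result` with `status` one of `"stable"`,
#'   `"not_stable"`, `"inconclusive"`; `steady_state` when stable; `witness`
#'   (`kind` `"cycle"` or `"multiple_fixed_points"` plus the states) when
#'   refuted; and the phase-1 `reduced_ranges`.
#' @export
prove_stability <- function(model, inputs, search_budget = 2L^16, n_sim_seeds = 64L) {
  ivals <- check_inputs(model, inputs)
  sets <- range_reduction(model, ivals)
  unresolved <- model$nodes[vapply(sets, length, integer(1)) > 1L]
  base <- stats::setNames(vapply(sets, function(s) s[1L], integer(1)), model$nodes)
  if (!length(unresolved)) {
    s <- base
    stopifnot(identical(sync_step(model, s, ivals), s))  # soundness guard
    return(new_stability_result("stable", steady_state = s, reduced_ranges = sets))
  }
  k <- length(unresolved)
  step_fn <- compile_model(model)
  if (2^k <= search_budget) {
    S <- reduced_space_matrix(base, unresolved, sets)
    nxt_mat <- step_fn(S)
    nxt_mat[, names(ivals)] <- rep(ivals, each = nrow(S))
    weights <- 2^(seq_len(k) - 1)
    # reduced space is forward-closed, so successors index back into it;
    # shift maps each unresolved node's lower set value to bit 0
    shift <- vapply(unresolved, function(nm) sets[[nm]][1L], integer(1))
    idx_next <- as.integer((nxt_mat[, unresolved, drop = FALSE] -
                              rep(shift, each = nrow(S))) %*% weights) + 1L
    fg <- functional_graph_cycles(idx_next)
    if (length(fg$cycles)) {
      cyc <- fg$cycles[[1L]]
      states <- S[cyc, , drop = FALSE]
      storage.mode(states) <- "integer"
      return(new_stability_result("not_stable",
        witness = list(kind = "cycle",
                       attractor = new_attractor("cyclic", states, ivals)),
        reduced_ranges = sets))
    }
    if (length(fg$fixed_points) == 1L) {
      s <- stats::setNames(as.integer(S[fg$fixed_points, ]), model$nodes)
      stopifnot(identical(sync_step(model, s, ivals), s))  # soundness guard
      return(new_stability_result("stable", steady_state = s, reduced_ranges = sets))
    }
    fps <- S[fg$fixed_points, , drop = FALSE]
    storage.mode(fps) <- "integer"
    return(new_stability_result("not_stable",
      witness = list(kind = "multiple_fixed_points", states = fps),
      reduced_ranges = sets))
  }
  # fallback: seeded simulations can refute stability but not prove it
  draw <- lcg_stream(.fallback_stream_seed)
  fixed_seen <- character(0)
  fixed_states <- list()
  for (i in seq_len(n_sim_seeds)) {
    s <- base
    s[unresolved] <- vapply(unresolved, function(nm) {
      # use a high-order bit: the LCG's low bits alternate deterministically
      sets[[nm]][1L + (draw(1) %/% 65536) %% 2]
    }, integer(1))
    sim <- tryCatch(
      simulate(model, s, ivals, max_steps = min(4L * length(model$nodes) + 100L, 2000L)),
      error = function(e) NULL)
    if (is.null(sim)) next
    if (sim$attractor$kind == "cyclic") {
      return(new_stability_result("not_stable",
        witness = list(kind = "cycle", attractor = sim$attractor),
        reduced_ranges = sets))
    }
    key <- paste(sim$attractor$states[1L, ], collapse = "")
    if (!key %in% fixed_seen) {
      fixed_seen <- c(fixed_seen, key)
      fixed_states[[length(fixed_states) + 1L]] <- sim$attractor$states[1L, ]
    }
    if (length(fixed_seen) >= 2L) {
      fps <- do.call(rbind, fixed_states)
      return(new_stability_result("not_stable",
        witness = list(kind = "multiple_fixed_points", states = fps),
        reduced_ranges = sets))
    }
  }
  new_stability_result("inconclusive", reduced_ranges = sets)
}
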