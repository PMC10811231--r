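# Seeded generators and oracles used to validate every analysis stage:
# random/acyclic Boolean models with topology-derived rules, an exact
# brute-force attractor oracle over the full synchronous transition graph,
# planted observation vectors, and a hand-built miniature macrophage model
# exercising the whole scan -> calibrate -> knockout pipeline.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded random Boolean model
#'
#' Inputs are named `I01..`, internal nodes `N01..`. Each internal node
#' draws an in-degree between 1 and `max_in_degree` and a signed regulator
#' set from the seeded stream; rules follow the topology-derived default
#' (`(OR activators) AND NOT (OR inhibitors)`). With `acyclic = TRUE`
#' internal node `j` may only be regulated by inputs and internal nodes with
#' smaller index, forcing a DAG (such models always stabilize). Identical
#' arguments produce identical models.
#'
#' @param n_internal Number of ruled nodes (at least 1).
#' @param n_inputs Number of input nodes (0 allowed).
#' @param max_in_degree Maximum regulators per node.
#' @param acyclic Force a feedback-free regulation graph.
#' @param seed Integer seed.
#' @return A `boolean_model`.
#' @export
random_boolean_model <- function(n_internal, n_inputs = 2L, max_in_degree = 3L,
                                 acyclic = FALSE, seed = 1L) {
  stopifnot(n_internal >= 1L, n_inputs >= 0L, max_in_degree >= 1L)
  inputs <- if (n_inputs) sprintf("I%02d", seq_len(n_inputs)) else character(0)
  internals <- sprintf("N%02d", seq_len(n_internal))
  nodes <- c(inputs, internals)
  with_local_seed(seed, {
    edges <- NULL
    for (j in seq_len(n_internal)) {
      pool <- if (acyclic) c(inputs, internals[seq_len(j - 1L)]) else nodes
      if (!length(pool)) next  # no candidate regulators: becomes a constant
      d <- sample.int(min(max_in_degree, length(pool)), 1L)
      regs <- sample(pool, d)
      signs <- sample(c("activator", "inhibitor"), d, replace = TRUE)
      edges <- rbind(edges, data.frame(source = regs, target = internals[j],
                                       sign = signs, stringsAsFactors = FALSE))
    }
    model <- infer_default_rules(edges, nodes = nodes,
                                 name = sprintf("random_%d", seed))
    # regulator-free internals degenerate to constants so the node set and
    # input/internal split always match the requested spec
    for (j in seq_len(n_internal)) {
      nm <- internals[j]
      if (!nm %in% names(model$rules)) {
        model$rules[[nm]] <- b_const(sample(0:1, 1L))
        model$kind[[nm]] <- "internal"
      }
    }
    model
  })
}

#' Exact attractors by full state-space enumeration
#'
#' Oracle for the stability proof: enumerates all `2^n` assignments of the
#' non-input nodes under one input valuation, computes the complete
#' synchronous successor map, and returns every fixed point and every cycle
#' of the functional graph. Exact by construction; guarded at 20 non-input
#' nodes (about 10^6 states).
#'
#' @param model A `boolean_model`.
#' @param inputs Named 0/1 vector valuing every input node.
#' @param guard Maximum number of non-input nodes.
#' @return List with `fixed_points` (integer matrix, one row per fixed
#'   point) and `cycles` (list of state matrices, cycle order, length >= 2).
#' @export
brute_force_attractors <- function(model, inputs, guard = 20L) {
  ivals <- check_inputs(model, inputs)
  ruled <- model$nodes[model$nodes %in% names(model$rules)]
  n <- length(ruled)
  if (n > guard) {
    stop("brute force refused: ", n, " non-input nodes exceed the guard (",
         guard, ")", call. = FALSE)
  }
  m <- 2L^n
  base <- stats::setNames(integer(length(model$nodes)), model$nodes)
  base[names(ivals)] <- ivals
  S <- matrix(rep(base, each = m), nrow = m, dimnames = list(NULL, model$nodes))
  idx <- 0:(m - 1)
  for (j in seq_len(n)) S[, ruled[j]] <- (idx %/% 2^(j - 1)) %% 2
  step_fn <- compile_model(model)
  nxt_mat <- step_fn(S)
  if (length(ivals)) nxt_mat[, names(ivals)] <- rep(ivals, each = m)
  weights <- 2^(seq_len(n) - 1)
  idx_next <- as.integer(nxt_mat[, ruled, drop = FALSE] %*% weights) + 1L
  fg <- functional_graph_cycles(idx_next)
  fixed <- S[fg$fixed_points, , drop = FALSE]
  storage.mode(fixed) <- "integer"
  cycles <- lapply(fg$cycles, function(cyc) {
    st <- S[cyc, , drop = FALSE]
    storage.mode(st) <- "integer"
    st
  })
  list(fixed_points = fixed, cycles = cycles)
}

#' Plant an observation vector around a steady state
#'
#' Copies a verified steady state and complements `n_flips` seeded
#' positions, giving an observation whose best-matching state is known by
#' construction (similarity of the planted state is `(n - k) / n`).
#'
#' @param model A `boolean_model` (supplies the node order).
#' @param steady_state Named 0/1 vector; must satisfy the fixed-point
#'   equation for its input values.
#' @param n_flips Number of positions to complement.
#' @param seed Integer seed choosing the flipped positions.
#' @return An `observation_vector` over all nodes, provenance
#'   `"expression"`, with attribute `flipped` naming the complemented nodes.
#' @export
plant_observation <- function(model, steady_state, n_flips = 0L, seed = 1L) {
  s <- as_state(model, steady_state)
  stopifnot(n_flips >= 0L, n_flips <= length(s))
  flip <- if (n_flips > 0L) {
    with_local_seed(seed, sample(model$nodes, n_flips))
  } else character(0)
  obs <- s
  obs[flip] <- 1L - obs[flip]
  out <- observation_vector(obs, provenance = "expression")
  attr(out, "flipped") <- flip
  out
}

#' Miniature macrophage signalling fixture
#'
#' A 17-node hand-built model of a pro-inflammatory macrophage: four
#' environmental inputs (IFNG, LPS, GF, IL10), an interferon/JAK/STAT branch
#' with two redundant kinases, an NFkB hub, an ERK growth branch, an
#' anti-inflammatory STAT3 branch, and three suffix-named phenotype nodes
#' (Apoptosis and Proliferation as cell-specific phenotypes, Inflammation as
#' a tissue signal). The regulation graph is acyclic, so every input
#' combination reaches a unique steady state. The fixture is wired so that:
#' the inflammatory constraint (Apoptosis OFF, Proliferation ON) is
#' satisfiable; knocking out the NFkB hub induces Apoptosis and suppresses
#' Proliferation; an ERK knockout suppresses Proliferation only; and the
#' JAK1/JAK2 pair is synergistic (neither single knockout changes any
#' phenotype, the pair flips both cell-specific ones).
#'
#' @return List with `model` (classified `boolean_model`), `observation`
#'   (an `observation_vector` over 8 internal/phenotype nodes),
#'   `constraint` (the inflammatory phenotype constraint), and `targets`
#'   (five candidate knockout targets).
#' @export
toy_macrophage_fixture <- function() {
  rules <- list(
    IFNGR = b_var("IFNG"),
    TLR4 = b_var("LPS"),
    JAK1 = b_var("IFNGR"),
    JAK2 = b_var("IFNGR"),
    STAT1 = b_and(b_var("IFNGR"), b_or(b_var("JAK1"), b_var("JAK2"))),
    NFkB = b_or(b_var("TLR4"), b_var("STAT1")),
    ERK = b_var("GF"),
    IL10R = b_var("IL10"),
    STAT3 = b_var("IL10R"),
    TNF = b_var("NFkB"),
    Proliferation_M1_macrophage = b_and(b_var("NFkB"), b_var("ERK"),
                                        b_not(b_var("STAT3"))),
    Apoptosis_M1_macrophage = b_not(b_var("NFkB")),
    Inflammation_signal = b_var("TNF")
  )
  nodes <- c("IFNG", "LPS", "GF", "IL10",
             "IFNGR", "TLR4", "JAK1", "JAK2", "STAT1", "NFkB", "ERK",
             "IL10R", "STAT3", "TNF",
             "Proliferation_M1_macrophage", "Apoptosis_M1_macrophage",
             "Inflammation_signal")
  model <- classify_nodes(boolean_model(nodes, rules, name = "toy_m1_macrophage"))
  observation <- observation_vector(
    c(IFNGR = 1L, STAT1 = 1L, NFkB = 1L, ERK = 1L, STAT3 = 0L, TNF = 1L,
      Proliferation_M1_macrophage = 1L, Apoptosis_M1_macrophage = 0L),
    provenance = c("expression", "expression", "literature", "expression",
                   "expression", "both", "literature", "literature")
  )
  constraint <- c(Apoptosis_M1_macrophage = 0L, Proliferation_M1_macrophage = 1L)
  targets <- c("NFkB", "ERK", "JAK1", "JAK2", "STAT3")
  list(model = model, observation = observation, constraint = constraint,
       targets = targets)
}
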