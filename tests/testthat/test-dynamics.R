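test_that("sync_step applies all rules simultaneously and clamps inputs", {
  m <- loop_model()  # A = NOT B, B = A
  s <- sync_step(m, c(A = 0L, B = 0L), c())
  expect_identical(s, c(A = 1L, B = 0L))
  # constant-rule model maps any state to the constant vector
  mc <- boolean_model(c("X", "Y"), list(X = b_const(1), Y = b_const(0)))
  expect_identical(sync_step(mc, c(X = 0L, Y = 1L), c()), c(X = 1L, Y = 0L))
  # input stays clamped even if the state disagrees
  mi <- boolean_model(c("I", "X"), list(X = b_var("I")))
  expect_identical(sync_step(mi, c(I = 0L, X = 0L), c(I = 1L)), c(I = 1L, X = 0L))
  expect_error(sync_step(mi, c(I = 0L, X = 0L), c()), "incomplete")
})

test_that("simulate finds the 4-cycle of the negative feedback loop", {
  m <- loop_model()
  sim <- simulate(m, c(A = 0L, B = 0L), c())
  expect_identical(sim$attractor$kind, "cyclic")
  expect_identical(nrow(sim$attractor$states), 4L)
  # cycle states map consecutively and wrap around
  st <- sim$attractor$states
  for (i in seq_len(4)) {
    expect_identical(unname(sync_step(m, st[i, ], c())),
                     unname(st[if (i == 4) 1 else i + 1, ]))
  }
})

test_that("simulate reaches the DAG steady state and detects fixed points", {
  m <- boolean_model(c("I", "A", "B"), list(A = b_var("I"), B = b_var("A")))
  sim <- simulate(m, c(I = 0L, A = 0L, B = 0L), c(I = 1L))
  expect_identical(sim$attractor$kind, "steady")
  expect_identical(sim$attractor$states[1, ], c(I = 1L, A = 1L, B = 1L))
  expect_lte(nrow(sim$trajectory), 5L)  # within <= 3 steps plus repeat row
  # starting at the fixed point: trajectory of length 2, steady
  sim2 <- simulate(m, c(I = 1L, A = 1L, B = 1L), c(I = 1L))
  expect_identical(nrow(sim2$trajectory), 2L)
  expect_identical(sim2$attractor$kind, "steady")
  # nontermination guard
  expect_error(simulate(loop_model(), c(A = 0L, B = 0L), c(), max_steps = 2),
               "nontermination")
})

test_that("trajectory export is long-format step/node/value", {
  m <- loop_model()
  sim <- simulate(m, c(A = 0L, B = 0L), c())
  df <- trajectory_table(sim)
  expect_identical(names(df), c("step", "node", "value"))
  expect_identical(nrow(df), nrow(sim$trajectory) * 2L)
  expect_identical(df$value[df$step == 0 & df$node == "A"], 0L)
})

test_that("range reduction narrows DAGs to singletons and leaves loops wide", {
  m <- boolean_model(c("I", "A", "B"), list(A = b_var("I"), B = b_var("A")))
  rr <- range_reduction(m, c(I = 1L))
  expect_true(all(vapply(rr, length, integer(1)) == 1L))
  expect_identical(rr$B, 1L)
  # negative feedback loop: both nodes keep {0,1}
  rr2 <- range_reduction(loop_model(), c())
  expect_identical(rr2$A, c(0L, 1L))
  expect_identical(rr2$B, c(0L, 1L))
  # constant rule collapses immediately
  m0 <- boolean_model("X", list(X = b_const(0)))
  expect_identical(range_reduction(m0, c())$X, 0L)
})

test_that("range reduction is conservative w.r.t. the exact attractor set", {
  for (seed in 1:20) {
    m <- random_boolean_model(n_internal = 6, n_inputs = 2, max_in_degree = 3,
                              acyclic = seed %% 2 == 0, seed = seed)
    enum <- enumerate_input_combinations(m)
    for (i in 0:(enum$n_combinations - 1)) {
      iv <- combination_inputs(enum, i)
      rr <- range_reduction(m, iv)
      bf <- brute_force_attractors(m, iv)
      long_run <- rbind(bf$fixed_points, do.call(rbind, bf$cycles))
      for (nm in colnames(long_run)) {
        expect_true(all(unique(long_run[, nm]) %in% rr[[nm]]),
                    label = paste("node", nm, "seed", seed, "combo", i))
      }
    }
  }
})

test_that("prove_stability matches hand-derived verdicts", {
  # DAG with clamped input: stable at the topological evaluation
  m <- boolean_model(c("I", "A", "B"), list(A = b_var("I"), B = b_var("A")))
  r <- prove_stability(m, c(I = 1L))
  expect_identical(r$status, "stable")
  expect_identical(r$steady_state, topo_eval(m, c(I = 1L)))
  # negative feedback loop: a 4-cycle witness
  r2 <- prove_stability(loop_model(), c())
  expect_identical(r2$status, "not_stable")
  expect_identical(r2$witness$kind, "cycle")
  expect_identical(nrow(r2$witness$attractor$states), 4L)
  # self-sustaining A = A OR B with B clamped 1: range reduction proves it
  m3 <- boolean_model(c("A", "B"), list(A = b_or(b_var("A"), b_var("B"))))
  r3 <- prove_stability(m3, c(B = 1L))
  expect_identical(r3$status, "stable")
  expect_identical(r3$steady_state, c(A = 1L, B = 1L))
  expect_identical(r3$reduced_ranges$A, 1L)
  # A = A with B removed: two fixed points, multistability witness
  m4 <- boolean_model("A", list(A = b_var("A")))
  r4 <- prove_stability(m4, c())
  expect_identical(r4$status, "not_stable")
  expect_identical(r4$witness$kind, "multiple_fixed_points")
  expect_identical(nrow(r4$witness$states), 2L)
})

test_that("an exhausted search budget yields inconclusive, not a guess", {
  # 12 coupled copies of A = A cannot be resolved by range reduction, and a
  # tiny budget forces the simulation fallback, which cannot prove stability
  nodes <- sprintf("A%02d", 1:12)
  rules <- stats::setNames(lapply(nodes, b_var), nodes)
  m <- boolean_model(nodes, rules)
  r <- prove_stability(m, c(), search_budget = 2, n_sim_seeds = 1)
  # one seed sees one fixed point: no witness, no proof
  expect_identical(r$status, "inconclusive")
  # more seeds find a second fixed point and refute stability
  r2 <- prove_stability(m, c(), search_budget = 2, n_sim_seeds = 32)
  expect_identical(r2$status, "not_stable")
  expect_identical(r2$witness$kind, "multiple_fixed_points")
})

test_that("acyclic models always prove stable at the closed form", {
  for (seed in 1:15) {
    m <- random_boolean_model(n_internal = 8, n_inputs = 3, acyclic = TRUE,
                              seed = seed)
    enum <- enumerate_input_combinations(m)
    for (i in 0:(enum$n_combinations - 1)) {
      iv <- combination_inputs(enum, i)
      r <- prove_stability(m, iv)
      expect_identical(r$status, "stable")
      expect_identical(r$steady_state, topo_eval(m, iv))
      # soundness: the returned state is a fixed point
      expect_identical(sync_step(m, r$steady_state, iv), r$steady_state)
    }
  }
})
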