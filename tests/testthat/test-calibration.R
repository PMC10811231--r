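test_that("DEG discretization maps significant calls to Boolean values", {
  deg <- data.frame(
    gene = c("geneX", "geneY", "geneZ", "geneW"),
    logFC = c(2.3, -1.2, 3.0, 0),
    adjP = c(0.001, 0.01, 0.20, 0.001)
  )
  obs <- discretize_deg_table(deg)
  expect_identical(obs$values, c(geneX = 1L, geneY = 0L))   # Z fails p, W has logFC 0
  expect_true(all(obs$provenance == "expression"))
  # threshold is strict by default, inclusive on request
  at_thr <- data.frame(gene = "g", logFC = 1, adjP = 0.05)
  expect_length(discretize_deg_table(at_thr)$values, 0)
  expect_identical(discretize_deg_table(at_thr, strict = FALSE)$values, c(g = 1L))
  # duplicate genes with conflicting calls fail loudly
  conf <- data.frame(gene = c("g", "g"), logFC = c(1, -1), adjP = c(0.01, 0.01))
  expect_error(discretize_deg_table(conf), "conflicting.*g")
  # name mapping onto model nodes
  mapped <- discretize_deg_table(data.frame(gene = "TNFA", logFC = 2, adjP = 0.01),
                                 name_map = c(TNFA = "TNF"))
  expect_identical(names(mapped$values), "TNF")
})

test_that("merging observations unions entries and resolves conflicts by policy", {
  lit <- observation_vector(c(A = 1L, B = 0L), provenance = "literature")
  expr <- observation_vector(c(B = 0L, C = 1L, D = 0L), provenance = "expression")
  merged <- merge_observations(lit, expr)
  expect_identical(merged$values, c(A = 1L, B = 0L, C = 1L, D = 0L))
  expect_identical(unname(merged$provenance[c("A", "B", "C")]),
                   c("literature", "both", "expression"))
  # disagreement errors by default and follows the chosen winner otherwise
  expr2 <- observation_vector(c(B = 1L), provenance = "expression")
  expect_error(merge_observations(lit, expr2), "disagree.*B")
  expect_identical(
    suppressMessages(merge_observations(lit, expr2, policy = "literature_wins"))$values[["B"]],
    0L)
  expect_identical(
    suppressMessages(merge_observations(lit, expr2, policy = "expression_wins"))$values[["B"]],
    1L)
})

test_that("phenotype filtering keeps exactly the matching states, monotonically", {
  states <- rbind(
    c(Apoptosis = 1L, Proliferation = 0L, X = 1L),
    c(Apoptosis = 0L, Proliferation = 1L, X = 0L),
    c(Apoptosis = 1L, Proliferation = 1L, X = 1L),
    c(Apoptosis = 1L, Proliferation = 0L, X = 0L)
  )
  colnames(states) <- c("Apoptosis", "Proliferation", "X")
  # empty constraint is vacuous
  expect_identical(filter_by_phenotype(states, c()), states)
  got <- filter_by_phenotype(states, c(Apoptosis = 1L, Proliferation = 0L))
  hand <- states[states[, "Apoptosis"] == 1 & states[, "Proliferation"] == 0, ]
  expect_identical(got, hand)
  # adding a constraint never enlarges the survivor set
  tighter <- filter_by_phenotype(got, c(X = 1L))
  expect_lte(nrow(tighter), nrow(got))
  # contradictory constraint on a constant column empties the list
  expect_identical(nrow(filter_by_phenotype(states[states[, "X"] == 1, , drop = FALSE],
                                            c(X = 0L))), 0L)
  expect_error(filter_by_phenotype(states, c(Ghost = 1L)), "unknown")
})

test_that("similarity implements the simple matching coefficient", {
  obs <- observation_vector(c(A = 1L, B = 0L, P = 1L))
  s <- similarity(c(A = 1L, B = 1L, P = 1L), obs)
  expect_identical(s$N11, 2L)
  expect_identical(s$N10, 1L)
  expect_equal(s$S, 2 / 3)
  expect_identical(s$N00 + s$N01 + s$N10 + s$N11, 3L)
  # perfect and zero matches
  expect_equal(similarity(c(A = 1L, B = 0L, P = 1L), obs)$S, 1)
  expect_equal(similarity(c(A = 0L, B = 1L, P = 0L), obs)$S, 0)
  # symmetry: swapping state and observation leaves S unchanged
  st <- c(A = 1L, B = 1L, P = 0L)
  expect_equal(similarity(st, obs)$S, similarity(obs$values, st)$S)
  # unresolvable observed nodes are quarantined, all-unresolvable errors
  s2 <- similarity(c(A = 1L), observation_vector(c(A = 1L, Zz = 0L)))
  expect_identical(s2$unresolved, "Zz")
  expect_error(similarity(c(A = 1L), observation_vector(c(Zz = 0L))),
               "no observed node")
})

test_that("similarity is bounded in [0,1] over random vectors", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    nm <- paste0("n", seq_len(n))
    st <- stats::setNames(sample(0:1, n, replace = TRUE), nm)
    obs <- stats::setNames(sample(0:1, n, replace = TRUE), nm)
    S <- similarity(st, obs)$S
    expect_gte(S, 0); expect_lte(S, 1)
  }
})

test_that("select_top keeps all argmax states and mean_state flags fixedness", {
  states <- rbind(c(A = 1L, B = 0L), c(A = 1L, B = 1L))
  colnames(states) <- c("A", "B")
  obs <- observation_vector(c(A = 1L))
  top <- select_top(states, obs)
  expect_identical(nrow(top$states), 2L)   # tie kept
  expect_equal(top$score, 1)
  cal <- mean_state(top$states)
  expect_equal(unname(cal$mean), c(1, 0.5))
  expect_identical(cal$fixed, "A")
  expect_identical(cal$unfixed, "B")
  expect_identical(cal$n_states, 2L)
  # a single state is returned as itself, fully fixed
  cal1 <- mean_state(states[1, , drop = FALSE])
  expect_length(cal1$unfixed, 0)
  expect_equal(unname(cal1$mean), c(1, 0))
})

test_that("mean of identical copies is the state itself, all fixed", {
  s <- c(X = 1L, Y = 0L, Z = 1L)
  cal <- mean_state(rbind(s, s, s))
  expect_equal(cal$mean, c(X = 1, Y = 0, Z = 1))
  expect_length(cal$unfixed, 0)
})

test_that("match_report separates matches, mismatches and unfixed overlaps", {
  cal <- mean_state(rbind(c(A = 1L, B = 0L, C = 1L), c(A = 1L, B = 0L, C = 0L)))
  obs <- observation_vector(c(A = 1L, B = 1L, C = 1L))
  rep <- match_report(cal, obs)
  expect_identical(rep$matches, "A")
  expect_identical(rep$mismatches, "B")
  expect_identical(rep$unfixed, "C")
  expect_equal(rep$percentage, 33.3)
  # a planted flip among 20 observed nodes gives 95.0% and names the node
  nm <- paste0("n", 1:20)
  state <- stats::setNames(rep(1L, 20), nm)
  obs20 <- state; obs20[["n7"]] <- 0L
  rep20 <- match_report(mean_state(rbind(state)), observation_vector(obs20))
  expect_equal(rep20$percentage, 95.0)
  expect_identical(rep20$mismatches, "n7")
  # all observed nodes unfixed: zero matches
  cal_unfixed <- mean_state(rbind(c(A = 0L, B = 0L), c(A = 1L, B = 1L)))
  rep_u <- match_report(cal_unfixed, observation_vector(c(A = 1L, B = 0L)))
  expect_length(rep_u$matches, 0)
  expect_identical(rep_u$unfixed, c("A", "B"))
})

test_that("calibration recovers a planted steady state below the Hamming margin", {
  recovered <- 0L
  for (seed in 1:25) {
    m <- random_boolean_model(n_internal = 7, n_inputs = 3, acyclic = TRUE,
                              seed = 100 + seed)
    sc <- scan(m)
    states <- filter_steady(sc)$states
    states <- states[!duplicated(apply(states, 1, paste, collapse = "")), , drop = FALSE]
    if (nrow(states) < 2) next
    planted_row <- 1L + (seed %% nrow(states))
    planted <- stats::setNames(states[planted_row, ], colnames(states))
    dists <- apply(states[-planted_row, , drop = FALSE], 1, hamming, b = planted)
    margin <- min(dists)
    k <- max(0L, (margin - 1L) %/% 2L)
    obs <- plant_observation(m, planted, n_flips = k, seed = seed)
    top <- select_top(states, obs)
    expect_identical(nrow(top$states), 1L)
    expect_identical(unname(top$states[1, ]), unname(planted))
    n <- length(planted)
    expect_equal(top$score, (n - k) / n)
    # match percentage equals (n - k)/n exactly (to the reported decimal)
    repp <- match_report(mean_state(top$states), obs)
    expect_equal(repp$percentage, floor(100 * (n - k) / n * 10 + 0.5) / 10)
    recovered <- recovered + 1L
  }
  expect_gte(recovered, 15L)  # the loop must actually exercise recovery
})
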