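# Shared oracles and fixture builders, independent of the code paths under
# test: truth-table equality uses direct expression evaluation over all
# regulator assignments; the DAG oracle evaluates rules to fixpoint by plain
# iteration.

# assert two models have identical rule truth tables (exhaustive over each
# rule's regulators; regulator counts are small in all fixtures)
expect_same_truth_tables <- function(m1, m2) {
  expect_identical(sort(m1$nodes), sort(m2$nodes))
  expect_identical(sort(names(m1$rules)), sort(names(m2$rules)))
  for (nm in names(m1$rules)) {
    refs <- sort(unique(c(expr_refs(m1$rules[[nm]]), expr_refs(m2$rules[[nm]]))))
    k <- length(refs)
    for (i in 0:(2^k - 1)) {
      vals <- stats::setNames(as.integer((i %/% 2^(seq_len(k) - 1)) %% 2), refs)
      expect_identical(eval_expr(m1$rules[[nm]], vals),
                       eval_expr(m2$rules[[nm]], vals),
                       label = paste0("rule ", nm, " row ", i))
    }
  }
}

# closed-form steady state of an acyclic model: iterate plain rule
# evaluation from the inputs until nothing changes (at most n passes)
topo_eval <- function(model, inputs) {
  s <- stats::setNames(integer(length(model$nodes)), model$nodes)
  s[names(inputs)] <- as.integer(inputs)
  for (pass in seq_len(length(model$nodes) + 1L)) {
    nxt <- s
    for (nm in names(model$rules)) nxt[[nm]] <- eval_expr(model$rules[[nm]], s)
    if (identical(nxt, s)) return(s)
    s <- nxt
  }
  stop("model is not acyclic")
}

# two-node negative feedback loop: A = NOT B, B = A (pure 4-cycle)
loop_model <- function() {
  boolean_model(c("A", "B"),
                list(A = b_not(b_var("B")), B = b_var("A")),
                name = "loop")
}

# three-node chain I -> A -> P with a disconnected input J
chain_model <- function() {
  boolean_model(c("I", "J", "A", "P"),
                list(A = b_var("I"), P = b_var("A")),
                name = "chain")
}

# hamming distance between two 0/1 vectors over shared names
hamming <- function(a, b) sum(a[names(b)] != b)
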