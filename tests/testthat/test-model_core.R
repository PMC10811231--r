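test_that("expression evaluation follows Boolean semantics", {
  e <- b_and(b_var("A"), b_not(b_var("B")))
  expect_identical(eval_expr(e, c(A = 1L, B = 0L)), 1L)
  expect_identical(eval_expr(e, c(A = 1L, B = 1L)), 0L)
  expect_identical(eval_expr(b_or(b_const(0), b_const(1)), c()), 1L)
  expect_setequal(expr_refs(e), c("A", "B"))
  expect_error(eval_expr(b_var("Z"), c(A = 1L)), "unvalued")
})

test_that("model construction enforces closure and uniqueness invariants", {
  expect_error(boolean_model(c("A", "A"), list()), "duplicate")
  expect_error(boolean_model("A", list(B = b_const(1))), "unknown node")
  expect_error(boolean_model("A", list(A = b_var("Ghost"))), "unknown node")
  m <- boolean_model(c("I", "X"), list(X = b_var("I")))
  expect_identical(input_nodes(m), "I")
  expect_identical(internal_nodes(m), "X")
})

test_that("classify_nodes partitions by suffix and regulator presence", {
  m <- boolean_model(
    c("LPS", "NFkB", "Apoptosis_M1_macrophage", "Inflammation_signal"),
    list(NFkB = b_var("LPS"),
         Apoptosis_M1_macrophage = b_not(b_var("NFkB")),
         Inflammation_signal = b_var("NFkB"))
  )
  m <- classify_nodes(m)
  expect_identical(unname(m$kind),
                   c("input", "internal", "phenotype", "phenotype"))
  expect_identical(unname(m$phenotype_class[c(3, 4)]), c("cell_specific", "signal"))
  # every node has exactly one kind
  expect_true(all(m$kind %in% c("input", "internal", "phenotype")))
  # a node matching both a cell suffix and the signal suffix is ambiguous
  m2 <- boolean_model(c("X", "Bad_M1_macrophage_signal"),
                      list(Bad_M1_macrophage_signal = b_var("X")))
  expect_error(classify_nodes(m2, cell_suffixes = "_M1_macrophage_signal"),
               "ambiguous")
})

test_that("restrict_to_upstream keeps the ancestor closure and is idempotent", {
  m <- chain_model()   # I -> A -> P plus disconnected input J
  r <- restrict_to_upstream(m, "P")
  expect_identical(r$model$nodes, c("I", "A", "P"))
  expect_identical(r$report$removed, "J")
  expect_identical(r$report$n_removed_inputs, 1L)
  # no retained rule references a removed node
  for (rule in r$model$rules) {
    expect_length(setdiff(expr_refs(rule), r$model$nodes), 0)
  }
  # idempotent
  r2 <- restrict_to_upstream(r$model, "P")
  expect_identical(r2$model$nodes, r$model$nodes)
  expect_identical(r2$report$n_removed, 0L)
  # closure of everything = identity
  all_r <- restrict_to_upstream(m, m$nodes)
  expect_identical(all_r$model$nodes, m$nodes)
  expect_error(restrict_to_upstream(m, "Nope"), "unknown phenotype")
})

test_that("infer_default_rules builds activator-OR / inhibitor-veto rules", {
  edges <- data.frame(
    source = c("A", "B", "C"), target = "T",
    sign = c("activator", "activator", "inhibitor")
  )
  m <- infer_default_rules(edges)
  # T = (A | B) & !C, checked over all 8 assignments
  for (i in 0:7) {
    v <- c(A = i %% 2, B = (i %/% 2) %% 2, C = (i %/% 4) %% 2)
    expect_identical(eval_expr(m$rules$T, v),
                     as.integer((v[["A"]] | v[["B"]]) && !v[["C"]]))
  }
  # single activator degenerates to a bare reference
  m1 <- infer_default_rules(data.frame(source = "A", target = "T", sign = "activator"))
  expect_identical(format(m1$rules$T), "A")
  expect_identical(input_nodes(m1), "A")
  # only-inhibitor target
  m2 <- infer_default_rules(data.frame(source = "A", target = "T", sign = "inhibitor"))
  expect_identical(eval_expr(m2$rules$T, c(A = 0L)), 1L)
  expect_error(
    infer_default_rules(data.frame(source = c("A", "A"), target = "T",
                                   sign = c("activator", "inhibitor"))),
    "conflicting"
  )
})

test_that("BMA JSON round-trip preserves nodes, inputs and truth tables", {
  # 1-input degenerate model
  m0 <- boolean_model("I", list())
  expect_identical(parse_bma_json(write_bma_json(m0))$nodes, "I")
  # hand model with nesting
  m <- boolean_model(
    c("A", "B", "C", "T"),
    list(T = b_or(b_and(b_var("A"), b_not(b_var("B"))),
                  b_not(b_or(b_var("C"), b_const(0)))))
  )
  expect_same_truth_tables(m, parse_bma_json(write_bma_json(m)))
  # random expressions of depth 5 round-trip (seeded generator)
  rand_expr <- function(depth, vars) {
    if (depth == 0L) {
      if (stats::runif(1) < 0.8) b_var(sample(vars, 1)) else b_const(sample(0:1, 1))
    } else {
      switch(sample(3, 1),
             b_not(rand_expr(depth - 1L, vars)),
             b_and(rand_expr(depth - 1L, vars), rand_expr(depth - 1L, vars)),
             b_or(rand_expr(depth - 1L, vars), rand_expr(depth - 1L, vars)))
    }
  }
  set.seed(42)
  for (rep in 1:10) {
    e <- rand_expr(5L, c("A", "B", "C"))
    m <- boolean_model(c("A", "B", "C", "T"), list(T = e))
    expect_same_truth_tables(m, parse_bma_json(write_bma_json(m)))
  }
})

test_that("BMA formula grammar maps min/max/complement and rejects the rest", {
  doc <- jsonlite::toJSON(list(Model = list(
    Name = "g",
    Variables = list(
      list(Id = 3, Name = "A", RangeFrom = 0, RangeTo = 1, Formula = ""),
      list(Id = 5, Name = "B", RangeFrom = 0, RangeTo = 1, Formula = ""),
      list(Id = 7, Name = "T", RangeFrom = 0, RangeTo = 1,
           Formula = "min(var(3), 1 - var(5))")
    ),
    Relationships = list()
  )), auto_unbox = TRUE)
  m <- parse_bma_json(doc)
  expect_identical(format(m$rules$T), "A & !B")
  expect_setequal(input_nodes(m), c("A", "B"))

  bad_range <- sub('"RangeTo":1,"Formula":"min', '"RangeTo":2,"Formula":"min', doc)
  expect_error(parse_bma_json(bad_range), "granularity|range")
  bad_fn <- sub("min\\(var\\(3\\), 1 - var\\(5\\)\\)", "avg(var(3), var(5))", doc)
  expect_error(parse_bma_json(bad_fn), "unsupported")
  dangling <- sub("var\\(3\\)", "var(99)", doc)
  expect_error(parse_bma_json(dangling), "missing variable")
})

test_that("empty formulas fall back to relationships or input status", {
  doc <- jsonlite::toJSON(list(Model = list(
    Name = "g",
    Variables = list(
      list(Id = 1, Name = "A", RangeFrom = 0, RangeTo = 1, Formula = ""),
      list(Id = 2, Name = "B", RangeFrom = 0, RangeTo = 1, Formula = ""),
      list(Id = 3, Name = "T", RangeFrom = 0, RangeTo = 1, Formula = "")
    ),
    Relationships = list(
      list(Id = 1, FromVariable = 1, ToVariable = 3, Type = "Activator"),
      list(Id = 2, FromVariable = 2, ToVariable = 3, Type = "Inhibitor")
    )
  )), auto_unbox = TRUE)
  m <- parse_bma_json(doc)
  expect_setequal(input_nodes(m), c("A", "B"))
  expect_identical(eval_expr(m$rules$T, c(A = 1L, B = 0L)), 1L)
  expect_identical(eval_expr(m$rules$T, c(A = 1L, B = 1L)), 0L)
})

test_that("SBML-qual documents parse to the expected model", {
  path <- system.file("extdata", "sbml", "toy_chain.sbml", package = "boolcal")
  m <- parse_sbml_qual(path)
  expect_identical(m$nodes, c("A", "B", "C"))
  expect_identical(input_nodes(m), "A")
  expect_identical(format(m$rules$B), "A")
  expect_identical(format(m$rules$C), "A & !B")
  # species ids preserved in annotations
  expect_identical(m$annotations$A$sbml_id, "s_A")
  # degenerate document: one species, no transitions -> single input, no rules
  single <- sub("<qual:listOfTransitions>.*</qual:listOfTransitions>", "",
                paste(readLines(path), collapse = "\n"))
  single <- gsub("<qual:qualitativeSpecies qual:id=\"s_B\".*?/>", "", single)
  single <- gsub("<qual:qualitativeSpecies qual:id=\"s_C\".*?/>", "", single)
  m1 <- parse_sbml_qual(single)
  expect_identical(m1$nodes, "A")
  expect_length(m1$rules, 0)
  # maxLevel > 1 is a granularity error
  multi <- sub('qual:id="s_B" qual:maxLevel="1"', 'qual:id="s_B" qual:maxLevel="2"',
               sub('qual:name="B" ', "", paste(readLines(path), collapse = "\n")))
  expect_error(parse_sbml_qual(multi), "maxLevel")
})

test_that("model summary reports kind and in-degree per node", {
  fx <- toy_macrophage_fixture()
  s <- model_summary(fx$model)
  expect_identical(nrow(s), 17L)
  expect_identical(s$in_degree[s$node == "STAT1"], 3L)
  expect_identical(s$kind[s$node == "IFNG"], "input")
  expect_identical(s$phenotype_class[s$node == "Inflammation_signal"], "signal")
})
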