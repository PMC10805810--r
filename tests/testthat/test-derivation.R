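# helpers to build little worlds of derivations ------------------------------

fresh_world <- function(seed = 1L) {
  g <- kg_new(seed)
  ag <- register_agent(g, task_type = "Analysis")
  list(g = g, agent = ag)
}

noop_handler <- function(g, d, inputs, outs) {
  for (o in outs) kg_add(g, o, "kg:filled", "true", "boolean")
  outs
}

test_that("derivation creation validates registration and inputs", {
  w <- fresh_world()
  kg_add(w$g, "kg:in1", "rdf:type", "kg:Thing")
  d <- create_derivation(w$g, w$agent, "kg:in1", "Analysis")
  expect_identical(kg_value(w$g, d$iri, "kg:hasStatus"), "Requested")

  expect_error(create_derivation(w$g, w$agent, "kg:in1", "DoE"), "not registered")
  expect_error(create_derivation(w$g, w$agent, "kg:nope", "Analysis"), "kg:nope")
})

test_that("is_outdated agrees with a brute-force timestamp oracle", {
  set.seed(5)
  for (rep in 1:10) {
    w <- fresh_world(rep)
    ins <- sprintf("kg:in%d", 1:4)
    for (i in ins) kg_add(w$g, i, "rdf:type", "kg:Thing")
    d <- create_derivation(w$g, w$agent, ins, "Analysis",
                           placeholder_outputs = "Thing")
    poll_and_execute(w$g, w$agent, noop_handler)
    # random writes after completion
    touched <- sample(ins, sample(0:4, 1))
    for (i in touched) kg_add(w$g, i, "kg:touched", as.character(runif(1)), "double")
    finished_at <- kg_value(w$g, d$iri, "kg:finishedAtTick")
    oracle <- any(vapply(ins, function(i) kg_last_write(w$g, i) > finished_at, logical(1)))
    expect_identical(is_outdated(w$g, d$iri), oracle)
  }
})

test_that("chained derivations execute in dependency order", {
  w <- fresh_world()
  kg_add(w$g, "kg:seed", "rdf:type", "kg:Thing")
  d1 <- create_derivation(w$g, w$agent, "kg:seed", "Analysis", "Thing")
  d2 <- create_derivation(w$g, w$agent, d1$outputs, "Analysis", "Thing")
  # d2 depends on unfinished d1: first poll runs d1 then d2 (oldest first,
  # d2 becomes executable within the same poll only after d1 finished)
  run1 <- poll_and_execute(w$g, w$agent, noop_handler)
  expect_equal(run1[1], d1$iri)
  if (length(run1) == 1L) {
    expect_identical(kg_value(w$g, d2$iri, "kg:hasStatus"), "Requested")
    run2 <- poll_and_execute(w$g, w$agent, noop_handler)
    expect_equal(run2, d2$iri)
  }
  expect_identical(kg_value(w$g, d2$iri, "kg:hasStatus"), "Finished")
})

test_that("random DAGs complete in a valid topological order", {
  set.seed(42)
  for (rep in 1:20) {
    g <- kg_new(rep)
    ag <- register_agent(g, task_type = "Analysis")
    n <- sample(3:20, 1)
    derivs <- character(n); outs <- character(n)
    edges <- NULL
    for (i in seq_len(n)) {
      parents <- if (i > 1) which(runif(i - 1) < 0.3) else integer(0)
      ins <- if (length(parents)) outs[parents] else character(0)
      if (length(ins) == 0L) {
        root <- sprintf("kg:root%d_%d", rep, i)
        kg_add(g, root, "rdf:type", "kg:Thing")
        ins <- root
      }
      d <- create_derivation(g, ag, ins, "Analysis", "Thing")
      derivs[i] <- d$iri; outs[i] <- d$outputs
      if (length(parents)) edges <- rbind(edges, cbind(derivs[parents], d$iri))
    }
    log <- run_until_quiescent(g, stats::setNames(list(noop_handler), ag))
    ev <- event_log_df(log)
    finished <- ev$derivation[ev$transition == "Finished"]
    expect_setequal(finished, derivs)
    if (!is.null(edges)) expect_true(is_topological(finished, edges))
    expect_length(log$deadlock, 0L)
  }
})

test_that("cyclic dependencies deadlock with a report, never loop forever", {
  g <- kg_new(1)
  ag <- register_agent(g, task_type = "Analysis")
  kg_add(g, "kg:seed", "rdf:type", "kg:Thing")
  d1 <- create_derivation(g, ag, "kg:seed", "Analysis", "Thing")
  d2 <- create_derivation(g, ag, d1$outputs, "Analysis", "Thing")
  # close the cycle: d1 additionally depends on d2's future output
  kg_add(g, d1$iri, "kg:isDerivedFrom", d2$outputs)
  log <- run_until_quiescent(g, stats::setNames(list(noop_handler), ag),
                             max_ticks = 50L)
  expect_setequal(log$deadlock, c(d1$iri, d2$iri))
})

test_that("a failing handler yields Error without blocking independent branches", {
  g <- kg_new(1)
  ag_ok <- register_agent(g, task_type = "Analysis")
  ag_bad <- register_agent(g, task_type = "DoE")
  kg_add(g, "kg:seed", "rdf:type", "kg:Thing")
  d_bad <- create_derivation(g, ag_bad, "kg:seed", "DoE", "Thing")
  d_ok <- create_derivation(g, ag_ok, "kg:seed", "Analysis", "Thing")
  d_down <- create_derivation(g, ag_ok, d_bad$outputs, "Analysis", "Thing")
  handlers <- stats::setNames(
    list(noop_handler, function(g, d, i, o) stop("boom")),
    c(ag_ok, ag_bad))
  log <- run_until_quiescent(g, handlers, max_ticks = 20L)
  expect_identical(kg_value(g, d_bad$iri, "kg:hasStatus"), "Error")
  expect_identical(kg_value(g, d_bad$iri, "kg:hasErrorMessage"), "boom")
  expect_identical(kg_value(g, d_ok$iri, "kg:hasStatus"), "Finished")
  # downstream of the error is blocked, but not reported as deadlock
  expect_identical(log$blocked, d_down$iri)
  expect_length(log$deadlock, 0L)
  # no partial outputs were linked
  expect_length(deriv_outputs(g, d_bad$iri), 0L)
})

test_that("event logs are identical across runs with the same seed and roster", {
  build_and_run <- function() {
    g <- kg_new(77)
    ag <- register_agent(g, task_type = "Analysis")
    kg_add(g, "kg:seed", "rdf:type", "kg:Thing")
    d1 <- create_derivation(g, ag, "kg:seed", "Analysis", "Thing")
    d2 <- create_derivation(g, ag, d1$outputs, "Analysis", "Thing")
    create_derivation(g, ag, "kg:seed", "Analysis", "Thing")
    event_log_df(run_until_quiescent(g, stats::setNames(list(noop_handler), ag)))
  }
  expect_identical(build_and_run(), build_and_run())
})
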