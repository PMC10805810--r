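cfg <- default_campaign_config(1)
lab_iris <- c(cambridge = "kg:Lab_cambridge", singapore = "kg:Lab_singapore")

goal_world <- function(seed = 1L) {
  g <- kg_new(seed)
  for (iri in lab_iris) kg_add(g, iri, "rdf:type", "kg:Laboratory")
  g
}

test_that("a goal request instantiates goals, restriction, labs and bounds", {
  g <- goal_world()
  gs <- parse_goal_request(g, cfg$goal_request, lab_iris)
  expect_equal(nrow(kg_query(g, s = gs, p = "kg:hasGoal")), 2L)
  expect_equal(nrow(kg_query(g, s = gs, p = "kg:hasParticipatingLab")), 2L)
  goals <- goalset_goals(g, gs)
  expect_setequal(goals$objective, c("yield", "run_material_cost"))
  restr <- kg_values(g, gs, "kg:hasRestriction")
  expect_length(restr, 1L)
  expect_equal(kg_value(g, restr, "kg:hasCycleAllowance"), 65L)
  ss2 <- goalset_search_space(g, gs)
  expect_equal(ss2$temperature, cfg$goal_request$search_space$temperature)

  # single objective is degenerate but legal
  one <- cfg$goal_request
  one$objectives <- one$objectives[1]
  gs1 <- parse_goal_request(g, one, lab_iris)
  expect_equal(nrow(kg_query(g, s = gs1, p = "kg:hasGoal")), 1L)
})

test_that("invalid goal requests are rejected with the offending fields", {
  g <- goal_world()
  bad <- cfg$goal_request
  bad$objectives <- NULL
  expect_error(parse_goal_request(g, bad, lab_iris), "objectives")
  flat <- cfg$goal_request
  flat$search_space$temperature <- c(50, 50)
  expect_error(parse_goal_request(g, flat, lab_iris), "lower < upper")
  stranger <- cfg$goal_request
  stranger$labs <- c("cambridge", "atlantis")
  expect_error(parse_goal_request(g, stranger, lab_iris), "atlantis")
})

test_that("one goal-iteration derivation is spawned per participating lab", {
  g <- goal_world()
  rogi <- register_agent(g, "kg:Agent_rogi", "GoalIteration")
  gs <- parse_goal_request(g, cfg$goal_request, lab_iris)
  ds <- spawn_goal_iterations(g, gs, rogi)
  expect_length(ds, 2L)

  # removing a lab from the list before spawning drops its derivation
  ds1 <- spawn_goal_iterations(g, gs, rogi, labs = lab_iris[["cambridge"]])
  expect_length(ds1, 1L)
  expect_error(spawn_goal_iterations(g, gs, "kg:Agent_ghost"), "ghost")
})

test_that("an iteration plan wires the four-stage DMTA chain in order", {
  g <- goal_world()
  state <- new.env()
  state$agents <- list(
    rogi = register_agent(g, "kg:Agent_rogi", "GoalIteration"),
    doe = register_agent(g, "kg:Agent_doe", "DoE"),
    schedule = register_agent(g, "kg:Agent_schedule", "Schedule"),
    executor = register_agent(g, "kg:Agent_executor", "Execution"),
    postproc = register_agent(g, "kg:Agent_postproc", "Analysis"))
  gs <- parse_goal_request(g, cfg$goal_request, lab_iris)
  chain <- rogi_plan_iteration(g, state, gs, lab_iris[["cambridge"]])
  derivs <- c(chain$doe, chain$schedule, chain$execution, chain$analysis)
  expect_length(derivs, 4L)
  for (d in derivs) expect_identical(kg_value(g, d, "kg:hasStatus"), "Requested")
  # dependency chain: each stage consumes the previous placeholder
  expect_true(chain$condition %in% deriv_inputs(g, chain$schedule))
  expect_true(chain$experiment %in% deriv_inputs(g, chain$execution))
  expect_true(chain$report %in% deriv_inputs(g, chain$analysis))
})

test_that("stage completion order within a campaign is DoE, Schedule, Execution, Analysis", {
  res <- acceptance_campaign()
  ev <- res$events
  g <- res$graph
  task_of <- function(d) kg_value(g, d, "kg:hasTaskType", default = NA_character_)
  fin <- ev[ev$transition == "Finished", ]
  fin$task <- vapply(fin$derivation, task_of, character(1))
  # for every analysis derivation, its chain predecessors finished earlier
  stages <- c("DoE", "Schedule", "Execution", "Analysis")
  pos <- lapply(stages, function(tt) which(fin$task == tt))
  names(pos) <- stages
  expect_true(all(lengths(pos) > 0))
  # pair up chains through the experiment each analysis reports on
  for (i in pos$Analysis) {
    d_ana <- fin$derivation[i]
    rep_iri <- intersect(deriv_inputs(g, d_ana),
                         kg_query(g, p = "rdf:type", o = "kg:HPLCReport")$s)
    d_exec <- kg_values(g, rep_iri[1], "kg:belongsTo")[1]
    expect_lt(which(fin$derivation == d_exec), i)
  }
})

test_that("a missing stage agent fails that iteration without touching other labs", {
  g <- goal_world()
  state <- new.env()
  state$agents <- list(
    rogi = register_agent(g, "kg:Agent_rogi", "GoalIteration"),
    doe = register_agent(g, "kg:Agent_doe", "DoE"),
    # Schedule agent deliberately absent
    schedule = "kg:Agent_missing",
    executor = register_agent(g, "kg:Agent_executor", "Execution"),
    postproc = register_agent(g, "kg:Agent_postproc", "Analysis"))
  gs <- parse_goal_request(g, cfg$goal_request, lab_iris)
  expect_error(rogi_plan_iteration(g, state, gs, lab_iris[["cambridge"]]),
               "not registered")
})

test_that("progress evaluation applies joint thresholds and resource limits", {
  g <- goal_world()
  state <- new.env()
  state$agents <- list(rogi = register_agent(g, "kg:Agent_rogi", "GoalIteration"))
  state$allowance_left <- 5L
  state$deadline_ticks <- 100000L
  state$stopped <- FALSE
  state$decisions <- list()
  state$twin_by_iri <- list()

  req <- cfg$goal_request
  req$objectives[[1]]$threshold <- 90   # yield >= 90
  req$objectives[[2]]$threshold <- 6    # cost <= 6
  gs <- parse_goal_request(g, req, lab_iris)

  add_pt <- function(id, yield, cost) {
    e <- sprintf("kg:ReactionExperiment_%s", id)
    ci <- sprintf("kg:ReactionCondition_%s", id)
    pi <- sprintf("kg:PerformanceIndicator_%s", id)
    kg_add(g, e, "rdf:type", "kg:ReactionExperiment")
    kg_add(g, e, "kg:hasStatus", "Analysed", "string")
    kg_add(g, e, "kg:hasLab", lab_iris[["cambridge"]])
    kg_add(g, e, "kg:hasReactionCondition", ci)
    for (p in c("kg:hasEquivAcetone", "kg:hasEquivNaOH", "kg:hasResidenceTime",
                "kg:hasTemperature"))
      kg_add(g, ci, p, "5", "double")
    kg_add(g, e, "kg:hasPerformanceIndicator", pi)
    kg_add(g, pi, "kg:hasYield", kg_lex_double(yield), "double")
    kg_add(g, pi, "kg:hasRunMaterialCost", kg_lex_double(cost), "double")
    kg_add(g, pi, "kg:hasAbnormalFlag", "false", "boolean")
  }

  # goals unmet (each threshold met separately, never jointly) -> Continue
  add_pt("a", 95, 7); add_pt("b", 60, 5)
  d1 <- evaluate_progress(g, state, gs, lab_iris[["cambridge"]])
  expect_identical(kg_value(g, d1, "kg:hasVerdict"), "Continue")

  # a jointly satisfying Pareto point -> StopGoalsMet
  add_pt("c", 95, 5.5)
  d2 <- evaluate_progress(g, state, gs, lab_iris[["cambridge"]])
  expect_identical(kg_value(g, d2, "kg:hasVerdict"), "StopGoalsMet")

  # exhausted allowance dominates everything
  state$stopped <- FALSE
  state$allowance_left <- 0L
  d3 <- evaluate_progress(g, state, gs, lab_iris[["cambridge"]])
  expect_identical(kg_value(g, d3, "kg:hasVerdict"), "StopResourcesExhausted")
})
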