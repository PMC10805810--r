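# Reaction Optimisation Goal (ROG) and Goal Iteration (ROGI) agents:
# translate a scientist's request into GoalSet triples, spawn per-lab
# goal-iteration derivations, wire each iteration's DMTA chain, and
# decide continuation after every analysed experiment.

#' Instantiate a goal request as GoalSet triples
#'
#' @param g a `kg_graph`
#' @param request goal-request block (objectives, search_space, labs,
#'   cycle_allowance, deadline_ticks)
#' @param lab_iris named character vector mapping lab name -> lab IRI;
#'   every requested lab must be present
#' @return the GoalSet IRI
#' @export
parse_goal_request <- function(g, request, lab_iris) {
  missing <- setdiff(c("objectives", "search_space", "labs",
                       "cycle_allowance", "deadline_ticks"), names(request))
  if (length(missing))
    stop("goal request is missing fields: ", paste(missing, collapse = ", "))
  unknown <- setdiff(request$labs, names(lab_iris))
  if (length(unknown)) stop("unknown lab in goal request: ", paste(unknown, collapse = ", "))
  for (v in cond_vars) {
    b <- request$search_space[[v]]
    if (is.null(b)) stop("goal request is missing fields: search_space$", v)
    if (b[1] >= b[2]) stop("search-space bounds for ", v, " must satisfy lower < upper")
  }
  gs <- kg_mint_iri(g, "GoalSet")
  kg_add(g, gs, "rdf:type", "kg:GoalSet")
  for (ob in request$objectives) {
    goal <- kg_mint_iri(g, "Goal")
    kg_add(g, goal, "rdf:type", "kg:Goal")
    kg_add(g, goal, "kg:hasObjective", ob$objective, "string")
    kg_add(g, goal, "kg:hasDirection", ob$direction, "string")
    kg_add(g, goal, "kg:hasThreshold", kg_lex_double(ob$threshold), "double")
    kg_add(g, gs, "kg:hasGoal", goal)
  }
  restr <- kg_mint_iri(g, "Restriction")
  kg_add(g, restr, "rdf:type", "kg:Restriction")
  kg_add(g, restr, "kg:hasCycleAllowance", as.character(request$cycle_allowance), "integer")
  kg_add(g, restr, "kg:hasDeadlineTicks", as.character(request$deadline_ticks), "integer")
  kg_add(g, gs, "kg:hasRestriction", restr)
  for (nm in request$labs) kg_add(g, gs, "kg:hasParticipatingLab", lab_iris[[nm]])
  for (v in cond_vars) {
    b <- request$search_space[[v]]
    kg_add(g, gs, paste0("kg:hasLowerBound_", v), kg_lex_double(b[1]), "double")
    kg_add(g, gs, paste0("kg:hasUpperBound_", v), kg_lex_double(b[2]), "double")
  }
  gs
}

#' Read a GoalSet's goals back from the graph
#' @param g a `kg_graph`
#' @param goalset GoalSet IRI
#' @return data.frame objective/direction/threshold
#' @export
goalset_goals <- function(g, goalset) {
  goals <- kg_values(g, goalset, "kg:hasGoal")
  do.call(rbind, lapply(goals, function(gl) data.frame(
    objective = kg_value(g, gl, "kg:hasObjective"),
    direction = kg_value(g, gl, "kg:hasDirection"),
    threshold = kg_value(g, gl, "kg:hasThreshold"),
    stringsAsFactors = FALSE
  )))
}

goalset_search_space <- function(g, goalset) {
  ss <- lapply(cond_vars, function(v) c(
    kg_value(g, goalset, paste0("kg:hasLowerBound_", v)),
    kg_value(g, goalset, paste0("kg:hasUpperBound_", v))))
  names(ss) <- cond_vars
  ss
}

#' Spawn one GoalIteration derivation per participating lab
#'
#' @param g a `kg_graph`
#' @param goalset GoalSet IRI
#' @param rogi_agent IRI of the agent registered for `GoalIteration`
#' @param labs lab IRIs to spawn for (defaults to the GoalSet's list)
#' @return character vector of derivation IRIs
#' @export
spawn_goal_iterations <- function(g, goalset, rogi_agent,
                                  labs = kg_values(g, goalset, "kg:hasParticipatingLab")) {
  if (!agent_registered(g, rogi_agent, "GoalIteration"))
    stop("no registered goal-iteration agent: ", rogi_agent)
  vapply(labs, function(lab) {
    create_derivation(g, rogi_agent, inputs = c(goalset, lab),
                      task_type = "GoalIteration",
                      placeholder_outputs = "IterationPlan")$iri
  }, character(1))
}

#' Wire one iteration's DMTA chain: DoE -> Schedule -> Execution -> Analysis
#'
#' Four derivations are created Requested, each downstream one consuming
#' the previous one's placeholder output.
#'
#' @param g a `kg_graph`
#' @param state campaign state environment (provides the agent roster)
#' @param goalset GoalSet IRI
#' @param lab lab IRI
#' @return named list of the four derivation IRIs and the placeholder IRIs
#' @export
rogi_plan_iteration <- function(g, state, goalset, lab) {
  ag <- state$agents
  doe <- create_derivation(g, ag$doe, inputs = c(goalset, lab), task_type = "DoE",
                           placeholder_outputs = "ReactionCondition")
  sched <- create_derivation(g, ag$schedule, inputs = c(goalset, lab, doe$outputs),
                             task_type = "Schedule",
                             placeholder_outputs = "ReactionExperiment")
  exec <- create_derivation(g, ag$executor, inputs = sched$outputs,
                            task_type = "Execution",
                            placeholder_outputs = "HPLCReport")
  ana <- create_derivation(g, ag$postproc, inputs = c(exec$outputs, sched$outputs),
                           task_type = "Analysis",
                           placeholder_outputs = "PerformanceIndicator")
  list(doe = doe$iri, schedule = sched$iri, execution = exec$iri, analysis = ana$iri,
       condition = doe$outputs, experiment = sched$outputs,
       report = exec$outputs, indicator = ana$outputs)
}

#' Evaluate campaign progress for one lab and decide continuation
#'
#' Checks the current Pareto front against every goal threshold jointly
#' and the remaining resources; writes a GoalDecision to the graph.  On
#' Continue (and a serviceable lab), spawns the lab's next GoalIteration
#' derivation so the just-finished experiment becomes historical data for
#' all participating labs.
#'
#' @param g a `kg_graph`
#' @param state campaign state environment
#' @param goalset GoalSet IRI
#' @param lab lab IRI of the iteration that just finished
#' @return GoalDecision IRI
#' @export
evaluate_progress <- function(g, state, goalset, lab) {
  history <- gather_history(g, goalset)
  goals <- goalset_goals(g, goalset)
  front <- if (nrow(history)) pareto_front(history) else history
  goals_met <- FALSE
  if (nrow(front)) {
    meets <- rep(TRUE, nrow(front))
    for (i in seq_len(nrow(goals))) {
      val <- if (goals$objective[i] == "yield") front$yield else front$cost
      meets <- meets & if (goals$direction[i] == "maximise") val >= goals$threshold[i]
                       else val <= goals$threshold[i]
    }
    goals_met <- any(meets)
  }
  resources_out <- state$allowance_left <= 0L || g$clock > state$deadline_ticks
  verdict <- if (resources_out) "StopResourcesExhausted"
             else if (goals_met) "StopGoalsMet"
             else "Continue"
  rationale <- sprintf(
    "allowance_left=%d, clock=%d/%d, pareto_points=%d, goals_met=%s",
    state$allowance_left, g$clock, state$deadline_ticks, nrow(front), goals_met)
  dec <- kg_mint_iri(g, "GoalDecision")
  kg_add(g, dec, "rdf:type", "kg:GoalDecision")
  kg_add(g, dec, "kg:hasVerdict", verdict, "string")
  kg_add(g, dec, "kg:hasRationale", rationale, "string")
  kg_add(g, dec, "kg:decidesFor", lab)
  kg_add(g, dec, "kg:aboutGoalSet", goalset)
  state$decisions[[length(state$decisions) + 1L]] <-
    list(lab = lab, verdict = verdict, rationale = rationale, tick = g$clock)
  if (verdict != "Continue") state$stopped <- TRUE
  if (verdict == "Continue" && !state$stopped) {
    twin <- state$twin_by_iri[[lab]]
    serviceable <- !is.null(twin) && twin$rig_state != "OutOfService" &&
      twin$hplc_state == "Ok"
    if (serviceable) {
      create_derivation(g, state$agents$rogi, inputs = c(goalset, lab),
                        task_type = "GoalIteration",
                        placeholder_outputs = "IterationPlan")
    }
  }
  dec
}
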