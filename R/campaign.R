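# End-to-end campaign orchestration: wire the agents, run the goal-driven
# loop to termination over the derivation engine, and export provenance
# (Turtle), results (CSV) and lineage answers.

new_campaign_state <- function(config, g) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$g <- g
  st$twins <- list()
  st$twin_by_iri <- list()
  st$agents <- list()
  st$allowance_left <- as.integer(config$goal_request$cycle_allowance)
  st$deadline_ticks <- as.integer(config$goal_request$deadline_ticks)
  st$executed <- 0L
  st$stopped <- FALSE
  st$lhs_queue <- NULL
  st$lhs_used <- 0L
  st$results <- list()
  st$hv_trace <- list()
  st$decisions <- list()
  st$chromatograms <- list()
  st$iteration_count <- list()
  st$ref_point <- NULL
  st$gp_warm <- new.env(parent = emptyenv())
  class(st) <- "campaign_state"
  st
}

fault_for_run <- function(config, lab_name, run_index) {
  for (f in config$faults) {
    if (identical(f$lab, lab_name) && f$run_index == run_index) return(f$mode)
  }
  "none"
}

# --- agent handlers (closures over the campaign state) ---------------------

make_rogi_handler <- function(state) {
  function(g, d, inputs, outs) {
    goalset <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:GoalSet"), logical(1))][1]
    lab <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:Laboratory"), logical(1))][1]
    if (is.na(goalset) || is.na(lab)) stop("goal iteration needs a GoalSet and a Laboratory input")
    chain <- rogi_plan_iteration(g, state, goalset, lab)
    prog <- create_derivation(g, state$agents$rog,
                              inputs = c(chain$indicator, goalset, lab),
                              task_type = "ProgressEvaluation",
                              placeholder_outputs = "GoalDecision")
    plan <- outs[1]
    kg_add(g, plan, "kg:plansIterationFor", lab)
    for (dd in c(chain$doe, chain$schedule, chain$execution, chain$analysis, prog$iri))
      kg_add(g, plan, "kg:hasStep", dd)
    plan
  }
}

make_doe_handler <- function(state) {
  function(g, d, inputs, outs) {
    goalset <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:GoalSet"), logical(1))][1]
    lab <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:Laboratory"), logical(1))][1]
    search_space <- goalset_search_space(g, goalset)
    history <- gather_history(g, goalset)
    # record what was perceived: the historical experiments become this
    # derivation's inputs, which is exactly what lineage queries replay
    for (e in history$experiment) kg_add(g, d, "kg:isDerivedFrom", e)
    n_init <- state$config$optimiser$n_init %||% 8L
    if (nrow(history) < n_init) {
      if (is.null(state$lhs_queue)) {
        state$lhs_queue <- lhs_sample(n_init, search_space)
      }
      if (state$lhs_used < nrow(state$lhs_queue)) {
        state$lhs_used <- state$lhs_used + 1L
        cond <- state$lhs_queue[state$lhs_used, , drop = FALSE]
      } else {
        cond <- propose_random(search_space)
      }
      proposer <- "random"
    } else {
      surr <- fit_surrogates(history, search_space, state$config$optimiser,
                             warm = state$gp_warm)
      cond <- propose_tsemo(surr, search_space, state$config$optimiser)
      proposer <- attr(cond, "proposer")
    }
    ci <- outs[1]
    kg_add(g, ci, "kg:hasEquivAcetone", kg_lex_double(cond$equiv_acetone), "double")
    kg_add(g, ci, "kg:hasEquivNaOH", kg_lex_double(cond$equiv_naoh), "double")
    kg_add(g, ci, "kg:hasResidenceTime", kg_lex_double(cond$residence_time), "double")
    kg_add(g, ci, "kg:hasTemperature", kg_lex_double(cond$temperature), "double")
    kg_add(g, ci, "kg:hasUnit_residence_time", "min", "string")
    kg_add(g, ci, "kg:hasUnit_temperature", "degC", "string")
    kg_add(g, ci, "kg:proposedBy", proposer, "string")
    ci
  }
}

condition_from_graph <- function(g, ci) {
  c(equiv_acetone = kg_value(g, ci, "kg:hasEquivAcetone"),
    equiv_naoh = kg_value(g, ci, "kg:hasEquivNaOH"),
    residence_time = kg_value(g, ci, "kg:hasResidenceTime"),
    temperature = kg_value(g, ci, "kg:hasTemperature"))
}

make_schedule_handler <- function(state) {
  function(g, d, inputs, outs) {
    lab <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:Laboratory"), logical(1))][1]
    ci <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:ReactionCondition"), logical(1))][1]
    cond <- condition_from_graph(g, ci)
    exp_iri <- outs[1]
    kg_add(g, exp_iri, "kg:hasReactionCondition", ci)
    kg_add(g, exp_iri, "kg:hasStatus", "Proposed", "string")
    twin <- state$twin_by_iri[[lab]]
    twins <- if (!is.null(twin)) stats::setNames(list(twin), twin$name) else list()
    tw <- select_equipment(g, cond, twins, experiment_iri = exp_iri)
    kg_set(g, exp_iri, "kg:hasStatus", "Assigned", "string")
    exp_iri
  }
}

make_execution_handler <- function(state) {
  function(g, d, inputs, outs) {
    exp_iri <- inputs[1]
    if (state$allowance_left <= 0L) stop("experiment allowance exhausted")
    rig <- kg_values(g, exp_iri, "kg:isAssignedTo")[1]
    lab <- kg_values(g, exp_iri, "kg:hasLab")[1]
    twin <- state$twin_by_iri[[lab]]
    ci <- kg_values(g, exp_iri, "kg:hasReactionCondition")[1]
    cond <- condition_from_graph(g, ci)
    mode <- fault_for_run(state$config, twin$name, twin$run_counter + 1L)
    run <- execute_run(g, twin, cond, state$config$kinetics, state$config$noise,
                       fault_mode = mode)
    state$executed <- state$executed + 1L
    state$allowance_left <- state$allowance_left - 1L
    release_rig(g, twin, g$clock)
    rep_iri <- outs[1]
    kg_add(g, rep_iri, "kg:reportsOn", exp_iri)
    kg_add(g, rep_iri, "kg:hasFaultAnnotation", mode, "string")
    kg_add(g, exp_iri, "kg:hasChromatogram", rep_iri)
    kg_set(g, exp_iri, "kg:hasStatus", "Executed", "string")
    state$chromatograms[[rep_iri]] <- run$chromatogram
    rep_iri
  }
}

make_analysis_handler <- function(state) {
  function(g, d, inputs, outs) {
    rep_iri <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:HPLCReport"), logical(1))][1]
    exp_iri <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:ReactionExperiment"), logical(1))][1]
    lab <- kg_values(g, exp_iri, "kg:hasLab")[1]
    twin <- state$twin_by_iri[[lab]]
    ci <- kg_values(g, exp_iri, "kg:hasReactionCondition")[1]
    cond <- condition_from_graph(g, ci)
    chrom <- state$chromatograms[[rep_iri]]
    pp <- postprocess_run(chrom, cond, twin$fixture, state$config$economics)
    pi_iri <- outs[1]
    if (is.finite(pp$yield))
      kg_add(g, pi_iri, "kg:hasYield", kg_lex_double(pp$yield), "double")
    kg_add(g, pi_iri, "kg:hasRunMaterialCost", kg_lex_double(pp$cost), "double")
    if (is.finite(pp$e_factor %||% NA_real_))
      kg_add(g, pi_iri, "kg:hasEFactor", kg_lex_double(pp$e_factor), "double")
    if (is.finite(pp$sty %||% NA_real_))
      kg_add(g, pi_iri, "kg:hasSpaceTimeYield", kg_lex_double(pp$sty), "double")
    kg_add(g, pi_iri, "kg:hasAbnormalFlag",
           if (pp$abnormal_flag) "true" else "false", "boolean")
    kg_add(g, exp_iri, "kg:hasPerformanceIndicator", pi_iri)
    kg_set(g, exp_iri, "kg:hasStatus", "Analysed", "string")
    fault <- kg_value(g, rep_iri, "kg:hasFaultAnnotation", default = "none")
    if (pp$abnormal_flag && fault == "is_peak_shift") {
      # superphysical yield traced to an internal-standard peak shift:
      # flag the HPLC faulty and take the hardware out of the campaign
      set_equipment_state(g, twin, "hplc", "Faulty", "internal-standard peak shift")
      set_equipment_state(g, twin, "hplc", "OutOfService", "abnormal yield from shifted internal standard")
      set_equipment_state(g, twin, "rig", "OutOfService", "analysis equipment down")
    }
    it <- (state$iteration_count[[lab]] %||% 0L) + 1L
    state$iteration_count[[lab]] <- it
    state$results[[length(state$results) + 1L]] <- data.frame(
      experiment = exp_iri, lab = twin$name, iteration = it,
      equiv_acetone = cond[["equiv_acetone"]], equiv_naoh = cond[["equiv_naoh"]],
      residence_time = cond[["residence_time"]], temperature = cond[["temperature"]],
      yield = pp$yield, cost = pp$cost,
      e_factor = pp$e_factor %||% NA_real_, sty = pp$sty %||% NA_real_,
      abnormal_flag = pp$abnormal_flag,
      proposer = kg_value(g, ci, "kg:proposedBy", default = NA_character_),
      tick = g$clock, stringsAsFactors = FALSE
    )
    hist <- gather_history(g, kg_query(g, p = "rdf:type", o = "kg:GoalSet")$s[1])
    if (nrow(hist) && !is.null(state$ref_point)) {
      hv <- hypervolume(hist, state$ref_point)
      state$hv_trace[[length(state$hv_trace) + 1L]] <-
        data.frame(experiment = exp_iri, n_experiments = state$executed,
                   hypervolume = hv, tick = g$clock, stringsAsFactors = FALSE)
    }
    pi_iri
  }
}

make_rog_handler <- function(state) {
  function(g, d, inputs, outs) {
    goalset <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:GoalSet"), logical(1))][1]
    lab <- inputs[vapply(inputs, function(i) kg_has(g, i, "rdf:type", "kg:Laboratory"), logical(1))][1]
    dec <- evaluate_progress(g, state, goalset, lab)
    # fill the placeholder: copy decision triples onto it for provenance
    out <- outs[1]
    kg_add(g, out, "kg:recordsDecision", dec)
    out
  }
}

# --- campaign entry points --------------------------------------------------

#' Run a complete closed-loop optimisation campaign
#'
#' Executes the control-condition gate, instantiates the goal set, spawns
#' per-lab goal iterations and runs the agent round-robin until every lab
#' stops (goals met, resources exhausted, or hardware out of service).
#' Outputs are bitwise-reproducible for identical config + seed.
#'
#' @param config campaign configuration, see [default_campaign_config()]
#' @return object of class `campaign_result`: `experiments` (data.frame),
#'   `hv_trace`, `decisions`, `events`, `graph` (`kg_graph`), `twins`,
#'   `control` (gate yields)
#' @export
run_campaign <- function(config = default_campaign_config()) {
  validate_config(config)
  set.seed(config$seed)
  g <- kg_new(seed = config$seed)
  state <- new_campaign_state(config, g)
  for (nm in config$goal_request$labs) {
    tw <- make_lab_twin(g, nm, config$labs[[nm]])
    state$twins[[nm]] <- tw
    state$twin_by_iri[[tw$iri]] <- tw
  }
  state$agents <- list(
    rog = register_agent(g, "kg:Agent_rog", "ProgressEvaluation"),
    rogi = register_agent(g, "kg:Agent_rogi", "GoalIteration"),
    doe = register_agent(g, "kg:Agent_doe", "DoE"),
    schedule = register_agent(g, "kg:Agent_schedule", "Schedule"),
    executor = register_agent(g, "kg:Agent_executor", "Execution"),
    postproc = register_agent(g, "kg:Agent_postproc", "Analysis")
  )
  # fixed hypervolume reference point for the whole campaign: below any
  # attainable yield and above the dearest corner of the search space
  ss <- config$goal_request$search_space
  worst <- data.frame(equiv_acetone = ss$equiv_acetone[2],
                      equiv_naoh = ss$equiv_naoh[2],
                      residence_time = ss$residence_time[1],
                      temperature = ss$temperature[1])
  max_cost <- max(vapply(config$goal_request$labs, function(nm)
    compute_cost(worst, config$labs[[nm]], config$economics), numeric(1)))
  state$ref_point <- c(-5, max_cost * 1.1)

  # control-condition onboarding gate
  control_pass <- verify_control_conditions(
    g, state$twins, config$control$conditions, config$control$tolerance, config)
  for (tw in state$twins) tw$run_counter <- 0L  # campaign runs count from 1
  active_labs <- names(control_pass)[control_pass]

  lab_iris <- vapply(state$twins, function(tw) tw$iri, character(1))
  request <- config$goal_request
  request$labs <- active_labs
  goalset <- parse_goal_request(g, request, lab_iris)
  state$goalset <- goalset

  events <- NULL
  if (state$allowance_left > 0L) {
    spawn_goal_iterations(g, goalset, state$agents$rogi)
    handlers <- stats::setNames(
      list(make_rog_handler(state), make_rogi_handler(state),
           make_doe_handler(state), make_schedule_handler(state),
           make_execution_handler(state), make_analysis_handler(state)),
      c(state$agents$rog, state$agents$rogi, state$agents$doe,
        state$agents$schedule, state$agents$executor, state$agents$postproc))
    events <- run_until_quiescent(g, handlers,
                                  max_ticks = 20L * state$allowance_left + 50L)
  } else {
    state$decisions[[1]] <- list(lab = NA_character_,
                                 verdict = "StopResourcesExhausted",
                                 rationale = "allowance 0 at start", tick = g$clock)
  }

  # if the run ended by exhausting the allowance mid-chain (execution
  # refused), make sure the decision history records the stop
  has_stop <- any(vapply(state$decisions, function(d)
    startsWith(d$verdict, "Stop"), logical(1)))
  if (!has_stop && state$allowance_left <= 0L) {
    state$decisions[[length(state$decisions) + 1L]] <-
      list(lab = NA_character_, verdict = "StopResourcesExhausted",
           rationale = "allowance exhausted during in-flight iterations",
           tick = g$clock)
  }

  experiments <- if (length(state$results)) do.call(rbind, state$results) else
    data.frame(experiment = character(0), lab = character(0), iteration = integer(0),
               equiv_acetone = numeric(0), equiv_naoh = numeric(0),
               residence_time = numeric(0), temperature = numeric(0),
               yield = numeric(0), cost = numeric(0), e_factor = numeric(0),
               sty = numeric(0), abnormal_flag = logical(0),
               proposer = character(0), tick = integer(0), stringsAsFactors = FALSE)
  hv_trace <- if (length(state$hv_trace)) do.call(rbind, state$hv_trace) else
    data.frame(experiment = character(0), n_experiments = integer(0),
               hypervolume = numeric(0), tick = integer(0), stringsAsFactors = FALSE)
  decisions <- if (length(state$decisions)) do.call(rbind, lapply(state$decisions, function(d)
    data.frame(lab = d$lab, verdict = d$verdict, rationale = d$rationale,
               tick = d$tick, stringsAsFactors = FALSE))) else
    data.frame(lab = character(0), verdict = character(0),
               rationale = character(0), tick = integer(0), stringsAsFactors = FALSE)
  res <- list(
    experiments = experiments, hv_trace = hv_trace, decisions = decisions,
    events = if (is.null(events)) event_log_df(new_event_log()) else event_log_df(events),
    deadlock = if (is.null(events)) character(0) else events$deadlock,
    graph = g, twins = state$twins, state = state,
    control = attr(control_pass, "yields")
  )
  class(res) <- "campaign_result"
  res
}

#' @export
print.campaign_result <- function(x, ...) {
  ok <- x$experiments[!x$experiments$abnormal_flag & is.finite(x$experiments$yield), ]
  cat(sprintf("<campaign_result> %d experiments (%d abnormal), %d labs\n",
              nrow(x$experiments), sum(x$experiments$abnormal_flag),
              length(x$twins)))
  if (nrow(ok)) {
    fr <- pareto_front(ok)
    cat(sprintf("  best yield %.1f%%, Pareto front of %d points, final hypervolume %.3f\n",
                max(ok$yield), nrow(fr),
                if (nrow(x$hv_trace)) x$hv_trace$hypervolume[nrow(x$hv_trace)] else NA))
  }
  if (nrow(x$decisions))
    cat("  final decision:", x$decisions$verdict[nrow(x$decisions)], "\n")
  invisible(x)
}

#' Which experiments informed the DoE that proposed a given experiment?
#'
#' Replays the provenance graph: finds the DoE derivation whose output is
#' the experiment's reaction condition and returns its historical-data
#' inputs with lab attribution.
#'
#' @param g a `kg_graph` (live or re-loaded from Turtle)
#' @param experiment_iri experiment IRI
#' @return data.frame `experiment`, `lab`; empty (with a `notice`
#'   attribute) when the experiment has no DoE ancestor
#' @export
lineage_query <- function(g, experiment_iri) {
  empty <- data.frame(experiment = character(0), lab = character(0),
                      stringsAsFactors = FALSE)
  if (!kg_exists(g, experiment_iri)) stop("no such experiment: ", experiment_iri)
  ci <- kg_values(g, experiment_iri, "kg:hasReactionCondition")
  if (length(ci) == 0L) {
    attr(empty, "notice") <- "experiment has no recorded condition (control run?)"
    return(empty)
  }
  prod <- kg_values(g, ci[1], "kg:belongsTo")
  prod <- prod[vapply(prod, function(d)
    identical(kg_value(g, d, "kg:hasTaskType"), "DoE"), logical(1))]
  if (length(prod) == 0L) {
    attr(empty, "notice") <- "experiment has no DoE ancestor"
    return(empty)
  }
  ins <- deriv_inputs(g, prod[1])
  exps <- ins[vapply(ins, function(i)
    kg_has(g, i, "rdf:type", "kg:ReactionExperiment"), logical(1))]
  exps <- sort(unname(exps))
  data.frame(
    experiment = exps,
    lab = vapply(exps, function(e) kg_value(g, e, "kg:hasLab", default = NA_character_),
                 character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Export campaign artifacts: results CSV, event-log CSV, provenance Turtle
#'
#' @param result a `campaign_result`
#' @param dir output directory (created if needed)
#' @return named character vector of the three file paths
#' @export
export_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  paths <- c(results = file.path(dir, "results.csv"),
             events = file.path(dir, "events.csv"),
             provenance = file.path(dir, "provenance.ttl"))
  utils::write.csv(result$experiments, paths[["results"]], row.names = FALSE)
  utils::write.csv(result$events, paths[["events"]], row.names = FALSE)
  kg_serialize_turtle(result$graph, paths[["provenance"]])
  paths
}
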