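# Derived-information workflow engine.
#
# A Derivation is a recorded unit of agent work linking input entities to
# output entities with a logical timestamp.  DMTA cycles are expressed as
# DAGs of derivations; agents poll the graph, execute the derivations
# assigned to them whose upstream dependencies are Finished, and write
# outputs back atomically.  All time is the store's logical clock.

DERIV_STATUSES <- c("Requested", "InProgress", "Finished", "Error")

#' Register an agent for a task type
#'
#' @param g a `kg_graph`
#' @param agent_iri agent IRI (minted if `NULL`)
#' @param task_type one of `"GoalIteration"`, `"DoE"`, `"Schedule"`,
#'   `"Execution"`, `"Analysis"`, `"ProgressEvaluation"`
#' @return the agent IRI
#' @export
register_agent <- function(g, agent_iri = NULL, task_type) {
  stopifnot(task_type %in% c("GoalIteration", "DoE", "Schedule",
                             "Execution", "Analysis", "ProgressEvaluation"))
  if (is.null(agent_iri)) agent_iri <- kg_mint_iri(g, "Agent")
  kg_add(g, agent_iri, "rdf:type", "kg:Agent")
  kg_add(g, agent_iri, "kg:acceptsTaskType", task_type, "string")
  agent_iri
}

agent_registered <- function(g, agent_iri, task_type) {
  kg_has(g, agent_iri, "kg:acceptsTaskType", task_type, "string")
}

#' Agents registered for a task type, in registration order
#' @param g a `kg_graph`
#' @param task_type task type string
#' @return character vector of agent IRIs
#' @export
agents_for_task <- function(g, task_type) {
  hits <- kg_query(g, p = "kg:acceptsTaskType", o = task_type)
  hits$s[order(hits$tick)]
}

#' Create a derivation (status Requested)
#'
#' Downstream derivations may depend on this one's future outputs through
#' placeholder IRIs declared here: placeholders are typed entities that
#' exist in the graph from creation time but are only *filled* when the
#' derivation finishes.
#'
#' @param g a `kg_graph`
#' @param agent registered agent IRI
#' @param inputs character vector of input entity IRIs (must exist)
#' @param task_type the task type the agent must be registered for
#' @param placeholder_outputs optional character vector of class names; one
#'   placeholder IRI is minted per entry and declared as this derivation's
#'   planned output
#' @return list with `iri` and `outputs` (placeholder IRIs)
#' @export
create_derivation <- function(g, agent, inputs, task_type,
                              placeholder_outputs = character(0)) {
  if (!agent_registered(g, agent, task_type))
    stop("agent ", agent, " is not registered for task type ", task_type)
  for (iri in inputs) {
    if (!kg_exists(g, iri)) stop("derivation input does not exist in graph: ", iri)
  }
  d <- kg_mint_iri(g, "Derivation")
  kg_add(g, d, "rdf:type", "kg:Derivation")
  kg_add(g, d, "kg:isDerivedUsing", agent)
  kg_add(g, d, "kg:hasTaskType", task_type, "string")
  kg_add(g, d, "kg:hasStatus", "Requested", "string")
  kg_add(g, d, "kg:requestedAtTick", as.character(g$clock), "integer")
  for (iri in inputs) kg_add(g, d, "kg:isDerivedFrom", iri)
  outs <- character(0)
  for (cls in placeholder_outputs) {
    ph <- kg_mint_iri(g, cls)
    kg_add(g, ph, "rdf:type", paste0("kg:", cls))
    kg_add(g, ph, "kg:isPlaceholder", "true", "boolean")
    kg_add(g, d, "kg:hasPlannedOutput", ph)
    outs <- c(outs, ph)
  }
  list(iri = d, outputs = outs)
}

deriv_status <- function(g, d) kg_value(g, d, "kg:hasStatus", default = NA_character_)
deriv_inputs <- function(g, d) kg_values(g, d, "kg:isDerivedFrom")
deriv_outputs <- function(g, d) sort(kg_query(g, p = "kg:belongsTo", o = d)$s)
deriv_agent <- function(g, d) kg_values(g, d, "kg:isDerivedUsing")[1]

#' Producer derivation of an entity (via planned output), or NA
#' @keywords internal
producer_of <- function(g, iri) {
  hits <- kg_query(g, p = "kg:hasPlannedOutput", o = iri)
  if (nrow(hits) == 0L) NA_character_ else hits$s[1]
}

#' Is a derivation outdated with respect to its inputs?
#'
#' A finished derivation is outdated when any input entity was written
#' after the derivation's completion timestamp.
#'
#' @param g a `kg_graph`
#' @param d derivation IRI
#' @return logical
#' @export
is_outdated <- function(g, d) {
  if (!kg_exists(g, d)) stop("no such derivation: ", d)
  ts <- kg_value(g, d, "kg:finishedAtTick", default = NA_integer_)
  if (is.na(ts)) return(FALSE)
  ins <- deriv_inputs(g, d)
  any(vapply(ins, function(i) kg_last_write(g, i) > ts, logical(1)))
}

deriv_executable <- function(g, d) {
  if (!identical(deriv_status(g, d), "Requested")) return(FALSE)
  for (iri in deriv_inputs(g, d)) {
    prod <- producer_of(g, iri)
    if (!is.na(prod)) {
      if (!identical(deriv_status(g, prod), "Finished")) return(FALSE)
    } else if (!kg_exists(g, iri)) {
      return(FALSE)
    } else if (isTRUE(kg_value(g, iri, "kg:isPlaceholder", default = FALSE))) {
      # unplanned placeholder never filled
      return(FALSE)
    }
  }
  TRUE
}

#' Poll the graph as one agent and execute its ready derivations
#'
#' Executes every Requested derivation assigned to `agent` whose inputs all
#' exist and whose upstream producer derivations are Finished, oldest
#' request first.  The handler receives `(g, derivation_iri, inputs,
#' planned_outputs)` and must return the character vector of output entity
#' IRIs (typically the filled placeholders).  A handler error marks the
#' derivation `Error` with the message, without partial output linkage.
#'
#' @param g a `kg_graph`
#' @param agent agent IRI
#' @param handler function, the agent's internal logic
#' @param log optional event-log accumulator environment (internal)
#' @param tick logical poll tick recorded in the event log
#' @return character vector of derivation IRIs executed this poll
#' @export
poll_and_execute <- function(g, agent, handler, log = NULL, tick = NA_integer_) {
  mine <- kg_query(g, p = "kg:isDerivedUsing", o = agent)$s
  if (length(mine) == 0L) return(character(0))
  req <- mine[vapply(mine, function(d) identical(deriv_status(g, d), "Requested"), logical(1))]
  req <- req[order(vapply(req, function(d) kg_value(g, d, "kg:requestedAtTick", default = 0L), integer(1)),
                   req, method = "radix")]
  done <- character(0)
  for (d in req) {
    if (!deriv_executable(g, d)) next
    kg_set(g, d, "kg:hasStatus", "InProgress", "string")
    log_event(log, tick, agent, d, "InProgress")
    res <- tryCatch(
      list(ok = TRUE,
           out = handler(g, d, deriv_inputs(g, d), kg_values(g, d, "kg:hasPlannedOutput"))),
      error = function(e) list(ok = FALSE, msg = conditionMessage(e))
    )
    if (res$ok) {
      outs <- res$out
      for (iri in outs) {
        kg_remove(g, s = iri, p = "kg:isPlaceholder")
        kg_add(g, iri, "kg:belongsTo", d)
      }
      kg_set(g, d, "kg:hasStatus", "Finished", "string")
      kg_set(g, d, "kg:finishedAtTick", as.character(g$clock), "integer")
      log_event(log, tick, agent, d, "Finished")
    } else {
      kg_set(g, d, "kg:hasStatus", "Error", "string")
      kg_set(g, d, "kg:hasErrorMessage", res$msg, "string")
      log_event(log, tick, agent, d, "Error")
    }
    done <- c(done, d)
  }
  done
}

log_event <- function(log, tick, agent, derivation, transition) {
  if (is.null(log)) return(invisible(NULL))
  log$events[[length(log$events) + 1L]] <-
    list(tick = tick, agent = agent, derivation = derivation, transition = transition)
  invisible(NULL)
}

new_event_log <- function() {
  e <- new.env(parent = emptyenv())
  e$events <- list()
  e
}

#' Event log as a data frame
#' @param log event log environment from [run_until_quiescent()]
#' @return data.frame with columns tick, agent, derivation, transition
#' @export
event_log_df <- function(log) {
  if (length(log$events) == 0L)
    return(data.frame(tick = integer(0), agent = character(0),
                      derivation = character(0), transition = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(log$events, function(e)
    data.frame(tick = e$tick, agent = e$agent, derivation = e$derivation,
               transition = e$transition, stringsAsFactors = FALSE)))
}

#' Run all agents round-robin until no derivation is executable
#'
#' Agents are polled in roster order; execution continues until a full
#' round produces no work or `max_ticks` is reached.  If Requested
#' derivations remain, none executable, and no upstream work is pending
#' (all producers Finished or Error), a deadlock is reported.
#'
#' @param g a `kg_graph`
#' @param agents named list mapping agent IRI -> handler function
#' @param max_ticks maximum number of poll rounds
#' @return event log environment; `$events` holds the ordered transitions,
#'   `$deadlock` the blocked derivation IRIs (if any)
#' @export
run_until_quiescent <- function(g, agents, max_ticks = 1000L) {
  stopifnot(max_ticks > 0L)
  log <- new_event_log()
  log$deadlock <- character(0)
  log$blocked <- character(0)
  roster <- names(agents)
  for (tk in seq_len(max_ticks)) {
    worked <- FALSE
    for (a in roster) {
      done <- poll_and_execute(g, a, agents[[a]], log = log, tick = tk)
      if (length(done)) worked <- TRUE
    }
    pending <- kg_query(g, p = "kg:hasStatus", o = "Requested")$s
    pending <- pending[vapply(pending, function(d) kg_has(g, d, "rdf:type", "kg:Derivation"), logical(1))]
    if (length(pending) == 0L) break
    if (!worked) {
      # nothing ran this round: split the stalled derivations into those
      # downstream of an Error (expected under fault injection) and genuine
      # deadlocks (cyclic or unsatisfiable dependencies)
      tainted <- character(0)
      repeat {
        newly <- pending[!pending %in% tainted & vapply(pending, function(d) {
          any(vapply(deriv_inputs(g, d), function(iri) {
            prod <- producer_of(g, iri)
            !is.na(prod) &&
              (identical(deriv_status(g, prod), "Error") || prod %in% tainted)
          }, logical(1)))
        }, logical(1))]
        if (length(newly) == 0L) break
        tainted <- c(tainted, newly)
      }
      log$blocked <- sort(tainted)
      log$deadlock <- sort(setdiff(pending, tainted))
      break
    }
  }
  log
}
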