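# DoE agent internals: history gathering, space-filling random start,
# GP surrogates, TSEMO proposal, Pareto front and 2-D hypervolume.
#
# Orientation throughout: yield is maximised, run material cost minimised.

#' Gather cross-lab history for a goal set
#'
#' Returns every Analysed experiment across all participating labs,
#' excluding abnormal-flagged points; zero-yield points are retained.
#'
#' @param g a `kg_graph`
#' @param goalset goal-set IRI
#' @return data.frame: experiment IRI, lab, the four condition variables,
#'   yield, cost
#' @export
gather_history <- function(g, goalset) {
  empty <- data.frame(experiment = character(0), lab = character(0),
                      equiv_acetone = numeric(0), equiv_naoh = numeric(0),
                      residence_time = numeric(0), temperature = numeric(0),
                      yield = numeric(0), cost = numeric(0),
                      stringsAsFactors = FALSE)
  exps <- intersect(kg_query(g, p = "rdf:type", o = "kg:ReactionExperiment")$s,
                    kg_query(g, p = "kg:hasStatus", o = "Analysed")$s)
  if (length(exps) == 0L) return(empty)
  # one pattern query per predicate, joined by subject (fast path: a
  # per-entity scan would be quadratic in campaign length)
  lookup <- function(p) {
    q <- kg_query(g, p = p)
    stats::setNames(q$o, q$s)
  }
  pi_of <- lookup("kg:hasPerformanceIndicator")
  abnormal <- kg_query(g, p = "kg:hasAbnormalFlag", o = "true")$s
  cond_of <- lookup("kg:hasReactionCondition")
  lab_of <- lookup("kg:hasLab")
  yields <- lookup("kg:hasYield"); costs <- lookup("kg:hasRunMaterialCost")
  ea <- lookup("kg:hasEquivAcetone"); en <- lookup("kg:hasEquivNaOH")
  rt <- lookup("kg:hasResidenceTime"); tp <- lookup("kg:hasTemperature")
  pis <- pi_of[exps]
  keep <- !is.na(pis) & !(pis %in% abnormal) & !is.na(yields[pis])
  exps <- exps[keep]; pis <- pis[keep]
  if (length(exps) == 0L) return(empty)
  conds <- cond_of[exps]
  out <- data.frame(
    experiment = exps, lab = unname(lab_of[exps]),
    equiv_acetone = as.numeric(ea[conds]), equiv_naoh = as.numeric(en[conds]),
    residence_time = as.numeric(rt[conds]), temperature = as.numeric(tp[conds]),
    yield = as.numeric(yields[pis]), cost = as.numeric(costs[pis]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$experiment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ss_bounds <- function(search_space) {
  lo <- vapply(cond_vars, function(v) search_space[[v]][1], numeric(1))
  hi <- vapply(cond_vars, function(v) search_space[[v]][2], numeric(1))
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo))
    stop("degenerate search-space bounds")
  list(lo = lo, hi = hi)
}

to_unit <- function(X, search_space) {
  b <- ss_bounds(search_space)
  sweep(sweep(as.matrix(X[, cond_vars, drop = FALSE]), 2, b$lo), 2, b$hi - b$lo, "/")
}

from_unit <- function(U, search_space) {
  b <- ss_bounds(search_space)
  X <- sweep(sweep(as.matrix(U), 2, b$hi - b$lo, "*"), 2, b$lo, "+")
  colnames(X) <- cond_vars
  as.data.frame(X)
}

#' Latin hypercube sample over a search space
#'
#' Each dimension has exactly one sample per 1/n stratum.
#'
#' @param n number of points
#' @param search_space named list of `(lower, upper)` bounds
#' @return data.frame of n conditions
#' @export
lhs_sample <- function(n, search_space) {
  d <- length(cond_vars)
  U <- matrix(0, n, d)
  for (k in seq_len(d)) {
    U[, k] <- (sample.int(n) - stats::runif(n)) / n
  }
  from_unit(U, search_space)
}

#' Uniform random condition within a search space
#'
#' @param search_space named list of bounds
#' @param n number of draws
#' @return data.frame of conditions strictly inside the bounds
#' @export
propose_random <- function(search_space, n = 1L) {
  from_unit(matrix(stats::runif(n * length(cond_vars)), n), search_space)
}

#' Non-dominated subset of (yield, cost) points
#'
#' Maximise yield, minimise cost.  Duplicated objective vectors keep a
#' single representative (the first).
#'
#' @param points data.frame with columns `yield` and `cost` (extra
#'   columns, e.g. experiment IRIs, are carried through)
#' @return the non-dominated rows of `points`
#' @export
pareto_front <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) return(points)
  stopifnot(all(is.finite(points$yield)), all(is.finite(points$cost)))
  dup <- duplicated(points[, c("yield", "cost")])
  pts <- points[!dup, , drop = FALSE]
  ord <- order(pts$cost, -pts$yield)
  pts <- pts[ord, , drop = FALSE]
  best <- -Inf
  keep <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (pts$yield[i] > best) { keep[i] <- TRUE; best <- pts$yield[i] }
  }
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' 2-D hypervolume of a yield/cost front
#'
#' Maximise yield, minimise cost; the reference point must be dominated
#' by every front point (lower yield, higher cost).  Computed by the
#' standard rectangle sweep.
#'
#' @param front data.frame with `yield`, `cost` (need not be reduced; the
#'   non-dominated subset is used)
#' @param ref numeric `c(yield_ref, cost_ref)`
#' @return non-negative number
#' @export
hypervolume <- function(front, ref) {
  front <- as.data.frame(front)
  if (nrow(front) == 0L) return(0)
  front <- pareto_front(front)
  if (any(front$yield <= ref[1]) || any(front$cost >= ref[2]))
    stop("reference point is not dominated by every front point")
  ord <- order(front$cost)
  y <- front$yield[ord]; cst <- front$cost[ord]
  hv <- 0
  prev_y <- ref[1]
  for (i in seq_along(y)) {
    # after sorting by cost ascending, yields ascend too (non-dominated)
    hv <- hv + (y[i] - prev_y) * (ref[2] - cst[i])
    prev_y <- y[i]
  }
  hv
}

#' Fit the yield/cost GP surrogate pair
#'
#' @param history data.frame from [gather_history()] (non-abnormal only)
#' @param search_space bounds list
#' @param settings optimiser settings block
#' @param warm optional environment carrying `yield` / `cost` log
#'   hyperparameters from the previous fit (warm starts across iterations)
#' @return list of class `surrogate_pair` with elements `yield`, `cost`
#'   (both `kg_gp`), plus the normalised training inputs
#' @export
fit_surrogates <- function(history, search_space,
                           settings = list(gp_restarts = 2L), warm = NULL) {
  U <- to_unit(history, search_space)
  r <- settings$gp_restarts %||% 2L
  gy <- fit_gp(U, history$yield, restarts = r,
               init = if (!is.null(warm)) warm$yield else NULL)
  gc <- fit_gp(U, history$cost, restarts = r,
               init = if (!is.null(warm)) warm$cost else NULL)
  if (!is.null(warm)) {
    warm$yield <- gy$log_theta
    warm$cost <- gc$log_theta
  }
  list(yield = gy, cost = gc, U = U, history = history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' TSEMO proposal: spectral Thompson samples + NSGA-II + hypervolume improvement
#'
#' Draws one approximate posterior sample per objective, runs NSGA-II on
#' the sampled functions (maximise sampled yield, minimise sampled cost),
#' and returns the candidate with the largest hypervolume improvement
#' over the current front evaluated in sampled-objective space.  Falls
#' back to a random in-bounds proposal (with a warning) if the
#' evolutionary search fails.
#'
#' @param surrogates a `surrogate_pair`
#' @param search_space bounds list
#' @param settings optimiser settings (spectral_features, nsga_pop,
#'   nsga_gen, ref_margin)
#' @return one-row data.frame condition, with attribute `proposer`
#' @export
propose_tsemo <- function(surrogates, search_space,
                          settings = list(spectral_features = 500L,
                                          nsga_pop = 100L, nsga_gen = 100L,
                                          ref_margin = 0.1)) {
  m <- settings$spectral_features %||% 500L
  res <- tryCatch({
    f_yield <- gp_spectral_sample(surrogates$yield, m = m)
    f_cost <- gp_spectral_sample(surrogates$cost, m = m)
    fn <- function(U) cbind(-f_yield(U), f_cost(U))
    opt <- nsga2(fn, d = length(cond_vars),
                 pop = settings$nsga_pop %||% 100L,
                 gen = settings$nsga_gen %||% 100L)
    # current front in sampled-objective space (at the training inputs)
    cur <- data.frame(yield = f_yield(surrogates$U), cost = f_cost(surrogates$U))
    cand <- data.frame(yield = -opt$F[, 1], cost = opt$F[, 2])
    allpts <- rbind(cur, cand)
    ref <- c(min(allpts$yield) - settings$ref_margin %||% 0.1 * max(1, diff(range(allpts$yield))),
             max(allpts$cost) + settings$ref_margin %||% 0.1 * max(1, diff(range(allpts$cost))))
    hv0 <- hypervolume(cur, ref)
    hvi <- vapply(seq_len(nrow(cand)), function(i)
      hypervolume(rbind(cur, cand[i, ]), ref) - hv0, numeric(1))
    best <- which.max(hvi)
    from_unit(opt$X[best, , drop = FALSE], search_space)
  }, error = function(e) {
    warning("TSEMO proposal failed (", conditionMessage(e), "); falling back to random")
    r <- propose_random(search_space)
    attr(r, "proposer") <- "random_fallback"
    r
  })
  if (is.null(attr(res, "proposer"))) attr(res, "proposer") <- "tsemo"
  res
}
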