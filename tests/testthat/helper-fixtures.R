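# Shared fixtures and independent oracles for the test suite.

# Fast campaign config: noise-free unless asked, lighter optimiser
# settings (the defaults are config-exposed; tests scale the evolutionary
# search down to desk runtime).
fast_config <- function(seed = 1L, allowance = 10L, noise = FALSE) {
  cfg <- default_campaign_config(seed)
  cfg$goal_request$cycle_allowance <- as.integer(allowance)
  if (!noise) cfg$noise <- list(area_sd = 0, rt_jitter_sd = 0, detection_limit = 1e-4)
  cfg$optimiser$nsga_pop <- 40L
  cfg$optimiser$nsga_gen <- 20L
  cfg$optimiser$spectral_features <- 150L
  cfg
}

# Brute-force O(n^2) Pareto dominance oracle (maximise yield, minimise cost)
pareto_oracle <- function(pts) {
  n <- nrow(pts)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (pts$yield[j] >= pts$yield[i] && pts$cost[j] <= pts$cost[i] &&
          (pts$yield[j] > pts$yield[i] || pts$cost[j] < pts$cost[i])) {
        dominated <- TRUE; break
      }
    }
    keep[i] <- !dominated
  }
  unique(pts[keep, c("yield", "cost")])
}

# Monte-Carlo hypervolume oracle: uniform samples in the ref-to-ideal box,
# dominated fraction x box area.  Returns estimate and its standard error.
hv_mc_oracle <- function(front, ref, n = 1e6L) {
  ymax <- max(front$yield); cmin <- min(front$cost)
  box <- (ymax - ref[1]) * (ref[2] - cmin)
  ys <- runif(n, ref[1], ymax)
  cs <- runif(n, cmin, ref[2])
  ord <- order(front$cost)
  fc <- front$cost[ord]
  fy <- cummax(front$yield[ord])   # best yield achievable at cost <= c
  idx <- findInterval(cs, fc)      # number of front points with cost <= c
  dominated <- idx > 0 & ys <= c(-Inf, fy)[idx + 1L]
  p <- mean(dominated)
  list(hv = box * p, se = box * sqrt(p * (1 - p) / n))
}

# Validate that an ordering of derivation executions respects DAG edges:
# edges is a 2-column matrix (from, to) of derivation IRIs.
is_topological <- function(order_vec, edges) {
  pos <- match(edges, order_vec)
  dim(pos) <- dim(edges)
  all(stats::complete.cases(pos)) && all(pos[, 1] < pos[, 2])
}

# Memoised campaign shared by several acceptance checks
.acc_cache <- new.env(parent = emptyenv())
acceptance_campaign <- function() {
  if (is.null(.acc_cache$res)) {
    .acc_cache$cfg <- fast_config(seed = 11L, allowance = 14L)
    .acc_cache$res <- run_campaign(.acc_cache$cfg)
  }
  .acc_cache$res
}
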