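ss <- default_campaign_config(1)$goal_request$search_space

test_that("history gathering excludes abnormal points and keeps zero yields", {
  g <- kg_new(1)
  add_exp <- function(id, yield, abnormal) {
    e <- sprintf("kg:ReactionExperiment_%s", id)
    ci <- sprintf("kg:ReactionCondition_%s", id)
    pi <- sprintf("kg:PerformanceIndicator_%s", id)
    kg_add(g, e, "rdf:type", "kg:ReactionExperiment")
    kg_add(g, e, "kg:hasStatus", "Analysed", "string")
    kg_add(g, e, "kg:hasLab", "kg:Lab_cambridge")
    kg_add(g, e, "kg:hasReactionCondition", ci)
    kg_add(g, ci, "kg:hasEquivAcetone", "10", "double")
    kg_add(g, ci, "kg:hasEquivNaOH", "0.2", "double")
    kg_add(g, ci, "kg:hasResidenceTime", "5", "double")
    kg_add(g, ci, "kg:hasTemperature", "50", "double")
    kg_add(g, e, "kg:hasPerformanceIndicator", pi)
    if (is.finite(yield)) kg_add(g, pi, "kg:hasYield", kg_lex_double(yield), "double")
    kg_add(g, pi, "kg:hasRunMaterialCost", "4.0", "double")
    kg_add(g, pi, "kg:hasAbnormalFlag", if (abnormal) "true" else "false", "boolean")
    e
  }
  expect_equal(nrow(gather_history(g, "kg:gs")), 0L)
  for (i in 1:9) add_exp(sprintf("n%02d", i), yield = 50 + i, abnormal = FALSE)
  bad <- add_exp("abn", yield = 3500, abnormal = TRUE)
  zero <- add_exp("z00", yield = 0, abnormal = FALSE)
  h <- gather_history(g, "kg:gs")
  expect_equal(nrow(h), 10L)
  expect_false(bad %in% h$experiment)
  expect_true(zero %in% h$experiment)
})

test_that("random proposals are reproducible, in-bounds and uniform", {
  set.seed(123); a <- propose_random(ss)
  set.seed(123); b <- propose_random(ss)
  expect_identical(a, b)

  set.seed(9)
  X <- propose_random(ss, n = 10000L)
  for (v in cond_vars) {
    expect_gte(min(X[[v]]), ss[[v]][1])
    expect_lte(max(X[[v]]), ss[[v]][2])
    u <- (X[[v]] - ss[[v]][1]) / diff(ss[[v]])
    expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
  }
  degenerate <- ss; degenerate$temperature <- c(50, 50)
  expect_error(propose_random(degenerate), "degenerate")
})

test_that("Latin hypercube puts exactly one sample in each stratum", {
  set.seed(4)
  n <- 16L
  X <- lhs_sample(n, ss)
  for (v in cond_vars) {
    u <- (X[[v]] - ss[[v]][1]) / diff(ss[[v]])
    expect_identical(sort(findInterval(u, seq(0, 1, length.out = n + 1),
                                       rightmost.closed = TRUE)),
                     1:n)
  }
})

test_that("pareto_front matches hand cases and the brute-force oracle", {
  pts <- data.frame(yield = c(90, 80, 70), cost = c(5, 3, 4))
  fr <- pareto_front(pts)
  expect_setequal(paste(fr$yield, fr$cost), c("90 5", "80 3"))

  same <- data.frame(yield = rep(50, 4), cost = rep(2, 4))
  expect_equal(nrow(pareto_front(same)), 1L)

  set.seed(11)
  pts <- data.frame(yield = round(runif(500, 0, 100), 1),
                    cost = round(runif(500, 1, 10), 2))
  fr <- pareto_front(pts)
  oracle <- pareto_oracle(pts)
  expect_setequal(paste(fr$yield, fr$cost), paste(oracle$yield, oracle$cost))
})

test_that("hypervolume: rectangles, empty front, bad reference, MC oracle", {
  expect_equal(hypervolume(data.frame(yield = 1, cost = 1), c(0, 2)), 1)
  expect_equal(hypervolume(data.frame(yield = numeric(0), cost = numeric(0)),
                           c(0, 2)), 0)
  expect_error(hypervolume(data.frame(yield = 1, cost = 3), c(0, 2)),
               "not dominated")

  set.seed(21)
  for (rep in 1:5) {
    front <- pareto_front(data.frame(yield = runif(15, 10, 90),
                                     cost = runif(15, 2, 9)))
    ref <- c(0, 10)
    hv <- hypervolume(front, ref)
    mc <- hv_mc_oracle(front, ref, n = 2e5L)
    expect_lt(abs(hv - mc$hv), 3 * mc$se + 1e-9)
    # adding a non-dominated point strictly increases the value
    extra <- rbind(front[, c("yield", "cost")],
                   data.frame(yield = max(front$yield) + 1, cost = min(front$cost)))
    expect_gt(hypervolume(extra, ref), hv)
  }
})

test_that("GP surrogates recover a known function at its training points", {
  set.seed(2)
  X <- matrix(runif(60), ncol = 4)
  y <- rowSums(X^2)
  gp <- fit_gp(X, y, restarts = 2)
  expect_lt(max(abs(gp_predict(gp, X) - y)), 1e-3)

  # duplicated inputs with conflicting responses: no numerical failure
  Xd <- rbind(X, X[1, , drop = FALSE])
  yd <- c(y, y[1] + 0.5)
  expect_no_error(gp2 <- fit_gp(Xd, yd, restarts = 1))
  expect_gt(gp2$sn2, 0)

  expect_warning(gp3 <- fit_gp(X, rep(5, nrow(X))), "degenerate")
  expect_equal(gp_predict(gp3, X[1:3, ]), rep(5, 3))
})

test_that("surrogate training sets exclude abnormal points by construction", {
  # fit_surrogates consumes gather_history output, which never contains
  # abnormal rows; verify the wiring end to end on a constructed graph
  g <- kg_new(2)
  for (i in 1:9) {
    e <- sprintf("kg:ReactionExperiment_h%d", i)
    ci <- sprintf("kg:ReactionCondition_h%d", i)
    pi <- sprintf("kg:PerformanceIndicator_h%d", i)
    kg_add(g, e, "rdf:type", "kg:ReactionExperiment")
    kg_add(g, e, "kg:hasStatus", "Analysed", "string")
    kg_add(g, e, "kg:hasLab", "kg:Lab_x")
    kg_add(g, e, "kg:hasReactionCondition", ci)
    kg_add(g, ci, "kg:hasEquivAcetone", kg_lex_double(5 + 4 * i), "double")
    kg_add(g, ci, "kg:hasEquivNaOH", kg_lex_double(0.05 + 0.04 * i), "double")
    kg_add(g, ci, "kg:hasResidenceTime", kg_lex_double(2 + 0.8 * i), "double")
    kg_add(g, ci, "kg:hasTemperature", kg_lex_double(30 + 4 * i), "double")
    kg_add(g, e, "kg:hasPerformanceIndicator", pi)
    kg_add(g, pi, "kg:hasYield", kg_lex_double(if (i == 5) 4000 else 10 * i), "double")
    kg_add(g, pi, "kg:hasRunMaterialCost", kg_lex_double(3 + 0.2 * i), "double")
    kg_add(g, pi, "kg:hasAbnormalFlag", if (i == 5) "true" else "false", "boolean")
  }
  h <- gather_history(g, "kg:gs")
  surr <- fit_surrogates(h, ss, list(gp_restarts = 1L))
  expect_equal(nrow(surr$U), 8L)
  expect_false(any(surr$history$yield > 100))
})

test_that("TSEMO proposals are deterministic, in-bounds and robust", {
  set.seed(6)
  h <- data.frame(
    equiv_acetone = runif(10, 5, 50), equiv_naoh = runif(10, 0.05, 0.5),
    residence_time = runif(10, 2, 10), temperature = runif(10, 30, 70))
  h$yield <- 2 * h$temperature - abs(h$equiv_acetone - 25)
  h$cost <- 3 + 0.1 * h$equiv_acetone
  surr <- fit_surrogates(h, ss, list(gp_restarts = 1L))
  settings <- list(spectral_features = 100L, nsga_pop = 24L, nsga_gen = 10L,
                   ref_margin = 0.1)
  set.seed(31); p1 <- propose_tsemo(surr, ss, settings)
  set.seed(31); p2 <- propose_tsemo(surr, ss, settings)
  expect_equal(p1, p2)
  for (v in cond_vars) {
    expect_gte(p1[[v]], ss[[v]][1]); expect_lte(p1[[v]], ss[[v]][2])
  }
  expect_identical(attr(p1, "proposer"), "tsemo")
})

test_that("TSEMO closes in on a known bi-objective Pareto front", {
  # convex bi-objective quadratics on [0,1]^2:
  #   f1 = -sum((x - a)^2) (maximised as "yield"),
  #   f2 =  sum((x - b)^2) (minimised as "cost");
  # the true Pareto set is the segment between a and b, and the true
  # front/hypervolume come from a dense grid oracle
  a <- c(0.2, 0.3); b <- c(0.8, 0.7)
  f1 <- function(X) -((X[, 1] - a[1])^2 + (X[, 2] - a[2])^2)
  f2 <- function(X) (X[, 1] - b[1])^2 + (X[, 2] - b[2])^2
  grid <- as.matrix(expand.grid(seq(0, 1, length.out = 120),
                                seq(0, 1, length.out = 120)))
  truth <- pareto_front(data.frame(yield = f1(grid), cost = f2(grid)))
  ref <- c(min(f1(grid)) - 0.1, max(f2(grid)) + 0.1)
  hv_true <- hypervolume(truth, ref)

  set.seed(77)
  X <- cbind(runif(6), runif(6))
  # third/fourth condition variables pinned to a sliver so the sampled
  # posterior cannot vary along directions the toy functions ignore
  sp <- list(equiv_acetone = c(0, 1), equiv_naoh = c(0, 1),
             residence_time = 0.5 + c(-1e-6, 1e-6),
             temperature = 0.5 + c(-1e-6, 1e-6))
  for (it in 1:30) {
    h <- data.frame(equiv_acetone = X[, 1], equiv_naoh = X[, 2],
                    residence_time = 0.5, temperature = 0.5,
                    yield = f1(X), cost = f2(X))
    surr <- fit_surrogates(h, sp, list(gp_restarts = 1L))
    prop <- propose_tsemo(surr, sp, list(spectral_features = 100L,
                                         nsga_pop = 30L, nsga_gen = 15L,
                                         ref_margin = 0.1))
    X <- rbind(X, c(prop$equiv_acetone, prop$equiv_naoh))
  }
  hv_got <- hypervolume(data.frame(yield = f1(X), cost = f2(X)), ref)
  expect_gte(hv_got / hv_true, 0.95)
})
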