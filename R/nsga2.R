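# Compact real-coded NSGA-II used inside TSEMO to optimise the sampled
# posterior functions.  Minimises M objectives over the unit hypercube.
# SBX crossover, polynomial mutation, fast non-dominated sorting,
# crowding-distance selection.

# rank vector by non-dominated fronts (minimisation); O(n^2), fine at
# population scale
nds_rank <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dominated_count <- integer(n)
  dominates <- vector("list", n)
  tF <- t(F)
  for (i in seq_len(n)) {
    le <- colSums(tF >= F[i, ]) == ncol(F)   # i weakly better everywhere
    lt <- colSums(tF > F[i, ]) > 0           # i strictly better somewhere
    dominates[[i]] <- which(le & lt & seq_len(n) != i)
  }
  for (i in seq_len(n)) for (j in dominates[[i]]) dominated_count[j] <- dominated_count[j] + 1L
  front <- which(dominated_count == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominates[[i]]) {
        dominated_count[j] <- dominated_count[j] - 1L
        if (dominated_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

crowding <- function(F) {
  n <- nrow(F); M <- ncol(F)
  cd <- numeric(n)
  for (m in seq_len(M)) {
    ord <- order(F[, m])
    cd[ord[c(1, n)]] <- Inf
    rng <- F[ord[n], m] - F[ord[1], m]
    if (rng > 0 && n > 2) {
      cd[ord[2:(n - 1)]] <- cd[ord[2:(n - 1)]] +
        (F[ord[3:n], m] - F[ord[1:(n - 2)], m]) / rng
    }
  }
  cd
}

sbx_crossover <- function(p1, p2, eta = 15) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)), (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

poly_mutate <- function(x, pm, eta = 20) {
  do_it <- stats::runif(length(x)) < pm
  u <- stats::runif(length(x))
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1, 1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[do_it] <- x[do_it] + delta[do_it]
  pmin(pmax(x, 0), 1)
}

#' NSGA-II minimiser over the unit hypercube
#'
#' @param fn vectorised objective: matrix (n x d) -> matrix (n x M)
#' @param d number of decision variables
#' @param pop population size (even)
#' @param gen number of generations
#' @return list `X` (decision matrix) and `F` (objective matrix) of the
#'   final population's first non-dominated front
#' @export
nsga2 <- function(fn, d, pop = 100L, gen = 100L) {
  pop <- as.integer(pop); if (pop %% 2L == 1L) pop <- pop + 1L
  X <- matrix(stats::runif(pop * d), pop, d)
  F <- fn(X)
  for (g in seq_len(gen)) {
    rank <- nds_rank(F)
    cd <- numeric(pop)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      cd[idx] <- if (length(idx) > 1) crowding(F[idx, , drop = FALSE]) else Inf
    }
    # binary tournaments
    pick <- function() {
      i <- sample.int(pop, 2L)
      if (rank[i[1]] < rank[i[2]]) i[1]
      else if (rank[i[2]] < rank[i[1]]) i[2]
      else if (cd[i[1]] >= cd[i[2]]) i[1] else i[2]
    }
    Xc <- matrix(0, pop, d)
    for (k in seq(1, pop, by = 2)) {
      ch <- sbx_crossover(X[pick(), ], X[pick(), ])
      Xc[k, ] <- poly_mutate(ch[[1]], pm = 1 / d)
      Xc[k + 1, ] <- poly_mutate(ch[[2]], pm = 1 / d)
    }
    Fc <- fn(Xc)
    Xall <- rbind(X, Xc); Fall <- rbind(F, Fc)
    rank <- nds_rank(Fall)
    ord <- order(rank)
    chosen <- integer(0)
    for (r in seq_len(max(rank))) {
      idx <- which(rank == r)
      if (length(chosen) + length(idx) <= pop) {
        chosen <- c(chosen, idx)
      } else {
        need <- pop - length(chosen)
        cdr <- if (length(idx) > 1) crowding(Fall[idx, , drop = FALSE]) else Inf
        chosen <- c(chosen, idx[order(cdr, decreasing = TRUE)][seq_len(need)])
      }
      if (length(chosen) >= pop) break
    }
    X <- Xall[chosen, , drop = FALSE]
    F <- Fall[chosen, , drop = FALSE]
  }
  rank <- nds_rank(F)
  keep <- rank == 1L
  list(X = X[keep, , drop = FALSE], F = F[keep, , drop = FALSE])
}
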