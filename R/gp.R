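# Gaussian-process surrogate with squared-exponential ARD kernel,
# marginal-likelihood hyperparameter fitting and spectral (random Fourier
# feature) posterior sampling for Thompson sampling.

se_ard <- function(X1, X2, ls, sf2) {
  d <- ncol(X1)
  D2 <- matrix(0, nrow(X1), nrow(X2))
  for (k in seq_len(d)) {
    D2 <- D2 + outer(X1[, k] / ls[k], X2[, k] / ls[k], "-")^2
  }
  sf2 * exp(-0.5 * D2)
}

gp_nll <- function(theta, X, y) {
  d <- ncol(X)
  ls <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1]); sn2 <- exp(theta[d + 2])
  n <- length(y)
  K <- se_ard(X, X, ls, sf2) + diag(sn2 + 1e-8, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

#' Fit a GP with SE-ARD kernel by marginal-likelihood maximisation
#'
#' Inputs are expected in the unit cube; the response is standardised
#' internally.  Multi-restart L-BFGS-B on log hyperparameters.  A
#' constant (degenerate) response falls back to a prior-only GP with a
#' warning.
#'
#' @param X matrix of inputs in `[0,1]^d`
#' @param y numeric response
#' @param restarts extra random restarts beyond the default start
#' @param init optional warm-start log-hyperparameter vector
#'   `c(log ls_1..d, log sf2, log sn2)` from a previous fit
#' @return list of class `kg_gp`
#' @export
fit_gp <- function(X, y, restarts = 2L, init = NULL) {
  X <- as.matrix(X); d <- ncol(X); n <- nrow(X)
  mu_y <- mean(y); sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y < 1e-12) {
    warning("degenerate (constant) objective; using prior-only GP")
    gp <- list(X = X, ys = rep(0, n), mu_y = mu_y, sd_y = 1,
               ls = rep(0.5, d), sf2 = 1, sn2 = 1e-6, degenerate = TRUE)
    class(gp) <- "kg_gp"
    return(gp)
  }
  ys <- (y - mu_y) / sd_y
  starts <- list(c(rep(log(0.3), d), log(1), log(1e-4)))
  if (!is.null(init) && length(init) == d + 2L) starts <- c(list(init), starts)
  for (r in seq_len(restarts)) {
    starts[[length(starts) + 1L]] <- c(stats::runif(d, log(0.1), log(1)),
                                       stats::runif(1, log(0.5), log(2)),
                                       stats::runif(1, log(1e-6), log(1e-2)))
  }
  lower <- c(rep(log(0.02), d), log(1e-3), log(1e-8))
  upper <- c(rep(log(10), d), log(1e3), log(1))
  best <- NULL; best_val <- Inf
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, gp_nll, X = X, y = ys, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best_val) { best <- fit$par; best_val <- fit$value }
  }
  if (is.null(best)) best <- starts[[1]]
  ls <- exp(best[seq_len(d)]); sf2 <- exp(best[d + 1]); sn2 <- exp(best[d + 2])
  K <- se_ard(X, X, ls, sf2) + diag(sn2 + 1e-8, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  gp <- list(X = X, ys = ys, mu_y = mu_y, sd_y = sd_y, ls = ls, sf2 = sf2,
             sn2 = sn2, L = L, alpha = alpha, degenerate = FALSE,
             log_theta = best)
  class(gp) <- "kg_gp"
  gp
}

#' GP posterior mean (and sd) at new inputs
#' @param gp a `kg_gp`
#' @param Xnew matrix of inputs in the unit cube
#' @param sd also return posterior sd?
#' @return numeric vector of means, or list(mean, sd)
#' @export
gp_predict <- function(gp, Xnew, sd = FALSE) {
  Xnew <- as.matrix(Xnew)
  if (isTRUE(gp$degenerate)) {
    m <- rep(gp$mu_y, nrow(Xnew))
    if (!sd) return(m)
    return(list(mean = m, sd = rep(sqrt(gp$sf2) * gp$sd_y, nrow(Xnew))))
  }
  Ks <- se_ard(Xnew, gp$X, gp$ls, gp$sf2)
  m <- gp$mu_y + gp$sd_y * as.numeric(Ks %*% gp$alpha)
  if (!sd) return(m)
  v <- forwardsolve(t(gp$L), t(Ks))
  s2 <- pmax(gp$sf2 - colSums(v^2), 1e-12)
  list(mean = m, sd = sqrt(s2) * gp$sd_y)
}

#' Draw one approximate posterior sample path via random Fourier features
#'
#' Spectral approximation of the SE-ARD kernel: `m` random features,
#' Bayesian linear-model posterior over feature weights, one weight draw.
#' Returns a deterministic function of the input (closure over the drawn
#' weights), on the original response scale.
#'
#' @param gp a `kg_gp`
#' @param m number of spectral features
#' @return function: matrix in unit cube -> numeric vector
#' @export
gp_spectral_sample <- function(gp, m = 500L) {
  d <- ncol(gp$X)
  Omega <- matrix(stats::rnorm(m * d), m, d) / rep(gp$ls, each = m)
  b <- stats::runif(m, 0, 2 * pi)
  scale <- sqrt(2 * gp$sf2 / m)
  phi <- function(X) scale * cos(as.matrix(X) %*% t(Omega) + rep(b, each = nrow(X)))
  if (isTRUE(gp$degenerate)) {
    w <- stats::rnorm(m)
    return(function(X) gp$mu_y + gp$sd_y * as.numeric(phi(X) %*% w))
  }
  P <- phi(gp$X)
  sn2 <- max(gp$sn2, 1e-8)
  A <- crossprod(P) + diag(sn2, m)
  LA <- chol(A)
  w_mean <- backsolve(LA, forwardsolve(t(LA), crossprod(P, gp$ys)))
  z <- stats::rnorm(m)
  w <- w_mean + sqrt(sn2) * backsolve(LA, z)
  function(X) gp$mu_y + gp$sd_y * as.numeric(phi(X) %*% w)
}
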