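# Covariance matrix adaptation evolution strategy (mu/mu_w, lambda),
# standard Hansen formulation, searching in coordinates normalised to the
# unit box. Box constraints are handled by evaluating the clipped
# candidate plus a quadratic out-of-bounds penalty.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' CMA-ES minimisation under box constraints
#'
#' Evolution-strategy minimiser with covariance matrix adaptation;
#' population size `4 + floor(3 log n)` by default, initial step 25% of
#' each bound range, candidates clipped into the box with a quadratic
#' penalty on the violation. Deterministic for a fixed seed; the caller's
#' RNG state is preserved.
#'
#' @param fn objective taking a parameter vector (inside bounds).
#' @param lower,upper numeric bound vectors.
#' @param seed integer RNG seed.
#' @param budget_iterations number of generations.
#' @param sigma0 initial step size in normalised coordinates.
#' @param lambda population size (default `4 + floor(3 log n)`).
#' @param x0 optional initial mean (inside bounds; default mid-box).
#' @return List with `best_parameters`, `best_loss`, `loss_history`
#'   (best-of-generation), `running_minimum`, `initial_population_losses`,
#'   `n_evaluations`, `seed`.
#' @export
cma_es_minimise <- function(fn, lower, upper, seed = 1L,
                            budget_iterations = 200, sigma0 = 0.25,
                            lambda = NULL, x0 = NULL) {
  n <- length(lower)
  stopifnot(length(upper) == n, all(lower < upper), budget_iterations >= 1)
  span <- upper - lower
  to_x <- function(z) lower + pmin(pmax(z, 0), 1) * span
  penalty <- function(z) 1e3 * sum((z - pmin(pmax(z, 0), 1))^2)
  eval_z <- function(z) fn(to_x(z)) + penalty(z)

  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- if (is.null(x0)) rep(0.5, n) else (x0 - lower) / span
  sigma <- sigma0
  C <- diag(n)
  ps <- pc <- rep(0, n)
  best_loss <- Inf
  best_z <- m
  loss_history <- numeric(budget_iterations)
  init_losses <- NULL
  n_eval <- 0L

  local_seed(seed, {
    for (it in seq_len(budget_iterations)) {
      eig <- eigen(C, symmetric = TRUE)
      D_sqrt <- sqrt(pmax(eig$values, 1e-20))
      B <- eig$vectors
      Z <- matrix(stats::rnorm(n * lambda), n, lambda)
      Y <- B %*% (D_sqrt * Z)
      X <- m + sigma * Y
      losses <- apply(X, 2, eval_z)
      n_eval <- n_eval + lambda
      if (it == 1) init_losses <- losses
      ord <- order(losses)
      if (losses[ord[1]] < best_loss) {
        best_loss <- losses[ord[1]]
        best_z <- X[, ord[1]]
      }
      loss_history[it] <- losses[ord[1]]
      y_w <- Y[, ord[seq_len(mu)], drop = FALSE] %*% w
      m <- m + sigma * as.numeric(y_w)
      # step-size path (uses C^{-1/2} y_w)
      c_inv_half <- B %*% ((1 / D_sqrt) * t(B))
      ps <- (1 - cs) * ps +
        sqrt(cs * (2 - cs) * mu_eff) * as.numeric(c_inv_half %*% y_w)
      hsig <- sqrt(sum(ps^2)) /
        sqrt(1 - (1 - cs)^(2 * it)) / chi_n < 1.4 + 2 / (n + 1)
      pc <- (1 - cc) * pc +
        hsig * sqrt(cc * (2 - cc) * mu_eff) * as.numeric(y_w)
      rank_mu <- matrix(0, n, n)
      for (k in seq_len(mu)) {
        yk <- Y[, ord[k]]
        rank_mu <- rank_mu + w[k] * tcrossprod(yk)
      }
      C <- (1 - c1 - cmu) * C +
        c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
        cmu * rank_mu
      C <- (C + t(C)) / 2
      sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chi_n - 1))
      sigma <- min(sigma, 1)
    }
  })
  list(best_parameters = to_x(best_z),
       best_loss = best_loss,
       loss_history = loss_history,
       running_minimum = cummin(loss_history),
       initial_population_losses = init_losses,
       n_evaluations = n_eval,
       seed = seed)
}
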