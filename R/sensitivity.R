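#' Saltelli cross-sampling design
#'
#' Generates the Saltelli sample matrix for variance-based sensitivity
#' analysis: base matrices A and B of N rows drawn as a 2D-dimensional
#' Sobol' quasi-random sequence (with a seeded digital shift), plus the
#' cross matrices AB_i (A with column i taken from B) and, when second
#' order is requested, BA_i. Total rows: `N (2D + 2)` with second order,
#' `N (D + 2)` without. Deterministic for a fixed seed.
#'
#' @param n base sample size N (a power of 2 recommended).
#' @param d number of parameters D.
#' @param second_order include the BA_i blocks?
#' @param bounds two-column matrix (low, high) per parameter, default
#'   \[0, 1\].
#' @param seed integer seed.
#' @return Matrix of parameter rows with attribute `layout` (row-block
#'   labels "A", "B", "AB_i", "BA_i") and the design settings.
#' @export
saltelli_sample <- function(n, d, second_order = TRUE, bounds = NULL,
                            seed = 1L) {
  stopifnot(n >= 2, d >= 1)
  if (is.null(bounds))
    bounds <- cbind(low = rep(0, d), high = rep(1, d))
  base <- sobol_points(n, 2 * d, seed = seed)
  A <- base[, seq_len(d), drop = FALSE]
  B <- base[, d + seq_len(d), drop = FALSE]
  {
    blocks <- list(A = A, B = B)
    for (i in seq_len(d)) {
      AB <- A; AB[, i] <- B[, i]
      blocks[[paste0("AB_", i)]] <- AB
    }
    if (second_order) {
      for (i in seq_len(d)) {
        BA <- B; BA[, i] <- A[, i]
        blocks[[paste0("BA_", i)]] <- BA
      }
    }
    out <- do.call(rbind, blocks)
    out <- sweep(out, 2, bounds[, 2] - bounds[, 1], `*`)
    out <- sweep(out, 2, bounds[, 1], `+`)
    attr(out, "layout") <- rep(names(blocks), each = n)
    attr(out, "n") <- n
    attr(out, "d") <- d
    attr(out, "second_order") <- second_order
    out
  }
}

#' Sobol sensitivity indices from a Saltelli design
#'
#' Saltelli/Jansen estimators: first-order
#' `S1_i = mean(fB (fAB_i - fA)) / V`, total-order
#' `ST_i = mean((fA - fAB_i)^2) / (2 V)`, and, when the design carries
#' the BA blocks, closed second-order indices. A constant output (zero
#' variance) yields all-zero indices. Confidence half-widths are
#' bootstrap percentiles over the base samples.
#'
#' @param samples matrix from [saltelli_sample()].
#' @param outputs numeric model outputs, one per sample row; must be
#'   finite.
#' @param n_boot bootstrap resamples for confidence half-widths (0 to
#'   skip).
#' @param conf confidence level.
#' @return List with `S1`, `ST`, (optionally `S2` matrix), `S1_conf`,
#'   `ST_conf`.
#' @export
sobol_indices <- function(samples, outputs, n_boot = 100, conf = 0.95) {
  layout <- attr(samples, "layout")
  n <- attr(samples, "n"); d <- attr(samples, "d")
  second <- attr(samples, "second_order")
  if (length(outputs) != nrow(samples))
    stop("outputs length must equal the number of sample rows")
  if (any(!is.finite(outputs))) {
    bad <- which(!is.finite(outputs))
    stop("non-finite outputs at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  fA <- outputs[layout == "A"]
  fB <- outputs[layout == "B"]
  fAB <- sapply(seq_len(d), function(i) outputs[layout == paste0("AB_", i)])
  fBA <- if (second)
    sapply(seq_len(d), function(i) outputs[layout == paste0("BA_", i)])
  else NULL

  est <- function(idx) {
    a <- fA[idx]; b <- fB[idx]
    V <- stats::var(c(a, b))
    if (!is.finite(V) || V <= 0)
      return(list(S1 = rep(0, d), ST = rep(0, d),
                  S2 = if (second) matrix(0, d, d) else NULL))
    S1 <- sapply(seq_len(d), function(i)
      mean(b * (fAB[idx, i] - a)) / V)
    ST <- sapply(seq_len(d), function(i)
      mean((a - fAB[idx, i])^2) / (2 * V))
    S2 <- NULL
    if (second) {
      S2 <- matrix(NA_real_, d, d)
      for (i in seq_len(d - 1)) for (j in (i + 1):d) {
        vij <- mean(fBA[idx, i] * fAB[idx, j] - a * b) / V
        S2[i, j] <- S2[j, i] <- vij - S1[i] - S1[j]
      }
    }
    list(S1 = S1, ST = ST, S2 = S2)
  }
  full <- est(seq_len(n))
  out <- list(S1 = full$S1, ST = full$ST)
  if (second) out$S2 <- full$S2
  if (n_boot > 0) {
    bs1 <- matrix(NA_real_, n_boot, d)
    bst <- matrix(NA_real_, n_boot, d)
    for (k in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      e <- est(idx)
      bs1[k, ] <- e$S1; bst[k, ] <- e$ST
    }
    z <- stats::qnorm(0.5 + conf / 2)
    out$S1_conf <- z * apply(bs1, 2, stats::sd)
    out$ST_conf <- z * apply(bst, 2, stats::sd)
  }
  out
}

#' Sobol sensitivity of a simulation metric to the six pathway weights
#'
#' Draws a Saltelli design over the six synaptic strengths in \[0, 1\]
#' (all six vary jointly), runs one simulation per row, evaluates the
#' chosen metric and returns the Sobol indices. For the deviation metric
#' the perturbation onset is pinned once, at the peak elbow flexion of the
#' unperturbed zero-weight run, and every sample row runs perturbed.
#' Failed rows are imputed with the worst observed metric value and
#' counted.
#'
#' @param metric "rmse", "sal" or "deviation".
#' @param base_config a `simulation_config` (weights are replaced per
#'   row).
#' @param n base sample size (default 64, a desk-scale reduction;
#'   N = 512 reproduces the full published design size).
#' @param seed integer seed for the sample draw.
#' @param second_order include second-order blocks?
#' @param n_boot bootstrap resamples for confidence half-widths.
#' @return List from [sobol_indices()], with parameter names attached and
#'   `n_failed`.
#' @export
sensitivity_experiment <- function(metric = c("rmse", "sal", "deviation"),
                                   base_config, n = 64, seed = 1L,
                                   second_order = FALSE, n_boot = 0) {
  metric <- match.arg(metric)
  smp <- saltelli_sample(n, 6, second_order = second_order, seed = seed)
  colnames(smp) <- pathway_kinds()
  perturbed <- metric == "deviation"
  onset <- NULL
  if (perturbed) {
    cfg0 <- base_config
    cfg0$weights <- synaptic_weights()
    cfg0$perturbation <- NULL
    onset <- peak_flexion_time(cfg0)
  }
  evaluate_row <- function(w) {
    cfg <- base_config
    cfg$weights <- synaptic_weights(
      IaMN = w[1], IaINa = w[2], IaMNs = w[3],
      II = w[4], Ib = w[5], RN = w[6], max_weight = 1)
    if (perturbed) {
      cfg$perturbation <- perturbation(30, "upward", onset, 0.030)
    } else {
      cfg$perturbation <- NULL
    }
    tr <- run_simulation(cfg)
    switch(metric,
           rmse = trajectory_rmse(tr, cfg$target),
           sal = elbow_sal(tr),
           deviation = elbow_deviation(tr, onset))
  }
  outputs <- rep(NA_real_, nrow(smp))
  for (i in seq_len(nrow(smp))) {
    outputs[i] <- tryCatch(evaluate_row(smp[i, ]), error = function(e)
      NA_real_)
  }
  n_failed <- sum(!is.finite(outputs))
  if (n_failed > 0) {
    worst <- if (metric == "sal") min(outputs, na.rm = TRUE) else
      max(outputs, na.rm = TRUE)
    outputs[!is.finite(outputs)] <- worst
  }
  res <- sobol_indices(smp, outputs, n_boot = n_boot)
  names(res$S1) <- names(res$ST) <- pathway_kinds()
  res$n_failed <- n_failed
  res
}
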