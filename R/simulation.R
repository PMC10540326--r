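# Synthetic-data generator and study harnesses. The generator follows the
# model itself: a deterministic coverage grid M_i = 10 + 30 (i-1)/(n-1), a
# covariate X_i2 ~ Normal((i-1)/(n-1), sigma_x) whose correlation with
# coverage is controlled by sigma_x (smaller sigma_x = more correlation),
# latent presence lambda_i ~ Bernoulli(expit(X_i' beta)), and detection
# Y_i ~ Bernoulli(f(M_i)) when present, Bernoulli(epsilon) when absent.

#' Surrogate detection curve for simulations
#'
#' A fixed monotone coverage-to-detection curve,
#' `f(m) = expit(-2 + 0.3 m)` (logit clipped to +/- 10): detection is
#' unlikely (~0.12) at zero coverage, ~0.73 at 10x, and approaches 1 beyond
#' 30x, mimicking empirical detection curves obtained by read subsampling of
#' isolate genomes.
#'
#' @param m Coverage values (non-negative).
#' @return Detection probabilities.
#' @examples
#' surrogate_detection_curve(10)  # 0.731...
#' @export
surrogate_detection_curve <- function(m) {
  if (any(m < 0)) stop("coverage must be non-negative")
  expit(clamp(-2 + 0.3 * m, -10, 10))
}

#' Simulation configuration
#'
#' @param n Number of genomes (at least 4).
#' @param beta True presence coefficients `(beta0, beta1)`.
#' @param sigma_x Standard deviation of the covariate around its mean grid;
#'   controls the correlation between quality and covariate (larger
#'   `sigma_x`, less correlation).
#' @param epsilon Contamination probability used in the generative model.
#' @param curve Detection-probability function of coverage (default
#'   [surrogate_detection_curve()]).
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n = 100, beta = c(0, 0), sigma_x = 0.5, epsilon = 0,
                       curve = surrogate_detection_curve, seed = NULL) {
  stopifnot(n >= 4, sigma_x > 0, epsilon >= 0, epsilon < 1,
            is.function(curve), length(beta) == 2)
  structure(list(n = n, beta = beta, sigma_x = sigma_x, epsilon = epsilon,
                 curve = curve, seed = seed),
            class = "sim_config")
}

#' Simulate one gene's detection data
#'
#' Draws one dataset from the generative model described above. With a fixed
#' `seed` the result is bit-identical across calls; the caller's RNG state is
#' restored.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_dataset"` with `Y`, `X` (n x 2, intercept
#'   first), `M`, the latent truth `lambda`, and `config`.
#' @examples
#' d <- simulate_dataset(sim_config(n = 4, seed = 1))
#' d$M  # 10 20 30 40
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  draw <- function() {
    n <- config$n
    grid <- (seq_len(n) - 1) / (n - 1)
    M <- 10 + 30 * grid
    X <- cbind(1, stats::rnorm(n, mean = grid, sd = config$sigma_x))
    lambda <- stats::rbinom(n, 1, expit(drop(X %*% config$beta)))
    f <- config$curve(M)
    Y <- ifelse(lambda == 1,
                stats::rbinom(n, 1, f),
                stats::rbinom(n, 1, config$epsilon))
    structure(list(Y = Y, X = X, M = M, lambda = lambda, config = config),
              class = "sim_dataset")
  }
  if (is.null(config$seed)) draw() else with_local_seed(config$seed, draw())
}

# default control for error-rate and power studies: permutation-era settings
# (delta = 0.1, at least 16 EM iterations)
study_control <- function(epsilon = 0) {
  lp_control(epsilon = epsilon, t_max = 1000, delta = 0.1, min_iter = 16)
}

wald_ci <- function(rate, n) {
  se <- sqrt(rate * (1 - rate) / n)
  c(lo = max(0, rate - 1.96 * se), hi = min(1, rate + 1.96 * se))
}

# p-value for one simulated dataset under one method
sim_pvalue <- function(d, method, control, B, perm_seed) {
  hyp <- lp_hypothesis(test_cols = 2, p = 2)
  switch(method,
    "happi-a" = {
      s <- lrt_stat(d$Y, d$X, d$M, control, hyp)
      lp_lrt(s$fit_alt, s$fit_null)$p_value
    },
    "happi-np" = lp_perm_test(d$Y, d$X, d$M, control, hyp, B = B,
                              seed = perm_seed)$p_value,
    "glm-lrt" = glm_lrt(d$Y, d$X, hyp)$p_value,
    "glm-rao" = glm_rao(d$Y, d$X, hyp)$p_value,
    stop("unknown method: ", method)
  )
}

run_study_grid <- function(grid, methods, B, n_sim, alpha, seed, epsilon) {
  control <- study_control(epsilon)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    cell_seed <- (seed * 7919L + g * 104729L) %% .Machine$integer.max
    pmat <- with_local_seed(cell_seed, {
      out <- matrix(NA_real_, n_sim, length(methods),
                    dimnames = list(NULL, methods))
      for (s in seq_len(n_sim)) {
        d <- simulate_dataset(sim_config(
          n = cell$n, beta = c(0, cell$beta1), sigma_x = cell$sigma_x,
          epsilon = epsilon
        ))
        perm_seed <- sample.int(.Machine$integer.max - 1, 1)
        for (mth in methods) {
          out[s, mth] <- sim_pvalue(d, mth, control, B, perm_seed)
        }
      }
      out
    })
    for (mth in methods) {
      rate <- mean(pmat[, mth] < alpha)
      ci <- wald_ci(rate, n_sim)
      rows[[length(rows) + 1]] <- data.frame(
        n = cell$n, sigma_x = cell$sigma_x, beta1 = cell$beta1,
        method = mth, n_sim = n_sim, alpha = alpha,
        rejection_rate = rate, ci_lo = ci["lo"], ci_hi = ci["hi"],
        row.names = NULL
      )
    }
  }
  do.call(rbind, rows)
}

#' Type-1-error study
#'
#' Simulates null data (`beta1 = 0`) over a grid of sample sizes and
#' `sigma_x` values and reports, per cell and method, the fraction of
#' p-values below `alpha` with a 95% Wald binomial confidence interval.
#' Defaults mirror the standard study design: grid n in \{30, 50, 100\},
#' sigma_x in \{0.25, 0.5\}, 500 simulations per cell and 1000 permutations,
#' at level 5%.
#'
#' @param n_values,sigma_x_values Grid of sample sizes and covariate noise
#'   levels.
#' @param methods Subset of `c("happi-a", "happi-np", "glm-lrt", "glm-rao")`.
#' @param B Permutations per dataset (happi-np only).
#' @param n_sim Simulated datasets per grid cell.
#' @param alpha Test level.
#' @param seed Master seed; all per-cell and per-dataset seeds derive from
#'   it.
#' @param epsilon Contamination probability (0 in the standard design).
#' @return Tidy data frame, one row per cell x method.
#' @export
run_type1_study <- function(n_values = c(30, 50, 100),
                            sigma_x_values = c(0.25, 0.5),
                            methods = c("happi-a", "happi-np",
                                        "glm-lrt", "glm-rao"),
                            B = 1000, n_sim = 500, alpha = 0.05, seed = 1,
                            epsilon = 0) {
  grid <- expand.grid(n = n_values, sigma_x = sigma_x_values, beta1 = 0)
  run_study_grid(grid, methods, B, n_sim, alpha, seed, epsilon)
}

#' Power study
#'
#' Same harness as [run_type1_study()] but with nonzero effect sizes
#' `beta1`; a `beta1 = 0` row reproduces the type-1 cell.
#'
#' @inheritParams run_type1_study
#' @param beta1_values Effect sizes on the log-odds scale.
#' @return Tidy data frame, one row per cell x method.
#' @export
run_power_study <- function(n_values = c(30, 50, 100),
                            sigma_x_values = c(0.25, 0.5),
                            beta1_values = c(0.5, 1, 2),
                            methods = c("happi-a", "happi-np"),
                            B = 1000, n_sim = 500, alpha = 0.05, seed = 1,
                            epsilon = 0) {
  grid <- expand.grid(n = n_values, sigma_x = sigma_x_values,
                      beta1 = beta1_values)
  run_study_grid(grid, methods, B, n_sim, alpha, seed, epsilon)
}

#' Compare the two detection-curve estimators
#'
#' For every combination of `n`, `beta1` and `sigma_x`, simulates `n_rep`
#' datasets and fits the model with the I-spline curve class and the isotonic
#' curve class, recording the estimate of the covariate effect `beta1` from
#' each. Reports mean and median squared error per class, per cell.
#'
#' @inheritParams run_power_study
#' @param n_rep Draws per combination (default 250).
#' @return Tidy data frame with one row per combination and columns
#'   `mse_ispline`, `mse_isotone`, `medse_ispline`, `medse_isotone`;
#'   attribute `"ispline_wins_mse"` gives the fraction of combinations where
#'   the I-spline class has lower MSE.
#' @export
compare_f_estimators <- function(n_values = c(30, 50, 100),
                                 beta1_values = c(0.5, 1, 2),
                                 sigma_x_values = c(0.25, 0.5),
                                 n_rep = 250, seed = 1, epsilon = 0) {
  grid <- expand.grid(n = n_values, beta1 = beta1_values,
                      sigma_x = sigma_x_values)
  ctl_i <- study_control(epsilon)
  ctl_f <- study_control(epsilon)
  ctl_f$f_class <- "isotone"
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    cell_seed <- (seed * 6133L + g * 15485863L) %% .Machine$integer.max
    est <- with_local_seed(cell_seed, {
      bi <- bf <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        d <- simulate_dataset(sim_config(
          n = cell$n, beta = c(0, cell$beta1), sigma_x = cell$sigma_x,
          epsilon = epsilon
        ))
        bi[r] <- lp_fit(d$Y, d$X, d$M, ctl_i)$beta[2]
        bf[r] <- lp_fit(d$Y, d$X, d$M, ctl_f)$beta[2]
      }
      list(bi = bi, bf = bf)
    })
    rows[[g]] <- data.frame(
      n = cell$n, beta1 = cell$beta1, sigma_x = cell$sigma_x, n_rep = n_rep,
      mean_beta1_ispline = mean(est$bi), mean_beta1_isotone = mean(est$bf),
      mse_ispline = mean((est$bi - cell$beta1)^2),
      mse_isotone = mean((est$bf - cell$beta1)^2),
      medse_ispline = stats::median((est$bi - cell$beta1)^2),
      medse_isotone = stats::median((est$bf - cell$beta1)^2)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "ispline_wins_mse") <- mean(out$mse_ispline <= out$mse_isotone)
  out
}
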