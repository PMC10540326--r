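# Likelihood-ratio testing: asymptotic chi-squared reference (happi-a), the
# permutation reference for modest sample sizes (happi-np), BH adjustment
# across genes, and the epsilon-sensitivity sweep.

new_lp_test <- function(method, Q, p_value, h, B_used = NA_integer_,
                        fit_alt = NULL, fit_null = NULL) {
  structure(
    list(method = method, Q_LRT = Q, p_value = p_value, h = h,
         B_used = B_used, fit_alt = fit_alt, fit_null = fit_null),
    class = "lp_test"
  )
}

#' @export
print.lp_test <- function(x, ...) {
  cat(sprintf("%s test: Q_LRT = %.4f (df = %d), p = %.4g\n",
              x$method, x$Q_LRT, x$h, x$p_value))
  if (!is.na(x$B_used)) cat("  permutations:", x$B_used, "\n")
  invisible(x)
}

#' Asymptotic likelihood-ratio test
#'
#' `Q_LRT = 2 [L(theta_hat) - L(theta_hat_0)]` compared against the upper
#' tail of a chi-squared distribution with `h = rank(A)` degrees of freedom.
#' `L` is the unpenalized observed-data log-likelihood; the Firth penalty is
#' an estimation device only and is excluded from the statistic. `Q` is
#' floored at 0. If the null fit beats the alternative by more than `1e-6`
#' the alternative is refit starting from the null's parameters and the
#' better fit kept. A small negative `Q` can persist even at full
#' convergence because the Firth penalty is computed on the full design for
#' the alternative but on the reduced design for the null; such values are
#' floored and noted in the `note` field rather than treated as failures.
#'
#' @param fit_alt,fit_null `lp_fit` objects from [lp_fit()] and
#'   [lp_fit_null()] on the same data and control.
#' @param h Degrees of freedom; defaults to the rank of the null's
#'   constraint matrix.
#' @return An `lp_test` with method `"happi-a"`.
#' @export
lp_lrt <- function(fit_alt, fit_null, h = fit_null$hypothesis$h) {
  stopifnot(inherits(fit_alt, "lp_fit"), inherits(fit_null, "lp_fit"))
  note <- NULL
  if (fit_null$loglik > fit_alt$loglik + 1e-6) {
    refit <- lp_fit(fit_alt$y, fit_alt$X, fit_alt$M, fit_alt$control,
                    init = list(beta = fit_null$beta, curve = fit_null$curve),
                    basis = fit_alt$basis)
    if (refit$loglik > fit_alt$loglik) fit_alt <- refit
    if (fit_null$loglik > fit_alt$loglik + 1e-6) {
      note <- "negative LRT statistic floored at 0 (penalized estimation)"
    }
  }
  Q <- max(2 * (fit_alt$loglik - fit_null$loglik), 0)
  p <- stats::pchisq(Q, df = h, lower.tail = FALSE)
  out <- new_lp_test("happi-a", Q, p, h, fit_alt = fit_alt,
                     fit_null = fit_null)
  out$note <- note
  out
}

# evaluate the LRT statistic on one dataset, with optional warm starts
lrt_stat <- function(y, X, M, control, hypothesis, basis = NULL,
                     init_alt = NULL, init_null = NULL) {
  fa <- lp_fit(y, X, M, control, init = init_alt, basis = basis)
  f0 <- lp_fit_null(y, X, M, control, hypothesis, init = init_null,
                    basis = basis)
  list(Q = max(2 * (fa$loglik - f0$loglik), 0), fit_alt = fa, fit_null = f0)
}

#' Permutation likelihood-ratio test
#'
#' Builds the reference distribution of `Q_LRT` by permuting the tested
#' covariate columns of `X` jointly across genomes, keeping `y`, `M` and the
#' untested columns fixed. For each of the `B` permutations the full and
#' null models are refit (warm-started at the observed fits) and the
#' statistic recomputed; the p-value is the add-one estimator
#' `(1 + #\{Q_b >= Q_0\}) / (B + 1)`, so `p >= 1 / (B + 1)` always. The RNG
#' state is restored on exit; results are deterministic given `seed`.
#'
#' @inheritParams lp_fit
#' @param hypothesis An [lp_hypothesis()] testing a subset of coefficients
#'   (i.e. with non-`NULL` `test_cols`).
#' @param B Number of permutations (at least 19, so that level 0.05 is
#'   resolvable; default 1000).
#' @param seed Integer seed for the permutations.
#' @return An `lp_test` with method `"happi-np"`.
#' @export
lp_perm_test <- function(y, X, M, control = lp_control(delta = 0.1),
                         hypothesis, B = 1000, seed = 1) {
  if (B < 19) stop("B must be at least 19 to resolve alpha = 0.05")
  if (is.null(hypothesis$test_cols)) {
    stop("permutation test requires a hypothesis on a subset of ",
         "coefficients (test_cols)")
  }
  X <- as.matrix(X)
  cols <- hypothesis$test_cols
  basis <- if (control$f_class == "ispline") {
    ispline_basis(if (is.matrix(M)) M[, 1] else M, df = control$spline_df,
                  degree = control$spline_degree)
  }
  obs <- lrt_stat(y, X, M, control, hypothesis, basis = basis)
  Q0 <- obs$Q
  init_alt <- list(beta = obs$fit_alt$beta, curve = obs$fit_alt$curve)
  init_null <- list(beta = obs$fit_null$beta, curve = obs$fit_null$curve)

  n <- length(y)
  Qb <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      Xb <- X
      Xb[, cols] <- X[sample.int(n), cols]
      lrt_stat(y, Xb, M, control, hypothesis, basis = basis,
               init_alt = init_alt, init_null = init_null)$Q
    }, numeric(1))
  })
  p <- (1 + sum(Qb >= Q0 - 1e-9)) / (B + 1)  # >= tie rule, tiny slack for
                                             # exactly-tied refits
  out <- new_lp_test("happi-np", Q0, p, hypothesis$h, B_used = B,
                     fit_alt = obs$fit_alt, fit_null = obs$fit_null)
  out$Q_perm <- Qb
  out
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across genes (wrapper around
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Sensitivity of the test to the contamination hyperparameter
#'
#' Re-runs the full test over a grid of `epsilon` values. Results whose
#' significance hinges on assuming very low contamination (small `epsilon`)
#' and is not robust across small increases should be interpreted
#' cautiously.
#'
#' @inheritParams lp_perm_test
#' @param eps_grid Vector of `epsilon` values in `[0, 1)`; duplicates are
#'   dropped with a warning and rows are ordered by `epsilon`.
#' @param method `"asymptotic"` or `"permutation"`.
#' @return Data frame with columns `epsilon`, `Q_LRT`, `p_value`.
#' @export
lp_epsilon_sensitivity <- function(y, X, M, control = lp_control(),
                                   hypothesis,
                                   eps_grid = c(0, 0.01, 0.05, 0.1),
                                   method = c("asymptotic", "permutation"),
                                   B = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(all(eps_grid >= 0 & eps_grid < 1))
  if (anyDuplicated(eps_grid)) {
    warning("duplicate epsilon values dropped")
    eps_grid <- unique(eps_grid)
  }
  eps_grid <- sort(eps_grid)
  rows <- lapply(eps_grid, function(eps) {
    ctl <- control
    ctl$epsilon <- eps
    tst <- if (method == "asymptotic") {
      s <- lrt_stat(y, as.matrix(X), M, ctl, hypothesis)
      lp_lrt(s$fit_alt, s$fit_null)
    } else {
      lp_perm_test(y, X, M, ctl, hypothesis, B = B, seed = seed)
    }
    data.frame(epsilon = eps, Q_LRT = tst$Q_LRT, p_value = tst$p_value)
  })
  do.call(rbind, rows)
}

#' Test association between gene presence and covariates
#'
#' One-stop test for a single gene: fits the full and null models and applies
#' either the asymptotic chi-squared LRT (`happi-a`; recommended for large
#' n) or the permutation LRT (`happi-np`; recommended for modest n, where
#' the chi-squared approximation is anti-conservative).
#'
#' @inheritParams lp_perm_test
#' @param method `"asymptotic"` or `"permutation"`.
#' @return An `lp_test` object.
#' @examples
#' d <- simulate_dataset(sim_config(n = 50, beta = c(0, 1.5), seed = 11))
#' lp_single_test(d$Y, d$X, d$M, lp_hypothesis(test_cols = 2, p = 2),
#'                method = "asymptotic", control = lp_control(delta = 0.1))
#' @export
lp_single_test <- function(y, X, M, hypothesis,
                           method = c("asymptotic", "permutation"),
                           control = lp_control(), B = 1000, seed = 1) {
  method <- match.arg(method)
  if (method == "asymptotic") {
    s <- lrt_stat(y, as.matrix(X), M, control, hypothesis)
    lp_lrt(s$fit_alt, s$fit_null)
  } else {
    lp_perm_test(y, X, M, control, hypothesis, B = B, seed = seed)
  }
}
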