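# EM orchestration: full fits, null-constrained fits (A beta = c via
# reparameterization), and the shared engine. One gene at a time; genes are
# modeled independently.

# internal E-step / likelihood on the linear-predictor scale
e_step_eta <- function(eta, f, y, epsilon, clamp_p = TRUE) {
  pi <- expit(eta)
  fy <- y * f + (1 - y) * (1 - f)            # Pr(y | present)
  ey <- y * epsilon + (1 - y) * (1 - epsilon) # Pr(y | absent)
  num <- fy * pi
  den <- num + ey * (1 - pi)
  if (any(den == 0)) {
    stop("zero marginal detection probability for genome(s) ",
         paste(which(den == 0), collapse = ", "))
  }
  p <- num / den
  if (clamp_p) p <- clamp(p, P_CLAMP, 1 - P_CLAMP)
  p
}

obs_ll_eta <- function(eta, f, y, epsilon) {
  pi <- expit(eta)
  pr <- (y * f + (1 - y) * (1 - f)) * pi +
    (y * epsilon + (1 - y) * (1 - epsilon)) * (1 - pi)
  if (any(pr == 0)) return(-Inf)
  sum(log(pr))
}

#' Hypothesis specification `A beta = c`
#'
#' Builds the linear null hypothesis for the presence coefficients. Either
#' supply the `h x p` matrix `A` (full row rank) and right-hand side `c`, or
#' use the shortcut `test_cols` to test a set of coefficients against zero.
#'
#' @param A Constraint matrix (h x p), rank h.
#' @param c Right-hand side vector, length h (default zeros).
#' @param test_cols Shortcut: integer indices of the coefficients tested
#'   against 0.
#' @param p Number of columns of the design matrix (needed with `test_cols`).
#' @return List of class `"lp_hypothesis"` with `A`, `c`, `h`, and
#'   `test_cols` (`NULL` when the constraint is not a coordinate subset).
#' @examples
#' lp_hypothesis(test_cols = 2, p = 2)  # H0: beta_2 = 0
#' @export
lp_hypothesis <- function(A = NULL, c = NULL, test_cols = NULL, p = NULL) {
  if (!is.null(test_cols)) {
    stopifnot(!is.null(p), all(test_cols >= 1), all(test_cols <= p))
    A <- diag(p)[test_cols, , drop = FALSE]
    c <- rep(0, length(test_cols))
  } else {
    A <- as.matrix(A)
    c <- c %||% rep(0, nrow(A))
    # recover a coordinate subset if A selects single coefficients
    rows_simple <- apply(A, 1, function(r) sum(r != 0) == 1)
    test_cols <- if (all(rows_simple) && all(c == 0)) {
      unname(apply(A, 1, function(r) which(r != 0)))
    } else NULL
  }
  h <- nrow(A)
  if (qr(A)$rank < h) stop("constraint matrix A must have full row rank")
  structure(list(A = A, c = c, h = h, test_cols = test_cols),
            class = "lp_hypothesis")
}

# null-space reparameterization of {beta : A beta = c}:
# beta = beta0 + N gamma with A beta0 = c and A N = 0
null_reparam <- function(hypothesis, p) {
  A <- hypothesis$A
  stopifnot(ncol(A) == p)
  beta0 <- drop(crossprod(A, solve(tcrossprod(A), hypothesis$c)))
  sv <- svd(A, nu = 0, nv = p)
  N <- sv$v[, seq_len(p)[-seq_len(hypothesis$h)], drop = FALSE]
  list(beta0 = beta0, N = N)
}

# Shared EM engine. The presence coefficients enter through the (possibly
# reduced) design Z and offset: eta = offset + Z gamma, beta = beta0 + N gamma.
lp_em <- function(y, X, M, control, Z, offset, to_beta, init = NULL,
                  basis = NULL, fixed_curve = NULL) {
  n <- length(y)
  m <- if (is.matrix(M)) M else as.numeric(M)
  curve_is_free <- is.null(fixed_curve)
  if (curve_is_free && control$f_class %in% c("ispline", "isotone") &&
      is.matrix(M) && ncol(M) > 1) {
    stop("nonparametric detection curves support a single quality variable; ",
         "use f_class = \"linear\" for q >= 2")
  }
  if (is.null(basis) && curve_is_free && control$f_class == "ispline") {
    basis <- ispline_basis(m, df = control$spline_df,
                           degree = control$spline_degree)
  }
  eps <- control$epsilon
  identifiable <- !(eps == 0 && (all(y == 0) || all(y == 1)))

  gamma <- init$gamma %||% rep(0, ncol(Z))
  if (!is.null(init$curve)) attr(init$curve, "ft") <- NULL  # stale cache
  curve <- if (!curve_is_free) fixed_curve else init$curve %||% {
    a0 <- clamp(logit(clamp((sum(y) + 0.5) / (n + 1), 1e-8, 1 - 1e-8)),
                -control$logit_cap, control$logit_cap)
    if (control$f_class == "ispline") {
      new_ispline_curve(a0, rep(0, ncol(basis)), attr(basis, "iknots"),
                        attr(basis, "degree"), attr(basis, "boundary"),
                        control$logit_cap)
    } else if (control$f_class == "isotone") {
      new_isotone_curve(range(m), rep(a0, 2), control$logit_cap)
    } else {
      new_linear_curve(c(a0, rep(0, ncol(as.matrix(M)))), control$logit_cap)
    }
  }

  # fitted logits at the training m: cached by the M-step updates, computed
  # from the precomputed basis otherwise
  curve_ft <- function(curve) {
    ft <- attr(curve, "ft")
    if (!is.null(ft)) return(ft)
    if (inherits(curve, "ispline_curve") && !is.null(basis)) {
      clamp(curve$alpha0 + drop(basis %*% curve$alpha),
            -control$logit_cap, control$logit_cap)
    } else {
      eval_curve(curve, m)$ft
    }
  }

  pen_monitor <- function(gamma, curve, pen = NULL) {
    eta <- offset + drop(Z %*% gamma)
    ll <- obs_ll_eta(eta, expit(curve_ft(curve)), y, eps)
    if (is.null(pen)) {
      pen <- if (ncol(Z) > 0) firth_penalty(gamma, Z, offset) else 0
    }
    ll + pen
  }

  trace <- numeric(0)
  ll_prev <- pen_monitor(gamma, curve)
  consec <- 0L
  converged <- FALSE
  beta_conv <- TRUE
  pen <- NULL
  t <- 0L
  if (ncol(Z) > 0 && qr(Z)$rank < ncol(Z)) {
    stop("design matrix is rank deficient")
  }
  while (t < control$t_max) {
    t <- t + 1L
    eta <- offset + drop(Z %*% gamma)
    f <- expit(curve_ft(curve))
    p <- e_step_eta(eta, f, y, eps)
    if (ncol(Z) > 0) {
      bfit <- firth_logistic(Z, p, offset = offset, init = gamma,
                             check_rank = FALSE)
      gamma <- bfit$beta
      beta_conv <- bfit$converged
      pen <- bfit$penalty
    } else {
      pen <- 0
    }
    if (curve_is_free) {
      curve <- update_f(m, p, y, control, basis = basis,
                        init = curve_warm_start(curve))
    }
    ll <- pen_monitor(gamma, curve, pen)
    trace <- c(trace, ll)
    rel <- (ll - ll_prev) / (abs(ll_prev) + 1e-12)
    consec <- if (rel < control$delta) consec + 1L else 0L
    ll_prev <- ll
    if (t >= control$min_iter && consec >= control$consecutive_steps) {
      converged <- TRUE
      break
    }
  }

  beta <- to_beta(gamma)
  eta <- offset + drop(Z %*% gamma)
  fv <- eval_curve(curve, m)
  p <- e_step_eta(eta, fv$f, y, eps, clamp_p = FALSE)
  structure(
    list(
      beta = beta, gamma = gamma, curve = curve, p = p,
      loglik = obs_ll_eta(eta, fv$f, y, eps),
      pen_loglik = ll_prev, trace = trace,
      n_iter = t, converged = converged, beta_converged = beta_conv,
      identifiable = identifiable,
      control = control, y = y, X = X, M = M,
      basis = basis
    ),
    class = "lp_fit"
  )
}

#' Fit the latent presence model for one gene
#'
#' Runs the EM algorithm: the E-step computes posterior presence
#' probabilities, then the presence coefficients are updated by
#' Firth-penalized logistic regression on those posteriors and the detection
#' curve by the monotone-constrained weighted logistic fit of the chosen
#' class. Iterates until the relative increase of the penalized observed-data
#' log-likelihood stays below `delta` for `consecutive_steps` consecutive
#' iterations (with at least `min_iter` iterations), or `t_max` is reached.
#'
#' @param y Binary detection indicator for the gene across genomes.
#' @param X Covariate design matrix (n x p), first column typically the
#'   intercept.
#' @param M Quality variable (length-n vector; a matrix only with
#'   `f_class = "linear"`).
#' @param control An [lp_control()] object.
#' @param init Optional warm start: list with `beta` and/or `curve`.
#' @param basis Optional precomputed [ispline_basis()] of `M`.
#' @param fixed_curve Optional [fixed_detection_curve()]; when supplied the
#'   detection curve is held fixed and only `beta` is estimated.
#' @return An `lp_fit` object: `beta`, `curve`, posterior `p`, observed-data
#'   `loglik`, penalized monitor trace `trace`, `n_iter`, `converged`, and
#'   an `identifiable` flag (FALSE for all-zero / all-one `y` with
#'   `epsilon = 0`, where the fit sits on the boundary).
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(sim_config(n = 50, beta = c(0, 1), seed = 3))
#' fit <- lp_fit(d$Y, d$X, d$M, lp_control(delta = 0.1))
#' fit$beta
#' @export
lp_fit <- function(y, X, M, control = lp_control(), init = NULL,
                   basis = NULL, fixed_curve = NULL) {
  X <- as.matrix(X)
  check_fit_inputs(y, X, M)
  to_beta <- function(gamma) gamma
  init2 <- if (!is.null(init)) list(gamma = init$beta, curve = init$curve)
  lp_em(y, X, M, control, Z = X, offset = rep(0, length(y)),
        to_beta = to_beta, init = init2, basis = basis,
        fixed_curve = fixed_curve)
}

#' Fit the latent presence model under a null constraint
#'
#' Maximizes the same penalized objective subject to `A beta = c`, by
#' reparameterizing `beta = beta0 + N gamma` where `beta0` is a particular
#' solution and `N` spans the null space of `A`. The reduced design `X N`
#' with offset `X beta0` is fit exactly as in [lp_fit()]; the Firth penalty
#' is computed on the reduced design. The detection curve is estimated
#' freely. When `h = p` the coefficients are fully fixed and only the curve
#' is fitted.
#'
#' @inheritParams lp_fit
#' @param hypothesis An [lp_hypothesis()] object.
#' @return An `lp_fit` object (with `hypothesis` attached).
#' @export
lp_fit_null <- function(y, X, M, control = lp_control(), hypothesis,
                        init = NULL, basis = NULL, fixed_curve = NULL) {
  X <- as.matrix(X)
  check_fit_inputs(y, X, M)
  stopifnot(inherits(hypothesis, "lp_hypothesis"))
  rp <- null_reparam(hypothesis, ncol(X))
  Z <- X %*% rp$N
  offset <- drop(X %*% rp$beta0)
  to_beta <- function(gamma) drop(rp$beta0 + rp$N %*% gamma)
  init2 <- if (!is.null(init)) {
    g0 <- if (!is.null(init$beta) && ncol(rp$N) > 0) {
      drop(crossprod(rp$N, init$beta - rp$beta0))
    } else NULL
    list(gamma = g0, curve = init$curve)
  }
  fit <- lp_em(y, X, M, control, Z = Z, offset = offset, to_beta = to_beta,
               init = init2, basis = basis, fixed_curve = fixed_curve)
  fit$hypothesis <- hypothesis
  fit
}

check_fit_inputs <- function(y, X, M) {
  n <- length(y)
  Mn <- if (is.matrix(M)) nrow(M) else length(M)
  if (nrow(X) != n || Mn != n) stop("y, X and M must be aligned (same n)")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (anyNA(y) || anyNA(X) || anyNA(M)) stop("missing values are not allowed")
  if (n < ncol(X) + 1) stop("need n >= p + 1 genomes")
  invisible(TRUE)
}

#' @export
print.lp_fit <- function(x, ...) {
  cat("Latent presence model fit\n")
  cat("  beta:", format(x$beta, digits = 4), "\n")
  cat("  detection curve:", x$curve$f_class, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6),
      " iterations:", x$n_iter,
      " converged:", x$converged, "\n")
  if (!x$identifiable) {
    cat("  note: all-zero or all-one gene with epsilon = 0;",
        "parameters not identified (boundary fit)\n")
  }
  invisible(x)
}
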