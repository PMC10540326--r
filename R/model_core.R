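# Core probability model. For genome i with covariates X_i, quality M_i and
# detection indicator Y_i, the latent presence indicator lambda_i follows
#   logit Pr(lambda_i = 1 | X_i) = X_i' beta,
# and detection follows
#   Pr(Y_i = 1 | lambda_i = 1, M_i) = f(M_i),
#   Pr(Y_i = 1 | lambda_i = 0)      = epsilon,
# with f monotone non-decreasing in M. epsilon is a fixed hyperparameter.

#' Observed-data log-likelihood
#'
#' Marginal log-likelihood of the detections `y` after summing the latent
#' presence indicators out:
#' `sum_{i: y=0} log[(1 - eps)(1 - pi_i) + (1 - f(M_i)) pi_i] +
#'  sum_{i: y=1} log[eps (1 - pi_i) + f(M_i) pi_i]`,
#' with `pi_i = expit(X_i' beta)`. Computed on the probability scale; a
#' probability-0 datum (e.g. `y = 1` with `eps = 0` and `f = 0`) yields
#' `-Inf` with the offending genome indices in attribute `"zero_prob"`.
#'
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param f Probability-scale detection values at the observed quality values
#'   (length n), e.g. `eval_curve(curve, m)$f`.
#' @param y Binary detection indicators.
#' @param X Design matrix (n x p), first column typically all ones.
#' @param epsilon Probability of observing a truly absent gene.
#' @return Scalar log-likelihood.
#' @export
observed_loglik <- function(beta, f, y, X, epsilon) {
  pi <- expit(drop(X %*% beta))
  pr <- ifelse(y == 1,
               epsilon * (1 - pi) + f * pi,
               (1 - epsilon) * (1 - pi) + (1 - f) * pi)
  if (any(pr == 0)) {
    out <- -Inf
    attr(out, "zero_prob") <- which(pr == 0)
    return(out)
  }
  sum(log(pr))
}

#' Posterior presence probabilities (E-step)
#'
#' `p_i = Pr(lambda_i = 1 | y_i)` under current parameters, by Bayes' rule:
#' numerator `Pr(y_i | lambda_i = 1) pi_i`, denominator the marginal
#' `Pr(y_i)`. By default the result is clamped to `[1e-10, 1 - 1e-10]` for
#' M-step stability (exact 0/1 posteriors arise when `epsilon = 0`).
#'
#' @inheritParams observed_loglik
#' @param clamp_p Clamp the posteriors away from 0/1 (default `TRUE`).
#' @return Vector of posterior presence probabilities.
#' @export
posterior_presence <- function(beta, f, y, X, epsilon, clamp_p = TRUE) {
  pi <- expit(drop(X %*% beta))
  num <- ifelse(y == 1, f * pi, (1 - f) * pi)
  den <- num + ifelse(y == 1, epsilon * (1 - pi), (1 - epsilon) * (1 - pi))
  if (any(den == 0)) {
    stop("zero marginal detection probability for genome(s) ",
         paste(which(den == 0), collapse = ", "))
  }
  p <- num / den
  if (clamp_p) p <- clamp(p, P_CLAMP, 1 - P_CLAMP)
  p
}

# Firth penalty on the beta-submodel: 0.5 log | X' W X |, W = w(1 - w)
firth_penalty <- function(beta, X, offset = 0) {
  w <- expit(drop(X %*% beta) + offset)
  info <- crossprod(X * (w * (1 - w)), X)
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) stop("singular Firth information matrix; check X for collinearity")
  0.5 * as.numeric(ld$modulus)
}

#' Expected complete-data penalized log-likelihood
#'
#' The EM objective at posterior weights `p`: detection term
#' `p_i [y_i ft_i - log(1 + e^{ft_i})]`, contamination term
#' `(1 - p_i) [y_i logit(eps) - log(1 + e^{logit(eps)})]`, presence term
#' `p_i X_i' beta - log(1 + e^{X_i' beta})`, plus the Firth term
#' `0.5 log |sum_i X_i X_i' w_i (1 - w_i)|`. The contamination term is
#' constant in `(beta, f)` and is dropped when `epsilon = 0` (where it is
#' degenerate); it is included otherwise so the value is the full objective.
#' Used for diagnostics and for verifying the M-step updates.
#'
#' @param curve A fitted `detection_curve`.
#' @param p Posterior presence probabilities.
#' @param m Quality values.
#' @inheritParams observed_loglik
#' @return Scalar objective value.
#' @export
expected_penalized_loglik <- function(beta, curve, epsilon, p, y, X, m) {
  ft <- eval_curve(curve, m)$ft
  eta <- drop(X %*% beta)
  val <- sum(p * (y * ft - log1pexp(ft))) +
    sum(p * eta - log1pexp(eta)) +
    firth_penalty(beta, X)
  if (epsilon > 0) {
    et <- logit(epsilon)
    val <- val + sum((1 - p) * (y * et - log1pexp(et)))
  }
  val
}

# Newton solver for Firth-penalized weighted logistic regression with
# fractional outcomes p and optional offset. Adjusted score
#   U*(beta) = X' (p - w + h (0.5 - w)),   h = hat values of W^1/2 X,
# Fisher information X' W X as Hessian, step-halving on the penalized
# objective. Firth's penalty guarantees a finite maximizer even under
# separation.
firth_logistic <- function(X, p, offset = 0, init = NULL,
                           max_iter = 100L, tol = 1e-8, check_rank = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (check_rank && qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient")
  }
  beta <- init %||% rep(0, ncol(X))

  # penalized objective, reusing the Cholesky factor of the information
  pen_obj <- function(b) {
    eta <- drop(X %*% b) + offset
    w <- expit(eta)
    R <- tryCatch(chol(crossprod(X * (w * (1 - w)), X)), error = function(e)
      stop("singular Firth information matrix; check X for collinearity"))
    list(obj = sum(p * eta - log1pexp(eta)) + sum(log(diag(R))),
         w = w, R = R)
  }

  st <- pen_obj(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- st$w
    R <- st$R
    Xs <- X * sqrt(w * (1 - w))
    # hat values of W^{1/2} X
    V <- backsolve(R, forwardsolve(t(R), t(Xs)))
    h <- colSums(V * t(Xs))
    U <- drop(crossprod(X, p - w + h * (0.5 - w)))
    if (sqrt(sum(U^2)) <= tol) {
      converged <- TRUE
      break
    }
    step <- backsolve(R, forwardsolve(t(R), U))
    # step-halving on the penalized objective
    lam <- 1
    repeat {
      cand <- beta + lam * step
      st_new <- pen_obj(cand)
      if (is.finite(st_new$obj) && st_new$obj >= st$obj - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; st_new <- st; break }
    }
    beta <- cand
    st <- st_new
  }
  if (!converged && max_iter >= 100L) {
    warning("Firth-Newton did not reach gradient tolerance in ",
            max_iter, " iterations; returning best iterate")
  }
  # 0.5 log|I(beta)| at the returned estimate, reusable by callers
  eta <- drop(X %*% beta) + offset
  w <- expit(eta)
  penalty <- sum(log(diag(chol(crossprod(X * (w * (1 - w)), X)))))
  list(beta = beta, converged = converged, iter = iter, objective = st$obj,
       penalty = penalty)
}

#' M-step update of the presence coefficients (Firth-penalized)
#'
#' Maximizes `sum_i [p_i X_i' beta - log(1 + exp(X_i' beta))] +
#' 0.5 log |I(beta)|` over `beta` - a Firth-penalized logistic regression
#' with the posterior presence probabilities as fractional outcomes - by
#' Newton's method with step-halving. The Jeffreys-prior penalty keeps the
#' estimate finite even when the posteriors are separated by a covariate.
#'
#' @param X Design matrix (n x p), full column rank.
#' @param p Posterior presence probabilities in (0, 1).
#' @param offset Optional linear-predictor offset (used for constrained null
#'   fits).
#' @param init Optional warm start.
#' @return List with `beta`, `converged`, `iter`, `objective`.
#' @export
update_beta_firth <- function(X, p, offset = 0, init = NULL) {
  firth_logistic(X, p, offset = offset, init = init)
}
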