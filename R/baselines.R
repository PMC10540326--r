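# Logistic-regression comparators applied to the observed detections Y
# directly, ignoring genome quality: the likelihood-ratio test (glm-lrt) and
# the Rao score test (glm-rao, the test used by anvi'o for pangenome
# enrichment). Plain maximum likelihood, no Firth correction; separation is
# reported via the converged flag, not "fixed".

# null-model glm fit under A beta = c via the same reparameterization as the
# latent model; returns fitted probabilities, log-likelihood and flags
glm_null_fit <- function(y, X, hypothesis) {
  rp <- null_reparam(hypothesis, ncol(X))
  Z <- X %*% rp$N
  off <- drop(X %*% rp$beta0)
  sep <- FALSE
  fit <- withCallingHandlers(
    if (ncol(Z) > 0) {
      stats::glm.fit(Z, y, offset = off, family = stats::binomial())
    } else {
      list(fitted.values = expit(off), converged = TRUE)
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  mu <- fit$fitted.values
  if (!is.null(fit$coefficients) && any(abs(fit$coefficients) > 15)) {
    sep <- TRUE
  }
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(mu = mu, loglik = ll, converged = isTRUE(fit$converged) && !sep,
       separated = sep)
}

glm_full_fit <- function(y, X) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  mu <- fit$fitted.values
  if (any(abs(fit$coefficients) > 15)) sep <- TRUE
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(mu = mu, loglik = ll, converged = isTRUE(fit$converged) && !sep,
       separated = sep)
}

#' Logistic-regression likelihood-ratio test (GLM-LRT)
#'
#' Ordinary (unpenalized) logistic regression of the observed detections on
#' the covariates, with `Q = 2 [loglik(full) - loglik(null)]` against a
#' chi-squared with `h` degrees of freedom. Quality variables play no role
#' unless the caller includes them in `X` explicitly. Under separation the
#' statistic from the capped fit is still reported, flagged via
#' `converged = FALSE`.
#'
#' @param y Binary detection indicator.
#' @param X Design matrix (n x p), full column rank.
#' @param hypothesis An [lp_hypothesis()].
#' @return An `lp_test` with method `"glm-lrt"` and a `converged` field.
#' @export
glm_lrt <- function(y, X, hypothesis) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  full <- glm_full_fit(y, X)
  null <- glm_null_fit(y, X, hypothesis)
  Q <- max(2 * (full$loglik - null$loglik), 0)
  p <- stats::pchisq(Q, df = hypothesis$h, lower.tail = FALSE)
  out <- new_lp_test("glm-lrt", Q, p, hypothesis$h)
  out$converged <- full$converged && null$converged
  out
}

#' Logistic-regression Rao score test (GLM-Rao)
#'
#' Score statistic `U0' I0^{-1} U0` where `U0` is the full-model score and
#' `I0` the full-model Fisher information, both evaluated at the constrained
#' (null) maximum-likelihood fit; compared against a chi-squared with `h`
#' degrees of freedom. On a 2x2 layout this reduces to Pearson's chi-squared
#' statistic.
#'
#' @inheritParams glm_lrt
#' @return An `lp_test` with method `"glm-rao"` and a `converged` field.
#' @export
glm_rao <- function(y, X, hypothesis) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  null <- glm_null_fit(y, X, hypothesis)
  mu0 <- null$mu
  U <- drop(crossprod(X, y - mu0))
  I0 <- crossprod(X * (mu0 * (1 - mu0)), X)
  Q <- max(drop(crossprod(U, solve(I0, U))), 0)
  p <- stats::pchisq(Q, df = hypothesis$h, lower.tail = FALSE)
  out <- new_lp_test("glm-rao", Q, p, hypothesis$h)
  out$converged <- null$converged
  out
}
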