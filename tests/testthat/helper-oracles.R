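# Independent oracles used across test files. These deliberately avoid the
# package's own computational paths: enumeration over the latent indicator,
# direct maximization with general-purpose optimizers, and hand-written IRLS.

# marginal log-likelihood by brute-force enumeration of lambda_i in {0, 1}
enum_loglik <- function(beta, f, y, X, epsilon) {
  eta <- drop(X %*% beta)
  pi <- plogis(eta)
  ll <- 0
  for (i in seq_along(y)) {
    pr <- 0
    for (lam in c(0, 1)) {
      p_obs <- if (lam == 1) f[i] else epsilon
      p_y <- if (y[i] == 1) p_obs else 1 - p_obs
      p_lam <- if (lam == 1) pi[i] else 1 - pi[i]
      pr <- pr + p_y * p_lam
    }
    ll <- ll + log(pr)
  }
  ll
}

# Firth-penalized weighted logistic regression by direct BFGS maximization
# (outcomes may be fractional)
firth_oracle <- function(p, X, init = rep(0, ncol(X))) {
  pen <- function(b) {
    eta <- drop(X %*% b)
    w <- plogis(eta)
    ld <- determinant(crossprod(X * (w * (1 - w)), X), logarithm = TRUE)
    sum(p * eta - log1p(exp(eta))) + 0.5 * as.numeric(ld$modulus)
  }
  o <- stats::optim(init, function(b) -pen(b), method = "BFGS",
                    control = list(reltol = 1e-15, maxit = 500))
  list(beta = o$par, objective = -o$value)
}

# plain logistic regression by hand-written IRLS; returns the log-likelihood
irls_logistic <- function(y, X, offset = 0, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-10)
    z <- eta - offset + (y - mu) / W
    beta_new <- solve(crossprod(X * W, X), crossprod(X * W, z))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta) + offset
  mu <- plogis(eta)
  list(beta = beta,
       loglik = sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300))))
}

# small random fixture from the generative model with an arbitrary smooth
# monotone curve
make_fixture <- function(seed, n = 30, epsilon = 0, beta = c(0.2, 0.8)) {
  withr::with_seed(seed, {
    M <- sort(runif(n, 5, 45))
    X <- cbind(1, rnorm(n))
    f <- plogis(-1.5 + 0.25 * M)
    lam <- rbinom(n, 1, plogis(drop(X %*% beta)))
    y <- ifelse(lam == 1, rbinom(n, 1, f), rbinom(n, 1, epsilon))
    list(y = y, X = X, M = M, f = f)
  })
}
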