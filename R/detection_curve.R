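# Monotone detection curves: probability of detecting a truly present gene as
# a non-decreasing function of a scalar genome-quality variable (coverage,
# completion, ...). Two nonparametric representations are supported:
#   - "ispline": logit f(m) = alpha0 + sum_j alpha_j I_j(m), alpha_j >= 0,
#     where I_j are I-spline (integrated M-spline) basis functions, and
#   - "isotone": a non-decreasing step function on the observed m values.
# Both are evaluated with constant extrapolation outside the observed range
# and with logit values clipped to +/- logit_cap.

#' I-spline basis matrix
#'
#' Builds the I-spline (integrated M-spline) basis of Ramsay (1988) on the
#' range of `x`. I-splines are non-decreasing from 0 to 1, so any non-negative
#' combination is monotone non-decreasing. The basis is computed through the
#' B-spline partial-sum identity: the integral of the j-th degree-`degree`
#' M-spline equals the sum of B-splines of degree `degree + 1` with index
#' greater than j on the augmented knot sequence.
#'
#' @param x Evaluation points.
#' @param df Number of basis functions `k`.
#' @param degree M-spline degree (the I-splines are piecewise polynomials of
#'   degree `degree + 1`).
#' @param boundary Length-2 numeric range; values outside are clamped
#'   (constant extrapolation).
#' @param iknots Interior knots; defaults to `df - degree - 1` quantiles of
#'   `x` (none under the default `df = 4`, `degree = 3`).
#' @return Numeric matrix, `length(x)` by `df`, with attributes `"iknots"`,
#'   `"degree"`, `"boundary"`.
#' @export
ispline_basis <- function(x, df = 4L, degree = 3L, boundary = range(x),
                          iknots = NULL) {
  stopifnot(df >= degree + 1, boundary[2] > boundary[1])
  if (is.null(iknots)) {
    n_ik <- df - degree - 1L
    iknots <- if (n_ik > 0) {
      stats::quantile(x, probs = seq_len(n_ik) / (n_ik + 1), names = FALSE)
    } else {
      numeric(0)
    }
  }
  stopifnot(length(iknots) == df - degree - 1)
  xc <- clamp(x, boundary[1], boundary[2])
  ord2 <- degree + 2L  # B-spline order for the integrated basis
  knots2 <- c(rep(boundary[1], ord2), iknots, rep(boundary[2], ord2))
  B <- splines::splineDesign(knots2, xc, ord = ord2, outer.ok = FALSE)
  n_b <- ncol(B)              # df + 1 B-splines of degree degree + 1
  stopifnot(n_b == df + 1L)
  # I_j(x) = sum_{l > j} B_l(x)
  I <- B %*% outer(seq_len(n_b), seq_len(df), FUN = ">")
  storage.mode(I) <- "double"
  structure(I, iknots = iknots, degree = degree, boundary = boundary)
}

new_ispline_curve <- function(alpha0, alpha, iknots, degree, boundary,
                              logit_cap) {
  stopifnot(all(alpha >= 0))
  structure(
    list(
      f_class = "ispline", alpha0 = alpha0, alpha = alpha,
      iknots = iknots, degree = degree, boundary = boundary,
      logit_cap = logit_cap
    ),
    class = c("ispline_curve", "detection_curve")
  )
}

new_isotone_curve <- function(breaks, values, logit_cap) {
  stopifnot(length(breaks) == length(values), !is.unsorted(breaks),
            !is.unsorted(values))
  structure(
    list(
      f_class = "isotone", breaks = breaks, values = values,
      logit_cap = logit_cap
    ),
    class = c("isotone_curve", "detection_curve")
  )
}

new_linear_curve <- function(coef, logit_cap) {
  structure(
    list(f_class = "linear", coef = coef, logit_cap = logit_cap),
    class = c("linear_curve", "detection_curve")
  )
}

#' Evaluate a detection curve
#'
#' Returns the logit-scale and probability-scale detection values at quality
#' values `m`. Logits are clipped to `+/- logit_cap`; outside the fitted range
#' the curve extrapolates as a constant, preserving monotonicity.
#'
#' @param curve A `detection_curve` object from [lp_fit()] or one of the
#'   M-step updates.
#' @param m Numeric vector (or matrix for the linear parametric class) of
#'   quality values.
#' @return List with components `ft` (logit scale) and `f` (probability
#'   scale).
#' @export
eval_curve <- function(curve, m) {
  UseMethod("eval_curve")
}

#' @export
eval_curve.ispline_curve <- function(curve, m) {
  B <- ispline_basis(m, df = length(curve$alpha), degree = curve$degree,
                     boundary = curve$boundary, iknots = curve$iknots)
  ft <- clamp(drop(curve$alpha0 + B %*% curve$alpha),
              -curve$logit_cap, curve$logit_cap)
  list(ft = ft, f = expit(ft))
}

#' @export
eval_curve.isotone_curve <- function(curve, m) {
  idx <- pmax(findInterval(m, curve$breaks), 1L)
  ft <- clamp(curve$values[idx], -curve$logit_cap, curve$logit_cap)
  list(ft = ft, f = expit(ft))
}

#' @export
eval_curve.linear_curve <- function(curve, m) {
  Mm <- as.matrix(m)
  ft <- clamp(drop(cbind(1, Mm) %*% curve$coef),
              -curve$logit_cap, curve$logit_cap)
  list(ft = ft, f = expit(ft))
}

#' @export
eval_curve.fixed_curve <- function(curve, m) {
  f <- curve$fn(if (is.matrix(m)) m[, 1] else m)
  list(ft = logit(f), f = f)
}

#' @export
eval_curve.default <- function(curve, m) {
  stop("not a fitted detection curve")
}

#' Fixed (known) detection curve
#'
#' Wraps a known detection-probability function so it can be supplied to
#' [lp_fit()] via `fixed_curve`, bypassing curve estimation entirely. Useful
#' when the coverage-to-detection relationship has been measured directly
#' (e.g. by read subsampling of an isolate genome), and for reduction checks:
#' with `epsilon = 0` and `fixed_detection_curve(function(m) rep(1, length(m)))`
#' the model collapses to Firth-penalized logistic regression of the observed
#' detections on the covariates.
#'
#' @param fn Function mapping quality values to detection probabilities in
#'   `[0, 1]`; monotonicity is the caller's responsibility.
#' @return A `detection_curve` of class `"fixed_curve"`.
#' @export
fixed_detection_curve <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(f_class = "fixed", fn = fn),
            class = c("fixed_curve", "detection_curve"))
}

# constant curve at the p-weighted mean of y; used to initialize the EM and
# as the fallback when the constrained optimizer fails
constant_curve_logit <- function(y, p, cap) {
  mu <- sum(p * y) / sum(p)
  clamp(logit(clamp(mu, 1e-8, 1 - 1e-8)), -cap, cap)
}

# weighted Bernoulli log-likelihood of logits eta with weights p and outcome y
# (first term of the expected complete-data log-likelihood)
wbern_obj <- function(eta, p, y) {
  sum(p * (y * eta - log1pexp(eta)))
}

#' M-step update of the detection curve, I-spline class
#'
#' Maximizes the detection term of the expected complete-data log-likelihood,
#' `sum_i p_i [y_i ft(m_i) - log(1 + exp(ft(m_i)))]`, over curves
#' `ft = alpha0 + sum_j alpha_j I_j(m)` with `alpha_j >= 0`, i.e. a weighted
#' logistic regression on an I-spline basis with non-negative non-intercept
#' coefficients (box-constrained L-BFGS-B). Logits are clamped to
#' `+/- logit_cap` inside the objective so the optimized criterion is exactly
#' the one used for likelihood evaluation. Falls back to the constant fit if
#' the optimizer fails, and never returns a curve whose objective is below the
#' constant fit's.
#'
#' @param m Quality values (length n).
#' @param p Posterior presence probabilities, clamped to (0, 1).
#' @param y Binary detection indicators.
#' @param control An [lp_control()] object.
#' @param basis Optional precomputed [ispline_basis()] of `m` (an
#'   optimization for repeated fits on the same `m`).
#' @param init Optional warm-start coefficient vector `c(alpha0, alpha)`.
#' @return A `detection_curve` of class `"ispline_curve"` with attributes
#'   `"objective"` and `"converged"`.
#' @export
update_f_ispline <- function(m, p, y, control = lp_control(), basis = NULL,
                             init = NULL) {
  cap <- control$logit_cap
  if (is.null(basis)) {
    basis <- ispline_basis(m, df = control$spline_df,
                           degree = control$spline_degree)
  }
  K <- ncol(basis)
  B <- unclass(basis)

  negobj <- function(par) {
    eta <- clamp(par[1] + drop(B %*% par[-1]), -cap, cap)
    -wbern_obj(eta, p, y)
  }
  neggrad <- function(par) {
    eta_raw <- par[1] + drop(B %*% par[-1])
    inside <- abs(eta_raw) < cap
    d <- p * (y - expit(clamp(eta_raw, -cap, cap))) * inside
    -c(sum(d), drop(crossprod(B, d)))
  }

  par0 <- if (is.null(init)) c(constant_curve_logit(y, p, cap), rep(0, K))
          else init
  fit <- tryCatch(
    stats::optim(par0, fn = negobj, gr = neggrad, method = "L-BFGS-B",
                 lower = c(-2 * cap, rep(0, K)),
                 upper = rep(2 * cap, K + 1),
                 control = list(maxit = 200, factr = 1e6)),
    error = function(e) NULL
  )

  a0_const <- constant_curve_logit(y, p, cap)
  obj_const <- wbern_obj(rep(a0_const, length(y)), p, y)
  if (is.null(fit)) {
    warning("constrained I-spline optimizer failed; using constant fit")
    par <- c(a0_const, rep(0, K))
    obj <- obj_const
    conv <- FALSE
  } else {
    # project onto the feasible box (L-BFGS-B can overshoot by rounding error)
    par <- clamp(fit$par, c(-2 * cap, rep(0, K)), rep(2 * cap, K + 1))
    obj <- -negobj(par)
    conv <- fit$convergence == 0
    if (obj < obj_const) {  # never below the constant fit
      par <- c(a0_const, rep(0, K))
      obj <- obj_const
    }
  }
  curve <- new_ispline_curve(par[1], par[-1], attr(basis, "iknots"),
                             attr(basis, "degree"), attr(basis, "boundary"),
                             cap)
  # fitted logits at the training m, cached for the EM loop
  attr(curve, "ft") <- clamp(par[1] + drop(B %*% par[-1]), -cap, cap)
  attr(curve, "objective") <- obj
  attr(curve, "converged") <- conv
  curve
}

# 1-D block maximizer for the isotonic update: the pooled objective
#   Spy * u - Sp * log(1 + exp(u)) - nb * cosh((u / a)^2)
# is strictly concave in u (the cosh penalty is convex), so its stationary
# point is found by a vectorized bisection-safeguarded Newton on the score
#   g(u) = Spy - Sp expit(u) - nb (2u / a^2) sinh((u / a)^2),
# clamped to [-cap, cap]. All blocks are solved simultaneously.
solve_block <- function(Spy, Sp, nb, a, cap) {
  g <- function(u) {
    Spy - Sp * expit(u) - nb * (2 * u / a^2) * sinh((u / a)^2)
  }
  out <- numeric(length(Spy))
  at_lo <- g(rep(-cap, length(Spy))) <= 0
  at_hi <- g(rep(cap, length(Spy))) >= 0
  out[at_lo] <- -cap
  out[at_hi] <- cap
  act <- which(!at_lo & !at_hi)
  if (length(act)) {
    Spy <- Spy[act]; Sp <- Sp[act]; nb <- nb[act]
    lo <- rep(-cap, length(act)); hi <- rep(cap, length(act))
    u <- rep(0, length(act))
    for (it in 1:200) {
      s <- expit(u)
      g1 <- Spy - Sp * s - nb * (2 * u / a^2) * sinh((u / a)^2)
      pos <- g1 > 0
      lo[pos] <- u[pos]
      hi[!pos] <- u[!pos]
      g2 <- -(Sp * s * (1 - s) +
                nb * ((2 / a^2) * sinh((u / a)^2) +
                        (2 * u / a^2)^2 * cosh((u / a)^2)))
      un <- u - g1 / g2
      bad <- !is.finite(un) | un <= lo | un >= hi
      un[bad] <- (lo[bad] + hi[bad]) / 2
      done <- max(abs(un - u)) < 1e-12
      u <- un
      if (done) break
    }
    out[act] <- u
  }
  out
}

#' M-step update of the detection curve, isotonic class
#'
#' Maximizes `sum_i { p_i [y_i ft_i - log(1 + exp(ft_i))] - cosh((ft_i/a)^2) }`
#' over logit vectors `ft` non-decreasing in `m`, via pool-adjacent-violators
#' with an exact 1-D concave solve per block (the `-cosh` penalty keeps the
#' fitted logits bounded; `a = cosh_a`, default 50). Ties in `m` share a
#' fitted value.
#'
#' @inheritParams update_f_ispline
#' @return A `detection_curve` of class `"isotone_curve"` with attribute
#'   `"objective"`.
#' @export
update_f_isotone <- function(m, p, y, control = lp_control(f_class = "isotone"),
                             basis = NULL, init = NULL) {
  cap <- control$logit_cap
  a <- control$cosh_a
  ord <- order(m)
  mu <- unique(m[ord])
  grp <- match(m, mu)

  # per-distinct-m sufficient statistics
  Spy <- as.numeric(rowsum(p * y, grp))
  Sp <- as.numeric(rowsum(p, grp))
  nb <- as.numeric(table(grp))

  # PAVA: maintain a stack of blocks with non-decreasing solutions; all
  # singleton solutions are pre-solved in one vectorized pass
  k <- length(mu)
  sol1 <- solve_block(Spy, Sp, nb, a, cap)
  b_spy <- numeric(k); b_sp <- numeric(k); b_n <- numeric(k)
  b_val <- numeric(k); b_last <- integer(k)
  top <- 0L
  for (j in seq_len(k)) {
    top <- top + 1L
    b_spy[top] <- Spy[j]; b_sp[top] <- Sp[j]; b_n[top] <- nb[j]
    b_val[top] <- sol1[j]
    b_last[top] <- j
    while (top > 1L && b_val[top - 1L] > b_val[top] + 1e-12) {
      b_spy[top - 1L] <- b_spy[top - 1L] + b_spy[top]
      b_sp[top - 1L] <- b_sp[top - 1L] + b_sp[top]
      b_n[top - 1L] <- b_n[top - 1L] + b_n[top]
      b_last[top - 1L] <- b_last[top]
      top <- top - 1L
      b_val[top] <- solve_block(b_spy[top], b_sp[top], b_n[top], a, cap)
    }
  }
  values <- numeric(k)
  start <- 1L
  for (s in seq_len(top)) {
    values[start:b_last[s]] <- b_val[s]
    start <- b_last[s] + 1L
  }
  values <- cummax(values)  # guard against 1e-12 slack in the merge rule

  curve <- new_isotone_curve(mu, values, cap)
  ft <- values[grp]
  attr(curve, "ft") <- ft
  attr(curve, "objective") <-
    wbern_obj(ft, p, y) - sum(cosh((ft / a)^2))
  curve
}

# unconstrained weighted logistic fit on the columns of a quality matrix;
# the parametric fallback that supports q >= 2 quality variables
update_f_linear <- function(m, p, y, control = lp_control(f_class = "linear"),
                            basis = NULL, init = NULL) {
  Mm <- as.matrix(m)
  Z <- cbind(1, Mm)
  cap <- control$logit_cap
  # same clamped objective as the spline update, no penalty (the EM monitor
  # carries the Firth term for beta only); divergent fits flatten at the cap
  negobj <- function(par) {
    eta <- clamp(drop(Z %*% par), -cap, cap)
    -wbern_obj(eta, p, y)
  }
  neggrad <- function(par) {
    eta_raw <- drop(Z %*% par)
    d <- p * (y - expit(clamp(eta_raw, -cap, cap))) * (abs(eta_raw) < cap)
    -drop(crossprod(Z, d))
  }
  par0 <- init %||% rep(0, ncol(Z))
  fit <- tryCatch(
    stats::optim(par0, fn = negobj, gr = neggrad, method = "L-BFGS-B",
                 lower = rep(-1e6, ncol(Z)), upper = rep(1e6, ncol(Z)),
                 control = list(maxit = 200, factr = 1e6)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("linear detection-curve optimizer failed; using constant fit")
    par <- c(constant_curve_logit(y, p, cap), rep(0, ncol(Mm)))
    conv <- FALSE
  } else {
    par <- fit$par
    conv <- fit$convergence == 0
  }
  curve <- new_linear_curve(par, cap)
  attr(curve, "ft") <- clamp(drop(Z %*% par), -cap, cap)
  attr(curve, "objective") <- -negobj(par)
  attr(curve, "converged") <- conv
  curve
}

update_f <- function(m, p, y, control, basis = NULL, init = NULL) {
  switch(control$f_class,
    ispline = update_f_ispline(m, p, y, control, basis, init),
    isotone = update_f_isotone(m, p, y, control, basis, init),
    linear = update_f_linear(m, p, y, control, basis, init)
  )
}

curve_warm_start <- function(curve) {
  if (inherits(curve, "ispline_curve")) c(curve$alpha0, curve$alpha)
  else if (inherits(curve, "linear_curve")) curve$coef
  else NULL
}
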