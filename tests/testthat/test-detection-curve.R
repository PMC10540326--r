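test_that("I-spline basis agrees with numerical integration of the M-spline basis", {
  for (cfg in list(list(df = 4L, degree = 3L), list(df = 6L, degree = 3L),
                   list(df = 4L, degree = 2L))) {
    x <- seq(10, 40, length.out = 50)
    iknots <- if (cfg$df - cfg$degree - 1 > 0) {
      quantile(x, seq_len(cfg$df - cfg$degree - 1) /
                 (cfg$df - cfg$degree), names = FALSE)
    } else numeric(0)
    I <- ispline_basis(x, df = cfg$df, degree = cfg$degree,
                       boundary = c(10, 40), iknots = iknots)
    # M-spline basis: normalized B-splines of degree `degree`
    ord <- cfg$degree + 1L
    kn <- c(rep(10, ord), iknots, rep(40, ord))
    mspline <- function(t, j) {
      b <- splines::splineDesign(kn, t, ord = ord, outer.ok = TRUE)
      b[, j] * ord / (kn[j + ord] - kn[j])
    }
    for (j in seq_len(cfg$df)) {
      Iq <- vapply(x, function(xx) {
        integrate(mspline, lower = 10, upper = xx, j = j,
                  rel.tol = 1e-11, subdivisions = 400L)$value
      }, numeric(1))
      expect_lt(max(abs(I[, j] - Iq)), 1e-8)
    }
    # each I-spline rises from 0 to 1 and is non-decreasing
    expect_equal(unname(I[1, ]), rep(0, cfg$df))
    expect_equal(unname(I[50, ]), rep(1, cfg$df), tolerance = 1e-10)
    expect_true(all(diff(I) > -1e-12))
  }
})

test_that("curve evaluation: constant curve, monotonicity, extrapolation", {
  cap <- 10
  flat <- latentpan:::new_ispline_curve(0, rep(0, 4), numeric(0), 3L,
                                        c(10, 40), cap)
  ev <- eval_curve(flat, c(5, 10, 25, 40, 80))
  expect_equal(ev$ft, rep(0, 5))
  expect_equal(ev$f, rep(0.5, 5))

  set.seed(21)
  for (r in 1:5) {
    crv <- latentpan:::new_ispline_curve(rnorm(1), rexp(4), numeric(0), 3L,
                                         c(10, 40), cap)
    m <- sort(runif(40, 0, 50))
    ft <- eval_curve(crv, m)$ft
    expect_true(all(diff(ft) >= -1e-12))
    expect_true(all(abs(ft) <= cap))
    # constant extrapolation beyond the boundary
    expect_equal(eval_curve(crv, 0)$ft, eval_curve(crv, 10)$ft)
    expect_equal(eval_curve(crv, 99)$ft, eval_curve(crv, 40)$ft)
  }

  expect_error(eval_curve(list(), 1), "not a fitted detection curve")
})

test_that("I-spline M-step recovers a constant curve when detection is unrelated to quality", {
  n <- 200
  # one detection and one non-detection at every distinct quality value, so
  # the exact weighted MLE is the constant 1/2 regardless of curve shape
  m <- rep(seq(10, 40, length.out = n / 2), each = 2)
  y <- rep(c(0, 1), n / 2)
  p <- rep(1, n)
  crv <- update_f_ispline(m, p, y, lp_control())
  f <- eval_curve(crv, m)$f
  expect_lt(max(abs(f - mean(y))), 1e-3)
})

test_that("I-spline M-step hits the logit cap when every gene is detected", {
  n <- 50
  m <- seq(10, 40, length.out = n)
  crv <- update_f_ispline(m, p = rep(1, n), y = rep(1, n), lp_control())
  ev <- eval_curve(crv, m)
  expect_true(all(ev$ft == 10))
  expect_true(all(ev$f >= plogis(10 - 1e-6)))
})

test_that("I-spline M-step matches a general constrained optimizer", {
  fx <- make_fixture(7, n = 30)
  p <- runif(30, 0.05, 0.95)
  ctl <- lp_control()
  basis <- ispline_basis(fx$M, df = 4, degree = 3)
  crv <- update_f_ispline(fx$M, p, fx$y, ctl, basis = basis)

  # oracle: exact active-set enumeration. The objective is concave, so the
  # constrained maximum is attained by fixing some subset of the
  # non-negativity constraints active (coefficient = 0), maximizing freely
  # over the rest, and keeping the best feasible solution.
  B <- unclass(basis)
  obj_free <- function(par_free, free_idx) {
    alpha <- numeric(4)
    alpha[free_idx] <- par_free[-1]
    eta <- pmin(pmax(par_free[1] + drop(B %*% alpha), -10), 10)
    -sum(p * (fx$y * eta - log1p(exp(eta))))
  }
  best <- -Inf
  for (k in 0:4) {
    for (free_idx in combn(4, k, simplify = FALSE)) {
      o <- optim(rep(0, k + 1), obj_free, free_idx = free_idx,
                 method = "BFGS", control = list(reltol = 1e-15,
                                                 maxit = 1000))
      if (all(o$par[-1] >= -1e-9)) best <- max(best, -o$value)
    }
  }
  expect_lt(abs(attr(crv, "objective") - best), 1e-6)
})

test_that("isotonic M-step: pooled solution solves the 1-D penalized score equation", {
  n <- 12
  m <- seq(5, 45, length.out = n)
  p <- rep(0.6, n)
  y <- rep(1, n)  # all p_i y_i equal, all p_i equal -> constant solution
  ctl <- lp_control(f_class = "isotone")
  crv <- update_f_isotone(m, p, y, ctl)
  expect_equal(length(unique(crv$values)), 1L)
  u <- crv$values[1]
  # 1-D oracle: root of the pooled penalized score
  score <- function(u) {
    sum(p * y) - sum(p) * plogis(u) - n * (2 * u / 50^2) * sinh((u / 50)^2)
  }
  u_star <- uniroot(score, c(-10, 10), tol = 1e-12)$root
  expect_equal(u, u_star, tolerance = 1e-8)
})

test_that("isotonic M-step leaves non-violating inputs unpooled and is always monotone", {
  # per-point solutions already non-decreasing -> PAVA must not pool
  m <- c(1, 2, 3, 4)
  p <- rep(0.5, 4)
  y <- c(0, 0, 1, 1)
  ctl <- lp_control(f_class = "isotone")
  crv <- update_f_isotone(m, p, y, ctl)
  single <- latentpan:::solve_block(p * y, p, rep(1, 4), 50, 10)
  expect_true(!is.unsorted(single))
  expect_equal(crv$values, single, tolerance = 1e-10)

  # monotone on random fixtures, and ties in m share a fitted value
  for (s in 1:8) {
    fx <- make_fixture(100 + s, n = 25)
    p <- withr::with_seed(s, runif(25, 0.01, 0.99))
    m <- fx$M
    m[3] <- m[4]  # force a tie
    crv <- update_f_isotone(m, p, fx$y, ctl)
    expect_true(!is.unsorted(crv$values))
    ft <- eval_curve(crv, m)$ft
    expect_equal(ft[3], ft[4])
  }
})

test_that("both M-step updates never decrease their detection term", {
  for (s in 1:6) {
    fx <- make_fixture(200 + s, n = 40)
    p <- withr::with_seed(s, runif(40, 0.01, 0.99))
    ctl_i <- lp_control()
    ctl_f <- lp_control(f_class = "isotone")
    # start from an arbitrary curve and check the update improves on it
    start <- latentpan:::new_ispline_curve(-1, rep(0.2, 4), numeric(0), 3L,
                                           range(fx$M), 10)
    obj0 <- latentpan:::wbern_obj(eval_curve(start, fx$M)$ft, p, fx$y)
    crv_i <- update_f_ispline(fx$M, p, fx$y, ctl_i,
                              init = c(-1, rep(0.2, 4)))
    obj_i <- latentpan:::wbern_obj(eval_curve(crv_i, fx$M)$ft, p, fx$y)
    expect_gte(obj_i, obj0 - 1e-10)
    crv_f <- update_f_isotone(fx$M, p, fx$y, ctl_f)
    obj_f <- latentpan:::wbern_obj(eval_curve(crv_f, fx$M)$ft, p, fx$y) -
      sum(cosh((eval_curve(crv_f, fx$M)$ft / 50)^2))
    obj0_pen <- obj0 - sum(cosh((eval_curve(start, fx$M)$ft / 50)^2))
    expect_gte(obj_f, obj0_pen - 1e-10)
  }
})
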