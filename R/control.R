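#' Control parameters for the latent presence model
#'
#' Collects the hyperparameters and numerical settings used by [lp_fit()] and
#' the testing functions. `epsilon` is the probability that a gene is observed
#' in a genome in which it is truly absent (contamination / index-switching
#' crosstalk); it is a fixed hyperparameter, never estimated, because `epsilon`
#' and the detection curve are not jointly identifiable.
#'
#' @param epsilon Probability in `[0, 1)` of observing a truly absent gene.
#'   Default 0, appropriate for manually refined MAGs; use values such as the
#'   maximum CheckM contamination across genomes otherwise.
#' @param t_max Maximum number of EM iterations.
#' @param delta Convergence threshold: the EM stops once the relative increase
#'   of the penalized observed-data log-likelihood is below `delta` for
#'   `consecutive_steps` consecutive iterations.
#' @param min_iter Minimum number of EM iterations before convergence can be
#'   declared (default 16).
#' @param consecutive_steps Number of consecutive small-increase iterations
#'   required to declare convergence (default 5).
#' @param f_class Class of monotone detection curves: `"ispline"` (linear
#'   combinations of I-spline basis functions with non-negative coefficients
#'   plus a free intercept; the default) or `"isotone"` (bounded non-decreasing
#'   step functions fit by pool-adjacent-violators with a cosh penalty).
#' @param spline_df Number of I-spline basis functions `k` (default 4).
#' @param spline_degree Polynomial degree of the I-spline basis (default 3).
#' @param cosh_a Scale `a` of the `-cosh((x / a)^2)` penalty that bounds the
#'   isotonic fit (default 50).
#' @param logit_cap Hard bound on the absolute logit-scale detection values
#'   (default 10), so fitted detection probabilities stay within
#'   `[expit(-10), expit(10)]`.
#'
#' @return A list of class `"lp_control"`.
#' @examples
#' lp_control(epsilon = 0.05, delta = 0.01)
#' @export
lp_control <- function(epsilon = 0,
                       t_max = 1000,
                       delta = 0.01,
                       min_iter = 16,
                       consecutive_steps = 5,
                       f_class = c("ispline", "isotone", "linear"),
                       spline_df = 4,
                       spline_degree = 3,
                       cosh_a = 50,
                       logit_cap = 10) {
  f_class <- match.arg(f_class)
  stopifnot(
    is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0, epsilon < 1,
    is.numeric(delta), delta > 0,
    t_max >= 1, min_iter >= 1, t_max >= min_iter,
    consecutive_steps >= 1,
    spline_df >= 1, spline_degree >= 1,
    cosh_a > 0, logit_cap > 0
  )
  structure(
    list(
      epsilon = epsilon, t_max = as.integer(t_max), delta = delta,
      min_iter = as.integer(min_iter),
      consecutive_steps = as.integer(consecutive_steps),
      f_class = f_class, spline_df = as.integer(spline_df),
      spline_degree = as.integer(spline_degree),
      cosh_a = cosh_a, logit_cap = logit_cap
    ),
    class = "lp_control"
  )
}
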