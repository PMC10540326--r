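# Numerically safe link helpers used throughout the model code.

expit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

# log(1 + exp(x)) without overflow for large x
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# posterior probabilities are clamped before M-steps for weighted-logistic
# stability; exact 0/1 values arise when epsilon = 0
P_CLAMP <- 1e-10

`%||%` <- function(a, b) if (is.null(a)) b else a
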