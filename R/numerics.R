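# Quadrature rules, numerical design-row approximations, multivariate
# normal sampling and monotone root finding shared by the other modules.

# 15-point Gauss-Kronrod rule on [-1, 1]: the Kronrod extension of 7-point
# Gauss.  Constants are the published QUADPACK values, embedded as literals
# so results are bit-stable across platforms.
.gk15_x <- c(0.991455371120813, 0.949107912342759, 0.864864423359769,
             0.741531185599394, 0.586087235467691, 0.405845151377397,
             0.207784955007898, 0.000000000000000)
.gk15_w <- c(0.022935322010529, 0.063092092629979, 0.104790010322250,
             0.140653259715525, 0.169004726639267, 0.190350578064785,
             0.204432940075298, 0.209482141084728)

#' Quadrature rules
#'
#' `gk15_rule()` returns the 15-point Gauss-Kronrod rule on \[-1, 1\];
#' `gauss_hermite_rule(m)` returns the m-point Gauss-Hermite rule for
#' integrals of the form \eqn{\int e^{-x^2} f(x)\,dx \approx \sum_u w_u
#' f(x_u)} ("physicists" convention).  Gauss-Hermite nodes and weights are
#' computed by the Golub-Welsch eigendecomposition of the Jacobi matrix.
#'
#' @param m integer order (number of nodes) of the Gauss-Hermite rule.
#' @return A list with components `nodes`, `weights` and `kind`.
#' @examples
#' r <- gk15_rule()
#' sum(r$weights)            # 2, the length of [-1, 1]
#' g <- gauss_hermite_rule(5)
#' sum(g$weights * g$nodes^2) # sqrt(pi)/2, the second normal-kernel moment
#' @export
gk15_rule <- function() {
  list(nodes   = c(-.gk15_x[1:7], .gk15_x[8], rev(.gk15_x[1:7])),
       weights = c(.gk15_w[1:7], .gk15_w[8], rev(.gk15_w[1:7])),
       kind    = "gauss_kronrod_15")
}

#' @rdname gk15_rule
#' @export
gauss_hermite_rule <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1, m == round(m))
  m <- as.integer(m)
  if (m == 1L)
    return(list(nodes = 0, weights = sqrt(pi), kind = "gauss_hermite"))
  i <- seq_len(m - 1L)
  J <- matrix(0, m, m)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes   = e$values[ord],
       weights = sqrt(pi) * e$vectors[1L, ord]^2,
       kind    = "gauss_hermite")
}

#' Integrate a function with the 15-point Gauss-Kronrod rule
#'
#' Fixed (non-adaptive) quadrature of `f` over \[a, b\]; exact for
#' polynomials up to degree 22.
#'
#' @param f vectorized real function of one argument.
#' @param a,b integration limits, `a <= b`.
#' @return The approximate integral, a scalar.
#' @export
gk15_integrate <- function(f, a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (a > b) stop("gk15_integrate: lower limit exceeds upper limit")
  r <- gk15_rule()
  half <- (b - a) / 2
  fx <- f(half * r$nodes + (a + b) / 2)
  if (any(!is.finite(fx)))
    stop("gk15_integrate: integrand not finite at a quadrature node")
  half * sum(r$weights * fx)
}

#' Central-difference approximation of a design-row derivative
#'
#' Approximates the time derivative of a (vector-valued) design-row
#' function componentwise as \eqn{(x(t+\epsilon) - x(t-\epsilon)) /
#' (2\epsilon)}.  Exact for components quadratic in t; for cubic
#' components the absolute error is exactly \eqn{\epsilon^2}-scaled
#' (O(1e-6) at the default step).  If `t - eps` falls below
#' `lower`, a one-sided forward difference is used with a warning.
#'
#' @param x_fun function of time returning a numeric row vector.
#' @param t evaluation time.
#' @param eps step size (default 1e-3).
#' @param lower lower domain bound (default 0).
#' @return Numeric vector: the approximate derivative row.
#' @export
central_difference_row <- function(x_fun, t, eps = 1e-3, lower = 0) {
  stopifnot(eps > 0)
  if (t - eps < lower) {
    warning("central_difference_row: t - eps below domain; using one-sided difference")
    return((x_fun(t + eps) - x_fun(t)) / eps)
  }
  (x_fun(t + eps) - x_fun(t - eps)) / (2 * eps)
}

#' Componentwise Gauss-Kronrod integral of a design row over \[0, t\]
#'
#' @inheritParams central_difference_row
#' @return Numeric vector of the same length as `x_fun(t)`.
#' @export
cumulative_row <- function(x_fun, t) {
  stopifnot(t >= 0)
  if (t == 0) return(0 * x_fun(0))
  r <- gk15_rule()
  half <- t / 2
  vals <- vapply(half * r$nodes + half, x_fun, x_fun(t))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  if (any(!is.finite(vals)))
    stop("cumulative_row: design row not finite at a quadrature node")
  as.numeric(half * (vals %*% r$weights))
}

#' Sample from a multivariate normal distribution
#'
#' Eigendecomposition-based sampler that accepts any symmetric positive
#' semi-definite covariance (including exactly singular ones, e.g. the
#' zero matrix).  Reproducible given `seed`.
#'
#' @param mean numeric mean vector.
#' @param cov symmetric PSD covariance matrix.
#' @param count number of draws.
#' @param seed optional integer seed; when supplied, the draw is made in a
#'   local RNG state so the caller's stream is untouched.
#' @return `count` x `length(mean)` matrix of draws.
#' @export
sample_mvnormal <- function(mean, cov, count, seed = NULL) {
  stopifnot(count >= 1)
  d <- length(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("sample_mvnormal: covariance is not symmetric")
  cov <- (cov + t(cov)) / 2
  e <- eigen(cov, symmetric = TRUE)
  tol <- -1e-10 * max(1, max(abs(e$values)))
  if (min(e$values) < tol)
    stop(sprintf("sample_mvnormal: covariance not PSD (smallest eigenvalue %.3e)",
                 min(e$values)))
  ev <- pmax(e$values, 0)
  z <- with_seed(seed, matrix(stats::rnorm(count * d), count, d))
  sweep(z %*% (t(e$vectors) * sqrt(ev)), 2L, mean, `+`)
}

#' Invert a nondecreasing function
#'
#' Finds `t` in `bracket` with `fn(t) == target` to absolute tolerance
#' 1e-8.  If `fn(hi) < target` there is no root in the bracket and the
#' sentinel `NA_real_` is returned (callers typically censor
#' administratively in that case).
#'
#' @param fn continuous nondecreasing scalar function.
#' @param target target value.
#' @param bracket length-2 numeric `c(lo, hi)`.
#' @return The root, or `NA_real_` when `fn(hi) < target`.
#' @export
solve_increasing <- function(fn, target, bracket) {
  stopifnot(length(bracket) == 2L, bracket[1] <= bracket[2])
  flo <- fn(bracket[1]); fhi <- fn(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi))
    stop("solve_increasing: fn not finite at bracket endpoints")
  if (flo > target + 1e-8)
    stop("solve_increasing: fn(lo) exceeds target; bracket invalid")
  if (fhi < target) return(NA_real_)
  if (flo >= target - 1e-12) return(bracket[1])
  root <- stats::uniroot(function(t) fn(t) - target,
                         interval = bracket, tol = 1e-12)$root
  if (abs(fn(root) - target) > 1e-8)
    stop("solve_increasing: root did not reach tolerance 1e-8")
  root
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).  Restores the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-index substream seed below 2^31, so per-subject draws
# are reproducible independently of iteration order.  Multiplications stay
# below 2^53, keeping the arithmetic exact in doubles.
derive_seed <- function(base, index) {
  b <- as.numeric(base) %% 94906249
  ((b * 22695477 + as.numeric(index) * 7919 + 1) %% 2147483629) + 1
}
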