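# Subject-specific and marginal time-varying overall treatment-effect
# curves, the weighted-average effect over a trial window, and the
# simulation-based standard-error scheme with percentile bands.

new_effect_curve <- function(times, hr, flavor, lo = NULL, hi = NULL) {
  stopifnot(all(hr > 0))
  structure(list(times = times, hr = hr, lo = lo, hi = hi,
                 flavor = flavor), class = "jm_effect_curve")
}

#' @export
print.jm_effect_curve <- function(x, ...) {
  cat("Overall treatment-effect curve (", x$flavor, "), ",
      length(x$times), " time points\n", sep = "")
  df <- data.frame(time = x$times, hr = x$hr)
  if (!is.null(x$lo)) { df$lo <- x$lo; df$hi <- x$hi }
  print(utils::head(round(df, 4), 8))
  if (length(x$times) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.jm_effect_curve <- function(x, ...) {
  df <- data.frame(time = x$times, hr = x$hr, flavor = x$flavor)
  if (!is.null(x$lo)) { df$lo <- x$lo; df$hi <- x$hi }
  df
}

#' Time-varying overall treatment-effect curves
#'
#' The overall treatment effect is the treatment-vs-control hazard
#' ratio aggregating the direct effect on the hazard and the indirect
#' effect through the longitudinal trajectory:
#' \eqn{T(t) = \exp\{\bar W \gamma + \alpha \bar X(t) \beta\}}, with the
#' association transform applied to \eqn{\bar X(t)}.
#' `effect_curve_ss()` uses the subject-specific (conditional)
#' coefficients from the fit; `effect_curve_marginal()` uses the
#' population-averaged coefficients from [marginal_coefs()] (the
#' longitudinal fixed effects \eqn{\beta} are taken from the fit in both
#' cases).
#'
#' @param fit a `jm_fit`.
#' @param contrast a [treatment_contrast()].
#' @param times numeric vector of evaluation times.
#' @return A `jm_effect_curve` with the hazard-ratio values.
#' @export
effect_curve_ss <- function(fit, contrast, times) {
  params <- fit$params
  lhr <- sum(contrast$W_bar * params$gamma) +
    params$alpha * as.numeric(contrast$X_bar(times) %*% params$beta)
  new_effect_curve(times, exp(lhr), "SS")
}

#' @rdname effect_curve_ss
#' @param marginal a `jm_marginal` from [marginal_coefs()].
#' @export
effect_curve_marginal <- function(marginal, fit, contrast, times) {
  if (length(marginal$gamma_M) != length(contrast$W_bar))
    stop("contrast dimension does not match the marginal coefficients")
  lhr <- sum(contrast$W_bar * marginal$gamma_M) +
    marginal$alpha_M * as.numeric(contrast$X_bar(times) %*% fit$params$beta)
  new_effect_curve(times, exp(lhr), "marginal")
}

#' Weight functions over the trial window
#'
#' A weight Omega(t) on \[0, t0\] with \eqn{\int_0^{t_0} \Omega(t) dt = 1}
#' used to average the log hazard ratio over the trial.  `"uniform"` is
#' \eqn{\Omega = 1/t_0}; `"survival_weighted"` is proportional to a
#' pooled Kaplan-Meier survival estimate (more weight where more subjects
#' are at risk), Gauss-Kronrod-normalized; `"custom"` takes a
#' user-supplied density, which must integrate to 1 unless
#' `renormalize = TRUE`.
#'
#' @param kind one of `"uniform"`, `"survival_weighted"`, `"custom"`.
#' @param t0 end of the trial window, > 0.
#' @param density for `"custom"`: vectorized nonnegative function of time.
#' @param dataset for `"survival_weighted"`: the `jm_data` whose pooled
#'   survival curve supplies the weights.
#' @param renormalize for `"custom"` only: divide by the numerical
#'   integral instead of erroring when it is not 1.
#' @return A `jm_weight` list with `kind`, `t0` and `density`.
#' @export
weight_function <- function(kind = c("uniform", "survival_weighted", "custom"),
                            t0, density = NULL, dataset = NULL,
                            renormalize = FALSE) {
  kind <- match.arg(kind)
  stopifnot(t0 > 0)
  if (kind == "uniform") {
    density <- function(t) rep(1 / t0, length(t))
  } else if (kind == "survival_weighted") {
    if (is.null(dataset))
      stop("survival_weighted weights need a dataset")
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            data = dataset$survival)
    step <- stats::stepfun(sf$time, c(1, sf$surv))
    total <- gk15_integrate(function(t) step(t), 0, t0)
    density <- function(t) step(t) / total
  } else {
    if (is.null(density)) stop("custom weights need a density function")
    total <- gk15_integrate(density, 0, t0)
    if (renormalize) {
      base <- density
      density <- function(t) base(t) / total
    } else if (abs(total - 1) > 1e-6) {
      stop(sprintf(
        "weight function integrates to %.6f, not 1; supply a normalized density or set renormalize = TRUE",
        total))
    }
  }
  structure(list(kind = kind, t0 = t0, density = density),
            class = "jm_weight")
}

#' Weighted-average overall treatment effect
#'
#' \eqn{\phi(t_0) = \exp\{\int_0^{t_0} \log HR(t)\, \Omega(t)\, dt\}},
#' the Omega-weighted geometric mean of the hazard-ratio curve over the
#' trial window, computed with 15-point Gauss-Kronrod quadrature.
#'
#' @param loghr vectorized function of time returning the log hazard
#'   ratio (e.g. built from an effect curve's coefficients).
#' @param weight a [weight_function()].
#' @return The weighted effect, a positive scalar.
#' @export
weighted_effect <- function(loghr, weight) {
  stopifnot(inherits(weight, "jm_weight"))
  total <- gk15_integrate(weight$density, 0, weight$t0)
  if (abs(total - 1) > 1e-6)
    stop(sprintf("weight function integrates to %.6f, not 1", total))
  exp(gk15_integrate(function(t) loghr(t) * weight$density(t), 0, weight$t0))
}

# log hazard ratio function from fitted/marginal coefficients
loghr_function <- function(gamma, alpha, beta, contrast) {
  force(gamma); force(alpha); force(beta); force(contrast)
  function(t) {
    sum(contrast$W_bar * gamma) +
      alpha * as.numeric(contrast$X_bar(t) %*% beta)
  }
}

# ---- Monte-Carlo standard errors --------------------------------------------

#' Simulation-based standard errors for the marginal coefficients
#'
#' Repeats the marginalization `L` times, each time replacing the fitted
#' parameters by a draw from their approximate sampling distribution:
#' (1) draw the full parameter vector from N(estimate, Var) on the
#' unconstrained scale (log sigma, log-Cholesky of the random-effects
#' covariance) and back-transform, so every draw has a valid variance and
#' covariance; (2) recompute the stacked Monte-Carlo marginal log
#' hazards under the drawn parameters; (3) re-project.  Sample standard
#' deviations and percentile intervals over the `L` replicate
#' \eqn{\theta^{M*}} summarize the uncertainty.
#'
#' @param fit a converged `jm_fit` with a parameter covariance.
#' @param dataset the `jm_data` the model was fitted to.
#' @param config a [marg_config()]; replicate `l` uses the substream
#'   seed derived from `config$seed` and `l`.
#' @param L number of replicates (default 200).
#' @param ci_level confidence level for percentile intervals.
#' @param beta_in_design `"draw"` (default) rebuilds the stacked design
#'   with each replicate's drawn beta, so longitudinal-parameter
#'   uncertainty — including the near-collinearity of the association
#'   column with the baseline block when the treatment-time interaction
#'   approaches zero — propagates into the replicates; `"mle"` keeps the
#'   fitted beta in the design, which gives lighter-tailed replicates
#'   but understates the uncertainty in the marginal association.
#' @return A `jm_marg_uncertainty`: `replicates` (L x dim theta matrix),
#'   `se` (named), `ci` (percentile bounds), `ci_level`, counts of
#'   dropped replicates.
#' @export
marginal_se <- function(fit, dataset, config = marg_config(), L = 200L,
                        ci_level = 0.95,
                        beta_in_design = c("draw", "mle")) {
  beta_in_design <- match.arg(beta_in_design)
  if (!inherits(fit, "jm_fit")) stop("marginal_se needs a jm_fit")
  if (is.null(fit$vcov_unconstrained))
    stop("fit has no parameter covariance (not converged?)")
  stopifnot(L >= 2)
  L <- as.integer(L)
  spec <- fit$spec
  V <- fit$vcov_unconstrained
  zeroV <- max(abs(V)) == 0
  geom <- marg_geometry(spec, dataset,
                        include_censored = config$include_censored,
                        survival_horizon = config$survival_horizon)
  reps <- vector("list", L)
  for (l in seq_len(L)) {
    u_star <- if (zeroV) fit$u_hat
              else drop(sample_mvnormal(fit$u_hat, V, 1L,
                                        seed = derive_seed(config$seed,
                                                           1000L + l)))
    reps[[l]] <- tryCatch({
      p_star <- unpack_params(u_star, spec)
      p_design <- if (beta_in_design == "draw") p_star else {
        pd <- p_star; pd$beta <- fit$params$beta; pd
      }
      # common random numbers across replicates: every replicate reuses the
      # same marginalization draw streams, so replicate spread reflects
      # parameter uncertainty only (and a zero parameter covariance gives
      # exactly identical replicates)
      cfg_l <- config
      stacked <- stacked_from_geometry(geom, p_design)
      logH <- eval_marginal_logH(spec, p_star, geom, cfg_l)
      project_marginal(stacked, logH)$theta_M
    }, error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, TRUE)
  ok[ok] <- vapply(reps[ok], function(r) all(is.finite(r)), TRUE)
  dropped <- sum(!ok)
  if (dropped > 0.05 * L)
    stop(dropped, " of ", L, " replicates failed (> 5%)")
  R <- do.call(rbind, reps[ok])
  qh0 <- fit$spec$bh$q; qg <- length(fit$spec$baseline_terms)
  colnames(R) <- c(paste0("gamma_h0_M_", seq_len(qh0)),
                   paste0("gamma_M_", seq_len(qg)), "alpha_M")
  a <- (1 - ci_level) / 2
  structure(list(
    replicates = R,
    se = apply(R, 2L, stats::sd),
    ci = t(apply(R, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE,
                 type = 7)),
    ci_level = ci_level, L = L, dropped = dropped,
    beta_in_design = beta_in_design), class = "jm_marg_uncertainty")
}

#' @export
print.jm_marg_uncertainty <- function(x, ...) {
  cat("Marginal-coefficient uncertainty from", nrow(x$replicates),
      "replicates (", x$dropped, "dropped )\n")
  tab <- data.frame(se = x$se, lo = x$ci[, 1], hi = x$ci[, 2])
  print(round(utils::tail(tab, 3), 4))
  invisible(x)
}

#' Pointwise percentile band for the marginal effect curve
#'
#' Evaluates the replicate curves \eqn{\exp\{\bar W \gamma^{M*} +
#' \alpha^{M*} \bar X(t) \beta\}} and returns the per-time percentile
#' band together with the point curve (replicate medians are used for
#' the centre when no point estimate is supplied).
#'
#' @param uncertainty a `jm_marg_uncertainty` from [marginal_se()].
#' @param fit the `jm_fit` (supplies beta for the contrast).
#' @param contrast a [treatment_contrast()].
#' @param times evaluation times.
#' @param marginal optional `jm_marginal` point estimate for the centre
#'   curve.
#' @param ci_level confidence level (defaults to the one in
#'   `uncertainty`).
#' @return A `jm_effect_curve` with `lo`/`hi` bands.
#' @export
curve_band <- function(uncertainty, fit, contrast, times, marginal = NULL,
                       ci_level = uncertainty$ci_level) {
  R <- uncertainty$replicates
  qh0 <- fit$spec$bh$q; qg <- length(fit$spec$baseline_terms)
  gm <- R[, qh0 + seq_len(qg), drop = FALSE]
  am <- R[, qh0 + qg + 1L]
  Xb <- as.numeric(contrast$X_bar(times) %*% fit$params$beta)
  # L x T matrix of replicate log curves
  lcurves <- (gm %*% contrast$W_bar) %*% t(rep(1, length(times))) +
    outer(am, Xb)
  a <- (1 - ci_level) / 2
  lo <- exp(apply(lcurves, 2L, stats::quantile, probs = a, names = FALSE))
  hi <- exp(apply(lcurves, 2L, stats::quantile, probs = 1 - a,
                  names = FALSE))
  centre <- if (!is.null(marginal)) {
    exp(sum(contrast$W_bar * marginal$gamma_M) + marginal$alpha_M * Xb)
  } else exp(apply(lcurves, 2L, stats::median))
  new_effect_curve(times, centre, "marginal", lo = lo, hi = hi)
}
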