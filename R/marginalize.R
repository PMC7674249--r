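# The core of the package: conditional survival by Gauss-Kronrod,
# Monte-Carlo marginal log hazards, and the least-squares projection of
# the stacked marginal log hazards onto the model design, yielding
# population-averaged coefficients.

#' Marginalization configuration
#'
#' @param G Monte-Carlo draws for the numerator (default 5000).
#' @param K Monte-Carlo draws for the denominator (default 5000).
#' @param seed integer seed; per-subject substreams are derived from it.
#' @param draw_sharing `"independent"` (numerator and denominator use
#'   separate draw sets, as defined) or `"common"` (shared draws, a
#'   variance-reduction option used mainly in tests).
#' @param include_censored include censored subjects' observed times among
#'   the event-time rows of the stacked design (default TRUE).
#' @param survival_horizon `"row_time"` integrates the survival function
#'   in the marginalization weights up to each row's evaluation time
#'   (default); `"observed_time"` always integrates to the subject's
#'   observed survival time.
#' @return A list of class `marg_config`.
#' @export
marg_config <- function(G = 5000L, K = 5000L, seed = 1L,
                        draw_sharing = c("independent", "common"),
                        include_censored = TRUE,
                        survival_horizon = c("row_time", "observed_time")) {
  stopifnot(G >= 1, K >= 1)
  structure(list(G = as.integer(G), K = as.integer(K),
                 seed = as.integer(seed),
                 draw_sharing = match.arg(draw_sharing),
                 include_censored = isTRUE(include_censored),
                 survival_horizon = match.arg(survival_horizon)),
            class = "marg_config")
}

#' Conditional survival function
#'
#' \eqn{S_i(t \mid b) = \exp\{-\int_0^{t} h_i(u \mid b)\,du\}} with the
#' integral approximated by the 15-point Gauss-Kronrod rule on \[0, t\].
#'
#' @inheritParams linear_predictor
#' @param t evaluation time(s), >= 0.
#' @return Values in (0, 1\]; `S(0 | b) = 1` exactly.
#' @export
conditional_survival <- function(spec, params, covariates, b, t) {
  if (any(t < 0)) stop("conditional_survival: negative time")
  vapply(t, function(ti) {
    if (ti == 0) return(1)
    gk <- gk15_rule()
    u <- (ti / 2) * (gk$nodes + 1)
    h <- conditional_hazard(spec, params, covariates, b, pmax(u, 1e-12))
    exp(-(ti / 2) * sum(gk$weights * h))
  }, 0)
}

# ---- marginal log hazard ----------------------------------------------------

# Internal: given node/row design pieces for ONE subject and a draw matrix
# B (n_draws x d), return logS (R x n_draws) and logh (R x n_draws).
# pieces: list(base_row, xb_row (R), Za_row (R x d),
#              base_n, xb_n (R*15), Za_n (R*15 x d), gkw (R*15), rid (R*15))
row_draw_loghS <- function(pieces, alpha, B) {
  lin_row <- pieces$Za_row %*% t(B)                       # R x nd
  logh <- pieces$base_row + alpha * (pieces$xb_row + lin_row)
  lin_n <- pieces$Za_n %*% t(B)                           # R15 x nd
  Hn <- pieces$gkw * exp(pieces$base_n + alpha * (pieces$xb_n + lin_n))
  cumh <- rowsum(Hn, pieces$rid, reorder = TRUE)          # R x nd
  list(logh = logh, logS = -cumh)
}

# design pieces for one subject at the given row times
subject_row_pieces <- function(spec, params, covariates, tt, horizon_t = tt,
                               t_floor = 1e-6) {
  R <- length(tt)
  tt <- pmax(tt, t_floor)
  gk <- gk15_rule()
  tn <- as.vector(t(outer(horizon_t / 2, gk$nodes + 1)))  # row-major R x 15
  tn <- pmax(tn, t_floor)
  gkw <- as.vector(t(outer(horizon_t / 2, gk$weights)))
  rid <- rep(seq_len(R), each = 15L)
  mode <- spec$association
  w <- sum(term_row(spec$baseline_terms, covariates, 0) * params$gamma)
  list(
    base_row = as.numeric(bh_eval(spec$bh, tt) %*% params$gamma_h0) + w,
    xb_row = as.numeric(term_matrix(spec$fixed_terms, covariates, tt, mode) %*%
                          params$beta),
    Za_row = term_matrix(spec$random_terms, covariates, tt, mode),
    base_n = as.numeric(bh_eval(spec$bh, tn) %*% params$gamma_h0) + w,
    xb_n = as.numeric(term_matrix(spec$fixed_terms, covariates, tn, mode) %*%
                        params$beta),
    Za_n = term_matrix(spec$random_terms, covariates, tn, mode),
    gkw = gkw, rid = rid)
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Monte-Carlo marginal log hazard
#'
#' Approximates the population-averaged log hazard
#' \eqn{\log h^M(t) = \log[E_b\{h(t|b) S(t|b)\} / E_b\{S(t|b)\}]}
#' by drawing random effects from N(0, Sigma_b): the numerator averages
#' \eqn{h \cdot S} over `G` draws, the denominator averages \eqn{S} over
#' `K` independent draws (or the same draws under
#' `draw_sharing = "common"`).  All averaging is done in log space.
#'
#' @inheritParams linear_predictor
#' @param t evaluation time(s) > 0.
#' @param config a [marg_config()].
#' @return Numeric vector of marginal log hazards.
#' @export
marginal_log_hazard <- function(spec, params, covariates, t, config) {
  check_params_spec(params, spec)
  stopifnot(all(t > 0))
  d <- length(spec$random_terms)
  if (max(abs(params$Sigma_b)) == 0)
    return(log(conditional_hazard(spec, params, covariates, rep(0, d), t)))
  pieces <- subject_row_pieces(spec, params, covariates, t)
  BG <- sample_mvnormal(rep(0, d), params$Sigma_b, config$G,
                        seed = derive_seed(config$seed, 1))
  BK <- if (config$draw_sharing == "common" && config$K == config$G) BG
        else sample_mvnormal(rep(0, d), params$Sigma_b, config$K,
                             seed = derive_seed(config$seed, 2))
  num <- row_draw_loghS(pieces, params$alpha, BG)
  den <- if (identical(BK, BG)) num
         else row_draw_loghS(pieces, params$alpha, BK)
  out <- vapply(seq_along(t), function(r) {
    ln <- logmeanexp(num$logh[r, ] + num$logS[r, ])
    ld <- logmeanexp(den$logS[r, ])
    if (!is.finite(ld))
      stop("marginal_log_hazard: survival underflowed to zero for all draws")
    ln - ld
  }, 0)
  out
}

#' Deterministic Gauss-Hermite oracle for the marginal log hazard
#'
#' Evaluates the same ratio of integrals by a Gauss-Hermite product rule
#' over the random effects (dimension at most 2); used as the
#' deterministic reference for the Monte-Carlo path.
#'
#' @inheritParams marginal_log_hazard
#' @param gh_order nodes per random-effect dimension (default 60).
#' @return Numeric vector of marginal log hazards.
#' @export
marginal_log_hazard_oracle <- function(spec, params, covariates, t,
                                       gh_order = 60L) {
  check_params_spec(params, spec)
  stopifnot(all(t > 0))
  d <- length(spec$random_terms)
  if (d > 2L)
    stop("marginal_log_hazard_oracle supports at most 2 random effects")
  if (max(abs(params$Sigma_b)) == 0)
    return(log(conditional_hazard(spec, params, covariates, rep(0, d), t)))
  gh <- gh_product(gh_order, d)
  B <- sqrt(2) * gh$V %*% t(t(chol(params$Sigma_b)))    # Q x d: sqrt2 L v
  lw <- gh$lw - d / 2 * log(pi)                         # normalized weights
  pieces <- subject_row_pieces(spec, params, covariates, t)
  hs <- row_draw_loghS(pieces, params$alpha, B)
  vapply(seq_along(t), function(r) {
    mnum <- max(lw + hs$logh[r, ] + hs$logS[r, ])
    mden <- max(lw + hs$logS[r, ])
    (mnum + log(sum(exp(lw + hs$logh[r, ] + hs$logS[r, ] - mnum)))) -
      (mden + log(sum(exp(lw + hs$logS[r, ] - mden))))
  }, 0)
}

# ---- projection -------------------------------------------------------------

#' Project marginal log hazards onto the stacked design
#'
#' Ordinary least squares of the stacked marginal log-hazard vector on
#' the stacked design `[W_h0 | W | Xbeta]`, giving the marginal
#' parameters \eqn{\theta^M = (\tilde X^\top \tilde X)^{-1} \tilde X^\top
#' \log H^M}.
#'
#' @param stacked a `jm_stacked` from [build_stacked_design()].
#' @param logH numeric vector of marginal log hazards, one per stacked row.
#' @return A `jm_marginal` list: `gamma_h0_M`, `gamma_M`, `alpha_M`,
#'   `theta_M`, plus the residual-orthogonality diagnostic
#'   `max_orth` (relative).
#' @export
project_marginal <- function(stacked, logH) {
  X <- stacked$X
  if (length(logH) != nrow(X))
    stop("logH has length ", length(logH), " but the stacked design has ",
         nrow(X), " rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("stacked design is rank deficient; projection is unidentified")
  theta <- qr.coef(qrX, logH)
  res <- logH - as.numeric(X %*% theta)
  orth <- max(abs(crossprod(X, res))) /
    max(1, max(abs(crossprod(X, logH))))
  qh0 <- stacked$q_h0; qg <- stacked$q_gamma
  structure(list(
    gamma_h0_M = unname(theta[seq_len(qh0)]),
    gamma_M = unname(theta[qh0 + seq_len(qg)]),
    alpha_M = unname(theta[qh0 + qg + 1L]),
    theta_M = unname(theta), max_orth = orth), class = "jm_marginal")
}

#' @export
print.jm_marginal <- function(x, ...) {
  cat("Marginal (population-averaged) parameters\n")
  cat("  gamma_M   :", signif(x$gamma_M, 5), "\n")
  cat("  alpha_M   :", signif(x$alpha_M, 5), "\n")
  cat("  gamma_h0_M:", signif(x$gamma_h0_M, 4), "\n")
  if (!is.null(x$se))
    cat("  SE(gamma_M) =", signif(x$se_gamma, 4),
        " SE(alpha_M) =", signif(x$se_alpha, 4), "\n")
  invisible(x)
}

# ---- precomputed stacked geometry -------------------------------------------
# Everything about the stacked rows that does not depend on the parameter
# values: per-subject design matrices at the row times and at their
# Gauss-Kronrod nodes.  Lets the SE scheme re-evaluate designs and marginal
# log hazards for L parameter draws without rebuilding the geometry.

marg_geometry <- function(spec, dataset, include_censored = TRUE,
                          survival_horizon = "row_time", t_floor = 1e-6) {
  row_index <- stacked_row_index(dataset, include_censored)
  surv <- dataset$survival
  gk <- gk15_rule(); mode <- spec$association
  subs <- vector("list", nrow(surv))
  for (i in seq_len(nrow(surv))) {
    rows <- which(row_index$id == surv$id[i])
    if (!length(rows)) next
    tt <- pmax(row_index$time[rows], t_floor)
    covs <- subject_covariates(dataset, surv$id[i])
    horizon <- if (survival_horizon == "row_time") tt
               else rep(max(surv$time[i], t_floor), length(tt))
    tn <- pmax(as.vector(t(outer(horizon / 2, gk$nodes + 1))), t_floor)
    subs[[i]] <- list(
      rows = rows, tt = tt, index = i,
      Wh0_row = bh_eval(spec$bh, tt),
      X_row = term_matrix(spec$fixed_terms, covs, tt, mode),
      Za_row = term_matrix(spec$random_terms, covs, tt, mode),
      Wh0_n = bh_eval(spec$bh, tn),
      X_n = term_matrix(spec$fixed_terms, covs, tn, mode),
      Za_n = term_matrix(spec$random_terms, covs, tn, mode),
      w = term_row(spec$baseline_terms, covs, 0),
      gkw = as.vector(t(outer(horizon / 2, gk$weights))),
      rid = rep(seq_along(tt), each = 15L))
  }
  list(row_index = row_index, subjects = subs, q_h0 = spec$bh$q,
       q_gamma = length(spec$baseline_terms))
}

# stacked design [W_h0 | W | X beta] assembled from the geometry
stacked_from_geometry <- function(geom, params) {
  nr <- nrow(geom$row_index)
  X <- matrix(0, nr, geom$q_h0 + geom$q_gamma + 1L)
  for (s in geom$subjects) {
    if (is.null(s)) next
    X[s$rows, seq_len(geom$q_h0)] <- s$Wh0_row
    X[s$rows, geom$q_h0 + seq_len(geom$q_gamma)] <-
      matrix(s$w, length(s$rows), geom$q_gamma, byrow = TRUE)
    X[s$rows, geom$q_h0 + geom$q_gamma + 1L] <-
      as.numeric(s$X_row %*% params$beta)
  }
  if (qr(X)$rank < ncol(X))
    stop("stacked design is rank deficient; the marginal projection is ",
         "unidentified")
  structure(list(X = X, row_index = geom$row_index, q_h0 = geom$q_h0,
                 q_gamma = geom$q_gamma), class = "jm_stacked")
}

# evaluate the full stacked marginal log-hazard vector for given params
eval_marginal_logH <- function(spec, params, geom, config) {
  d <- length(spec$random_terms)
  logH <- numeric(nrow(geom$row_index))
  zero_Sb <- max(abs(params$Sigma_b)) == 0
  for (s in geom$subjects) {
    if (is.null(s)) next
    base_row <- as.numeric(s$Wh0_row %*% params$gamma_h0) +
      sum(s$w * params$gamma)
    xb_row <- as.numeric(s$X_row %*% params$beta)
    if (zero_Sb) {
      logH[s$rows] <- base_row + params$alpha * xb_row
      next
    }
    pieces <- list(
      base_row = base_row, xb_row = xb_row, Za_row = s$Za_row,
      base_n = as.numeric(s$Wh0_n %*% params$gamma_h0) +
        sum(s$w * params$gamma),
      xb_n = as.numeric(s$X_n %*% params$beta),
      Za_n = s$Za_n, gkw = s$gkw, rid = s$rid)
    BG <- sample_mvnormal(rep(0, d), params$Sigma_b, config$G,
                          seed = derive_seed(config$seed, 2L * s$index))
    BK <- if (config$draw_sharing == "common" && config$K == config$G) BG
          else sample_mvnormal(rep(0, d), params$Sigma_b, config$K,
                               seed = derive_seed(config$seed,
                                                  2L * s$index + 1L))
    num <- row_draw_loghS(pieces, params$alpha, BG)
    den <- if (identical(BK, BG)) num
           else row_draw_loghS(pieces, params$alpha, BK)
    logH[s$rows] <- vapply(seq_along(s$tt), function(r) {
      ln <- logmeanexp(num$logh[r, ] + num$logS[r, ])
      ld <- logmeanexp(den$logS[r, ])
      if (!is.finite(ld))
        stop("survival underflowed to zero for all draws (subject ",
             geom$row_index$id[s$rows][1], ")")
      ln - ld
    }, 0)
  }
  logH
}

#' Marginal coefficients from a fitted joint model
#'
#' The full pipeline: build the stacked design (with the association
#' transform applied to the `Xbeta` column when the association is not
#' the current value), evaluate the Monte-Carlo marginal log hazard at
#' every stacked row using per-subject random-effect draw substreams, and
#' project by least squares.
#'
#' @param fit a `jm_fit` (or a [jm_params()] together with `spec`).
#' @param dataset the `jm_data` the model was fitted to.
#' @param config a [marg_config()].
#' @param spec required when `fit` is a bare parameter set.
#' @return A `jm_marginal` with the marginal coefficients, the stacked
#'   `row_index`, the `logH` vector and the configuration used.
#' @export
marginal_coefs <- function(fit, dataset, config = marg_config(),
                           spec = NULL) {
  params <- if (inherits(fit, "jm_fit")) fit$params else fit
  if (is.null(spec)) spec <- fit$spec
  check_params_spec(params, spec)
  geom <- marg_geometry(spec, dataset,
                        include_censored = config$include_censored,
                        survival_horizon = config$survival_horizon)
  stacked <- stacked_from_geometry(geom, params)
  logH <- eval_marginal_logH(spec, params, geom, config)
  out <- project_marginal(stacked, logH)
  out$row_index <- stacked$row_index
  out$logH <- logH
  out$config <- config
  out$beta <- params$beta
  out
}
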