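# Maximum-likelihood estimation of the joint model with the random
# effects integrated out by (pseudo-adaptive) Gauss-Hermite quadrature,
# plus the parameter covariance needed by the simulation-based SE scheme.

# ---- precomputed design workspace -------------------------------------------
# Everything that depends only on (spec, dataset): design matrices at the
# longitudinal times, at the observed survival times, and at the per-subject
# Gauss-Kronrod nodes used for the cumulative hazard.  The association
# transform is applied to the hazard-side designs; the longitudinal density
# always uses the value-mode designs.

fit_workspace <- function(spec, dataset, t_floor = 1e-6) {
  long <- dataset$longitudinal; surv <- dataset$survival
  n <- dataset$n; N <- dataset$N
  dm <- spec_dims(spec)
  idx <- match(long$id, surv$id)
  Tobs <- pmax(surv$time, t_floor)
  covs <- lapply(surv$id, function(id) subject_covariates(dataset, id))
  mode <- spec$association

  X <- matrix(0, N, dm["p"]); Z <- matrix(0, N, dm["d"])
  W <- matrix(0, n, dm["qg"])
  Xa_T <- matrix(0, n, dm["p"]); Za_T <- matrix(0, n, dm["d"])
  gk <- gk15_rule()
  Tn <- outer(Tobs / 2, gk$nodes + 1)              # n x 15 node times
  gkw <- outer(Tobs / 2, gk$weights)               # n x 15 scaled weights
  nidx <- rep(seq_len(n), 15L)
  Xa_n <- matrix(0, n * 15L, dm["p"]); Za_n <- matrix(0, n * 15L, dm["d"])
  for (i in seq_len(n)) {
    ri <- which(idx == i)
    if (length(ri)) {
      X[ri, ] <- term_matrix(spec$fixed_terms, covs[[i]], long$time[ri])
      Z[ri, ] <- term_matrix(spec$random_terms, covs[[i]], long$time[ri])
    }
    W[i, ] <- term_row(spec$baseline_terms, covs[[i]], 0)
    Xa_T[i, ] <- term_matrix(spec$fixed_terms, covs[[i]], Tobs[i], mode)
    Za_T[i, ] <- term_matrix(spec$random_terms, covs[[i]], Tobs[i], mode)
    ni <- which(nidx == i)
    Xa_n[ni, ] <- term_matrix(spec$fixed_terms, covs[[i]], Tn[i, ], mode)
    Za_n[ni, ] <- term_matrix(spec$random_terms, covs[[i]], Tn[i, ], mode)
  }
  list(n = n, N = N, idx = idx, y = long$y, X = X, Z = Z,
       delta = surv$event, Tobs = Tobs, W = W,
       Wh0_T = bh_eval(spec$bh, Tobs), Xa_T = Xa_T, Za_T = Za_T,
       Wh0_n = bh_eval(spec$bh, pmax(as.vector(Tn), t_floor)),
       Xa_n = Xa_n, Za_n = Za_n, gkw = as.vector(gkw), nidx = nidx,
       n_i = tabulate(idx, n), covs = covs, t_floor = t_floor)
}

# product Gauss-Hermite rule over d dimensions: nodes Q x d, log-weights Q
gh_product <- function(m, d) {
  g <- gauss_hermite_rule(m)
  grids <- rep(list(seq_len(m)), d)
  combo <- as.matrix(expand.grid(grids))
  V <- matrix(g$nodes[combo], nrow(combo), d)
  lw <- rowSums(matrix(log(g$weights)[combo], nrow(combo), d))
  list(V = V, lw = lw, vv = rowSums(V^2), m = m, d = d)
}

# per-subject log integrand pieces for all Q quadrature points at once.
# B_all: list of d matrices (n x Q) of random-effect values.
loglik_core <- function(params, ws, B_all) {
  d <- length(B_all); n <- ws$n; Q <- ncol(B_all[[1]])
  r <- ws$y - as.numeric(ws$X %*% params$beta)
  base_T <- as.numeric(ws$Wh0_T %*% params$gamma_h0 + ws$W %*% params$gamma)
  xb_T <- as.numeric(ws$Xa_T %*% params$beta)
  base_n <- as.numeric(ws$Wh0_n %*% params$gamma_h0) +
    (as.numeric(ws$W %*% params$gamma))[ws$nidx]
  xb_n <- as.numeric(ws$Xa_n %*% params$beta)

  E <- r                                            # N x Q residuals
  E <- matrix(E, ws$N, Q)
  fT <- matrix(xb_T, n, Q)
  fn <- matrix(xb_n, n * 15L, Q)
  for (k in seq_len(d)) {
    Bk <- B_all[[k]]
    E <- E - ws$Z[, k] * Bk[ws$idx, , drop = FALSE]
    fT <- fT + ws$Za_T[, k] * Bk
    fn <- fn + ws$Za_n[, k] * Bk[ws$nidx, , drop = FALSE]
  }
  SSE <- rowsum(E * E, ws$idx, reorder = TRUE)      # n x Q
  logh_T <- base_T + params$alpha * fT
  H <- rowsum(ws$gkw * exp(base_n + params$alpha * fn), ws$nidx,
              reorder = TRUE)
  lg <- -SSE / (2 * params$sigma2) + ws$delta * logh_T - H
  list(lg = lg, B_all = B_all)
}

logsumexp_rows <- function(M) {
  m0 <- apply(M, 1L, max)
  m0 + log(rowSums(exp(M - m0)))
}

#' Joint-model log-likelihood
#'
#' Per subject, the random effects are integrated out of the product of
#' the Gaussian longitudinal density, the hazard contribution at the
#' observed time (events only), and the survival function (cumulative
#' hazard by Gauss-Kronrod), against the N(0, Sigma_b) random-effects
#' density, using a Gauss-Hermite product rule.  When `centers` and
#' `scales` are supplied the rule is recentred and rescaled per subject
#' (pseudo-adaptive quadrature); by default the rule is centred at 0 and
#' scaled by the Cholesky factor of Sigma_b, which integrates the prior
#' exactly.  A zero Sigma_b collapses the integral to b = 0.
#'
#' @param params a [jm_params()].
#' @param dataset a `jm_data`.
#' @param spec a [jm_spec()].
#' @param n_gh Gauss-Hermite order per random-effect dimension.
#' @param centers optional n x d matrix of per-subject quadrature centres.
#' @param scales optional list of n lower-triangular d x d scale matrices.
#' @param workspace internal precomputed design workspace (recomputed when
#'   omitted).
#' @return The log-likelihood, a finite scalar.
#' @export
joint_log_likelihood <- function(params, dataset, spec, n_gh = 9L,
                                 centers = NULL, scales = NULL,
                                 workspace = NULL) {
  check_params_spec(params, spec)
  ws <- if (is.null(workspace)) fit_workspace(spec, dataset) else workspace
  d <- length(spec$random_terms)
  n <- ws$n
  if (max(abs(params$Sigma_b)) == 0) {
    B_all <- rep(list(matrix(0, n, 1L)), d)
    core <- loglik_core(params, ws, B_all)
    return(sum(core$lg) - sum(ws$n_i) / 2 * log(2 * pi * params$sigma2))
  }
  ev <- eigen(params$Sigma_b, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev))
    stop("Sigma_b is singular but not zero; likelihood undefined")
  gh <- gh_product(n_gh, d)
  Lb <- t(chol(params$Sigma_b))
  if (is.null(centers)) centers <- matrix(0, n, d)
  if (is.null(scales)) scales <- rep(list(Lb), n)
  # b_iq = centers_i + sqrt(2) * scales_i %*% v_q, assembled columnwise
  Ls <- array(unlist(scales), dim = c(d, d, n))
  B_all <- vector("list", d)
  for (k in seq_len(d)) {
    Bk <- matrix(centers[, k], n, nrow(gh$V))
    for (j in seq_len(k)) {
      Bk <- Bk + sqrt(2) * outer(Ls[k, j, ], gh$V[, j])
    }
    B_all[[k]] <- Bk
  }
  core <- loglik_core(params, ws, B_all)
  # log N(b; 0, Sigma_b) over all (i, q)
  Sinv <- chol2inv(chol(params$Sigma_b))
  qf <- matrix(0, n, nrow(gh$V))
  for (j in seq_len(d)) for (k in seq_len(d))
    qf <- qf + Sinv[j, k] * B_all[[j]] * B_all[[k]]
  ldet <- 2 * sum(log(diag(Lb)))
  lphi <- -0.5 * (d * log(2 * pi) + ldet + qf)
  ldetLs <- vapply(seq_len(n), function(i)
    sum(log(abs(diag(Ls[, , i, drop = FALSE][, , 1L])))), 0)
  M <- core$lg + lphi +
    matrix(gh$lw + gh$vv, n, nrow(gh$V), byrow = TRUE)
  ll_i <- d / 2 * log(2) + ldetLs + logsumexp_rows(M) -
    ws$n_i / 2 * log(2 * pi * params$sigma2)
  sum(ll_i)
}

# ---- likelihood + analytic gradient on a fixed quadrature grid --------------
# During optimization the (pseudo-adaptive) quadrature grid is held fixed,
# so the gradient of the discretized log-likelihood is exact and reuses the
# likelihood pass: it is the posterior-weighted average of the per-point
# integrand gradients, which are available in closed form because the log
# hazard is linear in (gamma_h0, gamma, alpha-times-linear-predictor) and
# the longitudinal density is Gaussian.

# second-difference (P-spline) ridge on the log-baseline-hazard spline
# coefficients: stabilizes coefficients whose basis support holds no
# events (otherwise they drift to -Inf); exactly zero at any linear-in-t
# log baseline, so it does not bias flat or log-linear hazards
bh_penalty_matrix <- function(qh0, lambda = 1) {
  if (qh0 < 3L || lambda <= 0) return(matrix(0, qh0, qh0))
  D2 <- diff(diag(qh0), differences = 2L)
  lambda * crossprod(D2)
}

# index of the log-Cholesky diagonal entries within the unconstrained
# parameter vector
lchol_diag_idx <- function(spec) {
  dm <- spec_dims(spec); d <- dm[["d"]]
  base <- dm[["qh0"]] + dm[["p"]] + dm[["qg"]] + 2L
  pos <- integer(0); k <- 0L
  for (j in seq_len(d)) { k <- k + j; pos <- c(pos, k) }
  base + pos
}

make_nll_machine <- function(spec, ws, B_all, lwvv, ldetLs, lambda_bh = 1,
                             vc_ridge = NULL) {
  d <- length(B_all); n <- ws$n; Q <- ncol(B_all[[1]])
  qh0 <- spec$bh$q
  P <- bh_penalty_matrix(qh0, lambda_bh)
  cache <- new.env(parent = emptyenv())
  cache$u <- NULL
  evaluate <- function(u) {
    p <- tryCatch(unpack_params(u, spec), error = function(e) NULL)
    if (is.null(p)) return(list(fn = 1e10, gr = rep(0, length(u))))
    out <- tryCatch(
      eval_joint_grad(p, spec, ws, B_all, lwvv, ldetLs),
      error = function(e) NULL)
    if (is.null(out) || !is.finite(out$fn)) {
      return(list(fn = 1e10, gr = rep(0, length(u))))
    }
    Pg <- as.numeric(P %*% p$gamma_h0)
    out$fn <- out$fn + 0.5 * sum(p$gamma_h0 * Pg)
    out$gr[seq_len(qh0)] <- out$gr[seq_len(qh0)] + Pg
    if (!is.null(vc_ridge)) {
      # weak stabilizer on the log-Cholesky diagonal (log-scale sd
      # `vc_ridge$s`, centred at the two-stage estimate): inert when the
      # data identify the variance component, stops the boundary collapse
      # to -Inf when they do not
      dev <- u[vc_ridge$idx] - vc_ridge$center
      out$fn <- out$fn + 0.5 * sum((dev / vc_ridge$s)^2)
      out$gr[vc_ridge$idx] <- out$gr[vc_ridge$idx] + dev / vc_ridge$s^2
    }
    out
  }
  list(
    fn = function(u) {
      if (is.null(cache$u) || !identical(u, cache$u)) {
        cache$val <- evaluate(u); cache$u <- u
      }
      cache$val$fn
    },
    gr = function(u) {
      if (is.null(cache$u) || !identical(u, cache$u)) {
        cache$val <- evaluate(u); cache$u <- u
      }
      cache$val$gr
    })
}

# negative log-likelihood and its gradient w.r.t. the unconstrained vector
eval_joint_grad <- function(params, spec, ws, B_all, lwvv, ldetLs) {
  d <- length(B_all); n <- ws$n; Q <- ncol(B_all[[1]])
  s2 <- params$sigma2; alpha <- params$alpha
  r <- ws$y - as.numeric(ws$X %*% params$beta)
  base_T <- as.numeric(ws$Wh0_T %*% params$gamma_h0 + ws$W %*% params$gamma)
  xb_T <- as.numeric(ws$Xa_T %*% params$beta)
  base_n <- as.numeric(ws$Wh0_n %*% params$gamma_h0) +
    (as.numeric(ws$W %*% params$gamma))[ws$nidx]
  xb_n <- as.numeric(ws$Xa_n %*% params$beta)

  E <- matrix(r, ws$N, Q)
  fT <- matrix(xb_T, n, Q)
  fn <- matrix(xb_n, n * 15L, Q)
  for (k in seq_len(d)) {
    Bk <- B_all[[k]]
    E <- E - ws$Z[, k] * Bk[ws$idx, , drop = FALSE]
    fT <- fT + ws$Za_T[, k] * Bk
    fn <- fn + ws$Za_n[, k] * Bk[ws$nidx, , drop = FALSE]
  }
  SSE <- rowsum(E * E, ws$idx, reorder = TRUE)
  logh_T <- base_T + alpha * fT
  HW <- ws$gkw * exp(base_n + alpha * fn)          # weighted hazard at nodes
  H <- rowsum(HW, ws$nidx, reorder = TRUE)

  Lb <- t(chol(params$Sigma_b))
  Sinv <- chol2inv(chol(params$Sigma_b))
  qf <- matrix(0, n, Q)
  for (j in seq_len(d)) for (k in seq_len(d))
    qf <- qf + Sinv[j, k] * B_all[[j]] * B_all[[k]]
  ldet <- 2 * sum(log(diag(Lb)))
  lphi <- -0.5 * (d * log(2 * pi) + ldet + qf)

  M <- -SSE / (2 * s2) + ws$delta * logh_T - H + lphi +
    matrix(lwvv, n, Q, byrow = TRUE)
  m0 <- apply(M, 1L, max)
  lse <- m0 + log(rowSums(exp(M - m0)))
  ll <- sum(d / 2 * log(2) + ldetLs + lse) -
    sum(ws$n_i) / 2 * log(2 * pi * s2)

  # posterior quadrature weights, each row summing to 1
  P <- exp(M - lse)
  Pn <- P[ws$nidx, , drop = FALSE]
  A <- HW * Pn                                     # n15 x Q
  an <- rowSums(A)                                 # n15
  Pl <- P[ws$idx, , drop = FALSE]

  g_gh0 <- as.numeric(crossprod(ws$Wh0_T, ws$delta) -
                      crossprod(ws$Wh0_n, an))
  g_gam <- as.numeric(crossprod(ws$W, ws$delta - rowSums(H * P)))
  g_alpha <- sum(ws$delta * rowSums(fT * P)) - sum(A * fn)
  g_beta <- as.numeric(crossprod(ws$X, rowSums(E * Pl))) / s2 +
    alpha * (as.numeric(crossprod(ws$Xa_T, ws$delta)) -
             as.numeric(crossprod(ws$Xa_n, an)))
  g_lsig <- sum(P * SSE) / s2 - sum(ws$n_i)
  # expected b b' under the posterior weights, summed over subjects
  Mb <- matrix(0, d, d)
  for (j in seq_len(d)) for (k in seq_len(j)) {
    v <- sum(P * B_all[[j]] * B_all[[k]])
    Mb[j, k] <- v; Mb[k, j] <- v
  }
  G_Sigma <- 0.5 * (Sinv %*% Mb %*% Sinv - n * Sinv)
  G_L <- 2 * G_Sigma %*% Lb
  g_lch <- numeric(0)
  for (j in seq_len(d)) for (k in seq_len(j))
    g_lch <- c(g_lch, if (j == k) G_L[j, j] * Lb[j, j] else G_L[j, k])

  list(fn = -ll, gr = -c(g_gh0, g_beta, g_gam, g_alpha, g_lsig, g_lch))
}

# fixed quadrature grid from EB modes/scales (or the prior when eb = NULL)
build_quad_grid <- function(params, n, d, n_gh, eb = NULL) {
  gh <- gh_product(n_gh, d)
  centers <- if (is.null(eb)) matrix(0, n, d) else eb$modes
  scales <- if (is.null(eb)) rep(list(t(chol(params$Sigma_b))), n)
            else eb$scales
  Ls <- array(unlist(scales), dim = c(d, d, n))
  B_all <- vector("list", d)
  for (k in seq_len(d)) {
    Bk <- matrix(centers[, k], n, nrow(gh$V))
    for (j in seq_len(k))
      Bk <- Bk + sqrt(2) * outer(Ls[k, j, ], gh$V[, j])
    B_all[[k]] <- Bk
  }
  ldetLs <- vapply(seq_len(n), function(i) {
    Li <- matrix(Ls[, , i], d, d)
    sum(log(abs(diag(Li))))
  }, 0)
  list(B_all = B_all, lwvv = gh$lw + gh$vv, ldetLs = ldetLs)
}

# ---- unconstrained parameterization -----------------------------------------
# theta_u = (gamma_h0, beta, gamma, alpha, log sigma, log-Cholesky of
# Sigma_b): diagonal of the lower Cholesky factor logged, off-diagonals
# free, so every draw maps to sigma2 > 0 and a PSD Sigma_b.

pack_params <- function(params, spec) {
  d <- length(spec$random_terms)
  S <- params$Sigma_b
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(1, max(ev))) S <- S + diag(1e-8, d)
  L <- t(chol(S))
  lch <- numeric(0)
  for (j in seq_len(d)) for (k in seq_len(j))
    lch <- c(lch, if (j == k) log(L[j, j]) else L[j, k])
  c(params$gamma_h0, params$beta, params$gamma, params$alpha,
    0.5 * log(params$sigma2), lch)
}

unpack_params <- function(u, spec) {
  dm <- spec_dims(spec); d <- dm[["d"]]
  i <- 0L
  take <- function(k) { v <- u[i + seq_len(k)]; i <<- i + k; v }
  gamma_h0 <- take(dm[["qh0"]]); beta <- take(dm[["p"]])
  gamma <- take(dm[["qg"]]); alpha <- take(1L); lsig <- take(1L)
  L <- matrix(0, d, d)
  for (j in seq_len(d)) for (k in seq_len(j))
    L[j, k] <- if (j == k) exp(take(1L)) else take(1L)
  jm_params(gamma_h0, beta, gamma, alpha, exp(2 * lsig), L %*% t(L))
}

param_names_u <- function(spec) {
  dm <- spec_dims(spec); d <- dm[["d"]]
  lch <- character(0)
  for (j in seq_len(d)) for (k in seq_len(j))
    lch <- c(lch, sprintf("lchol_%d%d", j, k))
  c(paste0("gamma_h0_", seq_len(dm[["qh0"]])),
    paste0("beta_", term_labels(spec$fixed_terms)),
    paste0("gamma_", term_labels(spec$baseline_terms)),
    "alpha", "log_sigma", lch)
}

# ---- empirical Bayes modes --------------------------------------------------

# log integrand (up to constants) for one subject as a function of b
subject_logpost <- function(params, ws, i, Sinv, ldet) {
  ri <- which(ws$idx == i); ni <- which(ws$nidx == i)
  yi <- ws$y[ri]; Xi <- ws$X[ri, , drop = FALSE]
  Zi <- ws$Z[ri, , drop = FALSE]
  xb <- as.numeric(Xi %*% params$beta)
  base_T <- as.numeric(ws$Wh0_T[i, ] %*% params$gamma_h0 +
                       ws$W[i, ] %*% params$gamma)
  xb_T <- sum(ws$Xa_T[i, ] * params$beta)
  base_n <- as.numeric(ws$Wh0_n[ni, , drop = FALSE] %*% params$gamma_h0) +
    as.numeric(ws$W[i, ] %*% params$gamma)
  xb_n <- as.numeric(ws$Xa_n[ni, , drop = FALSE] %*% params$beta)
  Za_n <- ws$Za_n[ni, , drop = FALSE]
  gkw <- ws$gkw[ni]
  function(b) {
    e <- yi - xb - as.numeric(Zi %*% b)
    fT <- xb_T + sum(ws$Za_T[i, ] * b)
    H <- sum(gkw * exp(base_n + params$alpha * (xb_n + as.numeric(Za_n %*% b))))
    -sum(e^2) / (2 * params$sigma2) +
      ws$delta[i] * (base_T + params$alpha * fT) - H -
      0.5 * (ldet + as.numeric(t(b) %*% Sinv %*% b))
  }
}

#' Empirical Bayes modes of the random effects
#'
#' Per-subject maximizer of the log integrand over b, with the local
#' curvature used to recentre and rescale the Gauss-Hermite nodes
#' (pseudo-adaptive quadrature).  Subjects whose local curvature is not
#' positive definite fall back to the prior scale with a warning.
#'
#' @param fit a `jm_fit` (or a [jm_params()] when `spec` is given).
#' @param dataset a `jm_data`.
#' @param spec required when `fit` is a bare parameter set.
#' @param workspace optional precomputed workspace.
#' @return List with `modes` (n x d matrix) and `scales` (list of n lower
#'   triangular matrices, Cholesky factors of the local inverse
#'   curvature).
#' @export
empirical_bayes_modes <- function(fit, dataset, spec = NULL,
                                  workspace = NULL) {
  params <- if (inherits(fit, "jm_fit")) fit$params else fit
  if (is.null(spec)) spec <- fit$spec
  ws <- if (is.null(workspace)) fit_workspace(spec, dataset) else workspace
  d <- length(spec$random_terms); n <- ws$n
  if (max(abs(params$Sigma_b)) == 0)
    return(list(modes = matrix(0, n, d),
                scales = rep(list(matrix(0, d, d)), n)))
  Sinv <- chol2inv(chol(params$Sigma_b))
  ldet <- determinant(params$Sigma_b, logarithm = TRUE)$modulus
  Lb <- t(chol(params$Sigma_b))
  modes <- matrix(0, n, d)
  scales <- vector("list", n)
  fell_back <- 0L
  for (i in seq_len(n)) {
    lp <- subject_logpost(params, ws, i, Sinv, ldet)
    opt <- stats::optim(rep(0, d), function(b) -lp(b), method = "BFGS",
                        control = list(maxit = 100))
    modes[i, ] <- opt$par
    Hn <- stats::optimHess(opt$par, function(b) -lp(b))
    Hn <- (Hn + t(Hn)) / 2
    ok <- all(eigen(Hn, symmetric = TRUE, only.values = TRUE)$values > 1e-10)
    if (ok) scales[[i]] <- t(chol(chol2inv(chol(Hn))))
    else { scales[[i]] <- Lb; fell_back <- fell_back + 1L }
  }
  if (fell_back > 0L)
    warning(fell_back, " subject(s) had non-concave local curvature; ",
            "fell back to the prior scale")
  list(modes = modes, scales = scales)
}

# ---- two-stage starting values ----------------------------------------------

two_stage_start <- function(spec, dataset, ws) {
  dm <- spec_dims(spec)
  df <- data.frame(y = ws$y, id = dataset$longitudinal$id)
  Xn <- paste0("xf", seq_len(dm[["p"]])); Zn <- paste0("zr", seq_len(dm[["d"]]))
  for (j in seq_len(dm[["p"]])) df[[Xn[j]]] <- ws$X[, j]
  for (j in seq_len(dm[["d"]])) df[[Zn[j]]] <- ws$Z[, j]
  beta <- NULL
  lmm <- tryCatch({
    fml <- stats::as.formula(paste(
      "y ~ 0 +", paste(Xn, collapse = " + "),
      "+ (0 +", paste(Zn, collapse = " + "), "| id)"))
    lme4::lmer(fml, data = df, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  }, error = function(e) NULL)
  if (!is.null(lmm)) {
    beta <- unname(lme4::fixef(lmm))
    sigma2 <- stats::sigma(lmm)^2
    vc <- lme4::VarCorr(lmm)$id
    Sigma_b <- matrix(as.numeric(vc), dm[["d"]], dm[["d"]])
  }
  if (is.null(beta)) {
    ols <- stats::lm.fit(ws$X, ws$y)
    beta <- ols$coefficients
    sigma2 <- max(stats::var(ols$residuals) * 0.7, 1e-3)
    Sigma_b <- diag(pmax(stats::var(ols$residuals) * 0.3, 1e-3), dm[["d"]])
  }
  # floor the starting variances: a singular mixed-model fit would put the
  # log-Cholesky start (and the stabilizer centre) at a degenerate value
  floor_sd <- 0.05 * sqrt(sigma2)
  diag(Sigma_b) <- pmax(diag(Sigma_b), floor_sd^2)
  Sigma_b <- Sigma_b + diag(1e-8, dm[["d"]])
  ev <- eigen(Sigma_b, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6 * max(ev)) Sigma_b <- Sigma_b + diag(1e-4, dm[["d"]])
  # survival submodel with alpha = 0: free of the random effects
  gam0 <- tryCatch({
    W <- ws$W
    colnames(W) <- paste0("w", seq_len(ncol(W)))
    cf <- survival::coxph(survival::Surv(ws$Tobs, ws$delta) ~ W)$coefficients
    ifelse(is.finite(cf), cf, 0)
  }, error = function(e) rep(0, dm[["qg"]]))
  gh0_0 <- rep(log(max(sum(ws$delta), 1) / sum(ws$Tobs)), dm[["qh0"]])
  surv_nll <- function(th) {
    gh0 <- th[seq_len(dm[["qh0"]])]; gm <- th[dm[["qh0"]] + seq_len(dm[["qg"]])]
    base_T <- as.numeric(ws$Wh0_T %*% gh0 + ws$W %*% gm)
    base_n <- as.numeric(ws$Wh0_n %*% gh0) + as.numeric(ws$W %*% gm)[ws$nidx]
    H <- rowsum(ws$gkw * exp(base_n), ws$nidx)
    -(sum(ws$delta * base_T) - sum(H))
  }
  Pbh <- bh_penalty_matrix(dm[["qh0"]])
  surv_nll_pen <- function(th) {
    gh0 <- th[seq_len(dm[["qh0"]])]
    surv_nll(th) + 0.5 * sum(gh0 * (Pbh %*% gh0))
  }
  so <- stats::optim(c(gh0_0, unname(gam0)), surv_nll_pen, method = "BFGS",
                     control = list(maxit = 200))
  jm_params(gamma_h0 = so$par[seq_len(dm[["qh0"]])], beta = beta,
            gamma = so$par[dm[["qh0"]] + seq_len(dm[["qg"]])], alpha = 0,
            sigma2 = sigma2, Sigma_b = Sigma_b)
}

# ---- main fitter ------------------------------------------------------------

#' Fit a joint model by maximum likelihood
#'
#' Maximizes the Gauss-Hermite-integrated joint likelihood over the
#' unconstrained parameterization (log sigma, log-Cholesky of Sigma_b)
#' with BFGS, starting from a two-stage fit (mixed model for the
#' longitudinal submodel, then the survival submodel with no
#' association).  Quadrature is pseudo-adaptive: recentred and rescaled
#' at the empirical Bayes modes computed from the starting values and
#' refreshed once at the interim optimum.  The parameter covariance is
#' the inverse numerical Hessian on the unconstrained scale.
#'
#' @param dataset a `jm_data`.
#' @param spec a [jm_spec()].
#' @param config list of options: `n_gh` (quadrature order per dimension,
#'   default 9), `adaptive` (default TRUE), `maxit` (default 300),
#'   `refit` (refresh modes and re-optimize once, default TRUE),
#'   `hessian` (default TRUE).
#' @return An object of class `jm_fit`: `params`, `vcov_unconstrained`,
#'   `transform_map`, `loglik`, `converged`, `n_quad`, `eb_modes`,
#'   `spec`, plus diagnostics.
#' @export
fit_joint_model <- function(dataset, spec, config = list()) {
  cfg <- utils::modifyList(list(n_gh = 9L, adaptive = TRUE, maxit = 300L,
                                refit = TRUE, hessian = TRUE,
                                lambda_bh = 1, vc_ridge_sd = 3), config)
  if (sum(dataset$survival$event) < 1)
    stop("cannot fit a joint model with zero events")
  ws <- fit_workspace(spec, dataset)
  d <- length(spec$random_terms)
  start <- two_stage_start(spec, dataset, ws)
  eb <- if (cfg$adaptive)
    empirical_bayes_modes(start, dataset, spec, workspace = ws)
  else NULL
  grid <- build_quad_grid(start, dataset$n, d, cfg$n_gh, eb)
  u0 <- pack_params(start, spec)
  vc_ridge <- list(idx = lchol_diag_idx(spec),
                   center = u0[lchol_diag_idx(spec)], s = cfg$vc_ridge_sd)
  mach <- make_nll_machine(spec, ws, grid$B_all, grid$lwvv, grid$ldetLs,
                           lambda_bh = cfg$lambda_bh, vc_ridge = vc_ridge)
  opt <- stats::optim(u0, mach$fn, mach$gr, method = "BFGS",
                      control = list(maxit = cfg$maxit, reltol = 1e-10))
  if (cfg$adaptive && cfg$refit) {
    # refresh the quadrature grid at the interim optimum and re-optimize,
    # twice: the second refresh re-adapts the grid to wherever the fit
    # ended (e.g. a variance component at its boundary), so the gradient
    # and Hessian below are evaluated on a grid that still resolves the
    # integrand there
    for (pass in 1:2) {
      eb <- empirical_bayes_modes(unpack_params(opt$par, spec), dataset,
                                  spec, workspace = ws)
      grid <- build_quad_grid(start, dataset$n, d, cfg$n_gh, eb)
      mach <- make_nll_machine(spec, ws, grid$B_all, grid$lwvv,
                               grid$ldetLs, lambda_bh = cfg$lambda_bh,
                               vc_ridge = vc_ridge)
      opt <- stats::optim(opt$par, mach$fn, mach$gr, method = "BFGS",
                          control = list(maxit = cfg$maxit, reltol = 1e-10))
    }
  }
  u_hat <- opt$par
  params_hat <- unpack_params(u_hat, spec)
  penalty <- {
    P <- bh_penalty_matrix(spec$bh$q, cfg$lambda_bh)
    0.5 * sum(params_hat$gamma_h0 * (P %*% params_hat$gamma_h0)) +
      0.5 * sum(((u_hat[vc_ridge$idx] - vc_ridge$center) / vc_ridge$s)^2)
  }
  loglik <- -opt$value + penalty                 # unpenalized log-likelihood
  grad_rel <- max(abs(mach$gr(u_hat))) / max(1, abs(loglik))
  vcov_u <- NULL; vcov_floored <- 0L
  if (cfg$hessian) {
    H <- stats::optimHess(u_hat, mach$fn, mach$gr)
    H <- (H + t(H)) / 2
    # invert with a relative curvature floor: directions the data do not
    # identify (e.g. a variance component at its boundary) get a bounded,
    # not infinite, sampling variance
    e <- eigen(H, symmetric = TRUE)
    floor_ev <- 1e-5 * max(abs(e$values))
    vcov_floored <- sum(e$values < floor_ev)
    ev <- pmax(e$values, floor_ev)
    vcov_u <- e$vectors %*% (t(e$vectors) / ev)
    vcov_u <- (vcov_u + t(vcov_u)) / 2
    dimnames(vcov_u) <- list(param_names_u(spec), param_names_u(spec))
  }
  converged <- (opt$convergence == 0) && is.finite(loglik) &&
    grad_rel < 1e-3
  if (!converged)
    warning("fit did not converge cleanly (gradient ", signif(grad_rel, 3),
            ", optim code ", opt$convergence, ")")
  structure(list(
    params = params_hat,
    u_hat = u_hat,
    vcov_unconstrained = vcov_u,
    transform_map = param_names_u(spec),
    loglik = loglik, penalty = penalty, converged = converged,
    n_quad = cfg$n_gh, eb_modes = eb, spec = spec, config = cfg,
    grad_rel = grad_rel, vcov_floored = vcov_floored,
    n = dataset$n, N = dataset$N,
    n_events = sum(dataset$survival$event)), class = "jm_fit")
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Joint model fit (", if (x$converged) "converged" else "NOT converged",
      "), log-likelihood ", round(x$loglik, 2), "\n", sep = "")
  cat("  n =", x$n, "subjects,", x$N, "longitudinal records,",
      x$n_events, "events\n")
  se <- if (!is.null(x$vcov_unconstrained))
    sqrt(diag(x$vcov_unconstrained)) else rep(NA_real_, length(x$u_hat))
  tab <- data.frame(estimate = x$u_hat, se = se,
                    row.names = x$transform_map)
  print(round(tab, 4))
  invisible(x)
}
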