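# Joint-model specification, parameter vector, design construction
# (including the stacked design used for the marginal projection), linear
# predictor and conditional hazard under all association structures.

# ---- term grammar -----------------------------------------------------------
# Designs are described by formula-like strings, e.g. "1 + time + trt:time".
# Each term is a product of baseline covariates and a power of time, so a
# term parses to (covs: character vector, power: integer).  Polynomial time
# dependence means slope and cumulative transforms have exact closed forms.

parse_terms <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty term specification")
  parts <- strsplit(text, "+", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    if (!nzchar(p)) stop("malformed term specification: ", text)
    facs <- strsplit(p, ":", fixed = TRUE)[[1]]
    covs <- character(0); power <- 0L
    for (f in facs) {
      if (f == "1") next
      m <- regmatches(f, regexec("^time(\\^([0-9]+))?$", f))[[1]]
      if (length(m)) {
        power <- power + if (nzchar(m[3])) as.integer(m[3]) else 1L
      } else covs <- c(covs, f)
    }
    list(covs = covs, power = power, label = p)
  })
}

term_labels <- function(terms) vapply(terms, `[[`, "", "label")

# value of prod(covariates) for one term given a named covariate list/row
term_cov_value <- function(term, covariates) {
  if (!length(term$covs)) return(1)
  v <- 1
  for (cv in term$covs) {
    if (is.null(covariates[[cv]]) || is.na(covariates[[cv]]))
      stop("covariate '", cv, "' missing from covariate set")
    v <- v * as.numeric(covariates[[cv]])
  }
  v
}

# Row of the design at time t (mode: value / slope / cumulative applied to
# the time polynomial of each term).
term_row <- function(terms, covariates, t, mode = "value") {
  vapply(terms, function(tm) {
    cv <- term_cov_value(tm, covariates)
    p <- tm$power
    switch(mode,
      value      = cv * t^p,
      slope      = if (p == 0L) 0 else cv * p * t^(p - 1L),
      cumulative = cv * t^(p + 1L) / (p + 1L),
      stop("unsupported association tag: ", mode))
  }, 0)
}

# Vectorized over a time vector: returns length(t) x length(terms) matrix.
term_matrix <- function(terms, covariates, t, mode = "value") {
  out <- matrix(0, length(t), length(terms))
  for (j in seq_along(terms)) {
    tm <- terms[[j]]
    cv <- term_cov_value(tm, covariates)
    p <- tm$power
    out[, j] <- switch(mode,
      value      = cv * t^p,
      slope      = if (p == 0L) 0 else cv * p * t^(p - 1L),
      cumulative = cv * t^(p + 1L) / (p + 1L),
      stop("unsupported association tag: ", mode))
  }
  out
}

# ---- baseline hazard basis --------------------------------------------------

#' B-spline basis for the log baseline hazard
#'
#' The log baseline hazard is modeled as a B-spline in time with
#' coefficients entering linearly, so the marginal projection can reuse
#' the same basis for the marginal baseline coefficients.
#'
#' @param degree spline degree (default 3).
#' @param interior_knots strictly increasing knots inside `boundary`.
#' @param boundary length-2 vector `c(t_lo, t_hi)`.
#' @return An object of class `bh_basis`; evaluate with `bh_eval()`.
#' @export
bh_basis <- function(degree = 3L, interior_knots = numeric(0),
                     boundary = c(0, 1)) {
  stopifnot(degree >= 0, length(boundary) == 2L, boundary[1] < boundary[2])
  if (length(interior_knots)) {
    if (any(diff(interior_knots) <= 0))
      stop("interior knots must be strictly increasing")
    if (min(interior_knots) <= boundary[1] || max(interior_knots) >= boundary[2])
      stop("interior knots must lie strictly inside the boundary")
  }
  structure(list(degree = as.integer(degree),
                 interior_knots = as.numeric(interior_knots),
                 boundary = as.numeric(boundary),
                 q = length(interior_knots) + as.integer(degree) + 1L),
            class = "bh_basis")
}

#' @rdname bh_basis
#' @param basis a `bh_basis` object.
#' @param t numeric vector of evaluation times.
#' @return `bh_eval`: a `length(t)` x `q` matrix of basis values.
#' @export
bh_eval <- function(basis, t) {
  stopifnot(inherits(basis, "bh_basis"))
  if (any(t < basis$boundary[1] - 1e-12 | t > basis$boundary[2] + 1e-12))
    stop("time outside the baseline-hazard spline boundary [",
         basis$boundary[1], ", ", basis$boundary[2], "]")
  t <- pmin(pmax(t, basis$boundary[1]), basis$boundary[2])
  kn <- c(rep(basis$boundary[1], basis$degree + 1L), basis$interior_knots,
          rep(basis$boundary[2], basis$degree + 1L))
  splines::splineDesign(kn, t, ord = basis$degree + 1L)
}

# ---- model specification ----------------------------------------------------

#' Specify a joint model
#'
#' Describes the mixed-effects longitudinal submodel, the relative-risk
#' survival submodel and the association structure linking them.
#'
#' @param fixed formula-like string for the fixed part of the longitudinal
#'   submodel, e.g. `"1 + time + trt:time"`.  Terms are products of
#'   baseline covariates and integer powers of `time` (`time^2` etc.).
#' @param random same grammar, for the random-effects design (e.g.
#'   `"1 + time"` for random intercept and slope).
#' @param baseline formula-like string of baseline covariates entering the
#'   survival submodel linearly, e.g. `"trt"`.
#' @param association one of `"value"`, `"slope"`, `"cumulative"`: whether
#'   the hazard depends on the current value, the slope, or the
#'   time-integral of the true longitudinal trajectory.
#' @param treatment name of the binary treatment covariate.
#' @param bh a [bh_basis()] for the log baseline hazard.
#' @return An object of class `jm_spec`.
#' @export
jm_spec <- function(fixed, random, baseline, association = "value",
                    treatment = "trt", bh = bh_basis()) {
  association <- match.arg(association, c("value", "slope", "cumulative"))
  spec <- structure(list(
    fixed_terms    = parse_terms(fixed),
    random_terms   = parse_terms(random),
    baseline_terms = parse_terms(baseline),
    association    = association,
    bh             = bh,
    treatment      = treatment), class = "jm_spec")
  if (any(vapply(spec$baseline_terms, function(tm) tm$power > 0L, TRUE)))
    stop("baseline survival covariates must be time-constant")
  all_covs <- unlist(lapply(c(spec$fixed_terms, spec$baseline_terms),
                            `[[`, "covs"))
  if (!treatment %in% all_covs)
    stop("treatment covariate '", treatment,
         "' appears in neither submodel design")
  spec
}

#' @export
print.jm_spec <- function(x, ...) {
  cat("Joint model specification\n")
  cat("  longitudinal fixed : ", paste(term_labels(x$fixed_terms), collapse = " + "), "\n")
  cat("  longitudinal random: ", paste(term_labels(x$random_terms), collapse = " + "), "\n")
  cat("  survival baseline  : ", paste(term_labels(x$baseline_terms), collapse = " + "), "\n")
  cat("  association        : ", x$association, "\n")
  cat("  log baseline hazard: B-spline degree", x$bh$degree, "with",
      length(x$bh$interior_knots), "interior knots on [",
      x$bh$boundary[1], ",", x$bh$boundary[2], "]\n")
  invisible(x)
}

spec_dims <- function(spec) {
  c(p = length(spec$fixed_terms), d = length(spec$random_terms),
    qg = length(spec$baseline_terms), qh0 = spec$bh$q)
}

# ---- parameter vector -------------------------------------------------------

#' Joint-model parameter vector
#'
#' Bundles the full parameter vector: log-baseline-hazard spline
#' coefficients, longitudinal fixed effects, survival covariate
#' coefficients, the association strength, the measurement-error variance
#' and the random-effects covariance.
#'
#' @param gamma_h0 numeric vector of spline coefficients for the log
#'   baseline hazard.
#' @param beta longitudinal fixed effects.
#' @param gamma survival covariate coefficients.
#' @param alpha scalar association parameter.
#' @param sigma2 measurement-error variance, > 0.
#' @param Sigma_b symmetric PSD random-effects covariance.
#' @return An object of class `jm_params`.
#' @export
jm_params <- function(gamma_h0, beta, gamma, alpha, sigma2, Sigma_b) {
  Sigma_b <- as.matrix(Sigma_b)
  stopifnot(length(alpha) == 1L, length(sigma2) == 1L)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (max(abs(Sigma_b - t(Sigma_b))) > 1e-8 * max(1, max(abs(Sigma_b))))
    stop("Sigma_b must be symmetric")
  ev <- eigen((Sigma_b + t(Sigma_b)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, max(abs(ev))))
    stop(sprintf("Sigma_b not PSD (smallest eigenvalue %.3e)", min(ev)))
  structure(list(gamma_h0 = as.numeric(gamma_h0), beta = as.numeric(beta),
                 gamma = as.numeric(gamma), alpha = as.numeric(alpha),
                 sigma2 = as.numeric(sigma2),
                 Sigma_b = (Sigma_b + t(Sigma_b)) / 2),
            class = "jm_params")
}

check_params_spec <- function(params, spec) {
  dm <- spec_dims(spec)
  if (length(params$gamma_h0) != dm["qh0"])
    stop("gamma_h0 has length ", length(params$gamma_h0),
         " but the baseline basis has ", dm["qh0"], " columns")
  if (length(params$beta) != dm["p"])
    stop("beta has length ", length(params$beta), ", expected ", dm["p"])
  if (length(params$gamma) != dm["qg"])
    stop("gamma has length ", length(params$gamma), ", expected ", dm["qg"])
  if (nrow(params$Sigma_b) != dm["d"])
    stop("Sigma_b is ", nrow(params$Sigma_b), "x", ncol(params$Sigma_b),
         " but there are ", dm["d"], " random terms")
  invisible(TRUE)
}

#' @export
print.jm_params <- function(x, ...) {
  cat("Joint model parameters\n")
  cat("  beta    :", signif(x$beta, 4), "\n")
  cat("  gamma   :", signif(x$gamma, 4), "\n")
  cat("  alpha   :", signif(x$alpha, 4), "\n")
  cat("  sigma2  :", signif(x$sigma2, 4), "\n")
  cat("  Sigma_b :", paste(signif(x$Sigma_b[upper.tri(x$Sigma_b, diag = TRUE)], 4),
                           collapse = " "), "(upper triangle)\n")
  cat("  gamma_h0:", signif(x$gamma_h0, 4), "\n")
  invisible(x)
}

# ---- dataset ----------------------------------------------------------------

#' Validate and assemble a joint-model dataset
#'
#' Checks a long-format longitudinal table (`id`, `time`, `y`, covariates)
#' against a survival table (`id`, `time`, `event`, baseline covariates)
#' and returns a `jm_data` object.  Longitudinal records after a subject's
#' observed survival time are rejected, not silently dropped.
#'
#' @param long_table data frame with columns `id`, `time`, `y`.
#' @param surv_table data frame with columns `id`, `time`, `event` plus
#'   baseline covariates (one row per subject).
#' @return An object of class `jm_data` with elements `longitudinal`,
#'   `survival`, `N` (longitudinal rows) and `n` (subjects).
#' @export
validate_dataset <- function(long_table, surv_table) {
  long_table <- as.data.frame(long_table)
  surv_table <- as.data.frame(surv_table)
  if (!nrow(long_table)) stop("longitudinal table is empty")
  if (!nrow(surv_table)) stop("survival table is empty")
  for (cl in c("id", "time", "y"))
    if (!cl %in% names(long_table))
      stop("longitudinal table lacks required column '", cl, "'")
  for (cl in c("id", "time", "event"))
    if (!cl %in% names(surv_table))
      stop("survival table lacks required column '", cl, "'")
  if (anyDuplicated(surv_table$id))
    stop("duplicate subject id in survival table: ",
         surv_table$id[duplicated(surv_table$id)][1])
  bad <- !long_table$id %in% surv_table$id
  if (any(bad))
    stop("subject '", long_table$id[bad][1],
         "' has longitudinal records but no survival record")
  if (any(surv_table$time < 0))
    stop("negative survival time for subject '",
         surv_table$id[surv_table$time < 0][1], "'")
  if (any(long_table$time < 0))
    stop("negative measurement time for subject '",
         long_table$id[long_table$time < 0][1], "'")
  if (!all(surv_table$event %in% c(0, 1)))
    stop("event indicator not in {0,1} for subject '",
         surv_table$id[!surv_table$event %in% c(0, 1)][1], "'")
  Tmap <- stats::setNames(surv_table$time, as.character(surv_table$id))
  over <- long_table$time > Tmap[as.character(long_table$id)] + 1e-12
  if (any(over))
    stop("longitudinal record after the observed survival time for subject '",
         long_table$id[over][1], "'")
  ord <- order(match(long_table$id, surv_table$id), long_table$time)
  structure(list(longitudinal = long_table[ord, , drop = FALSE],
                 survival = surv_table,
                 N = nrow(long_table), n = nrow(surv_table)),
            class = "jm_data")
}

#' @export
print.jm_data <- function(x, ...) {
  cat("Joint-model dataset: ", x$n, " subjects, ", x$N,
      " longitudinal records, ", sum(x$survival$event), " events (",
      round(100 * mean(x$survival$event), 1), "%)\n", sep = "")
  invisible(x)
}

# baseline covariate row (named list) for a subject id
subject_covariates <- function(dataset, id) {
  i <- match(id, dataset$survival$id)
  if (is.na(i)) stop("unknown subject id: ", id)
  as.list(dataset$survival[i, , drop = FALSE])
}

# ---- linear predictor, association feature, hazard --------------------------

#' Longitudinal linear predictor and association feature
#'
#' `linear_predictor()` evaluates the true (error-free) longitudinal value
#' \eqn{\eta_i(t) = x_i(t)^\top\beta + z_i(t)^\top b_i}.
#' `association_feature()` evaluates the trajectory summary entering the
#' hazard: the current value, its time derivative (slope), or its
#' integral over \[0, t\] (cumulative), depending on `spec$association`
#' or the `mode` override.  Polynomial time terms use exact closed forms;
#' `numeric = TRUE` forces the central-difference / Gauss-Kronrod
#' approximations instead.
#'
#' @param spec a [jm_spec()].
#' @param params a [jm_params()].
#' @param covariates named list of baseline covariate values.
#' @param b numeric vector of random effects.
#' @param t evaluation time(s).
#' @param mode association override, defaults to `spec$association`.
#' @param numeric use numerical differentiation/integration.
#' @return Numeric vector, same length as `t`.
#' @export
linear_predictor <- function(spec, params, covariates, b, t) {
  check_params_spec(params, spec)
  if (length(b) != length(spec$random_terms))
    stop("random-effects vector has length ", length(b), ", expected ",
         length(spec$random_terms))
  X <- term_matrix(spec$fixed_terms, covariates, t)
  Z <- term_matrix(spec$random_terms, covariates, t)
  as.numeric(X %*% params$beta + Z %*% b)
}

#' @rdname linear_predictor
#' @export
association_feature <- function(spec, params, covariates, b, t,
                                mode = spec$association, numeric = FALSE) {
  check_params_spec(params, spec)
  if (length(b) != length(spec$random_terms))
    stop("random-effects vector has length ", length(b), ", expected ",
         length(spec$random_terms))
  if (!mode %in% c("value", "slope", "cumulative"))
    stop("unsupported association tag: ", mode)
  if (numeric && mode != "value") {
    eta_fun <- function(s) {
      as.numeric(term_matrix(spec$fixed_terms, covariates, s) %*% params$beta +
                 term_matrix(spec$random_terms, covariates, s) %*% b)
    }
    return(switch(mode,
      slope = vapply(t, function(ti)
        central_difference_row(eta_fun, ti, lower = -Inf), 0),
      cumulative = vapply(t, function(ti)
        if (ti == 0) 0 else gk15_integrate(eta_fun, 0, ti), 0)))
  }
  X <- term_matrix(spec$fixed_terms, covariates, t, mode)
  Z <- term_matrix(spec$random_terms, covariates, t, mode)
  as.numeric(X %*% params$beta + Z %*% b)
}

#' Conditional (subject-specific) hazard
#'
#' Evaluates \eqn{h_i(t \mid b) = h_0(t) \exp\{w_i^\top\gamma + \alpha
#' f_i(t \mid b)\}} where \eqn{f_i} is the association feature and the log
#' baseline hazard is the spline \eqn{w_{h0}(t)^\top \gamma_{h0}}.
#'
#' @inheritParams linear_predictor
#' @return Strictly positive numeric vector, same length as `t`.
#' @export
conditional_hazard <- function(spec, params, covariates, b, t) {
  if (any(t <= 0)) stop("conditional_hazard: t must be > 0")
  Wh0 <- bh_eval(spec$bh, t)
  w <- term_row(spec$baseline_terms, covariates, 0)
  f <- association_feature(spec, params, covariates, b, t)
  as.numeric(exp(Wh0 %*% params$gamma_h0 + sum(w * params$gamma) +
                 params$alpha * f))
}

# ---- treatment contrast -----------------------------------------------------

#' Treatment contrast rows
#'
#' Builds the design differences \eqn{\bar W = W^{D=1} - W^{D=0}} and
#' \eqn{\bar X(t) = X^{D=1}(t) - X^{D=0}(t)} (with the association
#' transform applied to the time polynomial), holding all other
#' covariates at reference values.  Coordinates not involving the
#' treatment are zero by construction.
#'
#' @param spec a [jm_spec()].
#' @param dataset optional [validate_dataset()] result used to derive
#'   reference values (mode for binary covariates, mean otherwise).
#' @param reference optional named list of reference covariate values,
#'   overriding data-derived ones.
#' @return A list with `W_bar` (numeric vector) and `X_bar` (function of
#'   t returning the transformed contrast row).
#' @export
treatment_contrast <- function(spec, dataset = NULL, reference = NULL) {
  covs <- unique(unlist(lapply(c(spec$fixed_terms, spec$baseline_terms,
                                 spec$random_terms), `[[`, "covs")))
  ref <- list()
  for (cv in setdiff(covs, spec$treatment)) {
    val <- 0
    if (!is.null(reference) && !is.null(reference[[cv]])) {
      val <- reference[[cv]]
    } else if (!is.null(dataset) && cv %in% names(dataset$survival)) {
      v <- dataset$survival[[cv]]
      val <- if (all(v %in% c(0, 1))) as.numeric(names(which.max(table(v))))
             else mean(v)
    }
    ref[[cv]] <- val
  }
  c1 <- c(ref, stats::setNames(list(1), spec$treatment))
  c0 <- c(ref, stats::setNames(list(0), spec$treatment))
  mode <- spec$association
  list(
    W_bar = term_row(spec$baseline_terms, c1, 0) -
            term_row(spec$baseline_terms, c0, 0),
    X_bar = function(t) {
      term_matrix(spec$fixed_terms, c1, t, mode) -
        term_matrix(spec$fixed_terms, c0, t, mode)
    })
}

# ---- stacked design ---------------------------------------------------------

# Canonical stacking order shared by the design builder and the marginal
# log-hazard evaluator: subjects in survival-table order, each subject's
# longitudinal rows (ascending time) before their event-time row.
stacked_row_index <- function(dataset, include_censored = TRUE) {
  surv <- dataset$survival
  keep <- if (include_censored) rep(TRUE, nrow(surv)) else surv$event == 1
  idx <- data.frame(
    id = c(dataset$longitudinal$id, surv$id[keep]),
    time = c(dataset$longitudinal$time, surv$time[keep]),
    origin = rep(c("longitudinal", "event"),
                 c(nrow(dataset$longitudinal), sum(keep))),
    stringsAsFactors = FALSE)
  ord <- order(match(idx$id, surv$id), idx$origin == "event", idx$time)
  idx[ord, , drop = FALSE]
}

#' Build the stacked design for the marginal projection
#'
#' Stacks one row per longitudinal measurement time and one per observed
#' survival time (all subjects by default, events and censored alike,
#' consistent with the counting-process formulation), with columns
#' `[W_h0 | W | Xbeta]`: the baseline-hazard spline basis, the survival
#' covariate design, and the scalar \eqn{x_i(t)^\top \beta} with the
#' association transform applied when the association is not the current
#' value.  Times at 0 are floored at `t_floor` so the log baseline hazard
#' stays finite.
#'
#' @param spec a [jm_spec()].
#' @param params a [jm_params()] supplying `beta` for the last column.
#' @param dataset a [validate_dataset()] result.
#' @param include_censored include censored subjects' observed times among
#'   the event-time rows (default TRUE).
#' @param t_floor lower clamp for row times (default 1e-6).
#' @return An object of class `jm_stacked`: list with `X` (the matrix),
#'   `row_index` (data frame `id`, `time`, `origin`) and column counts.
#' @export
build_stacked_design <- function(spec, params, dataset,
                                 include_censored = TRUE, t_floor = 1e-6) {
  check_params_spec(params, spec)
  surv <- dataset$survival
  idx <- stacked_row_index(dataset, include_censored)
  tt <- pmax(idx$time, t_floor)
  Wh0 <- bh_eval(spec$bh, tt)
  qg <- length(spec$baseline_terms)
  W <- matrix(0, nrow(idx), qg)
  xb <- numeric(nrow(idx))
  mode <- spec$association
  for (id in surv$id) {
    rows <- which(idx$id == id)
    cv <- subject_covariates(dataset, id)
    W[rows, ] <- matrix(term_row(spec$baseline_terms, cv, 0),
                        length(rows), qg, byrow = TRUE)
    xb[rows] <- as.numeric(
      term_matrix(spec$fixed_terms, cv, tt[rows], mode) %*% params$beta)
  }
  X <- cbind(Wh0, W, xb)
  colnames(X) <- c(paste0("bh", seq_len(spec$bh$q)),
                   term_labels(spec$baseline_terms), "assoc")
  if (qr(X)$rank < ncol(X))
    stop("stacked design is rank deficient (rank ", qr(X)$rank, " < ",
         ncol(X), " columns); the marginal projection is unidentified")
  structure(list(X = X, row_index = idx, q_h0 = spec$bh$q, q_gamma = qg),
            class = "jm_stacked")
}
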