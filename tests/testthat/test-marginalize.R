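test_that("conditional survival: exact endpoints and closed forms", {
  spec <- simple_spec(); p <- simple_params()
  expect_identical(conditional_survival(spec, p, list(trt = 0),
                                        c(0, 0), 0), 1)
  # constant hazard: alpha = 0 makes h = h0 exp(gamma trt)
  p0 <- simple_params(alpha = 0)
  h <- 0.1 * exp(1.48)
  for (t in c(0.5, 3, 9))
    expect_equal(conditional_survival(spec, p0, list(trt = 1), c(0, 0), t),
                 exp(-h * t), tolerance = 1e-12)
  # nonincreasing in t
  s <- conditional_survival(spec, p, list(trt = 1), c(0.3, 0.1),
                            seq(0, 12, by = 0.5))
  expect_true(all(diff(s) <= 0))
  expect_error(conditional_survival(spec, p, list(trt = 1), c(0, 0), -1),
               "negative")
})

test_that("conditional survival matches a dense trapezoid oracle", {
  spec <- scenario_preset("II")$spec
  p <- scenario_preset("II")$params
  b <- c(0, 0)
  for (t in c(1.5, 4, 6.5)) {
    u <- seq(1e-9, t, length.out = 10000L)
    h <- conditional_hazard(spec, p, list(trt = 1), b, u)
    trap <- sum(diff(u) * (h[-1] + h[-length(h)]) / 2)
    expect_equal(conditional_survival(spec, p, list(trt = 1), b, t) /
                   exp(-trap), 1, tolerance = 1e-7)
  }
})

test_that("marginal log hazard collapses correctly in degenerate cases", {
  spec <- simple_spec()
  cfg <- marg_config(G = 500, K = 500, seed = 2)
  # Sigma_b = 0: equals the conditional log hazard at b = 0, exactly
  p0 <- simple_params(Sigma_b = matrix(0, 2, 2))
  tt <- c(1, 4, 9)
  expect_identical(
    marginal_log_hazard(spec, p0, list(trt = 1), tt, cfg),
    log(conditional_hazard(spec, p0, list(trt = 1), c(0, 0), tt)))
  # alpha = 0: hazard free of b, survival weights cancel
  pa <- simple_params(alpha = 0)
  expect_equal(
    marginal_log_hazard(spec, pa, list(trt = 1), tt, cfg),
    log(conditional_hazard(spec, pa, list(trt = 1), c(0, 0), tt)),
    tolerance = 1e-12)
})

test_that("MC marginal log hazard agrees with the Gauss-Hermite oracle (1-D)", {
  spec1 <- jm_spec("1 + time + trt:time", "1", "trt", treatment = "trt",
                   bh = const_bh())
  p1 <- jm_params(log(0.15), c(1.08, -0.08, 0.10), 1.48, -0.5, 0.25,
                  matrix(0.64, 1, 1))
  tt <- c(1, 5, 10)
  orc <- marginal_log_hazard_oracle(spec1, p1, list(trt = 1), tt,
                                    gh_order = 60)
  mcs <- vapply(1:8, function(s)
    marginal_log_hazard(spec1, p1, list(trt = 1), tt,
                        marg_config(G = 5000, K = 5000, seed = s)),
    numeric(3))
  sds <- apply(mcs, 1L, stats::sd)
  expect_true(all(abs(mcs[, 1] - orc) <= 3 * sds))
})

test_that("the GH oracle converges in its order and obeys the flip symmetry", {
  spec1 <- jm_spec("1 + time + trt:time", "1", "trt", treatment = "trt",
                   bh = const_bh())
  p1 <- jm_params(log(0.15), c(1.08, -0.08, 0.10), 1.48, -0.5, 0.25,
                  matrix(0.64, 1, 1))
  tt <- c(1, 5, 10)
  o40 <- marginal_log_hazard_oracle(spec1, p1, list(trt = 1), tt, 40)
  o60 <- marginal_log_hazard_oracle(spec1, p1, list(trt = 1), tt, 60)
  expect_lt(max(abs(o40 - o60)), 1e-8)
  # normal-kernel symmetry: negating alpha and all mean effects (with
  # gamma = 0) leaves the marginal log hazard unchanged, because b -> -b
  # maps one association-feature process onto the other
  pf <- jm_params(log(0.15), -c(1.08, -0.08, 0.10), 0, 0.5, 0.25,
                  matrix(0.64, 1, 1))
  pb <- jm_params(log(0.15), c(1.08, -0.08, 0.10), 0, -0.5, 0.25,
                  matrix(0.64, 1, 1))
  expect_equal(marginal_log_hazard_oracle(spec1, pf, list(trt = 1), tt, 60),
               marginal_log_hazard_oracle(spec1, pb, list(trt = 1), tt, 60),
               tolerance = 1e-10)
  # dimension > 2 unsupported
  spec3 <- jm_spec("1 + time + trt:time", "1 + time + time^2", "trt",
                   treatment = "trt", bh = const_bh())
  p3 <- jm_params(log(0.15), c(1.08, -0.08, 0.10), 1.48, -0.5, 0.25,
                  diag(0.1, 3))
  expect_error(marginal_log_hazard_oracle(spec3, p3, list(trt = 1), 1),
               "at most 2")
})

test_that("common draws bracket the marginal hazard by conditional hazards", {
  spec <- simple_spec(); p <- simple_params()
  cfg <- marg_config(G = 400, K = 400, seed = 6, draw_sharing = "common")
  for (t in c(2, 8)) {
    mlh <- marginal_log_hazard(spec, p, list(trt = 1), t, cfg)
    B <- jointmarg:::sample_mvnormal(c(0, 0), p$Sigma_b, 400,
                                     seed = jointmarg:::derive_seed(6, 1))
    hs <- vapply(seq_len(400), function(g)
      conditional_hazard(spec, p, list(trt = 1), B[g, ], t), 0)
    expect_gte(mlh, log(min(hs)))
    expect_lte(mlh, log(max(hs)))
  }
})

test_that("MC error of the marginal log hazard scales like 1/sqrt(G)", {
  spec <- simple_spec(); p <- simple_params()
  Gs <- c(500, 2000, 8000)
  sds <- vapply(Gs, function(G) {
    reps <- vapply(1:16, function(s)
      marginal_log_hazard(spec, p, list(trt = 1), 6,
                          marg_config(G = G, K = G, seed = 100 + s)), 0)
    stats::sd(reps)
  }, 0)
  slope <- stats::coef(stats::lm(log(sds) ~ log(Gs)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("projection recovers coefficients and detects rank problems", {
  ds <- small_dataset(n = 25)
  spec <- scenario_preset("II")$spec
  p <- scenario_preset("II")$params
  st <- build_stacked_design(spec, p, ds)
  set.seed(8)
  theta0 <- c(stats::rnorm(spec$bh$q), 1.2, -0.4)
  logH <- as.numeric(st$X %*% theta0)
  out <- project_marginal(st, logH)
  expect_equal(out$theta_M / theta0, rep(1, length(theta0)),
               tolerance = 1e-10)
  # adding a residual orthogonal to the columns leaves theta unchanged
  qrX <- qr(st$X)
  res <- stats::rnorm(nrow(st$X))
  res <- res - st$X %*% qr.coef(qrX, res)
  out2 <- project_marginal(st, logH + as.numeric(res))
  expect_equal(out2$theta_M, out$theta_M, tolerance = 1e-8)
  expect_lt(out2$max_orth, 1e-8)
  expect_error(project_marginal(st, logH[-1]), "length")
  st_bad <- st; st_bad$X[, 1] <- st_bad$X[, 2]
  expect_error(project_marginal(st_bad, logH), "rank deficient")
})

test_that("marginal_coefs: exact identities and end-to-end determinism", {
  ds <- small_dataset(n = 30)
  scen <- scenario_preset("II")
  cfg <- marg_config(G = 300, K = 300, seed = 5)
  # alpha = 0: no random-effect influence, theta^M = theta^SS
  pa <- scen$params; pa$alpha <- 0
  ma <- marginal_coefs(pa, ds, cfg, spec = scen$spec)
  expect_equal(ma$theta_M, c(pa$gamma_h0, pa$gamma, 0), tolerance = 1e-6)
  # Sigma_b = 0 end-to-end: recovers the SS parameters up to projection
  p0 <- scen$params; p0$Sigma_b <- matrix(0, 2, 2)
  m0 <- marginal_coefs(p0, ds, cfg, spec = scen$spec)
  expect_equal(m0$theta_M, c(p0$gamma_h0, p0$gamma, p0$alpha),
               tolerance = 1e-8)
  # identical seed => identical coefficients to the last bit
  m1 <- marginal_coefs(scen$params, ds, cfg, spec = scen$spec)
  m2 <- marginal_coefs(scen$params, ds, cfg, spec = scen$spec)
  expect_identical(m1$theta_M, m2$theta_M)
  # a different seed moves the MC estimate
  m3 <- marginal_coefs(scen$params, ds,
                       marg_config(G = 300, K = 300, seed = 6),
                       spec = scen$spec)
  expect_false(identical(m1$alpha_M, m3$alpha_M))
})

test_that("cumulative association expands the design as the antiderivative", {
  # quadratic trajectory model: fixed terms
  # (1, trt, t, t^2, trt t, trt t^2); cumulative transform gives
  # (t, trt t, t^2/2, t^3/3, trt t^2/2, trt t^3/3)
  spec <- jm_spec("1 + trt + time + time^2 + trt:time + trt:time^2",
                  "1 + time", "trt", association = "cumulative",
                  treatment = "trt", bh = const_bh())
  beta <- c(0.9, 0.3, -0.1, 0.01, 0.12, -0.02)
  p <- jm_params(log(0.2), beta, 0.8, -0.05, 0.2,
                 matrix(c(0.4, 0, 0, 0.04), 2, 2))
  tb <- tiny_tables()
  tb$surv$trt <- c(1, 0)
  ds <- validate_dataset(tb$long, tb$surv)
  st <- build_stacked_design(spec, p, ds)
  for (r in seq_len(nrow(st$X))) {
    t <- max(st$row_index$time[r], 1e-6)
    trt <- ds$survival$trt[match(st$row_index$id[r], ds$survival$id)]
    truth <- beta[1] * t + beta[2] * (trt * t) + beta[3] * t^2 / 2 +
      beta[4] * t^3 / 3 + beta[5] * trt * t^2 / 2 + beta[6] * trt * t^3 / 3
    expect_equal(unname(st$X[r, ncol(st$X)]), truth, tolerance = 1e-12)
  }
})
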