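test_that("validate_dataset accepts valid tables and names offenders", {
  tb <- tiny_tables()
  ds <- validate_dataset(tb$long, tb$surv)
  expect_s3_class(ds, "jm_data")
  expect_identical(ds$N, 6L)
  expect_identical(ds$n, 2L)

  bad <- tb; bad$long$time[3] <- 5   # t = 5 beyond subject a's T = 4
  expect_error(validate_dataset(bad$long, bad$surv),
               "after the observed survival time.*'a'")
  bad <- tb; bad$surv$event[2] <- 2
  expect_error(validate_dataset(bad$long, bad$surv), "not in \\{0,1\\}.*'b'")
  bad <- tb; bad$surv <- bad$surv[1, ]
  expect_error(validate_dataset(bad$long, bad$surv),
               "no survival record")
  bad <- tb; bad$long$time[1] <- -1
  expect_error(validate_dataset(bad$long, bad$surv), "negative measurement")
  expect_error(validate_dataset(tb$long[0, ], tb$surv), "empty")
})

test_that("linear_predictor evaluates x'beta + z'b", {
  spec <- simple_spec(); p <- simple_params()
  # beta = (1.08, -0.08, 0.10) on (1, t, trt*t), trt = 1, b = 0, t = 2
  expect_equal(linear_predictor(spec, p, list(trt = 1), c(0, 0), 2),
               1.08 - 0.16 + 0.20)
  # random intercept shifts the curve at t = 0
  expect_equal(linear_predictor(spec, p, list(trt = 0), c(0.5, 0.1), 0),
               1.08 + 0.5)
  p0 <- simple_params(); p0$beta <- c(0, 0, 0)
  expect_equal(linear_predictor(spec, p0, list(trt = 1), c(0, 0), 3), 0)
  expect_error(linear_predictor(spec, p, list(trt = 1), c(0, 0, 0), 1),
               "length")
})

test_that("association features: value = predictor; slope/cumulative closed forms", {
  spec <- simple_spec(); p <- simple_params()
  set.seed(1)
  for (i in 1:100) {
    t <- runif(1, 0, 10); b <- rnorm(2); trt <- rbinom(1, 1, 0.5)
    expect_identical(
      association_feature(spec, p, list(trt = trt), b, t, mode = "value"),
      linear_predictor(spec, p, list(trt = trt), b, t))
  }
  # cumulative of eta(s) = b0 + (beta0) + (beta1 + b1) s  (trt = 0):
  # beta0 t + beta1 t^2/2 + b0 t + b1 t^2/2
  b <- c(0.3, -0.2)
  for (t in c(0.5, 2, 7)) {
    truth <- 1.08 * t - 0.08 * t^2 / 2 + b[1] * t + b[2] * t^2 / 2
    expect_equal(
      association_feature(spec, p, list(trt = 0), b, t, mode = "cumulative"),
      truth, tolerance = 1e-12)
  }
  # slope of a linear trajectory is the slope coefficient at any t
  expect_equal(
    association_feature(spec, p, list(trt = 0), b, c(1, 5), mode = "slope"),
    rep(-0.08 + b[2], 2))
  expect_equal(
    association_feature(spec, p, list(trt = 0), b, 0, mode = "value"),
    1.08 + b[1])
  expect_error(
    association_feature(spec, p, list(trt = 0), b, 1, mode = "bogus"),
    "unsupported")
})

test_that("closed-form transforms agree with numerical approximations", {
  # quadratic time trend so the slope is non-trivial
  spec <- jm_spec("1 + trt + time + time^2 + trt:time", "1 + time",
                  "trt", treatment = "trt", bh = const_bh())
  p <- jm_params(log(0.2), c(1, 0.4, -0.1, 0.02, 0.15), 0.5, -0.3, 0.2,
                 matrix(c(0.4, 0, 0, 0.04), 2, 2))
  b <- c(0.2, -0.1)
  for (t in c(0.7, 3.1, 8)) {
    sl <- association_feature(spec, p, list(trt = 1), b, t, mode = "slope")
    sl_num <- association_feature(spec, p, list(trt = 1), b, t,
                                  mode = "slope", numeric = TRUE)
    expect_equal(sl, sl_num, tolerance = 1e-6)
    cu <- association_feature(spec, p, list(trt = 1), b, t,
                              mode = "cumulative")
    cu_num <- association_feature(spec, p, list(trt = 1), b, t,
                                  mode = "cumulative", numeric = TRUE)
    expect_equal(cu_num / cu, 1, tolerance = 1e-10)
  }
})

test_that("conditional_hazard has the relative-risk form and is positive", {
  spec <- simple_spec(); p <- simple_params()
  # alpha = 0: hazard free of b
  p0 <- simple_params(alpha = 0)
  for (b1 in c(-2, 0, 3))
    expect_equal(conditional_hazard(spec, p0, list(trt = 1), c(b1, b1), 2),
                 conditional_hazard(spec, p0, list(trt = 1), c(0, 0), 2))
  # h0 = 1, gamma = 0, alpha = 1, eta = 0 -> h = 1
  pu <- jm_params(0, c(0, 0, 0), 0, 1, 1, diag(0, 2))
  expect_equal(conditional_hazard(spec, pu, list(trt = 1), c(0, 0), 3), 1)
  # symbolic identity: h = h0 exp{gamma1 trt + alpha eta(t)}
  for (t in c(0.5, 4, 11)) {
    b <- c(0.4, -0.1)
    eta <- 1.08 - 0.08 * t + 0.10 * t + b[1] + b[2] * t
    expect_equal(conditional_hazard(spec, p, list(trt = 1), b, t),
                 0.1 * exp(1.48 + p$alpha * eta), tolerance = 1e-12)
  }
  expect_true(all(conditional_hazard(spec, p, list(trt = 0), c(1, 1),
                                     seq(0.1, 15, by = 0.7)) > 0))
  expect_error(conditional_hazard(spec, p, list(trt = 1), c(0, 0), 25),
               "boundary")
  expect_error(conditional_hazard(spec, p, list(trt = 1), c(0, 0), 0),
               "> 0")
})

test_that("stacked design has N + n rows and a consistent Xbeta column", {
  ds <- small_dataset(n = 20)
  spec <- scenario_preset("II")$spec
  p <- scenario_preset("II")$params
  st <- build_stacked_design(spec, p, ds)
  expect_identical(nrow(st$X), ds$N + ds$n)
  expect_identical(ncol(st$X), spec$bh$q + 1L + 1L)
  # cross-check the Xbeta column against association_feature with b = 0
  for (r in sample(nrow(st$X), 25)) {
    id <- st$row_index$id[r]
    cv <- list(trt = ds$survival$trt[match(id, ds$survival$id)])
    expect_equal(unname(st$X[r, ncol(st$X)]),
                 association_feature(spec, p, cv, c(0, 0),
                                     max(st$row_index$time[r], 1e-6)),
                 tolerance = 1e-12)
  }
  # event-time rows follow a subject's longitudinal rows
  expect_identical(
    unname(tapply(st$row_index$origin, st$row_index$id,
                  function(o) tail(o, 1))[as.character(ds$survival$id[1])]),
    "event")
  # beta = 0 zeroes the association column -> rank deficiency is an error
  p0 <- p; p0$beta <- c(0, 0, 0)
  expect_error(build_stacked_design(spec, p0, ds), "rank deficient")
  # censored subjects can be excluded from the event rows
  st2 <- build_stacked_design(spec, p, ds, include_censored = FALSE)
  expect_identical(nrow(st2$X), ds$N + sum(ds$survival$event))
})

test_that("treatment_contrast isolates treatment coordinates", {
  spec <- simple_spec()
  ctr <- treatment_contrast(spec)
  expect_identical(ctr$W_bar, 1)               # trt is the only w covariate
  expect_equal(as.numeric(ctr$X_bar(3)), c(0, 0, 3))  # only trt:time moves
  # with another covariate present, its coordinate stays zero
  spec2 <- jm_spec("1 + time + trt:time + site", "1 + time", "trt + site",
                   treatment = "trt", bh = const_bh())
  ds <- tiny_tables()
  ds$surv$site <- c(1, 0)
  d2 <- validate_dataset(ds$long, ds$surv)
  ctr2 <- treatment_contrast(spec2, d2)
  expect_equal(ctr2$W_bar, c(1, 0))
  expect_equal(as.numeric(ctr2$X_bar(5)), c(0, 0, 5, 0))
})

test_that("bh_basis validates inputs and evaluates to q columns", {
  b <- bh_basis(3, c(2, 4), c(0, 6))
  expect_identical(b$q, 6L)
  expect_identical(dim(bh_eval(b, c(0, 3, 6))), c(3L, 6L))
  expect_equal(rowSums(bh_eval(b, c(1, 5))), c(1, 1))  # B-spline partition
  expect_error(bh_basis(3, c(4, 2), c(0, 6)), "increasing")
  expect_error(bh_basis(3, c(7), c(0, 6)), "inside")
  expect_error(bh_eval(b, 7), "boundary")
})
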