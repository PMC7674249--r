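# Shared fixtures, all built in code.

# constant-baseline basis (degree 0): h0 = exp(gamma_h0), handy for
# closed-form oracles
const_bh <- function(hi = 20) bh_basis(0L, boundary = c(0, hi))

simple_spec <- function(association = "value", hi = 20) {
  jm_spec("1 + time + trt:time", "1 + time", "trt",
          association = association, treatment = "trt", bh = const_bh(hi))
}

simple_params <- function(alpha = -0.5, h0 = 0.1,
                          Sigma_b = matrix(c(0.64, 0.04, 0.04, 0.04), 2, 2),
                          sigma2 = 0.25) {
  jm_params(gamma_h0 = log(h0), beta = c(1.08, -0.08, 0.10), gamma = 1.48,
            alpha = alpha, sigma2 = sigma2, Sigma_b = Sigma_b)
}

# tiny hand-written two-subject dataset (3 visits each)
tiny_tables <- function() {
  list(long = data.frame(id = rep(c("a", "b"), each = 3),
                         time = rep(c(0, 1, 2), 2),
                         y = c(1.2, 1.1, 0.9, 0.7, 0.8, 0.6)),
       surv = data.frame(id = c("a", "b"), time = c(4, 3),
                         event = c(1, 0), trt = c(1, 0)))
}

# cached small scenario-II dataset and fit, shared across test files
.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function(n = 60, sc = "II", seed = 42) {
  key <- paste0("ds_", sc, "_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_dataset(
      scenario_preset(sc, n_subjects = n, seed = seed))
  .fixture_env[[key]]
}

small_fit <- function(n = 60, sc = "II", seed = 42) {
  key <- paste0("fit_", sc, "_", n, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- fit_joint_model(
      small_dataset(n, sc, seed), scenario_preset(sc)$spec)
  .fixture_env[[key]]
}
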