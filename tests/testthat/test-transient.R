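make_trace <- function(conc, alpha = 0.01, beta = 0.2, A = c(1, 0.4),
                       k = c(200, 20), noise = 0, t_max = 0.3, n = 400,
                       seed = 1, dead_time = 0.001) {
  t <- seq(0, t_max, length.out = n)
  y <- multi_exp_model(t, conc, alpha, beta, A, k)
  if (noise > 0) y <- with_seed_test(seed, y + rnorm(n, 0, noise))
  stopped_flow_trace(t, y, conc, dead_time = dead_time)
}
with_seed_test <- function(seed, expr) { set.seed(seed); force(expr) }

test_that("the multi-exponential observation model has its documented limits", {
  expect_equal(multi_exp_model(0, 50, 0.01, 0.2, c(1, 2), c(100, 10)),
               0.01 * 50 + 0.2)
  expect_equal(multi_exp_model(log(2), 0, 0, 0, 1, 1), 0.5)
  expect_equal(multi_exp_model(1e6, 10, 0.01, 0.2, c(1, 2), c(100, 10)),
               0.01 * 10 + 0.2 + 3)
})

test_that("global transient fit recovers rates and shares the baseline", {
  concs <- c(10, 25, 50, 100)
  k_true <- lapply(concs, function(mD) c(2 * mD + 15, 0.2 * mD + 3))
  traces <- Map(function(mD, k) make_trace(mD, A = c(0.8, 0.5), k = k),
                concs, k_true)
  fit <- global_fit_transients(traces, n_phases = 2)
  expect_equal(fit$alpha, 0.01, tolerance = 1e-3)
  expect_equal(fit$beta, 0.2, tolerance = 1e-3)
  for (i in seq_along(concs)) {
    expect_equal(fit$phases$k1[i], k_true[[i]][1], tolerance = 1e-3)
    expect_equal(fit$phases$k2[i], k_true[[i]][2], tolerance = 1e-3)
  }
  # fast/slow ordering is an invariant of the output
  expect_true(all(fit$phases$k1 > fit$phases$k2))
  # the assembled k_obs curve carries the fast phase
  expect_s3_class(fit$kobs, "kobs_curve")
  expect_equal(fit$kobs$k_obs, fit$phases$k1[order(fit$phases$conc)])
})

test_that("transient fitting enforces its preconditions", {
  expect_error(global_fit_transients(list(make_trace(10))),
               class = "invalid_argument")
  # traces truncated to within the dead time cannot be fitted
  tr <- make_trace(10, t_max = 0.0009, n = 30)
  expect_error(global_fit_transients(list(tr, make_trace(20)), n_phases = 2),
               class = "fit_error")
})

test_that("phase counting distinguishes one from two phases", {
  # pure single exponential + noise -> 1 phase in at least 95% of seeds
  ones <- 0L
  for (s in 1:60) {
    tr <- make_trace(50, A = c(1, 0), k = c(80, 1), noise = 0.01, seed = s)
    ones <- ones + (phase_count_test(tr)$n_phases == 1L)
  }
  expect_gte(ones / 60, 0.95)
  # well-separated double exponential with comparable amplitudes -> 2
  twos <- 0L
  for (s in 1:30) {
    tr <- make_trace(50, A = c(0.6, 0.6), k = c(150, 15), noise = 0.012,
                     seed = 1000 + s)
    twos <- twos + (phase_count_test(tr)$n_phases == 2L)
  }
  expect_gte(twos / 30, 0.95)
  # zero-variance constant trace -> 1 phase, no error
  flat <- stopped_flow_trace(seq(0, 0.1, length.out = 100),
                             rep(0.3, 100), 10)
  expect_equal(phase_count_test(flat)$n_phases, 1L)
})

test_that("scheme-simulated traces without auxiliary binding are monophasic", {
  truth <- ref_truth()
  truth$params$kw_on_intercept <- 0
  truth$params$kw_on_slope_ado <- 0
  ones <- 0L; total <- 0L
  for (s in 1:20) {
    traces <- gen_transients(truth, conc = c(20, 60, 100), seed = s)
    for (tr in traces) {
      ones <- ones + (phase_count_test(tr)$n_phases == 1L)
      total <- total + 1L
    }
  }
  expect_gte(ones / total, 0.95)
})

test_that("fast phase tracks catalytic binding, slow phase the auxiliary pathway", {
  # sweep at concentrations where the cooperative auxiliary sites carry
  # amplitude; assert rank correlation, not equality
  p0 <- recbcd_params()
  grid <- expand.grid(ks_on = c(1.5, 3), kw_scale = c(1, 1.8),
                      T = c(250, 350, 500))
  fast <- slow <- ks_pred <- kw_pred <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- recbcd_params(ks_on = grid$ks_on[i],
                       kw_on_intercept = p0$kw_on_intercept * grid$kw_scale[i])
    k <- predict_kobs(p, recbcd_condition(ligand_conc = grid$T[i]))
    fast[i] <- k$k_obs[1]; slow[i] <- k$k_obs[2]
    ks_pred[i] <- grid$ks_on[i] * grid$T[i]
    kw_pred[i] <- p$kw_on_intercept * grid$T[i]
  }
  expect_gt(cor(fast, ks_pred, method = "spearman"), 0.9)
  expect_gt(cor(slow, kw_pred, method = "spearman"), 0.9)
})

test_that("hyperbolic k_obs fits recover their parameters and stay monotone", {
  conc <- c(5, 10, 20, 40, 80, 160)
  y <- 5 + 100 * conc / (20 + conc)
  fit <- fit_kobs_hyperbola(kobs_curve(conc, y), with_offset = TRUE)
  expect_equal(unname(fit["k_max"]), 100, tolerance = 1e-6)
  expect_equal(unname(fit["K_half"]), 20, tolerance = 1e-6)
  expect_equal(unname(fit["offset"]), 5, tolerance = 1e-6)
  # half-saturation identity without offset
  y0 <- 100 * conc / (20 + conc)
  fit0 <- fit_kobs_hyperbola(kobs_curve(conc, y0))
  expect_equal(unname(fit0["k_max"] * 20 / (fit0["K_half"] + 20)), 50,
               tolerance = 1e-6)
  expect_equal(unname(fit0["offset"]), 0)
  pred <- fit0["offset"] + fit0["k_max"] * conc / (fit0["K_half"] + conc)
  expect_true(all(diff(pred) > 0))
  expect_error(fit_kobs_hyperbola(kobs_curve(c(1, 2, 3), c(1, 2, 3))),
               class = "invalid_argument")
})

test_that("stopped-flow traces round-trip through the long-format CSV", {
  traces <- list(make_trace(10), make_trace(50))
  f <- tempfile(fileext = ".csv")
  write_traces_csv(traces, f)
  back <- read_traces_csv(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$signal, traces[[1]]$signal)
  expect_equal(back[[2]]$conc, 50)
  expect_equal(back[[1]]$dead_time, 0.001)
})
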