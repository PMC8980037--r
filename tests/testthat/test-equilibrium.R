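test_that("double-Hill curve has the documented limits and values", {
  expect_equal(double_hill(10, 1, 10, 1, 100, 2), 0.5)
  expect_equal(double_hill(0, 0.5, 10, 1, 100, 2), 0)
  expect_equal(double_hill(1e12, 0.3, 10, 1.2, 100, 2), 1, tolerance = 1e-6)
  expect_equal(double_hill(100, 0.5, 10, 1, 100, 2), 0.7045, tolerance = 1e-4)
  # monotone nondecreasing for valid parameters
  x <- exp(seq(log(0.1), log(1e5), length.out = 60))
  set.seed(11)
  for (i in 1:6) {
    th <- c(p = runif(1), Ks = 10^runif(1, 0, 3), ns = runif(1, 0.5, 4),
            Kw = 10^runif(1, 1, 4), nw = runif(1, 0.5, 4))
    y <- double_hill(x, th[1], th[2], th[3], th[4], th[5])
    expect_true(all(diff(y) >= -1e-12))
  }
  expect_error(double_hill(1, 1.2, 10, 1, 10, 1), class = "invalid_argument")
})

test_that("double-Hill fitting recovers generating parameters on noiseless data", {
  x <- exp(seq(log(0.5), log(2000), length.out = 20))
  th <- c(p = 0.45, Ks = 8, ns = 1.1, Kw = 350, nw = 2.5)
  iso <- binding_isotherm(x, double_hill(x, th[1], th[2], th[3], th[4], th[5]))
  fit <- fit_double_hill(iso)
  expect_equal(unname(coef(fit)), unname(th), tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
})

test_that("single-phase data pin the partition coefficient at its boundary", {
  x <- exp(seq(log(0.5), log(2000), length.out = 20))
  y <- double_hill(x, 1, 15, 1.2, 100, 1)    # pure single Hill
  iso <- binding_isotherm(x, y)
  expect_warning(fit <- fit_double_hill(iso), "boundary|single-phase")
  expect_gte(unname(coef(fit)["p"]), 0.95)
})

test_that("isotherm fitting enforces its preconditions and supports weights", {
  x <- c(1, 5, 10, 50, 100)
  expect_error(fit_double_hill(binding_isotherm(x, rep(0.5, 5))),
               class = "fit_error")
  expect_error(binding_isotherm(c(2, 1, 3), c(1, 2, 3)),
               class = "invalid_argument")
  # weighted fit reproduces parameters with heteroscedastic sem
  xx <- exp(seq(log(0.5), log(2000), length.out = 24))
  th <- c(0.5, 10, 1, 300, 2)
  yy <- double_hill(xx, th[1], th[2], th[3], th[4], th[5])
  iso <- binding_isotherm(xx, yy, sem = 0.01 + 0.02 * (xx / max(xx)))
  fit <- fit_double_hill(iso)
  expect_equal(unname(coef(fit)), th, tolerance = 1e-3)
})

test_that("two-s.e. intervals cover the generating parameters at the nominal rate", {
  # 2% Gaussian noise; coverage pooled over the five parameters.  The
  # titration design (40 log-spaced points spanning both phases) keeps the
  # fit close to its linearised regime, where the reported s.e. are valid.
  x <- exp(seq(log(0.5), log(2000), length.out = 40))
  th <- c(p = 0.5, Ks = 8, ns = 1.1, Kw = 350, nw = 2.2)
  mu <- double_hill(x, th[1], th[2], th[3], th[4], th[5])
  set.seed(314)
  hits <- 0L; total <- 0L
  for (rep in 1:200) {
    y <- mu + rnorm(length(x), 0, 0.02)
    iso <- binding_isotherm(x, y, sem = rep(0.02, length(x)))
    fit <- tryCatch(suppressWarnings(fit_double_hill(iso)),
                    error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$se))) next
    covered <- abs(coef(fit) - th) <= 2 * fit$se
    hits <- hits + sum(covered); total <- total + length(covered)
  }
  expect_gt(total, 900)
  expect_gte(hits / total, 0.93)
})

test_that("model isotherms are biphasic with auxiliary sites and monophasic without", {
  p <- recbcd_params()
  conc <- exp(seq(log(0.5), log(550), length.out = 24))
  cond <- recbcd_condition()
  sig <- model_isotherm(p, cond, conc)
  expect_equal(sig[which.max(conc)], 1)
  # equal weights are proportional to the total mean occupancy
  r <- resolve_rates(p, cond)
  K <- association_constants(r)
  occ <- mean_occupancy(K$Ks, K$Kw, p$coop_a, conc)
  expect_equal(sig, occ / occ[length(occ)], tolerance = 1e-10)
  # single-Hill fit quality separates the two cases
  p0 <- recbcd_params(kw_on_intercept = 0, kw_on_slope_ado = 0)
  sig0 <- model_isotherm(p0, cond, conc)
  r2_full <- fit_single_hill_r2(conc, sig)
  r2_noaux <- fit_single_hill_r2(conc, sig0)
  expect_gt(r2_noaux, 0.999)
  expect_lt(r2_full, r2_noaux)
  # suppressing the weak-site signal weight leaves the catalytic shape
  sig_cat <- model_isotherm(p, cond, conc, signal_weights = c(1, 0))
  expect_equal(sig_cat, sig0, tolerance = 1e-10)
  expect_error(model_isotherm(p, cond, conc, signal_weights = c(0, 0)),
               class = "invalid_argument")
})

test_that("dialysis stoichiometry follows mass conservation", {
  expect_equal(dialysis_bound_count(dialysis_measurement(1000, 450, 45)),
               (1000 - 900) / 45)
  expect_equal(dialysis_bound_count(dialysis_measurement(200, 83, 17)), 2.0)
  expect_equal(dialysis_bound_count(dialysis_measurement(100, 50, 10)), 0)
  expect_error(dialysis_measurement(100, 50, 0), class = "invalid_argument")
  expect_warning(n <- dialysis_bound_count(dialysis_measurement(100, 51, 10)),
                 "negative")
  expect_lt(n, 0)
})

test_that("isotherm CSV round-trips with condition metadata", {
  iso <- binding_isotherm(c(1, 5, 20, 80, 200, 500),
                          c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                          sem = rep(0.02, 6),
                          condition = recbcd_condition(nacl = 200,
                                                       adenosine = 2,
                                                       temperature = 16))
  f <- tempfile(fileext = ".csv")
  write_isotherm_csv(iso, f)
  back <- read_isotherm_csv(f)
  expect_equal(back$conc, iso$conc)
  expect_equal(back$signal, iso$signal)
  expect_equal(back$sem, iso$sem)
  expect_equal(back$condition$nacl, 200)
  expect_equal(back$condition$adenosine, 2)
})
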