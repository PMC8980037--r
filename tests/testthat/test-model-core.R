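test_that("state enumeration covers every occupancy pair exactly once", {
  s <- enumerate_states(4, 2)
  expect_equal(nrow(s), 15)
  expect_equal(nrow(unique(s[, c("w", "c")])), 15)
  expect_equal(enumerate_states(0, 2)$c, 0:2)
  s11 <- enumerate_states(1, 1)
  expect_equal(s11$w, c(0, 0, 1, 1))
  expect_equal(s11$c, c(0, 1, 0, 1))
  expect_error(enumerate_states(-1, 2), class = "invalid_argument")
  expect_error(enumerate_states(4, 0), class = "invalid_argument")
})

test_that("condition resolution is linear with clamping at zero", {
  p <- recbcd_params(kw_on_intercept = 2, kw_on_slope_ado = -1,
                     ktr_fwd_intercept = 10, ktr_fwd_slope_nacl = -0.02)
  r0 <- resolve_rates(p, recbcd_condition(adenosine = 0, nacl = 0))
  expect_equal(r0$kw_on, 2)
  expect_equal(r0$ktr_fwd, 10)
  r1 <- resolve_rates(p, recbcd_condition(adenosine = 5, nacl = 0))
  expect_equal(r1$kw_on, 0)          # clamped, 2 - 5 < 0
  r2 <- resolve_rates(p, recbcd_condition(nacl = 300))
  expect_equal(r2$ktr_fwd, 4)        # 10 - 0.02 * 300
})

test_that("binding polynomial equals brute-force state-weight enumeration", {
  expect_equal(binding_polynomial(1, 1, 1, 0), 1)
  expect_equal(binding_polynomial(1, 0, 1, 1), 3)
  expect_equal(binding_polynomial(1, 1, 1, 1), 15)
  # exact on integer inputs for every state space up to (4, 2)
  for (nw in 0:4) for (nc in 1:2) {
    for (case in list(c(2, 3, 2, 1), c(1, 1, 5, 2), c(3, 2, 1, 4))) {
      expect_identical(
        binding_polynomial(case[1], case[2], case[3], case[4],
                           n_weak = nw, n_cat = nc),
        brute_psi(case[1], case[2], case[3], case[4], nw, nc),
        info = sprintf("nw=%d nc=%d", nw, nc))
    }
  }
  expect_error(binding_polynomial(-1, 1, 1, 1), class = "invalid_argument")
})

test_that("printed-coefficient variant differs from the product form in exactly two terms", {
  Ks <- 2; Kw <- 3; a <- 5
  prod_cf <- recbcdkin:::psi_coefficients(Ks, Kw, a, "product")
  prn_cf <- recbcdkin:::psi_coefficients(Ks, Kw, a, "as_printed")
  expect_length(prod_cf, 7)
  expect_length(prn_cf, 7)
  expect_equal(sum(abs(prod_cf - prn_cf) > 1e-12), 2)
  # the discrepant coefficients are the T^4 and T^5 ones
  expect_equal(which(abs(prod_cf - prn_cf) > 1e-12), c(5, 6))
  expect_equal(binding_polynomial(Ks, Kw, a, 0, form = "as_printed"), 1)
})

test_that("mean occupancy is the log-derivative of the polynomial, monotone and bounded", {
  expect_equal(mean_occupancy(1, 1, 1, 0), 0)
  expect_equal(mean_occupancy(1, 0, 1, 1), 1)
  expect_equal(mean_occupancy(0.1, 3e-4, 18, 1e9), 6, tolerance = 1e-6)
  Tg <- c(0.1, 1, 5, 20, 80, 300, 1000, 5000)
  for (case in list(c(0.13, 3e-4, 18), c(2, 0.5, 1), c(0.01, 0.02, 40))) {
    occ <- mean_occupancy(case[1], case[2], case[3], Tg)
    expect_true(all(diff(occ) >= -1e-12))
    expect_true(all(occ <= 6 + 1e-12))
    expect_equal(occ, vapply(Tg, function(T)
      brute_mean_occ(case[1], case[2], case[3], T), numeric(1)))
  }
})

test_that("the generator has the specified transitions and zero row sums", {
  p <- recbcd_params()
  r <- resolve_rates(p, recbcd_condition(ligand_conc = 100))
  s <- enumerate_states(4, 2)
  Q <- build_generator(s, r, 100)
  expect_equal(Q["w0c0", "w0c1"], r$ks_on * 100)
  expect_equal(Q["w0c1", "w0c0"], r$ks_off)
  expect_equal(Q["w0c0", "w1c0"], r$kw_on * 100)
  expect_equal(Q["w1c0", "w2c0"], r$coop_a * r$kw_on * 100)  # cooperative step
  expect_equal(Q["w2c0", "w1c0"], r$kw_off)                  # off-rate occupancy-independent
  expect_equal(Q["w1c0", "w0c1"], r$ktr_fwd)
  expect_equal(Q["w0c1", "w1c0"], r$ktr_rev)
  expect_equal(Q["w1c2", "w0c2"], r$kw_off)     # forward transfer blocked at c = 2
  expect_equal(Q["w1c2", "w2c1"], r$ktr_rev)    # reverse transfer open while w < 4
  # all rates zero -> zero matrix
  r0 <- r; for (nm in c("ks_on","ks_off","kw_on","kw_off","ktr_fwd","ktr_rev")) r0[[nm]] <- 0
  expect_true(all(build_generator(s, r0, 50) == 0))
  # conservation for random positive rates
  set.seed(7)
  for (i in 1:5) {
    rr <- r
    for (nm in c("ks_on","ks_off","kw_on","kw_off","ktr_fwd","ktr_rev"))
      rr[[nm]] <- stats::runif(1, 0, 100)
    Qr <- build_generator(s, rr, stats::runif(1, 1, 500))
    expect_lt(max(abs(rowSums(Qr))), 1e-9)
  }
})

test_that("reverse transfer enters the generator only where the scheme allows it", {
  # (w, c) -> (w+1, c-1) requires c >= 1 and a free auxiliary site
  p <- recbcd_params()
  r <- resolve_rates(p, recbcd_condition(ligand_conc = 10))
  Q <- build_generator(enumerate_states(4, 2), r, 10)
  expect_equal(Q["w4c1", "w4c0"], r$ks_off)   # no reverse transfer at w = 4
  expect_equal(Q["w3c1", "w4c0"], r$ktr_rev)
})

test_that("binding trajectories conserve probability and reach the expected plateau", {
  p <- recbcd_params()
  tr0 <- simulate_binding_kinetics(p, recbcd_condition(ligand_conc = 0),
                                   t_max = 0.01, n_points = 40)
  expect_true(all(abs(tr0$observable) < 1e-10))
  tr <- simulate_binding_kinetics(p, recbcd_condition(ligand_conc = 200),
                                  t_max = 0.5, n_points = 100)
  expect_lt(max(abs(rowSums(tr$p) - 1)), 1e-8)
  expect_equal(tr$observable[1], 0)
  expect_true(all(tr$observable >= -1e-10 & tr$observable <= 6 + 1e-8))
})

test_that("stationary ODE occupancy matches the polynomial under cycle-consistent transfer", {
  # ktr_fwd / ktr_rev = Ks / (a^min(w-1,1) Kw) holds on every cycle when a = 1
  p <- recbcd_params(ks_on = 2, ks_off = 20, kw_on_intercept = 0.5,
                     kw_on_slope_ado = 0, kw_off_intercept = 100,
                     kw_off_slope_nacl = 0, coop_a = 1,
                     ktr_fwd_intercept = 50, ktr_fwd_slope_nacl = 0,
                     ktr_rev = 50 / ((2 / 20) / (0.5 / 100)))
  cond <- recbcd_condition(ligand_conc = 150)
  tr <- simulate_binding_kinetics(p, cond, t_max = 5, n_points = 60)
  r <- resolve_rates(p, cond)
  K <- association_constants(r)
  occ <- mean_occupancy(K$Ks, K$Kw, 1, 150)
  expect_equal(tr$observable[length(tr$observable)], occ, tolerance = 1e-4)
  # and with a single auxiliary site, any cooperativity value
  p1 <- recbcd_params(n_weak_sites = 1, ktr_fwd_intercept = 300,
                      ktr_fwd_slope_nacl = 0, kw_off_slope_nacl = 0,
                      kw_on_slope_ado = 0,
                      ktr_rev = 300 / ((2 / 15) / (0.35 / 1070)))
  tr1 <- simulate_binding_kinetics(p1, cond, t_max = 5, n_points = 60)
  r1 <- resolve_rates(p1, cond)
  K1 <- association_constants(r1)
  occ1 <- mean_occupancy(K1$Ks, K1$Kw, p1$coop_a, 150, n_weak = 1)
  expect_equal(tr1$observable[length(tr1$observable)], occ1, tolerance = 1e-4)
})

test_that("stationary distribution solves the generator and matches oracles", {
  p <- recbcd_params()
  r <- resolve_rates(p, recbcd_condition(ligand_conc = 80))
  s <- enumerate_states(4, 2)
  # no binding at all: all probability stays on the empty state
  r0 <- r; r0$ks_on <- 0; r0$kw_on <- 0; r0$ktr_fwd <- 0; r0$ktr_rev <- 0
  pi0 <- stationary_distribution(build_generator(s, r0, 100))
  expect_equal(unname(pi0[1]), 1)
  # detailed balance (no transfer): Boltzmann weights from state products
  rdb <- r; rdb$ktr_fwd <- 0; rdb$ktr_rev <- 0
  Q <- build_generator(s, rdb, 80)
  pi <- stationary_distribution(Q)
  K <- association_constants(rdb)
  w <- mapply(brute_state_weight, s$w, s$c,
              MoreArgs = list(Ks = K$Ks, Kw = K$Kw, a = rdb$coop_a, T = 80))
  expect_equal(pi, w / sum(w), tolerance = 1e-8, ignore_attr = TRUE)
  # two-method consistency: long-time ODE equals the null-space solution
  cond <- recbcd_condition(ligand_conc = 80)
  tr <- simulate_binding_kinetics(p, cond, t_max = 10, n_points = 50)
  pi2 <- stationary_distribution(build_generator(s, r, 80))
  expect_lt(max(abs(tr$p[nrow(tr$p), ] - pi2)), 1e-6)
})

test_that("unwinding simulation: zero catalysis gives zero rate, rate increases and saturates in ATP", {
  p0 <- recbcd_params(vmax = 0)
  sim0 <- simulate_unwinding(p0, recbcd_condition(ligand_conc = 200),
                             t_max = 2, n_points = 60)
  expect_equal(sim0$rate_bp_per_s, 0, tolerance = 1e-8)
  p <- recbcd_params()
  Tg <- c(25, 100, 350, 1000)
  rates <- vapply(Tg, function(T)
    steady_state_unwinding_rate(p, recbcd_condition(ligand_conc = T)),
    numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[length(rates)], p$vmax * 2 * 0.5)  # bounded by the flux ceiling
})

test_that("ODE unwinding trace agrees with the stationary-flux rate", {
  p <- recbcd_params()
  cond <- recbcd_condition(ligand_conc = 350)
  sim <- simulate_unwinding(p, cond, t_max = 5, n_points = 80)
  expect_equal(sim$rate_bp_per_s, steady_state_unwinding_rate(p, cond),
               tolerance = 1e-3)
  # any-occupied catalysis variant is slower than proportional at saturation
  r_any <- steady_state_unwinding_rate(p, cond, catalysis = "any_occupied")
  expect_lt(r_any, sim$rate_bp_per_s)
})

test_that("direct pathway alone behaves as a single hyperbola in ATP", {
  p <- recbcd_params(kw_on_intercept = 0, kw_on_slope_ado = 0,
                     ktr_fwd_intercept = 0, ktr_fwd_slope_nacl = 0,
                     ktr_rev = 0)
  Tg <- exp(seq(log(25), log(700), length.out = 10))  # unwinding assay range
  rates <- vapply(Tg, function(T)
    steady_state_unwinding_rate(p, recbcd_condition(ligand_conc = T)),
    numeric(1))
  fit <- stats::nls(rates ~ vm * Tg / (K + Tg),
                    start = list(vm = max(rates) * 1.1, K = 300))
  r2 <- 1 - sum(resid(fit)^2) / sum((rates - mean(rates))^2)
  expect_gt(r2, 0.999)
})

test_that("trajectory CSV round-trips", {
  p <- recbcd_params()
  tr <- simulate_binding_kinetics(p, recbcd_condition(ligand_conc = 50),
                                  t_max = 0.01, n_points = 20)
  f <- tempfile(fileext = ".csv")
  trajectory_to_csv(tr, f)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(df$time_s, tr$time)
  expect_equal(df$observable, tr$observable, tolerance = 1e-12)
  expect_true(all(tr$space$label %in% names(df)))
})
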