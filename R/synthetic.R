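## Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for the synthetic-data generators
#'
#' Bundles the kinetic parameters, auxiliary observation-model constants and
#' per-modality noise levels that define a synthetic study.  Identical seed
#' and truth give byte-identical generator output.  The default parameter
#' magnitudes echo the system's qualitative behaviour (strong-site
#' dissociation constant ~10 uM, cooperative weak phase centred near 400 uM
#' and above 280 uM, fast directional transfer, cooperativity factor 18),
#' but every value is synthetic.
#'
#' @param params A [recbcd_params()] object (the kinetic truth).
#' @param noise Named list of noise levels: `isotherm` (fraction of signal
#'   span), `stopped_flow` (fraction of span), `fa` (absolute anisotropy
#'   units), `tweezers_nm` (extension r.m.s., nm), `dialysis` (fraction of
#'   the final free-ligand concentration), `kobs` (fraction of the rate),
#'   `unwinding_rate` (fraction of the rate).
#' @param unwinding List with the trace observation model: `intercept`
#'   (complex-formation time, s), `k_diss` (product-release decay rate,
#'   s^-1), `A`, `B` (initial/final signal levels).
#' @param sm List with the single-molecule scenario: `velocity` (bp/s),
#'   `start_bp`, `force_range` (pN over the trace), and `pauses` (data frame
#'   `start_s`, `duration_s`).
#' @param bp_per_atp Base pairs unwound per ATP hydrolysed (default 0.5).
#' @return Object of class `"recbcd_truth"`.
#' @export
synthetic_truth <- function(params = recbcd_params(),
                            noise = list(isotherm = 0.02, stopped_flow = 0.01,
                                         fa = 0.005, tweezers_nm = 2,
                                         dialysis = 0.01, kobs = 0.05,
                                         unwinding_rate = 0.05),
                            unwinding = list(intercept = 0.02, k_diss = 10,
                                             A = 0.30, B = 0.10),
                            sm = list(velocity = 500, start_bp = 500,
                                      force_range = c(10, 15),
                                      pauses = data.frame(start_s = 1.0,
                                                          duration_s = 1.0)),
                            bp_per_atp = 0.5) {
  stopifnot(inherits(params, "recbcd_params"))
  structure(list(params = params, noise = noise, unwinding = unwinding,
                 sm = sm, bp_per_atp = bp_per_atp),
            class = "recbcd_truth")
}

#' @export
print.recbcd_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  print(x$params)
  cat("noise:", paste(names(x$noise), unlist(x$noise), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic binding isotherm
#'
#' Model isotherm from the truth parameters plus Gaussian noise
#' (`noise$isotherm` times the signal span).  The default design titrates 20
#' log-spaced points between 0.5 and 550 uM, the range over which the
#' biphasic curve reaches saturation.
#'
#' @param truth A [synthetic_truth()].
#' @param conc Concentrations (uM); default 20 log-spaced points, 0.5-550.
#' @param condition A [recbcd_condition()].
#' @param seed Integer seed.
#' @return A [binding_isotherm()]; the noiseless curve is in attribute
#'   `"truth_signal"`.
#' @export
gen_isotherm <- function(truth, conc = exp(seq(log(0.5), log(550),
                                               length.out = 20)),
                         condition = recbcd_condition(), seed = 1) {
  stopifnot(inherits(truth, "recbcd_truth"))
  mu <- model_isotherm(truth$params, condition, conc)
  sd <- truth$noise$isotherm * diff(range(mu))
  sig <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd))
  iso <- binding_isotherm(conc, sig, sem = rep(max(sd, 1e-12), length(conc)),
                          condition = condition)
  attr(iso, "truth_signal") <- mu
  iso
}

#' Generate a synthetic equilibrium-dialysis measurement
#'
#' Solves the closed-system equilibrium for the free-ligand concentration
#' `f` satisfying mass conservation `2 f + n(f) [protein] = [N]_i`, with the
#' bound count `n(f)` given by the truth's mean occupancy at `f`, then adds
#' measurement noise to the final free concentration.
#'
#' @param truth A [synthetic_truth()].
#' @param protein_uM Protein concentration (uM).
#' @param ligand_uM Initial ligand concentration (uM).
#' @param condition A [recbcd_condition()].
#' @param seed Integer seed.
#' @return A [dialysis_measurement()]; attributes `"truth_free"` and
#'   `"truth_n"` carry the noiseless solution.
#' @export
gen_dialysis <- function(truth, protein_uM = 45, ligand_uM = 1000,
                         condition = recbcd_condition(), seed = 1) {
  stopifnot(inherits(truth, "recbcd_truth"))
  if (protein_uM <= 0 || ligand_uM <= 0)
    stop_recbcd("invalid_argument", "concentrations must be > 0")
  f <- dialysis_free_ligand(truth$params, condition, protein_uM, ligand_uM)
  n_true <- (ligand_uM - 2 * f) / protein_uM
  f_obs <- with_seed(seed, f * (1 + stats::rnorm(1, 0, truth$noise$dialysis)))
  m <- dialysis_measurement(ligand_uM, f_obs, protein_uM)
  attr(m, "truth_free") <- f
  attr(m, "truth_n") <- n_true
  m
}

## Free ligand in the two-chamber equilibrium; root of
## g(f) = 2 f + occ(f) * protein - ligand on (0, ligand/2].
dialysis_free_ligand <- function(params, condition, protein_uM, ligand_uM,
                                 temp_model = NULL) {
  rates <- resolve_rates(params, condition, temp_model)
  K <- association_constants(rates)
  g <- function(f) 2 * f +
    mean_occupancy(K$Ks, K$Kw, rates$coop_a, f,
                   n_weak = params$n_weak_sites,
                   n_cat = params$n_cat_sites) * protein_uM - ligand_uM
  if (g(ligand_uM / 2) < 0)   # no binding cannot exceed the no-binding root
    return(ligand_uM / 2)
  r <- tryCatch(stats::uniroot(g, c(1e-12, ligand_uM / 2), tol = 1e-10),
                error = function(e)
                  stop_recbcd("numerical_error",
                              "no dialysis equilibrium in (0, ligand/2]"))
  r$root
}

#' Generate synthetic stopped-flow transients
#'
#' Simulates the binding observable for each concentration, maps it to
#' fluorescence through the linear concentration baseline
#' `alpha * [mD] + beta` plus an amplitude scale, and adds Gaussian noise
#' (`noise$stopped_flow` times the span).  Nothing is masked --- the dead
#' time is recorded on each trace for the fitters.
#'
#' @param truth A [synthetic_truth()].
#' @param conc Concentration set (uM); the default mirrors a 0-100 uM
#'   design.
#' @param condition Base condition (its `ligand_conc` is overridden per
#'   trace).
#' @param t_max,n_points Time grid (defaults 0.2 s, 800 points).
#' @param alpha,beta,scale Observation-model constants.
#' @param dead_time Recorded dead time (s).
#' @param seed Integer seed.
#' @return List of [stopped_flow_trace()] objects.
#' @export
gen_transients <- function(truth, conc = c(10, 20, 40, 60, 80, 100),
                           condition = recbcd_condition(), t_max = 0.2,
                           n_points = 800L, alpha = 0.002, beta = 0.1,
                           scale = 0.05, dead_time = 0.001, seed = 1) {
  stopifnot(inherits(truth, "recbcd_truth"))
  with_seed(seed, lapply(conc, function(mD) {
    cond <- condition; cond$ligand_conc <- mD
    times <- seq(0, t_max, length.out = n_points)
    obs <- exact_observable(truth$params, cond, times)
    mu <- alpha * mD + beta + scale * obs
    sd <- truth$noise$stopped_flow * max(diff(range(mu)), 1e-12)
    stopped_flow_trace(times, mu + stats::rnorm(n_points, 0, sd), mD,
                       dead_time = dead_time, condition = cond)
  }))
}

#' Generate synthetic single-turnover unwinding traces
#'
#' Builds lag-plus-decay traces with `t_lag = intercept + length / rate`,
#' where the rate is the truth model's steady-state unwinding rate at the
#' trace's condition, and adds Gaussian noise (`noise$fa`).
#'
#' @param truth A [synthetic_truth()].
#' @param lengths_bp Construct lengths (bp), default `c(24, 38, 52)`.
#' @param condition A [recbcd_condition()] (its `ligand_conc` is the ATP
#'   concentration).
#' @param n_points Samples per trace (default 600).
#' @param seed Integer seed.
#' @return List of [unwinding_trace()] objects; attribute `"truth"` carries
#'   the generating `(rate, intercept, k_diss)`.
#' @export
gen_unwinding <- function(truth, lengths_bp = c(24, 38, 52),
                          condition = recbcd_condition(ligand_conc = 350,
                                                       temperature = 16),
                          n_points = 600L, seed = 1) {
  stopifnot(inherits(truth, "recbcd_truth"))
  if (any(lengths_bp <= 0))
    stop_recbcd("invalid_argument", "lengths must be positive")
  uw <- truth$unwinding
  rate <- steady_state_unwinding_rate(truth$params, condition,
                                      bp_per_atp = truth$bp_per_atp)
  traces <- with_seed(seed, lapply(lengths_bp, function(L) {
    t_lag <- uw$intercept + L / rate
    times <- seq(0, t_lag + 6 / uw$k_diss, length.out = n_points)
    mu <- lag_decay_model(times, uw$A, uw$B, uw$k_diss, t_lag)
    unwinding_trace(times, mu + stats::rnorm(n_points, 0, truth$noise$fa),
                    L, condition, modality = "FA")
  }))
  attr(traces, "truth") <- list(rate = rate, intercept = uw$intercept,
                                k_diss = uw$k_diss)
  traces
}

#' Generate a synthetic optical-tweezers trace
#'
#' Integrates a piecewise-constant velocity profile (translocation at
#' `sm$velocity`, zero during scheduled pauses) into a contour trajectory,
#' maps contour to extension through the forward worm-like chain at a linear
#' force ramp across `sm$force_range`, and adds Gaussian extension noise.
#'
#' @param truth A [synthetic_truth()].
#' @param duration_s Trace duration (s).
#' @param fs Sampling rate (Hz), default 2500.
#' @param pauses Optional pause schedule (data frame `start_s`,
#'   `duration_s`) overriding `truth$sm$pauses`.
#' @param velocity Optional translocation velocity (bp/s) override.
#' @param persistence_nm,rise_nm_per_bp,stretch_pN,kT Forward WLC constants.
#' @param seed Integer seed.
#' @return A [tweezers_trace()]; attributes `"truth_contour"` (noise-free
#'   contour, bp) and `"pauses"` (the schedule actually applied).
#' @export
gen_tweezers_trace <- function(truth, duration_s = 4, fs = 2500,
                               pauses = NULL, velocity = NULL,
                               persistence_nm = 50, rise_nm_per_bp = 0.34,
                               stretch_pN = 1200, kT = 4.114, seed = 1) {
  stopifnot(inherits(truth, "recbcd_truth"))
  if (duration_s <= 0) stop_recbcd("invalid_argument", "duration must be > 0")
  if (is.null(pauses)) pauses <- truth$sm$pauses
  if (is.null(velocity)) velocity <- truth$sm$velocity
  n <- floor(duration_s * fs)
  time <- seq_len(n) / fs
  v <- rep(velocity, n)
  for (i in seq_len(NROW(pauses))) {
    v[time >= pauses$start_s[i] &
        time < pauses$start_s[i] + pauses$duration_s[i]] <- 0
  }
  contour_bp <- truth$sm$start_bp + cumsum(v) / fs
  force <- seq(truth$sm$force_range[1], truth$sm$force_range[2],
               length.out = n)
  ext <- wlc_extension(contour_bp * rise_nm_per_bp, force,
                       persistence_nm, stretch_pN, kT)
  ext <- with_seed(seed, ext + stats::rnorm(n, 0, truth$noise$tweezers_nm))
  tr <- tweezers_trace(time, ext, force)
  attr(tr, "truth_contour") <- contour_bp
  attr(tr, "pauses") <- pauses
  tr
}

#' Generate the reference multi-modality dataset
#'
#' Assembles a full synthetic study at the reference condition grid ---
#' isotherms at NaCl 75/200/300 mM crossed with adenosine 0/2 mM, calibrated
#' transient traces at seven concentrations (10-350 uM) with and without
#' adenosine, steady-state unwinding rates at six ATP concentrations for
#' three conditions, and equilibrium dialysis at the high (45 uM protein /
#' 1 mM ligand) and low (17 uM / 200 uM) regimes --- with known ground
#' truth and per-record uncertainties equal to the generator noise.  The
#' transient traces cover three conditions (NaCl 75 mM with and without 2 mM
#' adenosine, and NaCl 300 mM) so both the adenosine and the NaCl dependence
#' of the auxiliary pathway are kinetically constrained.
#'
#' @param truth A [synthetic_truth()].
#' @param seed Integer master seed; each record derives its own sub-seed.
#' @return A [recbcd_dataset()]; attribute `"truth"` is the generating
#'   truth.
#' @export
gen_dataset <- function(truth = synthetic_truth(), seed = 1) {
  stopifnot(inherits(truth, "recbcd_truth"))
  sub <- function(i) (seed * 1000L + i) %% .Machine$integer.max
  i <- 0L
  isotherms <- list()
  for (nacl in c(75, 200, 300)) for (ado in c(0, 2)) {
    i <- i + 1L
    isotherms[[i]] <- gen_isotherm(truth,
                                   condition = recbcd_condition(nacl = nacl,
                                                                adenosine = ado),
                                   seed = sub(i))
  }
  trans <- list()
  tconc <- c(10, 20, 40, 60, 80, 100, 350)
  tcond <- list(c(75, 0), c(75, 2), c(300, 0))
  for (cc in tcond) for (mD in tconc) {
    i <- i + 1L
    cond <- recbcd_condition(ligand_conc = mD, nacl = cc[1],
                             adenosine = cc[2])
    times <- seq(0.002, 0.3, length.out = 120)
    mu <- exact_observable(truth$params, cond, times)
    sd <- truth$noise$stopped_flow * max(diff(range(mu)), 1e-9)
    y <- with_seed(sub(i), mu + stats::rnorm(length(mu), 0, sd))
    trans[[length(trans) + 1L]] <-
      list(time = times, occupancy = y, sem = max(sd, 1e-9), condition = cond)
  }
  uw <- NULL
  uconc <- c(25, 50, 100, 200, 350, 700)
  for (cc in list(c(75, 0), c(300, 0), c(75, 2))) for (atp in uconc) {
    i <- i + 1L
    cond <- recbcd_condition(ligand_conc = atp, nacl = cc[1], adenosine = cc[2])
    r <- steady_state_unwinding_rate(truth$params, cond,
                                     bp_per_atp = truth$bp_per_atp)
    sd <- truth$noise$unwinding_rate * r
    robs <- with_seed(sub(i), r + stats::rnorm(1, 0, sd))
    sd <- max(sd, 1e-9)
    uw <- rbind(uw, data.frame(atp_uM = atp, nacl_mM = cc[1],
                               adenosine_mM = cc[2], temperature_C = 25,
                               rate_bp_s = robs, sem = sd))
  }
  dia <- list()
  for (d in list(c(45, 1000), c(17, 200))) {
    i <- i + 1L
    m <- gen_dialysis(truth, d[1], d[2], seed = sub(i))
    n_obs <- dialysis_bound_count(m)
    sem <- 2 * truth$noise$dialysis * m$ligand_final / m$protein
    dia[[length(dia) + 1L]] <- list(measurement = m, bound_n = n_obs,
                                    sem = max(sem, 1e-6),
                                    condition = recbcd_condition())
  }
  ds <- recbcd_dataset(isotherms = isotherms, transients = trans,
                       unwinding = uw, dialysis = dia)
  attr(ds, "truth") <- truth
  ds
}
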