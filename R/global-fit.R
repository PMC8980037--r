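#' Multi-experiment dataset
#'
#' Container for the heterogeneous records entering the joint fit.  Every
#' record carries an [recbcd_condition()] and a positive uncertainty.
#'
#' @param isotherms List of [binding_isotherm()] (with `sem`).
#' @param transients List of calibrated transient records: each a list with
#'   `time`, `occupancy` (baseline-corrected, occupancy-proportional
#'   signal), `sem`, `condition`.
#' @param kobs List of observed-rate records: each a list with a
#'   [kobs_curve()] as `curve` (fast phase; optionally `slow` rates),
#'   `condition`.
#' @param unwinding Data frame with columns `atp_uM`, `nacl_mM`,
#'   `adenosine_mM`, `temperature_C`, `rate_bp_s`, `sem`.
#' @param dialysis List of records: each a list with `measurement`
#'   (a [dialysis_measurement()]), `bound_n`, `sem`, `condition`.
#' @return Object of class `"recbcd_dataset"`.
#' @export
recbcd_dataset <- function(isotherms = list(), transients = list(),
                           kobs = list(), unwinding = NULL, dialysis = list()) {
  if (length(isotherms) &&
      !all(vapply(isotherms, inherits, TRUE, "binding_isotherm")))
    stop_recbcd("invalid_argument", "isotherms must be binding_isotherm objects")
  for (r in c(transients, dialysis))
    if (is.null(r$sem) || any(r$sem <= 0))
      stop_recbcd("invalid_argument", "every record needs a positive uncertainty")
  if (!is.null(unwinding) && any(unwinding$sem <= 0))
    stop_recbcd("invalid_argument", "unwinding records need positive sem")
  structure(list(isotherms = isotherms, transients = transients,
                 kobs = kobs, unwinding = unwinding, dialysis = dialysis),
            class = "recbcd_dataset")
}

#' @export
print.recbcd_dataset <- function(x, ...) {
  cat(sprintf(paste0("Multi-experiment dataset: %d isotherms, %d transient traces, ",
                     "%d k_obs curves, %d unwinding rates, %d dialysis points\n"),
              length(x$isotherms), length(x$transients), length(x$kobs),
              if (is.null(x$unwinding)) 0L else nrow(x$unwinding),
              length(x$dialysis)))
  invisible(x)
}

#' Names of the free parameters of the joint fit
#'
#' With the condition-linear substitutions (auxiliary on-rate linear in
#' adenosine; auxiliary off-rate and forward transfer linear in NaCl) the
#' scheme's free parameter vector is: `ks_on`, `ks_off`, `ktr_rev`,
#' `coop_a`, `vmax`, plus the six linear coefficients --- eleven parameters
#' in total.
#'
#' @return Character vector of length 11.
#' @export
free_parameter_names <- function() {
  c("ks_on", "ks_off", "kw_on_intercept", "kw_on_slope_ado",
    "kw_off_intercept", "kw_off_slope_nacl", "ktr_fwd_intercept",
    "ktr_fwd_slope_nacl", "ktr_rev", "coop_a", "vmax")
}

## Positive parameters are optimised on the log scale; the three
## condition slopes stay linear (their sign is free, clamping in
## resolve_rates enforces nonnegative rates).
.log_scale_params <- c("ks_on", "ks_off", "kw_on_intercept",
                       "kw_off_intercept", "ktr_fwd_intercept", "ktr_rev",
                       "coop_a", "vmax")
.slope_params <- c("kw_on_slope_ado", "kw_off_slope_nacl", "ktr_fwd_slope_nacl")

#' Default box bounds of the joint fit
#'
#' Natural-scale bounds per free parameter (rows `lower`, `upper`); rate
#' and cooperativity parameters are sampled and optimised in log space
#' within these bounds, condition slopes on the linear scale.
#'
#' @return A 2 x 11 matrix.
#' @export
default_fit_bounds <- function() {
  b <- rbind(
    lower = c(ks_on = 0.05, ks_off = 1, kw_on_intercept = 0.005,
              kw_on_slope_ado = -5, kw_off_intercept = 10,
              kw_off_slope_nacl = -20, ktr_fwd_intercept = 1,
              ktr_fwd_slope_nacl = -30, ktr_rev = 0.05, coop_a = 1,
              vmax = 10),
    upper = c(ks_on = 50, ks_off = 2000, kw_on_intercept = 20,
              kw_on_slope_ado = 0, kw_off_intercept = 2e4,
              kw_off_slope_nacl = 20, ktr_fwd_intercept = 2e4,
              ktr_fwd_slope_nacl = 0, ktr_rev = 1000, coop_a = 300,
              vmax = 2e4))
  b[, free_parameter_names()]
}

theta_to_params <- function(theta, n_weak = 4L, n_cat = 2L) {
  do.call(recbcd_params, c(as.list(theta),
                           list(n_weak_sites = n_weak, n_cat_sites = n_cat)))
}

to_internal <- function(theta) {
  out <- theta
  out[.log_scale_params] <- log(theta[.log_scale_params])
  out
}
from_internal <- function(z) {
  out <- z
  out[.log_scale_params] <- exp(z[.log_scale_params])
  out
}

#' Joint objective over all experiment blocks
#'
#' Sum of normalised squared errors: for every record the model predicts the
#' observation at the record's condition (rates scaled by the temperature
#' model's multiplier), residuals are standardised by the record
#' uncertainties, and each experiment block's squared residuals are divided
#' by the block's residual count, so no modality dominates by sheer point
#' count.  For the transient block a single amplitude scale (instrument
#' calibration) is profiled out analytically.  Prediction failures
#' contribute a large penalty instead of aborting the optimisation.
#'
#' @param theta Named parameter vector over [free_parameter_names()].
#' @param dataset A [recbcd_dataset()].
#' @param temp_model Optional [temperature_model()].
#' @param n_weak,n_cat Site counts of the candidate scheme.
#' @param breakdown Return the per-block breakdown as an attribute?
#' @return Nonnegative scalar.
#' @export
objective <- function(theta, dataset, temp_model = NULL,
                      n_weak = 4L, n_cat = 2L, breakdown = FALSE) {
  stopifnot(inherits(dataset, "recbcd_dataset"))
  theta <- theta[free_parameter_names()]
  if (any(is.na(theta)))
    stop_recbcd("invalid_argument", "theta must cover all free parameters")
  params <- tryCatch(theta_to_params(theta, n_weak, n_cat),
                     error = function(e) NULL)
  if (is.null(params)) return(1e12)
  blocks <- c(isotherm = 0, transient = 0, kobs = 0, unwinding = 0,
              dialysis = 0)
  counts <- blocks
  penalty <- FALSE
  safely <- function(expr) tryCatch(expr, error = function(e) NULL)

  for (iso in dataset$isotherms) {
    pred <- safely(model_isotherm(params, iso$condition, iso$conc,
                                  temp_model = temp_model))
    if (is.null(pred)) { penalty <- TRUE; next }
    sem <- if (is.null(iso$sem)) rep(1, length(pred)) else iso$sem
    blocks["isotherm"] <- blocks["isotherm"] + sum(((iso$signal - pred) / sem)^2)
    counts["isotherm"] <- counts["isotherm"] + length(pred)
  }
  if (length(dataset$transients)) {
    preds <- lapply(dataset$transients, function(r)
      safely(exact_observable(params, r$condition, r$time, temp_model)))
    if (any(vapply(preds, is.null, TRUE))) penalty <- TRUE
    ok <- !vapply(preds, is.null, TRUE)
    if (any(ok)) {
      y <- unlist(lapply(dataset$transients[ok], `[[`, "occupancy"))
      mu <- unlist(preds[ok])
      sem <- unlist(lapply(dataset$transients[ok], function(r)
        rep(r$sem, length(r$time))))
      s <- sum(y * mu / sem^2) / max(sum(mu^2 / sem^2), 1e-300)
      s <- max(s, 0)   # one shared instrument amplitude, profiled
      blocks["transient"] <- sum(((y - s * mu) / sem)^2)
      counts["transient"] <- length(y)
    }
  }
  for (r in dataset$kobs) {
    sem <- if (is.null(r$curve$se)) pmax(0.05 * r$curve$k_obs, 1e-9) else r$curve$se
    ## the curve holds fast-phase rates
    p_fast <- vapply(r$curve$conc, function(mD) {
      cond <- r$condition; cond$ligand_conc <- mD
      p <- safely(predict_kobs(params, cond, temp_model = temp_model)$k_obs[1])
      if (is.null(p) || is.na(p)) NA_real_ else p
    }, numeric(1))
    if (any(is.na(p_fast))) { penalty <- TRUE; next }
    blocks["kobs"] <- blocks["kobs"] + sum(((r$curve$k_obs - p_fast) / sem)^2)
    counts["kobs"] <- counts["kobs"] + length(p_fast)
  }
  if (!is.null(dataset$unwinding)) {
    uw <- dataset$unwinding
    for (i in seq_len(nrow(uw))) {
      cond <- recbcd_condition(ligand_conc = uw$atp_uM[i], nacl = uw$nacl_mM[i],
                               adenosine = uw$adenosine_mM[i],
                               temperature = uw$temperature_C[i])
      pred <- safely(steady_state_unwinding_rate(params, cond,
                                                 temp_model = temp_model))
      if (is.null(pred)) { penalty <- TRUE; next }
      blocks["unwinding"] <- blocks["unwinding"] +
        ((uw$rate_bp_s[i] - pred) / uw$sem[i])^2
      counts["unwinding"] <- counts["unwinding"] + 1
    }
  }
  for (r in dataset$dialysis) {
    pred <- safely({
      f <- dialysis_free_ligand(params, r$condition,
                                r$measurement$protein,
                                r$measurement$ligand_initial, temp_model)
      (r$measurement$ligand_initial - 2 * f) / r$measurement$protein
    })
    if (is.null(pred)) { penalty <- TRUE; next }
    blocks["dialysis"] <- blocks["dialysis"] + ((r$bound_n - pred) / r$sem)^2
    counts["dialysis"] <- counts["dialysis"] + 1
  }
  used <- counts > 0
  val <- sum(blocks[used] / counts[used]) + if (penalty) 1e6 else 0
  if (breakdown)
    attr(val, "blocks") <- data.frame(block = names(blocks)[used],
                                      sse = unname(blocks[used]),
                                      n = unname(counts[used]),
                                      normalised = unname(blocks[used] / counts[used]))
  val
}

## Identifiability of the condition slopes requires condition contrast.
check_condition_coverage <- function(dataset) {
  conds <- c(lapply(dataset$isotherms, `[[`, "condition"),
             lapply(dataset$transients, `[[`, "condition"),
             lapply(dataset$kobs, `[[`, "condition"),
             lapply(dataset$dialysis, `[[`, "condition"))
  ado <- vapply(conds, `[[`, numeric(1), "adenosine")
  nacl <- vapply(conds, `[[`, numeric(1), "nacl")
  if (!is.null(dataset$unwinding)) {
    ado <- c(ado, dataset$unwinding$adenosine_mM)
    nacl <- c(nacl, dataset$unwinding$nacl_mM)
  }
  list(n_ado = length(unique(ado)), n_nacl = length(unique(nacl)))
}

#' Fit the transfer scheme jointly to a multi-experiment dataset
#'
#' Seeded multi-start local optimisation of the eleven-parameter objective:
#' starting points are drawn log-uniformly (slopes uniformly) inside the box
#' bounds, a start at the box centre is always included, each start is
#' polished with a quasi-Newton bounded minimiser, and the best optimum is
#' returned together with every start's outcome.  Identical seed and
#' dataset give identical results.  If the dataset varies fewer than two
#' adenosine (NaCl) levels the corresponding slope coefficients are
#' unidentifiable and are fixed at zero with a warning.
#'
#' @param dataset A [recbcd_dataset()].
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed for the start scatter.
#' @param bounds Bounds matrix as [default_fit_bounds()].
#' @param fix Optional named vector of parameters to hold fixed.
#' @param n_weak,n_cat Site counts of the fitted scheme.
#' @param temp_model Optional [temperature_model()].
#' @param start Optional named start vector; when given it is used as an
#'   additional (first) start.
#' @param maxit Iteration cap per start.
#' @param n_polish Number of screened starts polished on the full dataset.
#' @param include_default_starts Include the deterministic centre and
#'   data-driven starts in the scatter (disabled for warm-started refits).
#' @return Object of class `"recbcd_fit"`.
#' @export
run_global_fit <- function(dataset, n_starts = 20L, seed = 1L,
                           bounds = default_fit_bounds(), fix = NULL,
                           n_weak = 4L, n_cat = 2L, temp_model = NULL,
                           start = NULL, maxit = 250L, n_polish = 6L,
                           include_default_starts = TRUE) {
  stopifnot(inherits(dataset, "recbcd_dataset"))
  nm <- free_parameter_names()
  cov <- check_condition_coverage(dataset)
  fix <- fix %||% numeric(0)
  if (cov$n_ado < 2 && !"kw_on_slope_ado" %in% names(fix)) {
    warning("single adenosine level: fixing kw_on_slope_ado = 0 (reduced fit)",
            call. = FALSE)
    fix <- c(fix, kw_on_slope_ado = 0)
  }
  if (cov$n_nacl < 2 &&
      !all(c("kw_off_slope_nacl", "ktr_fwd_slope_nacl") %in% names(fix))) {
    warning("single NaCl level: fixing the NaCl slopes at 0 (reduced fit)",
            call. = FALSE)
    fix <- c(fix, kw_off_slope_nacl = 0, ktr_fwd_slope_nacl = 0)
    fix <- fix[!duplicated(names(fix))]
  }
  free <- setdiff(nm, names(fix))
  full_theta <- function(th_free) {
    th <- c(th_free, fix)[nm]
    names(th) <- nm
    th
  }
  obj_free <- function(z_free) {
    th_free <- from_internal_sub(z_free, free)
    objective(full_theta(th_free), dataset, temp_model, n_weak, n_cat)
  }
  from_internal_sub <- function(z, names_) {
    out <- z
    lg <- intersect(names_, .log_scale_params)
    out[lg] <- exp(z[lg])
    names(out) <- names_
    out
  }
  to_internal_sub <- function(th, names_) {
    out <- th
    lg <- intersect(names_, .log_scale_params)
    out[lg] <- log(pmax(th[lg], 1e-300))
    names(out) <- names_
    out
  }
  lo <- to_internal_sub(bounds["lower", free], free)
  hi <- to_internal_sub(bounds["upper", free], free)

  ## scatter: log-uniform draws for the log-scale parameters; slopes get a
  ## log-uniform magnitude (sign from the bounds, random where both allowed)
  draw_start <- function() {
    z <- lo + stats::runif(length(free)) * (hi - lo)
    names(z) <- free
    for (sp in intersect(free, .slope_params)) {
      l <- bounds["lower", sp]; u <- bounds["upper", sp]
      mx <- max(abs(c(l, u)))
      mag <- 10^stats::runif(1, log10(mx) - 3, log10(mx))
      sgn <- if (u <= 0) -1 else if (l >= 0) 1 else sample(c(-1, 1), 1)
      z[sp] <- min(max(sgn * mag, l), u)
    }
    z
  }
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) draw_start()))
  if (include_default_starts) {
    starts <- c(list((lo + hi) / 2), starts)        # deterministic centre start
    ss <- tryCatch(smart_start(dataset, bounds), error = function(e) NULL)
    if (!is.null(ss)) {
      ## the data-driven seed pins the well-identified parameters; scatter
      ## the dimensions it cannot estimate (transfer rate, cooperativity)
      variants <- list(c(1, 1), c(8, 1), c(40, 1), c(8, 0.3), c(8, 3))
      smart <- lapply(variants, function(v) {
        th <- ss
        th["ktr_fwd_intercept"] <- min(max(ss[["ktr_fwd_intercept"]] * v[1],
                                           bounds["lower", "ktr_fwd_intercept"]),
                                       bounds["upper", "ktr_fwd_intercept"])
        th["coop_a"] <- min(max(ss[["coop_a"]] * v[2],
                                bounds["lower", "coop_a"]),
                            bounds["upper", "coop_a"])
        to_internal_sub(th[free], free)
      })
      starts <- c(smart, starts)
    }
  }
  if (!is.null(start))
    starts <- c(list(to_internal_sub(start[free], free)), starts)

  mk_polish <- function(objfun) function(z0, iters) {
    o <- tryCatch(stats::nlminb(pmin(pmax(z0, lo), hi), objfun,
                                lower = lo, upper = hi,
                                control = list(iter.max = iters,
                                               eval.max = 4 * iters)),
                  error = function(e) NULL)
    if (is.null(o)) return(list(ok = FALSE, objective = Inf))
    list(ok = TRUE, objective = o$objective, par = o$par,
         convergence = o$convergence, message = o$message)
  }
  polish <- mk_polish(obj_free)
  ## stage 1 screens every start on a decimated dataset (transient traces
  ## subsampled 3x): same landscape shape at a third of the cost
  ds_coarse <- dataset
  ds_coarse$transients <- lapply(dataset$transients, function(r) {
    keep <- seq(1, length(r$time), by = 3)
    r$time <- r$time[keep]; r$occupancy <- r$occupancy[keep]
    r
  })
  obj_coarse <- function(z_free) {
    th_free <- from_internal_sub(z_free, free)
    objective(full_theta(th_free), ds_coarse, temp_model, n_weak, n_cat)
  }
  coarse <- lapply(starts, mk_polish(obj_coarse), iters = min(60L, maxit))
  objs <- vapply(coarse, `[[`, numeric(1), "objective")
  if (!any(is.finite(objs)))
    stop_recbcd("fit_error", "all optimisation starts failed")
  top <- order(objs)[seq_len(min(n_polish, sum(is.finite(objs))))]
  runs <- lapply(coarse, function(r) { r$objective <- Inf; r })
  for (i in top) {
    if (!isTRUE(coarse[[i]]$ok)) next
    r <- polish(coarse[[i]]$par, maxit)
    if (isTRUE(r$ok)) runs[[i]] <- r
  }
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- runs[[which.min(objs)]]
  ## clamp-aware restart: when the fitted adenosine slope drives the
  ## auxiliary on-rate to zero at the highest measured adenosine, the
  ## objective is flat in that direction (the rate is clamped) and the
  ## optimum may sit on the plateau; retry once from a half-blocked slope
  ado_max <- max(c(0, vapply(dataset$isotherms, function(i)
    i$condition$adenosine, numeric(1)),
    vapply(dataset$transients, function(r) r$condition$adenosine, numeric(1)),
    if (!is.null(dataset$unwinding)) dataset$unwinding$adenosine_mM))
  if (ado_max > 0 && "kw_on_slope_ado" %in% free && isTRUE(best$ok)) {
    th_b <- full_theta(from_internal_sub(best$par, free))
    if (th_b["kw_on_intercept"] + th_b["kw_on_slope_ado"] * ado_max <= 0) {
      th_retry <- th_b
      th_retry["kw_on_slope_ado"] <-
        max(-0.5 * th_b[["kw_on_intercept"]] / ado_max,
            bounds["lower", "kw_on_slope_ado"])
      r <- polish(to_internal_sub(th_retry[free], free), maxit)
      if (isTRUE(r$ok) && r$objective < best$objective) {
        runs <- c(runs, list(r))
        objs <- c(objs, r$objective)
        best <- r
      }
    }
  }
  th_best <- full_theta(from_internal_sub(best$par, free))
  val <- objective(th_best, dataset, temp_model, n_weak, n_cat,
                   breakdown = TRUE)
  structure(list(
    coefficients = th_best, objective = as.numeric(val),
    blocks = attr(val, "blocks"), free = free, fixed = fix,
    n_weak = n_weak, n_cat = n_cat,
    starts = data.frame(start = seq_along(runs), objective = objs,
                        converged = vapply(runs, function(r)
                          isTRUE(r$ok) && isTRUE(r$convergence == 0), TRUE)),
    seed = seed, bounds = bounds, temp_model = temp_model,
    dataset = dataset),
    class = "recbcd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Data-driven starting point: rough single-modality estimates, the way a
## kineticist would seed the joint fit by hand.  Every value is clipped into
## the box bounds; failures fall back to the bound mid-point.
smart_start <- function(dataset, bounds = default_fit_bounds()) {
  nm <- free_parameter_names()
  gmid <- function(p) if (bounds["lower", p] > 0)
    sqrt(bounds["lower", p] * bounds["upper", p])
  else (bounds["lower", p] + bounds["upper", p]) / 2
  th <- vapply(nm, gmid, numeric(1))
  clip <- function(p, v) {
    if (!is.finite(v)) return(th[[p]])
    min(max(v, bounds["lower", p]), bounds["upper", p])
  }
  ## catalytic rates from the concentration dependence of the single-
  ## exponential relaxation of low-concentration transients
  tr <- Filter(function(r) r$condition$adenosine == 0 &&
                 r$condition$ligand_conc <= 150, dataset$transients)
  if (length(tr) >= 3) {
    ks <- vapply(tr, function(r)
      tryCatch(varpro_exp_fit(r$time, r$occupancy, 1L)$k,
               error = function(e) NA_real_), numeric(1))
    cc <- vapply(tr, function(r) r$condition$ligand_conc, numeric(1))
    if (sum(is.finite(ks)) >= 3) {
      cf <- stats::coef(stats::lm(ks ~ cc))
      th["ks_on"] <- clip("ks_on", cf[2])
      th["ks_off"] <- clip("ks_off", cf[1])
    }
  }
  ## phase dissociation constants from per-condition double-Hill fits
  hill <- lapply(dataset$isotherms, function(iso)
    tryCatch(suppressWarnings(coef(fit_double_hill(iso))),
             error = function(e) NULL))
  cond <- lapply(dataset$isotherms, `[[`, "condition")
  ok <- !vapply(hill, is.null, TRUE)
  if (any(ok)) {
    ado <- vapply(cond, `[[`, numeric(1), "adenosine")[ok]
    nacl <- vapply(cond, `[[`, numeric(1), "nacl")[ok]
    Kd_s <- vapply(hill[ok], `[`, numeric(1), "Ks")
    Kd_w <- vapply(hill[ok], `[`, numeric(1), "Kw")
    base <- ado == 0 & is.finite(Kd_s)
    if (any(base))
      th["ks_off"] <- clip("ks_off", th[["ks_on"]] * mean(Kd_s[base]))
    a0 <- 15                              # nominal cooperativity for seeding
    Kw_assoc <- a0^(-3 / 4) / Kd_w        # half-saturation -> association
    th["kw_on_intercept"] <- clip("kw_on_intercept", 0.3)
    if (sum(base) >= 2 && length(unique(nacl[base])) >= 2) {
      cf <- stats::coef(stats::lm(th[["kw_on_intercept"]] / Kw_assoc[base] ~
                                    nacl[base]))
      th["kw_off_intercept"] <- clip("kw_off_intercept", cf[1])
      th["kw_off_slope_nacl"] <- clip("kw_off_slope_nacl", cf[2])
    } else if (any(base)) {
      th["kw_off_intercept"] <- clip("kw_off_intercept",
                                     th[["kw_on_intercept"]] /
                                       mean(Kw_assoc[base]))
    }
    blocked <- ado > 0 & is.finite(Kd_w)
    slope_ado <- if (any(blocked)) {
      kw_on_ado <- mean(Kw_assoc[blocked]) * th[["kw_off_intercept"]]
      (kw_on_ado - th[["kw_on_intercept"]]) / mean(ado[blocked])
    } else NA_real_
    ## blocked-condition weak phases are often unresolvable (monophasic
    ## curves), leaving the slope estimate useless: fall back to strong block
    if (!is.finite(slope_ado) || slope_ado >= 0)
      slope_ado <- -0.4 * th[["kw_on_intercept"]]
    th["kw_on_slope_ado"] <- clip("kw_on_slope_ado", slope_ado)
  }
  ## saturating catalysis from the largest observed unwinding rate
  if (!is.null(dataset$unwinding) && nrow(dataset$unwinding)) {
    vtop <- max(dataset$unwinding$rate_bp_s)
    th["vmax"] <- clip("vmax", vtop / (0.5 * 2 * 0.85))
    nacls <- unique(dataset$unwinding$nacl_mM)
    if (length(nacls) >= 2) {
      ktr0 <- th[["ktr_fwd_intercept"]]
      th["ktr_fwd_slope_nacl"] <- clip("ktr_fwd_slope_nacl",
                                       -0.8 * ktr0 / max(nacls))
    }
  }
  th[nm]
}

#' @export
coef.recbcd_fit <- function(object, ...) object$coefficients

#' @export
print.recbcd_fit <- function(x, ...) {
  cat(sprintf("Joint fit of the auxiliary-site transfer scheme (%d free parameters, %d starts)\n",
              length(x$free), nrow(x$starts)))
  cat(sprintf("  objective (normalised chi^2): %.6g\n", x$objective))
  print(round(x$coefficients, 5))
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), x$fixed, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.recbcd_fit <- function(object, ...) {
  print(object)
  cat("\nPer-block residual breakdown:\n")
  print(object$blocks, row.names = FALSE)
  cat("\nStart outcomes (best 5):\n")
  print(utils::head(object$starts[order(object$starts$objective), ], 5),
        row.names = FALSE)
  invisible(object)
}

#' Predict observables from a fitted scheme
#'
#' @param object A `recbcd_fit`.
#' @param type `"isotherm"`, `"unwinding"`, `"kobs"`, or `"occupancy"`.
#' @param condition A [recbcd_condition()].
#' @param conc Concentration grid where applicable.
#' @param ... Passed to the underlying model function.
#' @return Numeric predictions.
#' @export
predict.recbcd_fit <- function(object, type = c("isotherm", "unwinding",
                                                "kobs", "occupancy"),
                               condition = recbcd_condition(), conc = NULL,
                               ...) {
  type <- match.arg(type)
  params <- theta_to_params(object$coefficients, object$n_weak, object$n_cat)
  switch(type,
    isotherm = model_isotherm(params, condition,
                              conc %||% exp(seq(log(0.5), log(550),
                                                length.out = 50)),
                              temp_model = object$temp_model, ...),
    unwinding = vapply(conc %||% condition$ligand_conc, function(atp) {
      cond <- condition; cond$ligand_conc <- atp
      steady_state_unwinding_rate(params, cond,
                                  temp_model = object$temp_model, ...)
    }, numeric(1)),
    kobs = predict_kobs(params, condition, temp_model = object$temp_model,
                        ...)$k_obs,
    occupancy = {
      r <- resolve_rates(params, condition, object$temp_model)
      K <- association_constants(r)
      mean_occupancy(K$Ks, K$Kw, r$coop_a,
                     conc %||% condition$ligand_conc,
                     n_weak = object$n_weak, n_cat = object$n_cat)
    })
}

#' Bootstrap Monte Carlo over the measurement uncertainties
#'
#' Generates `n` perturbed datasets by drawing every measured value from a
#' Gaussian centred on the measurement with standard deviation equal to its
#' stated uncertainty (times `width`), refits each replicate (warm-started
#' from the point estimate), and summarises each parameter's replicate
#' histogram by a Gaussian (mean and s.d.).  Failed replicates are recorded
#' and excluded from the summaries.
#'
#' @param fit A [run_global_fit()] result.
#' @param n Number of replicates (default 100).
#' @param seed Integer seed.
#' @param width Perturbation scale in units of the stated uncertainties
#'   (default 1; 0 reproduces the point estimate exactly).
#' @param n_starts Starts per replicate refit (default 1, warm start).
#' @param maxit Iteration cap per replicate.
#' @return Object of class `"recbcd_bootstrap"`: `replicates` (matrix n x
#'   p), `summary` (per-parameter mean/sd), `converged` fraction, `seeds`.
#' @export
bootstrap <- function(fit, n = 100L, seed = 1L, width = 1, n_starts = 1L,
                      maxit = 150L) {
  stopifnot(inherits(fit, "recbcd_fit"))
  ds <- fit$dataset
  seeds <- seed * 10000L + seq_len(n)
  reps <- matrix(NA_real_, n, length(fit$coefficients),
                 dimnames = list(NULL, names(fit$coefficients)))
  ok <- logical(n)
  for (b in seq_len(n)) {
    ds_b <- with_seed(seeds[b], perturb_dataset(ds, width))
    r <- tryCatch(
      run_global_fit(ds_b, n_starts = n_starts - 1L, seed = seeds[b],
                     bounds = fit$bounds, fix = fit$fixed,
                     n_weak = fit$n_weak, n_cat = fit$n_cat,
                     temp_model = fit$temp_model,
                     start = fit$coefficients, maxit = maxit,
                     include_default_starts = FALSE),
      error = function(e) NULL)
    if (!is.null(r)) { reps[b, ] <- r$coefficients; ok[b] <- TRUE }
  }
  good <- reps[ok, , drop = FALSE]
  structure(list(
    replicates = reps,
    summary = data.frame(parameter = colnames(reps),
                         mean = colMeans(good),
                         sd = apply(good, 2, stats::sd)),
    converged = mean(ok), n = n, seeds = seeds, width = width,
    point = fit$coefficients),
    class = "recbcd_bootstrap")
}

#' @export
print.recbcd_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap Monte Carlo: %d replicates (%.0f%% converged, width %g)\n",
              x$n, 100 * x$converged, x$width))
  print(transform(x$summary, mean = signif(mean, 5), sd = signif(sd, 3)),
        row.names = FALSE)
  invisible(x)
}

## Gaussian perturbation of every measured value by its stated uncertainty.
perturb_dataset <- function(ds, width) {
  if (width == 0) return(ds)
  ds$isotherms <- lapply(ds$isotherms, function(iso) {
    iso$signal <- iso$signal + stats::rnorm(length(iso$signal), 0,
                                            width * (iso$sem %||% 0))
    iso
  })
  ds$transients <- lapply(ds$transients, function(r) {
    r$occupancy <- r$occupancy +
      stats::rnorm(length(r$occupancy), 0, width * r$sem)
    r
  })
  ds$kobs <- lapply(ds$kobs, function(r) {
    se <- r$curve$se %||% rep(0, length(r$curve$k_obs))
    r$curve$k_obs <- r$curve$k_obs +
      stats::rnorm(length(se), 0, width * se)
    r
  })
  if (!is.null(ds$unwinding))
    ds$unwinding$rate_bp_s <- ds$unwinding$rate_bp_s +
      stats::rnorm(nrow(ds$unwinding), 0, width * ds$unwinding$sem)
  ds$dialysis <- lapply(ds$dialysis, function(r) {
    r$bound_n <- r$bound_n + stats::rnorm(1, 0, width * r$sem)
    r
  })
  ds
}

#' Select the auxiliary-site count
#'
#' Refits the scheme for each candidate number of auxiliary sites and ranks
#' the candidates by the small-sample-corrected information criterion
#' computed from the total weighted residual sum of squares (the free
#' parameter count is the same for every candidate, so the ranking reflects
#' fit quality; AICc is still reported for reference).  Equilibrium
#' isotherms are the discriminating modality and must be present.
#'
#' @param dataset A [recbcd_dataset()] containing isotherms.
#' @param candidates Candidate auxiliary-site counts (default 2:6).
#' @param n_starts,seed,maxit Passed to [run_global_fit()].
#' @param ... Further arguments for [run_global_fit()].
#' @return Object of class `"site_selection"`: `best` (selected count) and
#'   `table` (candidate, objective, total weighted SSE, AICc).
#' @export
select_weak_site_count <- function(dataset, candidates = 2:6, n_starts = 6L,
                                   seed = 1L, maxit = 200L, ...) {
  stopifnot(inherits(dataset, "recbcd_dataset"))
  if (!length(dataset$isotherms))
    stop_recbcd("invalid_argument",
                "site-count selection needs equilibrium isotherms")
  rows <- lapply(candidates, function(nw) {
    fit <- run_global_fit(dataset, n_starts = n_starts, seed = seed,
                          n_weak = nw, maxit = maxit, ...)
    sse <- sum(fit$blocks$sse)
    N <- sum(fit$blocks$n)
    k <- length(fit$free)
    ## the deviance is the block-normalised objective the estimator
    ## minimises, so candidates are compared on the same footing as the fit
    aicc <- N * log(fit$objective / nrow(fit$blocks)) + 2 * k +
      2 * k * (k + 1) / max(N - k - 1, 1)
    data.frame(n_weak = nw, objective = fit$objective, sse = sse,
               aicc = aicc)
  })
  tab <- do.call(rbind, rows)
  structure(list(best = tab$n_weak[which.min(tab$aicc)], table = tab),
            class = "site_selection")
}

#' @export
print.site_selection <- function(x, ...) {
  cat(sprintf("Auxiliary-site count selection: best = %d\n", x$best))
  print(transform(x$table, objective = signif(objective, 5),
                  sse = signif(sse, 5), aicc = round(aicc, 1)),
        row.names = FALSE)
  invisible(x)
}

#' Write bootstrap replicates as CSV
#'
#' One row per replicate with the fitted parameter vector and a convergence
#' flag.
#'
#' @param bs A [bootstrap()] result.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_bootstrap_csv <- function(bs, path) {
  stopifnot(inherits(bs, "recbcd_bootstrap"))
  df <- data.frame(replicate = seq_len(nrow(bs$replicates)),
                   seed = bs$seeds, converged = !is.na(bs$replicates[, 1]),
                   bs$replicates, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
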