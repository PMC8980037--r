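#' Sum-of-two-Hill-equations binding isotherm
#'
#' Phenomenological model for a biphasic binding isotherm: a strong,
#' weakly-cooperative phase (dissociation constant `Ks`, Hill coefficient
#' `ns`) and a weak, cooperative phase (`Kw`, `nw`), mixed by the partition
#' coefficient `p`:
#' \deqn{y = \frac{p}{1 + (K_s/[mN])^{n_s}} +
#'       \frac{1 - p}{1 + (K_w/[mN])^{n_w}}.}
#' `y(0) = 0` and `y` tends to 1 at saturating ligand.  Note the Hill
#' coefficients are purely descriptive and are never converted to site
#' counts.
#'
#' @param mN Ligand concentration(s), uM (vectorised).
#' @param p Partition coefficient of the strong phase, in `[0, 1]`.
#' @param Ks,Kw Phase dissociation constants (uM, > 0).
#' @param ns,nw Phase Hill coefficients (> 0).
#' @return Fraction bound, same length as `mN`.
#' @export
#' @examples
#' double_hill(10, p = 1, Ks = 10, ns = 1, Kw = 100, nw = 2)  # 0.5
double_hill <- function(mN, p, Ks, ns, Kw, nw) {
  if (p < 0 || p > 1 || Ks <= 0 || Kw <= 0 || ns <= 0 || nw <= 0)
    stop_recbcd("invalid_argument",
                "need 0 <= p <= 1 and positive Ks, ns, Kw, nw")
  y <- numeric(length(mN))
  pos <- mN > 0
  y[pos] <- p / (1 + (Ks / mN[pos])^ns) + (1 - p) / (1 + (Kw / mN[pos])^nw)
  y  # mN = 0 handled as the limit y = 0
}

#' Binding isotherm record
#'
#' @param conc Ligand concentrations (uM), strictly increasing.
#' @param signal Normalised signal at each concentration.
#' @param sem Optional per-point standard errors (used as fit weights).
#' @param condition A [recbcd_condition()].
#' @return An object of class `"binding_isotherm"`.
#' @export
binding_isotherm <- function(conc, signal, sem = NULL,
                             condition = recbcd_condition()) {
  if (length(conc) != length(signal))
    stop_recbcd("invalid_argument", "conc and signal lengths differ")
  if (any(diff(conc) <= 0))
    stop_recbcd("invalid_argument", "concentrations must be strictly increasing")
  if (!is.null(sem) && (length(sem) != length(conc) || any(sem <= 0)))
    stop_recbcd("invalid_argument", "sem must be positive and match conc")
  structure(list(conc = conc, signal = signal, sem = sem,
                 condition = condition), class = "binding_isotherm")
}

#' Fit the double-Hill model to an isotherm
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt with box bounds;
#' weights `1/sem^2` when standard errors are present and `weighted = TRUE`).
#' The partition coefficient is constrained to `[0, 1]`.  Starting values,
#' unless supplied: `Ks` from the concentration at half the first-phase
#' amplitude, `Kw = 10 Ks`, `p = 0.5`, `ns = nw = 1` (the two phases overlap,
#' so the objective is multimodal and a neutral start is used).
#'
#' @param isotherm A [binding_isotherm()] with at least 6 points.
#' @param init Optional named list/vector of starting values
#'   (`p, Ks, ns, Kw, nw`).
#' @param weighted Use `1/sem^2` weights when `sem` is available?
#' @return Object of class `"hill_fit"`: `coefficients`, `se`, `rss`,
#'   `fitted`, `df`.  A warning is raised when the fitted `p` is pinned at a
#'   boundary (effectively single-phase data).
#' @export
fit_double_hill <- function(isotherm, init = NULL, weighted = TRUE) {
  stopifnot(inherits(isotherm, "binding_isotherm"))
  x <- isotherm$conc; y <- isotherm$signal
  if (length(x) < 6)
    stop_recbcd("fit_error", "need at least 6 points to fit a double-Hill isotherm")
  w <- if (weighted && !is.null(isotherm$sem)) 1 / isotherm$sem^2 else rep(1, length(x))
  conc_at <- function(frac) {
    i <- which(y >= frac * max(y))[1]
    if (is.na(i) || x[i] <= 0) stats::median(x) else x[i]
  }
  if (is.null(init)) {
    ## the objective is multimodal (phase overlap): scatter a few neutral
    ## starts and keep the best optimum
    Ks0 <- conc_at(0.25)
    starts <- list(
      c(p = 0.5, Ks = Ks0, ns = 1, Kw = 10 * Ks0, nw = 1),
      c(p = 0.5, Ks = conc_at(0.2), ns = 1, Kw = conc_at(0.75), nw = 2),
      c(p = 0.3, Ks = conc_at(0.15), ns = 1, Kw = conc_at(0.7), nw = 2),
      c(p = 0.7, Ks = conc_at(0.35), ns = 1, Kw = conc_at(0.85), nw = 2))
  } else {
    starts <- list(unlist(init)[c("p", "Ks", "ns", "Kw", "nw")])
  }
  resid_fun <- function(th)
    sqrt(w) * (y - double_hill(x, th[1], th[2], th[3], th[4], th[5]))
  lower <- c(0, 1e-6, 1e-2, 1e-6, 1e-2)
  upper <- c(1, 1e8, 25, 1e8, 25)
  fit <- NULL
  for (p0 in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f) || f$info == 0 || any(!is.finite(f$par))) next
    if (is.null(fit) || sum(f$fvec^2) < sum(fit$fvec^2)) fit <- f
  }
  if (is.null(fit))
    stop_recbcd("fit_error", "double-Hill fit did not converge from any start")
  th <- fit$par
  rss <- sum(fit$fvec^2)
  dof <- length(x) - 5L
  vc <- tryCatch(solve(fit$hessian) * rss / max(dof, 1), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 5) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(th)
  if (th["p"] > 0.995 || th["p"] < 0.005)
    warning("partition coefficient at boundary: data look single-phase",
            call. = FALSE)
  structure(list(coefficients = th, se = se, rss = rss,
                 fitted = double_hill(x, th[1], th[2], th[3], th[4], th[5]),
                 residuals = y - double_hill(x, th[1], th[2], th[3], th[4], th[5]),
                 df = dof, isotherm = isotherm),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cat("Double-Hill isotherm fit\n")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  cat(sprintf("Residual sum of squares: %.4g on %d degrees of freedom\n",
              x$rss, x$df))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

## Single-Hill fit (p pinned to 1): used for monophasic comparisons.
fit_single_hill <- function(conc, signal) {
  resid_fun <- function(th) signal - double_hill(conc, 1, th[1], th[2], 1, 1)
  K0 <- conc[which(signal >= 0.5 * max(signal))[1]]
  if (is.na(K0) || K0 <= 0) K0 <- stats::median(conc)
  fit <- minpack.lm::nls.lm(par = c(Ks = K0, ns = 1),
                            lower = c(1e-6, 1e-2), upper = c(1e8, 25),
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  rss <- sum(fit$fvec^2)
  tss <- sum((signal - mean(signal))^2)
  list(coefficients = fit$par, rss = rss, r_squared = 1 - rss / tss)
}

#' Model-predicted binding isotherm
#'
#' Equilibrium titration signal predicted by the transfer scheme: a weighted
#' sum of the mean catalytic-site and auxiliary-site occupancies (the two
#' site classes can differ in their optical response), normalised to its
#' value at the largest measured concentration (titration signals are scaled
#' by their end point, not by the asymptote).
#'
#' @param params A [recbcd_params()].
#' @param condition A [recbcd_condition()] (sets NaCl/adenosine; the `conc`
#'   grid supplies the ligand axis).
#' @param conc Ligand concentrations (uM).
#' @param signal_weights Length-2 nonnegative weights `(weight_cat,
#'   weight_weak)`; equal weights make the curve proportional to the total
#'   mean occupancy.
#' @param temp_model Optional [temperature_model()].
#' @return Predicted normalised signal, same length as `conc`.
#' @export
model_isotherm <- function(params, condition, conc, signal_weights = c(1, 1),
                           temp_model = NULL) {
  if (length(signal_weights) != 2 || any(signal_weights < 0))
    stop_recbcd("invalid_argument", "signal_weights must be 2 nonnegative numbers")
  if (sum(signal_weights) == 0)
    stop_recbcd("invalid_argument", "at least one signal weight must be positive")
  rates <- resolve_rates(params, condition, temp_model)
  K <- association_constants(rates)
  occ <- mean_occupancy_split(K$Ks, K$Kw, rates$coop_a, conc,
                              n_weak = params$n_weak_sites,
                              n_cat = params$n_cat_sites)
  sig <- signal_weights[1] * occ$cat + signal_weights[2] * occ$weak
  top <- sig[which.max(conc)]
  if (top <= 0) return(sig * 0)
  sig / top
}

#' Equilibrium-dialysis measurement record
#'
#' Two equal chambers separated by a ligand-permeable membrane; at
#' equilibrium the free ligand is equal on both sides, so mass conservation
#' reads `[N]_i = 2 [N]_f + n [protein]`.
#'
#' @param ligand_initial Ligand concentration loaded at the start (uM).
#' @param ligand_final Free-ligand concentration at the end, measured in the
#'   ligand-only chamber (uM).
#' @param protein Protein concentration in the protein chamber (uM, > 0).
#' @return An object of class `"dialysis_measurement"`.
#' @export
dialysis_measurement <- function(ligand_initial, ligand_final, protein) {
  if (protein <= 0)
    stop_recbcd("invalid_argument", "protein concentration must be > 0")
  if (ligand_final < 0 || ligand_initial < 0)
    stop_recbcd("invalid_argument", "concentrations must be >= 0")
  structure(list(ligand_initial = ligand_initial, ligand_final = ligand_final,
                 protein = protein), class = "dialysis_measurement")
}

#' Bound ligands per protein from equilibrium dialysis
#'
#' Applies the mass-conservation relation `n = ([N]_i - 2 [N]_f) /
#' [protein]`.  A negative result (possible under measurement noise) is
#' returned with a warning.
#'
#' @param m A [dialysis_measurement()].
#' @return Bound ligand molecules per protein molecule.
#' @export
#' @examples
#' dialysis_bound_count(dialysis_measurement(1000, 450, 45))  # 2.22
dialysis_bound_count <- function(m) {
  stopifnot(inherits(m, "dialysis_measurement"))
  n <- (m$ligand_initial - 2 * m$ligand_final) / m$protein
  if (n < 0)
    warning("negative bound count (measurement noise?)", call. = FALSE)
  n
}

#' Read / write isotherm CSV
#'
#' Columns: `conc_uM`, `signal`, optional `sem`, `nacl_mM`, `adenosine_mM`,
#' `temperature_C`.
#'
#' @param isotherm A [binding_isotherm()].
#' @param path CSV path.
#' @return `write_isotherm_csv` the path invisibly; `read_isotherm_csv` a
#'   `binding_isotherm`.
#' @export
write_isotherm_csv <- function(isotherm, path) {
  cond <- isotherm$condition
  df <- data.frame(conc_uM = isotherm$conc, signal = isotherm$signal,
                   sem = if (is.null(isotherm$sem)) NA_real_ else isotherm$sem,
                   nacl_mM = cond$nacl, adenosine_mM = cond$adenosine,
                   temperature_C = cond$temperature)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotherm_csv
#' @export
read_isotherm_csv <- function(path) {
  df <- utils::read.csv(path)
  sem <- if (all(is.na(df$sem))) NULL else df$sem
  binding_isotherm(df$conc_uM, df$signal, sem,
                   recbcd_condition(nacl = df$nacl_mM[1],
                                    adenosine = df$adenosine_mM[1],
                                    temperature = df$temperature_C[1]))
}
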