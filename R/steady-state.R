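#' Quadratic (tight-binding) Briggs-Haldane rate equation
#'
#' Steady-state turnover velocity as a function of *total* substrate, exact
#' at enzyme concentrations comparable to the apparent Michaelis constant:
#' \deqn{v = k_0 + (k_{cat} - k_0)\,
#'   \frac{(K_m + E_T + S) - \sqrt{(K_m + E_T + S)^2 - 4 E_T S}}{2 E_T},}
#' with \eqn{S = [ATP]_T} and \eqn{E_T} the total enzyme.  `v(0) = k0` and
#' `v` saturates at `kcat`.  A slightly negative discriminant from rounding
#' is clamped at zero.
#'
#' @param ATP_T Total ATP concentration(s), uM (vectorised).
#' @param E_T Total enzyme concentration (uM, > 0).
#' @param k0 Basal rate (s^-1).
#' @param kcat Saturating turnover rate (s^-1).
#' @param Km Apparent Michaelis constant (uM).
#' @return Velocity (s^-1).
#' @export
briggs_haldane <- function(ATP_T, E_T, k0, kcat, Km) {
  if (E_T <= 0) stop_recbcd("invalid_argument", "E_T must be > 0")
  if (any(c(ATP_T, k0, kcat, Km) < 0))
    stop_recbcd("invalid_argument", "all arguments must be >= 0")
  s <- Km + E_T + ATP_T
  disc <- pmax(s^2 - 4 * E_T * ATP_T, 0)
  k0 + (kcat - k0) * (s - sqrt(disc)) / (2 * E_T)
}

#' ATPase activity curve
#'
#' @param atp Total ATP concentrations (uM), increasing.
#' @param rate Measured turnover velocities (s^-1).
#' @param enzyme Total enzyme concentration (uM, > 0).
#' @param sem Optional standard errors.
#' @return Object of class `"atpase_curve"`.
#' @export
atpase_curve <- function(atp, rate, enzyme, sem = NULL) {
  if (length(atp) != length(rate))
    stop_recbcd("invalid_argument", "atp and rate lengths differ")
  if (any(diff(atp) <= 0))
    stop_recbcd("invalid_argument", "ATP concentrations must be increasing")
  if (enzyme <= 0)
    stop_recbcd("invalid_argument", "enzyme concentration must be > 0")
  structure(list(atp = atp, rate = rate, enzyme = enzyme, sem = sem),
            class = "atpase_curve")
}

#' Fit the quadratic Briggs-Haldane equation
#'
#' Least-squares fit of `(k0, kcat, Km)` with the enzyme concentration fixed
#' at its known value (at `E_T` far below `Km` a joint fit of `E_T` is
#' unidentifiable).
#'
#' @param curve An [atpase_curve()] with at least 5 points spanning below and
#'   above `Km`.
#' @return Object of class `"atpase_fit"`: `coefficients` (`k0`, `kcat`,
#'   `Km`), `se`, `rss`, `fitted`.
#' @export
fit_atpase <- function(curve) {
  stopifnot(inherits(curve, "atpase_curve"))
  x <- curve$atp; y <- curve$rate
  if (length(x) < 5)
    stop_recbcd("fit_error", "need at least 5 points")
  if (all(y == 0)) {
    warning("all velocities are zero: Km is unidentifiable", call. = FALSE)
    th <- c(k0 = 0, kcat = 0, Km = NA_real_)
    return(structure(list(coefficients = th,
                          se = c(k0 = 0, kcat = 0, Km = NA_real_),
                          rss = 0, fitted = y * 0, curve = curve),
                     class = "atpase_fit"))
  }
  w <- if (is.null(curve$sem)) rep(1, length(x)) else 1 / curve$sem^2
  half <- max(y) / 2
  Km0 <- x[which(y >= half)[1]]
  if (is.na(Km0) || Km0 <= 0) Km0 <- stats::median(x)
  p0 <- c(k0 = max(min(y), 0), kcat = max(y), Km = Km0)
  fit <- minpack.lm::nls.lm(
    par = p0, lower = c(0, 0, 1e-9),
    fn = function(th) sqrt(w) * (y - briggs_haldane(x, curve$enzyme,
                                                    th[1], th[2], th[3])),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info == 0 || any(!is.finite(fit$par)))
    stop_recbcd("fit_error", "Briggs-Haldane fit did not converge")
  th <- fit$par
  rss <- sum(fit$fvec^2)
  dof <- max(length(x) - 3L, 1L)
  vc <- tryCatch(solve(fit$hessian) * rss / dof, error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 3) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(th)
  structure(list(coefficients = th, se = se, rss = rss,
                 fitted = briggs_haldane(x, curve$enzyme, th[1], th[2], th[3]),
                 curve = curve),
            class = "atpase_fit")
}

#' @export
coef.atpase_fit <- function(object, ...) object$coefficients

#' @export
print.atpase_fit <- function(x, ...) {
  cat("Quadratic Briggs-Haldane fit (E_T fixed)\n")
  print(round(cbind(Estimate = x$coefficients, `Std. Error` = x$se), 4))
  cat(sprintf("RSS = %.4g\n", x$rss))
  invisible(x)
}

#' Read / write ATPase curve CSV
#'
#' Columns: `atp_uM`, `rate_per_s`, `sem`, `enzyme_uM`.
#' @param curve An [atpase_curve()].
#' @param path CSV path.
#' @return The path (write) or an `atpase_curve` (read).
#' @export
write_atpase_csv <- function(curve, path) {
  df <- data.frame(atp_uM = curve$atp, rate_per_s = curve$rate,
                   sem = if (is.null(curve$sem)) NA_real_ else curve$sem,
                   enzyme_uM = curve$enzyme)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atpase_csv
#' @export
read_atpase_csv <- function(path) {
  df <- utils::read.csv(path)
  sem <- if (all(is.na(df$sem))) NULL else df$sem
  atpase_curve(df$atp_uM, df$rate_per_s, df$enzyme_uM[1], sem)
}
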