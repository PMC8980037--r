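#' Single-turnover unwinding trace
#'
#' Real-time (fluorescence anisotropy or FRET) time course of a single
#' unwinding turnover: a plateau while the duplex is being unwound, then a
#' signal decay when the products are released.
#'
#' @param time Time (s), increasing.
#' @param signal FA or FRET signal (arbitrary units).
#' @param length_bp Duplex length of the construct (bp, > 0).
#' @param condition A [recbcd_condition()].
#' @param modality `"FA"` or `"FRET"` (metadata only; the model is shared).
#' @return Object of class `"unwinding_trace"`.
#' @export
unwinding_trace <- function(time, signal, length_bp,
                            condition = recbcd_condition(),
                            modality = c("FA", "FRET")) {
  modality <- match.arg(modality)
  if (length(time) != length(signal))
    stop_recbcd("invalid_argument", "time and signal lengths differ")
  if (any(diff(time) <= 0))
    stop_recbcd("invalid_argument", "time must be strictly increasing")
  if (length_bp <= 0)
    stop_recbcd("invalid_argument", "length_bp must be > 0")
  structure(list(time = time, signal = signal, length_bp = length_bp,
                 condition = condition, modality = modality),
            class = "unwinding_trace")
}

#' Lag-plus-exponential-decay model
#'
#' Piecewise single-turnover unwinding model: the signal stays at the initial
#' level `A` for the duration of unwinding (`t <= t_lag`), then decays
#' exponentially at `k_diss` to the final level `B`:
#' \deqn{y(t) = A \;(t \le t_{lag}); \quad
#'       (A - B) e^{-k_{diss} (t - t_{lag})} + B \;(t > t_{lag}).}
#' Continuous at `t_lag`.
#'
#' @param t Time (s), vectorised.
#' @param A,B Initial and final signal levels.
#' @param k_diss Decay rate (s^-1, > 0).
#' @param t_lag Lag time (s, >= 0).
#' @return Model signal.
#' @export
lag_decay_model <- function(t, A, B, k_diss, t_lag) {
  if (k_diss <= 0) stop_recbcd("invalid_argument", "k_diss must be > 0")
  if (t_lag < 0) stop_recbcd("invalid_argument", "t_lag must be >= 0")
  ifelse(t <= t_lag, A, (A - B) * exp(-k_diss * (t - t_lag)) + B)
}

#' Fit the lag-plus-decay model to an unwinding trace
#'
#' Minimises the sum of squared errors over `{A, B, k_diss, t_lag}` with a
#' derivative-free Nelder-Mead simplex, multi-started over a grid of lag
#' candidates spanning the trace (the objective is only piecewise smooth in
#' `t_lag`, and a single-start simplex stalls).
#'
#' @param trace An [unwinding_trace()] covering both the plateau and the
#'   decay.
#' @param n_starts Number of lag-grid starts (default 20).
#' @return Object of class `"lag_fit"`: `coefficients` (`A`, `B`, `k_diss`,
#'   `t_lag`), `sse`, `fitted`.
#' @export
fit_lag_trace <- function(trace, n_starts = 20L) {
  stopifnot(inherits(trace, "unwinding_trace"))
  t <- trace$time; y <- trace$signal
  ## precondition: a decay must actually be present
  n <- length(y)
  early <- mean(y[seq_len(max(3, n %/% 10))])
  late <- mean(y[seq(n - max(3, n %/% 10) + 1, n)])
  spread <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(spread)) spread <- 0
  if (early - late < 4 * spread || early - late <= 0)
    stop_recbcd("fit_error", "trace does not reach its decay phase")
  sse_fun <- function(th) {
    k <- exp(th[3]); tl <- th[4]
    if (tl < 0 || tl > max(t)) return(1e12)
    sum((y - lag_decay_model(t, th[1], th[2], k, tl))^2)
  }
  lag_grid <- seq(min(t), stats::quantile(t, 0.9), length.out = n_starts)
  k0 <- 2 / (max(t) - min(t))
  best <- NULL
  for (tl0 in lag_grid) {
    o <- stats::optim(c(early, late, log(k0 * 10), tl0), sse_fun,
                      method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- c(A = best$par[1], B = best$par[2], k_diss = exp(best$par[3]),
          t_lag = max(best$par[4], 0))
  structure(list(coefficients = th, sse = best$value,
                 fitted = lag_decay_model(t, th[1], th[2], th[3], th[4]),
                 trace = trace),
            class = "lag_fit")
}

#' @export
coef.lag_fit <- function(object, ...) object$coefficients

#' @export
print.lag_fit <- function(x, ...) {
  cat(sprintf("Lag-plus-decay fit (%s, %g bp): ", x$trace$modality,
              x$trace$length_bp))
  cat(sprintf("A = %.4g, B = %.4g, k_diss = %.4g /s, t_lag = %.4g s (SSE %.3g)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$coefficients[4], x$sse))
  invisible(x)
}

#' Unwinding rate from lag times versus construct length
#'
#' Weighted linear regression of the lag time on duplex length,
#' `t_lag = intercept + length / rate`: the reciprocal slope is the
#' unwinding rate (bp/s) and the intercept the initiation/complex-formation
#' time.  The rate standard error follows by the delta method.
#'
#' @param lags Data frame (or list) with columns `length_bp`, `t_lag`, and
#'   optionally `se`; at least 3 distinct lengths.
#' @return Object of class `"unwinding_rate"`: `rate`, `rate_se`,
#'   `intercept`, `intercept_se`, `slope`.
#' @export
#' @examples
#' unwinding_rate(data.frame(length_bp = c(24, 38, 52),
#'                           t_lag = 0.02 + c(24, 38, 52) / 800))
unwinding_rate <- function(lags) {
  lags <- as.data.frame(lags)
  if (!all(c("length_bp", "t_lag") %in% names(lags)))
    stop_recbcd("invalid_argument", "'lags' needs columns length_bp and t_lag")
  if (length(unique(lags$length_bp)) < 3)
    stop_recbcd("invalid_argument", "need at least 3 distinct construct lengths")
  known_se <- "se" %in% names(lags) && !any(is.na(lags$se)) && all(lags$se > 0)
  w <- if (known_se) 1 / lags$se^2 else rep(1, nrow(lags))
  fit <- stats::lm(t_lag ~ length_bp, data = lags, weights = w)
  sl <- stats::coef(fit)[["length_bp"]]
  if (sl <= 0)
    stop_recbcd("fit_error", "nonpositive slope: lag does not grow with length")
  ## with known per-point errors the parameter covariance is (X'WX)^-1
  ## (no residual-variance scaling); otherwise scale by the residual variance
  X <- cbind(1, lags$length_bp)
  xtwx_inv <- solve(crossprod(X * sqrt(w)))
  sigma2 <- if (known_se) 1 else {
    dof <- nrow(lags) - 2L
    sum(w * stats::resid(fit)^2) / max(dof, 1)
  }
  se <- sqrt(pmax(diag(xtwx_inv) * sigma2, 0))
  rate <- 1 / sl
  rate_se <- se[2] / sl^2   # delta method
  structure(list(rate = rate, rate_se = rate_se,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 intercept_se = se[1],
                 slope = sl, fit = fit),
            class = "unwinding_rate")
}

#' @export
print.unwinding_rate <- function(x, ...) {
  cat(sprintf("Unwinding rate: %.4g +/- %.2g bp/s (intercept %.4g +/- %.2g s)\n",
              x$rate, x$rate_se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Read / write unwinding trace CSV
#'
#' Columns: `time_s`, `signal`, `length_bp`, `modality`, `nacl_mM`,
#' `adenosine_mM`, `temperature_C`, `atp_uM`.
#' @param trace An [unwinding_trace()].
#' @param path CSV path.
#' @return The path (write) or an `unwinding_trace` (read).
#' @export
write_unwinding_csv <- function(trace, path) {
  cond <- trace$condition
  df <- data.frame(time_s = trace$time, signal = trace$signal,
                   length_bp = trace$length_bp, modality = trace$modality,
                   nacl_mM = cond$nacl, adenosine_mM = cond$adenosine,
                   temperature_C = cond$temperature, atp_uM = cond$ligand_conc)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_unwinding_csv
#' @export
read_unwinding_csv <- function(path) {
  df <- utils::read.csv(path)
  unwinding_trace(df$time_s, df$signal, df$length_bp[1],
                  recbcd_condition(ligand_conc = df$atp_uM[1],
                                   nacl = df$nacl_mM[1],
                                   adenosine = df$adenosine_mM[1],
                                   temperature = df$temperature_C[1]),
                  modality = df$modality[1])
}
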