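#' @keywords internal
"_PACKAGE"

## Classed error conditions used across the package: "invalid_argument",
## "fit_error", "numerical_error".  All inherit from "recbcd_error".
stop_recbcd <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "recbcd_error", "error")))
}

#' Kinetic parameters of the auxiliary-site transfer scheme
#'
#' Bundles the microscopic rate constants of the two-pathway ATP-binding
#' scheme: two identical, non-cooperative catalytic sites; `n_weak_sites`
#' cooperative auxiliary (non-catalytic) sites; and a direct transfer step
#' moving ATP from an auxiliary site onto a free catalytic site without
#' release to solution.  Three of the rates depend linearly on solution
#' conditions and are given as intercept/slope pairs, resolved at a given
#' condition by [resolve_rates()]:
#' \describe{
#'   \item{auxiliary on-rate}{`kw_on = max(0, kw_on_intercept +
#'     kw_on_slope_ado * adenosine)` (adenosine competes for the auxiliary
#'     sites, so the slope is typically negative);}
#'   \item{auxiliary off-rate}{`kw_off = max(0, kw_off_intercept +
#'     kw_off_slope_nacl * nacl)`;}
#'   \item{forward transfer}{`ktr_fwd = max(0, ktr_fwd_intercept +
#'     ktr_fwd_slope_nacl * nacl)`.}
#' }
#'
#' @param ks_on Association rate of a catalytic site (uM^-1 s^-1).
#' @param ks_off Dissociation rate of a catalytic site (s^-1).
#' @param kw_on_intercept Auxiliary-site association rate at zero adenosine
#'   (uM^-1 s^-1).
#' @param kw_on_slope_ado Linear slope of the auxiliary on-rate versus
#'   adenosine (uM^-1 s^-1 per mM adenosine).
#' @param kw_off_intercept Auxiliary-site dissociation rate at zero NaCl
#'   (s^-1).
#' @param kw_off_slope_nacl Linear slope of the auxiliary off-rate versus NaCl
#'   (s^-1 per mM NaCl).
#' @param ktr_fwd_intercept Auxiliary-to-catalytic transfer rate at zero NaCl
#'   (s^-1).
#' @param ktr_fwd_slope_nacl Linear slope of the forward transfer rate versus
#'   NaCl (s^-1 per mM NaCl).
#' @param ktr_rev Reverse transfer rate, catalytic back to auxiliary (s^-1).
#' @param coop_a Cooperativity factor: binding to the 2nd and later auxiliary
#'   sites is faster by this factor (dimensionless, > 0).
#' @param vmax Maximal catalysis (hydrolysis) rate per occupied catalytic site
#'   (s^-1).
#' @param n_weak_sites Number of auxiliary sites (default 4).
#' @param n_cat_sites Number of catalytic sites (default 2).
#'
#' @return An object of class `"recbcd_params"` (a named list).
#' @seealso [recbcd_condition()], [resolve_rates()]
#' @export
#' @examples
#' p <- recbcd_params()
#' resolve_rates(p, recbcd_condition(ligand_conc = 100))
recbcd_params <- function(ks_on = 2, ks_off = 15,
                          kw_on_intercept = 0.35, kw_on_slope_ado = -0.14,
                          kw_off_intercept = 1070, kw_off_slope_nacl = 1.3,
                          ktr_fwd_intercept = 735, ktr_fwd_slope_nacl = -2.06,
                          ktr_rev = 5, coop_a = 18, vmax = 1000,
                          n_weak_sites = 4L, n_cat_sites = 2L) {
  p <- list(ks_on = ks_on, ks_off = ks_off,
            kw_on_intercept = kw_on_intercept, kw_on_slope_ado = kw_on_slope_ado,
            kw_off_intercept = kw_off_intercept, kw_off_slope_nacl = kw_off_slope_nacl,
            ktr_fwd_intercept = ktr_fwd_intercept, ktr_fwd_slope_nacl = ktr_fwd_slope_nacl,
            ktr_rev = ktr_rev, coop_a = coop_a, vmax = vmax,
            n_weak_sites = as.integer(n_weak_sites),
            n_cat_sites = as.integer(n_cat_sites))
  for (nm in c("ks_on", "ks_off", "ktr_rev", "vmax"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) || p[[nm]] < 0)
      stop_recbcd("invalid_argument", "'%s' must be a single nonnegative number", nm)
  if (!is.numeric(coop_a) || coop_a <= 0)
    stop_recbcd("invalid_argument", "'coop_a' must be > 0")
  if (p$n_weak_sites < 0L)
    stop_recbcd("invalid_argument", "'n_weak_sites' must be >= 0")
  if (p$n_cat_sites < 1L)
    stop_recbcd("invalid_argument", "'n_cat_sites' must be >= 1")
  structure(p, class = "recbcd_params")
}

#' @export
print.recbcd_params <- function(x, ...) {
  cat("Auxiliary-site transfer scheme parameters\n")
  cat(sprintf("  catalytic sites : %d   (ks_on = %g uM^-1 s^-1, ks_off = %g s^-1)\n",
              x$n_cat_sites, x$ks_on, x$ks_off))
  cat(sprintf("  auxiliary sites : %d   (kw_on = %g %+g*[Ado], kw_off = %g %+g*[NaCl], a = %g)\n",
              x$n_weak_sites, x$kw_on_intercept, x$kw_on_slope_ado,
              x$kw_off_intercept, x$kw_off_slope_nacl, x$coop_a))
  cat(sprintf("  transfer        : ktr_fwd = %g %+g*[NaCl] s^-1, ktr_rev = %g s^-1\n",
              x$ktr_fwd_intercept, x$ktr_fwd_slope_nacl, x$ktr_rev))
  cat(sprintf("  catalysis       : vmax = %g s^-1 per occupied catalytic site\n", x$vmax))
  invisible(x)
}

#' Experimental condition
#'
#' Solution condition tag attached to every experimental record: ligand
#' (ATP or mant-nucleotide) concentration, NaCl, adenosine, temperature.
#'
#' @param ligand_conc Ligand concentration (uM).
#' @param nacl NaCl concentration (mM).
#' @param adenosine Adenosine concentration (mM).
#' @param temperature Temperature (degrees C).
#' @return An object of class `"recbcd_condition"`.
#' @export
recbcd_condition <- function(ligand_conc = 0, nacl = 75, adenosine = 0,
                             temperature = 25) {
  vals <- c(ligand_conc = ligand_conc, nacl = nacl, adenosine = adenosine)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_recbcd("invalid_argument",
                "ligand_conc, nacl and adenosine must be finite and >= 0")
  structure(list(ligand_conc = ligand_conc, nacl = nacl,
                 adenosine = adenosine, temperature = temperature),
            class = "recbcd_condition")
}

#' @export
print.recbcd_condition <- function(x, ...) {
  cat(sprintf("Condition: [ligand] = %g uM, [NaCl] = %g mM, [adenosine] = %g mM, %g C\n",
              x$ligand_conc, x$nacl, x$adenosine, x$temperature))
  invisible(x)
}

#' Resolve condition-dependent rates
#'
#' Evaluates the linear condition dependences of the auxiliary on/off rates
#' and the forward transfer rate at a given condition, clamping each at zero
#' (rates are nonnegative linear functions of the condition variables).  The
#' catalytic rates, reverse transfer, cooperativity and catalysis rate are
#' passed through, optionally scaled by a temperature multiplier.
#'
#' @param params A [recbcd_params()] object.
#' @param condition A [recbcd_condition()] object.
#' @param temp_model Optional [temperature_model()]; rate constants (not the
#'   cooperativity factor) are multiplied by its value at
#'   `condition$temperature`.
#' @return An object of class `"recbcd_rates"`: effective `ks_on`, `ks_off`,
#'   `kw_on`, `kw_off`, `ktr_fwd`, `ktr_rev`, `coop_a`, `vmax`, plus the site
#'   counts.
#' @export
resolve_rates <- function(params, condition, temp_model = NULL) {
  stopifnot(inherits(params, "recbcd_params"), inherits(condition, "recbcd_condition"))
  mult <- if (is.null(temp_model)) 1 else temp_multiplier(temp_model, condition$temperature)
  structure(list(
    ks_on  = params$ks_on * mult,
    ks_off = params$ks_off * mult,
    kw_on  = max(0, params$kw_on_intercept +
                   params$kw_on_slope_ado * condition$adenosine) * mult,
    kw_off = max(0, params$kw_off_intercept +
                    params$kw_off_slope_nacl * condition$nacl) * mult,
    ktr_fwd = max(0, params$ktr_fwd_intercept +
                     params$ktr_fwd_slope_nacl * condition$nacl) * mult,
    ktr_rev = params$ktr_rev * mult,
    coop_a  = params$coop_a,
    vmax    = params$vmax * mult,
    n_weak_sites = params$n_weak_sites,
    n_cat_sites  = params$n_cat_sites), class = "recbcd_rates")
}

#' Temperature-dependence model for the rate constants
#'
#' Maps temperature to a dimensionless multiplier applied to all rate
#' constants when resolving a condition.  The default is the identity
#' (multiplier 1 at any temperature).  The `"q10"` form uses
#' `multiplier = q10^((temperature - ref) / 10)`.
#'
#' @param type `"identity"` or `"q10"`.
#' @param q10 Fold change in rate per 10 C (used by `"q10"`), default 2.5.
#' @param ref Reference temperature (C) at which the multiplier is 1.
#' @return An object of class `"temperature_model"`.
#' @export
temperature_model <- function(type = c("identity", "q10"), q10 = 2.5, ref = 25) {
  type <- match.arg(type)
  if (q10 <= 0) stop_recbcd("invalid_argument", "'q10' must be > 0")
  structure(list(type = type, q10 = q10, ref = ref), class = "temperature_model")
}

temp_multiplier <- function(model, temperature) {
  if (is.null(model) || model$type == "identity") return(1)
  model$q10^((temperature - model$ref) / 10)
}

## Derived macroscopic association constants (uM^-1) at a condition.
association_constants <- function(rates) {
  list(Ks = rates$ks_on / rates$ks_off, Kw = rates$kw_on / rates$kw_off)
}

#' Serialize / restore parameters as JSON
#'
#' Flat key/value JSON with the field names of [recbcd_params()]; units are
#' those documented there.
#'
#' @param params A `recbcd_params` object.
#' @param path File path to write to, or `NULL` to return the JSON string.
#' @return `params_to_json` returns the path (or JSON string) invisibly;
#'   `params_from_json` returns a `recbcd_params` object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "recbcd_params"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname params_to_json
#' @param json A JSON string or file path produced by `params_to_json`.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(recbcd_params, x)
}
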