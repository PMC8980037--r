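# Shared fixtures: a light ground truth and small cached datasets so the
# expensive generators run once per session.

ref_truth <- function() synthetic_truth()

# brute-force equilibrium weight of state (w, c); oracle for the binding
# polynomial and for detailed-balance stationary checks
brute_state_weight <- function(w, c, Ks, Kw, a, T)
  Ks^c * a^max(w - 1, 0) * Kw^w * T^(w + c)

brute_psi <- function(Ks, Kw, a, T, n_weak = 4, n_cat = 2) {
  s <- 0
  for (w in 0:n_weak) for (c in 0:n_cat)
    s <- s + brute_state_weight(w, c, Ks, Kw, a, T)
  s
}

brute_mean_occ <- function(Ks, Kw, a, T, n_weak = 4, n_cat = 2) {
  num <- 0; den <- 0
  for (w in 0:n_weak) for (c in 0:n_cat) {
    wt <- brute_state_weight(w, c, Ks, Kw, a, T)
    num <- num + (w + c) * wt; den <- den + wt
  }
  num / den
}

local_cache <- new.env()
cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

fit_single_hill_r2 <- function(conc, signal)
  recbcdkin:::fit_single_hill(conc, signal)$r_squared
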