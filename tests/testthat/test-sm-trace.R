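test_that("worm-like-chain contour conversion inverts the forward model", {
  truth <- ref_truth()
  n <- 2000
  time <- seq_len(n) / 2500
  contour_bp <- seq(1000, 1400, length.out = n)
  force <- rep(12, n)
  ext <- recbcdkin:::wlc_extension(contour_bp * 0.34, force)
  tr <- tweezers_trace(time, ext, force)
  ct <- extension_to_contour(tr)
  expect_lt(max(abs(ct$contour_bp - contour_bp) / contour_bp), 0.001)
  # contour is linear in extension at fixed force
  tr2 <- tweezers_trace(time, 2 * ext, force)
  ct2 <- extension_to_contour(tr2)
  expect_equal(ct2$contour_bp, 2 * ct$contour_bp, tolerance = 1e-12)
  # zero-force samples are flagged and interpolated, not fatal
  force3 <- force; force3[500:510] <- 0
  ct3 <- extension_to_contour(tweezers_trace(time, ext, force3))
  expect_true(all(ct3$flagged[500:510]))
  expect_true(all(is.finite(ct3$contour_bp)))
})

test_that("Chung-Kennedy filtering preserves steps better than a moving average", {
  set.seed(21)
  n <- 1200
  edge_width <- function(y, lo, hi) {
    # samples needed to cross from 10% to 90% of the step
    i10 <- which(y > lo + 0.1 * (hi - lo))[1]
    i90 <- which(y > lo + 0.9 * (hi - lo))[1]
    i90 - i10
  }
  for (step in c(10, 25, 80)) {
    x <- c(rep(0, n / 2), rep(step, n / 2)) + rnorm(n, 0, 2)
    ck <- chung_kennedy(x)
    ma <- stats::filter(x, rep(1 / 100, 100), sides = 2)
    ma[is.na(ma)] <- x[is.na(ma)]
    expect_lt(edge_width(ck, 0, step), edge_width(as.numeric(ma), 0, step),
              label = sprintf("step %g", step))
  }
  # constant signal is reproduced exactly
  expect_equal(chung_kennedy(rep(5, 500)), rep(5, 500))
  # output stays within the local signal range (convexity of weighted means)
  x <- cumsum(rnorm(800))
  ck <- chung_kennedy(x)
  for (i in seq(101, 700, by = 50)) {
    win <- x[(i - 100):(i + 100)]
    expect_gte(ck[i], min(win) - 1e-9)
    expect_lte(ck[i], max(win) + 1e-9)
  }
  expect_error(chung_kennedy(rnorm(50)), class = "invalid_argument")
})

test_that("a scheduled dwell is detected as exactly one pause at its position", {
  truth <- ref_truth()
  tr <- gen_tweezers_trace(truth, duration_s = 4,
                           pauses = data.frame(start_s = 1.5,
                                               duration_s = 1.0),
                           seed = 3)
  ct <- extension_to_contour(tr)
  pauses <- detect_pauses(ct)
  expect_equal(nrow(pauses), 1)
  expect_gt(pauses$duration_s, 0.9)
  expect_lt(pauses$duration_s, 1.1)
  truth_contour <- attr(tr, "truth_contour")
  dwell_pos <- truth_contour[which(diff(truth_contour) == 0)[1]]
  expect_lt(abs(pauses$position_bp - dwell_pos), 5)
  # a constant-velocity trace has no pauses
  tr0 <- gen_tweezers_trace(truth, duration_s = 2,
                            pauses = data.frame(start_s = numeric(0),
                                                duration_s = numeric(0)),
                            seed = 4)
  expect_equal(nrow(detect_pauses(extension_to_contour(tr0))), 0)
})

test_that("dwells below the minimal pause duration are rejected", {
  truth <- ref_truth()
  tr <- gen_tweezers_trace(truth, duration_s = 2,
                           pauses = data.frame(start_s = 1.0,
                                               duration_s = 0.001),
                           seed = 5)
  ct <- extension_to_contour(tr)
  expect_equal(nrow(detect_pauses(ct)), 0)
})

test_that("pause detection has high sensitivity and low false-discovery at defaults", {
  truth <- ref_truth()
  found <- 0L; scheduled <- 0L; false_pos <- 0L
  for (s in 1:40) {
    starts <- c(0.8, 2.2) + (s %% 5) * 0.05
    sched <- data.frame(start_s = starts, duration_s = c(0.3, 0.5))
    tr <- gen_tweezers_trace(truth, duration_s = 4, pauses = sched, seed = s)
    ct <- extension_to_contour(tr)
    p <- detect_pauses(ct)
    scheduled <- scheduled + nrow(sched)
    for (i in seq_len(nrow(sched))) {
      hit <- any(p$start_s < starts[i] + sched$duration_s[i] &
                   p$end_s > starts[i])
      found <- found + hit
    }
    false_pos <- false_pos + max(0, nrow(p) - nrow(sched))
  }
  expect_gte(found / scheduled, 0.9)                     # sensitivity
  expect_lte(false_pos / max(found + false_pos, 1), 0.1) # false discovery
})

test_that("segment velocities recover programmed speeds and negate under time reversal", {
  truth <- ref_truth()
  truth$noise$tweezers_nm <- 0
  tr <- gen_tweezers_trace(truth, duration_s = 2,
                           pauses = data.frame(start_s = numeric(0),
                                               duration_s = numeric(0)),
                           seed = 6)
  ct <- extension_to_contour(tr)
  v <- segment_velocities(ct)
  expect_gt(length(v), 4)
  expect_lt(max(abs(v - truth$sm$velocity) / truth$sm$velocity), 0.01)
  # time reversal negates every segment velocity
  rev_ct <- structure(list(time = ct$time,
                           contour_bp = rev(ct$contour_bp),
                           force = rev(ct$force), flagged = rev(ct$flagged)),
                      class = "contour_trace", fs = attr(ct, "fs"))
  v_rev <- segment_velocities(rev_ct)
  expect_equal(sort(v_rev), sort(-v), tolerance = 1e-6)
  # with generator noise the mean velocity stays within 2%
  trn <- gen_tweezers_trace(ref_truth(), duration_s = 6,
                            pauses = data.frame(start_s = numeric(0),
                                                duration_s = numeric(0)),
                            seed = 7)
  vn <- segment_velocities(extension_to_contour(trn))
  expect_gt(length(vn), 20)
  expect_lt(abs(mean(vn) - 500) / 500, 0.02)
  # no samples inside the force window -> empty result
  ct_low <- ct; ct_low$force <- rep(5, length(ct$force))
  expect_length(segment_velocities(ct_low), 0)
})

test_that("pause density and its confidence interval follow both formula variants", {
  expect_equal(pause_density(0, 5000)$density, 0)
  d1 <- pause_density(25, 10000, "as_printed")
  expect_equal(d1$density, 0.0025)
  expect_equal(d1$ci_half_width, 1.96 * sqrt(25 / 10000))
  expect_equal(d1$ci_half_width, 0.098)
  d2 <- pause_density(25, 10000, "poisson_count")
  expect_equal(d2$ci_half_width, 1.96 * sqrt(25) / 10000)
  expect_equal(d2$ci_half_width, 0.00098)
  expect_error(pause_density(5, 0), class = "invalid_argument")
})

test_that("tweezers traces and pause tables round-trip through CSV", {
  truth <- ref_truth()
  tr <- gen_tweezers_trace(truth, duration_s = 0.5,
                           pauses = data.frame(start_s = numeric(0),
                                               duration_s = numeric(0)),
                           seed = 8)
  f <- tempfile(fileext = ".csv")
  write_tweezers_csv(tr, f)
  back <- read_tweezers_csv(f)
  expect_equal(back$extension, tr$extension)
  expect_equal(attr(back, "fs"), 2500, tolerance = 1e-6)
})
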