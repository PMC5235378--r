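# Closed-form curve evaluation and threshold crossings.

test_that("Gaussian drive evaluation matches an independent dnorm oracle", {
  p <- gaussian_params(2.576, 0.006, 0.064)
  # dnorm route: a * exp(-(t-b)^2/(2c^2)) = a * c * sqrt(2*pi) * dnorm(t, b, c)
  oracle <- function(pp, t)
    pp$amplitude * pp$width * sqrt(2 * pi) * dnorm(t, pp$peak_time, pp$width)
  tt <- seq(-0.4, 0.2, by = 0.01)
  expect_equal(eval_gaussian(p, tt), oracle(p, tt), tolerance = 1e-12)

  # value at the peak is the amplitude; symmetric about the peak
  expect_equal(eval_gaussian(p, 0.006), 2.576)
  d <- runif(20, 0, 0.2)
  expect_equal(eval_gaussian(p, 0.006 + d), eval_gaussian(p, 0.006 - d))

  # early-rise value computed from the oracle before the main build
  expect_equal(eval_gaussian(p, -0.150), 0.1320644, tolerance = 1e-6)

  withr::with_seed(4, {
    for (i in 1:10) {
      rp <- random_gaussian_params()
      t1 <- runif(1, -0.3, 0.2)
      expect_equal(eval_gaussian(rp, t1), oracle(rp, t1), tolerance = 1e-12)
      expect_lte(eval_gaussian(rp, t1), rp$amplitude)
      expect_gt(eval_gaussian(rp, t1), 0)
    }
  })
})

test_that("drive slope matches a finite-difference oracle and is antisymmetric", {
  p <- gaussian_params(2.576, 0.006, 0.064)
  fd <- function(pp, t, h = 1e-6)
    (eval_gaussian(pp, t + h) - eval_gaussian(pp, t - h)) / (2 * h)
  expect_equal(gaussian_slope(p, -0.048), fd(p, -0.048), tolerance = 1e-6)
  expect_equal(gaussian_slope(p, -0.048), 23.79, tolerance = 1e-3)
  expect_equal(gaussian_slope(p, p$peak_time), 0)
  withr::with_seed(5, {
    for (i in 1:10) {
      rp <- random_gaussian_params()
      t1 <- runif(1, -0.2, 0.2)
      expect_equal(gaussian_slope(rp, t1), fd(rp, t1), tolerance = 1e-5)
      # antisymmetric about the peak
      expect_equal(gaussian_slope(rp, t1),
                   -gaussian_slope(rp, 2 * rp$peak_time - t1),
                   tolerance = 1e-9)
    }
  })
})

test_that("closed-form onset times reproduce the reference curve onsets", {
  # go facilitation (ATM / HRM) and partial-trial curves, minimum level 0.1
  expect_equal(onset_time(gaussian_params(2.576, 0.006, 0.064), 0.1),
               -0.157, tolerance = 0.001 / 0.157)
  expect_equal(onset_time(gaussian_params(2.342, 0.007, 0.066), 0.1),
               -0.159, tolerance = 0.001 / 0.159)
  expect_equal(onset_time(gaussian_params(1.644, 0.015, 0.087), 0.1),
               -0.190, tolerance = 0.001 / 0.190)
  expect_equal(onset_time(gaussian_params(2.576, 0.108, 0.064), 0.1),
               -0.055, tolerance = 0.001 / 0.055)
})

test_that("onset_time returns the earlier root, agrees with uniroot, and rejects unreachable levels", {
  withr::with_seed(6, {
    for (i in 1:10) {
      p <- random_gaussian_params()
      thr <- runif(1, 0.05, 0.9 * p$amplitude)
      t0 <- onset_time(p, thr)
      # the curve equals the threshold there, and it is before the peak
      expect_equal(eval_gaussian(p, t0), thr, tolerance = 1e-10)
      expect_lt(t0, p$peak_time)
      # independent root-finder oracle on the rising limb
      root <- uniroot(function(t) eval_gaussian(p, t) - thr,
                      lower = p$peak_time - 10 * p$width,
                      upper = p$peak_time, tol = 1e-12)$root
      expect_equal(t0, root, tolerance = 1e-8)
    }
  })
  p <- gaussian_params(2, 0.01, 0.05)
  expect_equal(onset_time(p, 2), 0.01)  # peak just touches the level
  expect_error(onset_time(p, 2.5), "never reaches")
})

test_that("step inhibition rises from baseline with the stated time constant and bound", {
  p <- step_inhibition_params(1.798, 1.887, 0.060, 0.133)
  # clamped at baseline up to the step onset
  expect_equal(eval_step_inhibition(p, c(-0.4, -0.2, -0.133)),
               rep(1.798, 3))
  # one time constant after onset: baseline + k * (1 - exp(-1))
  expect_equal(eval_step_inhibition(p, -0.133 + 0.060),
               1.798 + 1.887 * (1 - exp(-1)), tolerance = 1e-12)
  # bounded by the asymptote, never exceeded
  tt <- seq(-0.4, 5, by = 0.01)
  expect_true(all(eval_step_inhibition(p, tt) <= 1.798 + 1.887))
  expect_equal(eval_step_inhibition(p, 50), 3.685, tolerance = 1e-6)
  # monotone non-decreasing for random parameter sets
  withr::with_seed(7, {
    for (i in 1:10) {
      rp <- step_inhibition_params(runif(1, 0.5, 3), runif(1, 0, 3),
                                   runif(1, 0.02, 0.2), runif(1, -0.1, 0.3))
      v <- eval_step_inhibition(rp, tt)
      expect_true(all(diff(v) >= -1e-12))
      expect_true(all(v <= rp$baseline + rp$k_inh + 1e-12))
    }
  })
})

test_that("the inhibitory step begins 117 ms after a stop signal at -250 ms", {
  p <- step_inhibition_params(1.798, 1.887, 0.060, 0.133)
  expect_equal(step_onset_latency(p), 0.117)
  expect_equal(step_onset_latency(p, stop_signal_time = -0.3), 0.167)
})

test_that("combined facilitation is the sum of both curves and dominates each", {
  prim <- gaussian_params(2.576, 0.006, 0.064)
  sec <- gaussian_params(2.576, 0.108, 0.064)
  # two independent single-curve evaluations summed
  expect_equal(eval_combined_facilitation(prim, sec, 0.023),
               eval_gaussian(prim, 0.023) + eval_gaussian(sec, 0.023))
  expect_equal(eval_combined_facilitation(prim, sec, 0.023), 3.55,
               tolerance = 1e-3)
  tt <- seq(-0.4, 0.2, by = 0.005)
  expect_equal(eval_combined_facilitation(prim, sec, tt),
               eval_combined_facilitation(sec, prim, tt))
  expect_true(all(eval_combined_facilitation(prim, sec, tt) >=
                    eval_gaussian(prim, tt)))
  expect_true(all(eval_combined_facilitation(prim, sec, tt) >=
                    eval_gaussian(sec, tt)))
  # a vanishing secondary contributes nothing
  tiny <- gaussian_params(1e-12, 0.108, 0.064)
  expect_equal(eval_combined_facilitation(prim, tiny, tt),
               eval_gaussian(prim, tt), tolerance = 1e-10)
})

test_that("grid crossing agrees with the closed form and finds the recross", {
  cst <- onset_constants()
  expect_false(first_crossing(0.5, 1.0, cst)$crossed)

  p <- gaussian_params(2.576, 0.006, 0.064)
  cr <- first_crossing(function(t) eval_gaussian(p, t), 1.798, cst)
  cf <- gauss_cross_closed_form(2.576, 0.006, 0.064, 1.798)
  expect_true(cr$crossed)
  expect_equal(cr$onset, unname(cf["onset"]), tolerance = 1e-4)
  expect_equal(cr$offset, unname(cf["offset"]), tolerance = 1e-4)
  # recross - cross equals the analytic full width at the threshold level
  expect_equal(cr$offset - cr$onset,
               2 * sqrt(-2 * 0.064^2 * log(1.798 / 2.576)),
               tolerance = 2 * cst$grid_step)

  # randomized agreement within one grid step
  withr::with_seed(8, {
    for (i in 1:20) {
      rp <- random_gaussian_params()
      thr <- runif(1, 0.2, 0.95 * rp$amplitude)
      cr <- first_crossing(function(t) eval_gaussian(rp, t), thr, cst)
      expect_true(cr$crossed)
      expect_lte(abs(cr$onset - onset_time(rp, thr)), cst$grid_step)
    }
  })

  # the primary go facilitation alone cannot pass the mean step-elevated
  # threshold on a partial trial
  step <- step_inhibition_params(1.798, 1.887, 0.060, 0.133)
  cr <- first_crossing(function(t) eval_gaussian(p, t),
                       function(t) eval_step_inhibition(step, t), cst)
  expect_false(cr$crossed)
})
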