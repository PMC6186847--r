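test_that("the AM generator reproduces its closed form when no shift occurs", {
  fs <- 500
  sig <- simulate_am(fs = fs, duration = 2, f_env = 0.5, f_carrier = 50,
                     epsilon = 0.05)
  t <- sig$time
  expected <- (cos(2 * pi * 0.5 * t)^2 + 0.05) * cos(2 * pi * 50 * t)
  expect_equal(sig$value, expected, tolerance = 1e-12)
  expect_identical(sig$value, sig$clean)
  expect_length(change_points(sig), 0)
  # envelope floor is epsilon
  env <- cos(2 * pi * 0.5 * t)^2 + 0.05
  expect_equal(min(env), 0.05, tolerance = 1e-4)
})

test_that("each shift adds a cumulative pi to the carrier phase", {
  fs <- 500
  sig <- simulate_am(fs = fs, duration = 4, shift_times = c(1.3, 2.6))
  t <- sig$time
  k <- findInterval(t, c(1.3, 2.6))
  expected <- (cos(2 * pi * 0.5 * t)^2 + 0.05) * cos(2 * pi * 50 * t + k * pi)
  expect_equal(sig$clean, expected, tolerance = 1e-12)
  expect_equal(change_points(sig), c(which(t >= 1.3)[1], which(t >= 2.6)[1]))
})

test_that("a single shift yields a residual step of about pi at the label", {
  sig <- simulate_am(fs = 500, duration = 4, shift_times = 2.18)
  d <- decompose_phase(sig$clean, fc = 50, fs = 500)
  idx <- change_points(sig)
  before <- median(d$residual[(idx - 150):(idx - 30)])
  after <- median(d$residual[(idx + 30):(idx + 150)])
  expect_equal(abs(after - before), pi, tolerance = 0.05)
})

test_that("generator noise has the requested variance", {
  sig <- simulate_am(fs = 500, duration = 200, noise_sd = 0.3, seed = 1)
  expect_equal(var(sig$value - sig$clean), 0.09, tolerance = 0.01)
})

test_that("AM generator rejects invalid shift configurations", {
  expect_error(simulate_am(shift_times = c(1, 1)), "duplicate")
  expect_error(simulate_am(shift_times = 9), "inside")
  expect_error(simulate_am(fs = 80, f_carrier = 50), "twice")
})

test_that("random-shift signals carry measurable labelled jumps", {
  sig <- simulate_random_shifts(fs = 250, duration = 6, fc = 7.4,
                                n_shifts = 3, seed = 42)
  idx <- change_points(sig)
  expect_length(idx, 3)
  expect_true(all(diff(idx) >= 25))
  d <- decompose_phase(sig$clean, fc = 7.4, fs = 250)
  for (i in idx) {
    jump <- abs(median(d$residual[(i + 5):(i + 20)]) -
                median(d$residual[(i - 20):(i - 5)]))
    expect_gte(jump, pi / 8 - 0.05)
    expect_lte(jump, 7 * pi / 8 + 0.05)
  }
})

test_that("random-shift generator honours its contracts", {
  s0 <- simulate_random_shifts(n_shifts = 0, seed = 1)
  expect_length(change_points(s0), 0)
  expect_equal(s0$value, cos(2 * pi * 7.4 * s0$time), tolerance = 1e-12)
  a <- simulate_random_shifts(n_shifts = 3, seed = 5)
  b <- simulate_random_shifts(n_shifts = 3, seed = 5)
  expect_identical(a$value, b$value)
  expect_identical(change_points(a), change_points(b))
  c2 <- simulate_random_shifts(n_shifts = 3, seed = 6)
  expect_false(identical(change_points(a), change_points(c2)))
  expect_error(simulate_random_shifts(n_shifts = 50, duration = 1,
                                      min_gap = 100),
               "infeasible")
})

test_that("on clean signals every labelled shift is a residual step and nothing else is", {
  for (seed in 1:5) {
    sig <- simulate_random_shifts(fs = 250, duration = 6, fc = 7.4,
                                  n_shifts = 2, min_gap = 50, seed = seed)
    d <- decompose_phase(sig$clean, fc = 7.4, fs = 250)
    idx <- change_points(sig)
    steps <- abs(d$residual[pmin(seq_len(nrow(d)) + 3, nrow(d))] -
                 d$residual[pmax(seq_len(nrow(d)) - 3, 1)])
    big <- which(steps >= pi / 8) # indices with a large local step
    interior <- big[big > 50 & big < nrow(d) - 50]
    expect_true(all(vapply(idx, function(i) any(abs(interior - i) <= 5),
                           logical(1))))
    expect_true(all(vapply(interior, function(i) any(abs(idx - i) <= 8),
                           logical(1))))
  }
})

test_that("synthetic EEG hits the target SNR essentially exactly", {
  for (snr in c(0.11, 0.43)) {
    sig <- simulate_eeg(fs = 250, duration = 40, target_snr = snr, seed = 3)
    realized <- var(sig$clean) / var(sig$value - sig$clean)
    expect_equal(realized, snr, tolerance = 1e-10)
    expect_length(change_points(sig), 0)
  }
})

test_that("synthetic EEG component structure behaves as specified", {
  comp <- tibble::tibble(freq = 7.6, amplitude = 1, phase = 0)
  sig <- simulate_eeg(comp, fs = 250, duration = 4, target_snr = 1e6, seed = 1)
  expect_equal(sig$value, sin(2 * pi * 7.6 * sig$time), tolerance = 1e-2)
  # doubling amplitudes quadruples the clean power
  c1 <- simulate_eeg(fs = 250, duration = 8, target_snr = 1, seed = 9)
  comps2 <- tibble::tibble(freq = c(2, 5, 7.6, 12, 20),
                           amplitude = 2 * c(1, 0.8, 1, 0.5, 0.3))
  c2 <- simulate_eeg(comps2, fs = 250, duration = 8, target_snr = 1, seed = 9)
  expect_equal(var(c2$clean) / var(c1$clean), 4, tolerance = 1e-6)
  expect_error(simulate_eeg(comp[0, ], target_snr = 1), "at least one")
  expect_error(simulate_eeg(tibble::tibble(freq = 200, amplitude = 1),
                            fs = 250, target_snr = 1),
               "fs/2")
})
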