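test_that("the signal chain maps fields to volts and back", {
  acq <- default_acq()
  # 2.2 uT at 1 V bias, 2.5 %/mT, gain 10 000 -> 0.55 V
  expect_equal(field_to_voltage(2.2e-6, acq), 0.55, tolerance = 1e-12)
  expect_identical(field_to_voltage(0, acq), 0)
  B <- c(1e-7, 3.3e-6, -2e-6)
  expect_equal(voltage_to_field(field_to_voltage(B, acq), acq), B,
               tolerance = 1e-15)
})

test_that("a vertical-moment transit yields one bipolar pulse crossing zero at the centerline", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  obj <- make_object("aggregate", 50, default_bead())
  ev <- one_event(obj, t_arrival = 0.005, height = 8e-6)
  tr <- simulate_trace(ev, acq, s, ch, duration_s = 0.01, noise = FALSE,
                       lowpass = FALSE)
  x <- tr$samples
  thr <- field_to_voltage(2.2e-6, acq)
  above <- which(abs(x) > thr)
  expect_gt(length(above), 0)
  # one contiguous excursion region (single object)
  expect_lt(max(diff(above)), 50)
  # antisymmetry: negative lobe first, zero crossing at the center sample
  center <- round(0.005 * acq$sample_rate) + 1L
  expect_lt(abs(x[center]), 1e-12)
  expect_lt(min(x), 0); expect_gt(max(x), 0)
  expect_equal(which.max(x) - center, center - which.min(x))
  # peak matches the continuous-transit amplitude up to sampling loss
  expect_equal(max(abs(x)),
               field_to_voltage(peak_amplitude(obj, 8e-6, s), acq),
               tolerance = 0.05)
})

test_that("traces superpose linearly and an empty stream is silent", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  b <- default_bead()
  e1 <- one_event(make_object("aggregate", 30, b), 0.002, 7e-6)
  e2 <- one_event(make_object("aggregate", 60, b), 0.006, 10e-6)
  both <- rbind(e1, e2)
  args <- list(acq = acq, sensor = s, channel = ch, duration_s = 0.01,
               noise = FALSE, lowpass = FALSE)
  t1 <- do.call(simulate_trace, c(list(e1), args))
  t2 <- do.call(simulate_trace, c(list(e2), args))
  t12 <- do.call(simulate_trace, c(list(both), args))
  expect_equal(t12$samples, t1$samples + t2$samples, tolerance = 1e-12)
  t0 <- do.call(simulate_trace, c(list(both[0, ]), args))
  expect_identical(t0$samples, numeric(round(0.01 * acq$sample_rate)))
})

test_that("noise injection is calibrated to the field-equivalent RMS", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  tr <- simulate_trace(NULL, acq, s, ch, duration_s = 0.25, noise = TRUE,
                       lowpass = TRUE, seed = 42)
  expect_equal(sd(tr$samples),
               field_to_voltage(acq$noise_rms_field, acq), tolerance = 0.05)
  # fixed seed reproduces the trace sample for sample
  tr2 <- simulate_trace(NULL, acq, s, ch, duration_s = 0.25, noise = TRUE,
                        lowpass = TRUE, seed = 42)
  expect_identical(tr$samples, tr2$samples)
})

test_that("the low-pass filter attenuates a resolved pulse by less than 5%", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  ev <- one_event(make_object("aggregate", 50, default_bead()), 0.005, 8e-6)
  raw <- simulate_trace(ev, acq, s, ch, duration_s = 0.01, noise = FALSE,
                        lowpass = FALSE)
  fil <- simulate_trace(ev, acq, s, ch, duration_s = 0.01, noise = FALSE,
                        lowpass = TRUE)
  expect_gt(sum(abs(raw$samples) > 0.1) , 10)  # transit spans >= 10 samples
  expect_equal(max(abs(fil$samples)), max(abs(raw$samples)), tolerance = 0.05)
})

test_that("trace CSV round-trips metadata exactly and samples to 1e-12", {
  acq <- default_acq()
  set.seed(9)
  tr <- gmr_trace(rnorm(1e5, 0, 0.02), acq)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$acquisition, acq)
  expect_equal(back$samples, tr$samples, tolerance = 1e-12)
  # header-only file is a valid empty trace
  empty <- gmr_trace(numeric(0), acq)
  p2 <- tempfile(fileext = ".csv")
  write_trace(empty, p2)
  expect_length(read_trace(p2)$samples, 0)
  # corrupted header names the missing key
  lines <- readLines(path)
  writeLines(lines[-2], p2)  # drop bias_v
  expect_error(read_trace(p2), "bias_v")
})

test_that("the default flow geometry gives a ~0.22 m/s plug flow", {
  expect_equal(mean_transit_speed(default_channel()), 0.2222, tolerance = 1e-3)
})
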