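make_trace <- function(x, acq = default_acq()) gmr_trace(x, acq)

test_that("extremum refinement finds the true lobes of a clean pulse", {
  acq <- default_acq()
  n <- 4000L
  x <- bipolar_pulse(n, center = 2000, half_width = 120, amplitude = 1)
  tr <- make_trace(x, acq)
  cfg <- detector_config(0.3)
  seed <- which(x > 0.3)[1]  # seed in the positive lobe
  got <- refine_extrema(tr, seed, cfg)
  expect_true(got$terminated)
  expect_identical(got$i_max, which.max(x))
  expect_identical(got$i_min, which.min(x))
  # idempotence: a different seed in the same pulse gives the same extrema
  seed2 <- which(x < -0.3)[5]
  got2 <- refine_extrema(tr, seed2, cfg)
  expect_identical(got[c("i_min", "i_max")], got2[c("i_min", "i_max")])
})

test_that("a monotone ramp never terminates the extremum search", {
  acq <- default_acq()
  x <- seq(0, 2, length.out = 5000)
  tr <- make_trace(x, acq)
  cfg <- detector_config(0.5)
  got <- refine_extrema(tr, 2500L, cfg)
  expect_false(got$terminated)
  ev <- validate_candidate(got, cfg, acq$sample_rate)
  expect_false(ev$accepted)
  expect_identical(ev$rejection_reason, "unterminated_search")
})

test_that("validation applies the four criteria in order", {
  acq <- default_acq()
  fs <- acq$sample_rate
  cand <- function(i_min, i_max, V_min, V_max)
    list(i_min = i_min, i_max = i_max, V_min = V_min, V_max = V_max,
         terminated = TRUE)
  cfg <- detector_config(0.3, direction_k = +1)
  # |V_min| = 0.05 < 0.1 = Vthr/3: not bipolar
  r <- validate_candidate(cand(150L, 100L, -0.05, 0.5), cfg, fs)
  expect_identical(r$rejection_reason, "bipolarity")
  # wrong lobe order for k = +1
  r <- validate_candidate(cand(100L, 150L, -0.4, 0.5), cfg, fs)
  expect_identical(r$rejection_reason, "orientation")
  # 2 samples at 200 kHz = 10 us < 25 us minimum width
  r <- validate_candidate(cand(102L, 100L, -0.4, 0.5), cfg, fs)
  expect_identical(r$rejection_reason, "width")
  # |1.0 - 0.4| / |1.0 + 0.4| = 0.6/1.4 > 0.4: too asymmetric
  r <- validate_candidate(cand(150L, 100L, -0.4, 1.0), cfg, fs)
  expect_identical(r$rejection_reason, "symmetry")
  expect_equal(r$symmetry, 0.6 / 1.4, tolerance = 1e-12)
  # all four pass: 50 samples = 250 us, near-symmetric lobes
  r <- validate_candidate(cand(150L, 100L, -0.9, 1.0), cfg, fs)
  expect_true(r$accepted)
  expect_true(is.na(r$rejection_reason))
})

test_that("detection recovers exactly the simulated super-threshold transits", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  b <- default_bead()
  heights <- c(7e-6, 9e-6, 8e-6, 11e-6, 7.5e-6)
  evs <- do.call(rbind, lapply(seq_along(heights), function(i)
    one_event(make_object("aggregate", 60, b), 0.004 * i, heights[i])))
  tr <- simulate_trace(evs, acq, s, ch, duration_s = 0.024, noise = FALSE,
                       lowpass = FALSE)
  cfg <- default_detector(acq)
  det <- detect_events(tr, cfg)
  acc <- det[det$accepted, ]
  expect_identical(nrow(acc), 5L)
  # each accepted event sits at its own transit (sorted arrival order)
  centers <- (pmin(acc$i_min, acc$i_max) + pmax(acc$i_min, acc$i_max)) / 2
  expect_equal((centers - 1) / acq$sample_rate, 0.004 * (1:5),
               tolerance = 0.02)
  # threshold above the largest peak: nothing left
  big <- detector_config(max(abs(tr$samples)) * 1.01)
  expect_identical(nrow(detect_events(tr, big)), 0L)
  # all-zero trace: empty result
  expect_identical(nrow(detect_events(make_trace(numeric(1000)), cfg)), 0L)
})

test_that("raising the threshold never increases the accepted count", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  b <- default_bead()
  set.seed(21)
  comp <- sample_composition(cells_per_mL = 0, beads_per_mL = 3e6)
  ev <- generate_sample(comp, ch, 2, seed = 21)
  tr <- simulate_trace(ev, acq, s, ch, noise = TRUE, lowpass = TRUE,
                       seed = 22)
  counts <- vapply(c(0.2, 0.35, 0.55, 0.8, 1.2), function(v)
    sum(detect_events(tr, detector_config(v))$accepted), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("time reversal with a k flip preserves the accepted count", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  b <- default_bead()
  ev <- rbind(one_event(make_object("aggregate", 40, b), 0.003, 7e-6),
              one_event(make_object("aggregate", 80, b), 0.008, 12e-6))
  tr <- simulate_trace(ev, acq, s, ch, duration_s = 0.012, noise = TRUE,
                       lowpass = TRUE, seed = 33)
  fwd <- detect_events(tr, default_detector(acq, k = -1))
  rev <- detect_events(make_trace(rev(tr$samples), acq),
                       default_detector(acq, k = +1))
  expect_identical(sum(fwd$accepted), sum(rev$accepted))
})

test_that("detection is deterministic and events round-trip through TSV", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  ev <- one_event(make_object("aggregate", 60, default_bead()), 0.005, 8e-6)
  tr <- simulate_trace(ev, acq, s, ch, duration_s = 0.01, noise = TRUE,
                       lowpass = TRUE, seed = 4)
  cfg <- default_detector(acq)
  d1 <- detect_events(tr, cfg); d2 <- detect_events(tr, cfg)
  expect_identical(d1, d2)
  path <- tempfile(fileext = ".tsv")
  write_events(d1, path)
  back <- read_events(path)
  expect_equal(back$amplitude_uT, d1$amplitude_T * 1e6, tolerance = 1e-6)
  expect_equal(back$accepted, d1$accepted)
})

test_that("random telegraph noise is rejected while a true transit survives", {
  s <- default_sensor(); ch <- default_channel(); acq <- default_acq()
  ev <- one_event(make_object("aggregate", 60, default_bead()), 0.02, 8e-6)
  clean <- simulate_trace(ev, acq, s, ch, duration_s = 0.04, noise = FALSE,
                          lowpass = TRUE, seed = 55)
  rtn <- add_telegraph_noise(clean, rate_hz = 400, amplitude_V = 1.2,
                             seed = 56)
  cfg <- default_detector(acq)
  base <- detect_events(clean, cfg)
  expect_identical(sum(base$accepted), 1L)
  noisy <- detect_events(rtn, cfg)
  # the telegraph steps generate candidates but no extra accepted events
  expect_gt(nrow(noisy), sum(noisy$accepted))
  expect_identical(sum(noisy$accepted), 1L)
  expect_true(any(noisy$rejection_reason %in% c("symmetry", "bipolarity",
                                                "unterminated_search")))
})
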