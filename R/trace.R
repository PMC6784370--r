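# Voltage-trace synthesis through the acquisition chain: sensitivity, gains,
# low-pass filtering and additive noise, plus the plain-text trace format.

#' Acquisition chain configuration
#'
#' Signal chain of the instrument: the sensor is biased at `bias_voltage`,
#' its relative resistance change per unit field is `sensitivity_per_mT`,
#' and the output is amplified by `preamp_gain`, low-pass filtered at
#' `filter_cutoff` with a further `post_gain`, then sampled at `sample_rate`.
#' `noise_rms_field` is the field-equivalent RMS noise measured on the
#' recording (in-band); it defaults to detectivity/3, i.e. a threshold at
#' three times the noise level corresponds to 2.2 uT.
#'
#' @param sample_rate sampling rate, Hz (default 200 kHz).
#' @param preamp_gain preamplifier gain (default 500).
#' @param post_gain post-filter gain (default 20).
#' @param filter_cutoff low-pass cutoff, Hz (default 15 kHz); the sample
#'   rate must exceed twice the cutoff.
#' @param bias_voltage sensor bias, volts (default 1).
#' @param sensitivity_per_mT relative sensitivity, fraction per mT
#'   (default 0.025 for 2.5 %/mT).
#' @param noise_rms_field field-equivalent RMS noise, tesla.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 200e3, preamp_gain = 500,
                               post_gain = 20, filter_cutoff = 15e3,
                               bias_voltage = 1, sensitivity_per_mT = 0.025,
                               noise_rms_field = 2.2e-6 / 3) {
  stopifnot(preamp_gain > 0, post_gain > 0, bias_voltage > 0,
            sensitivity_per_mT > 0, noise_rms_field >= 0)
  if (sample_rate <= 2 * filter_cutoff)
    stop("'sample_rate' must exceed twice 'filter_cutoff'")
  structure(list(sample_rate = sample_rate, preamp_gain = preamp_gain,
                 post_gain = post_gain, filter_cutoff = filter_cutoff,
                 bias_voltage = bias_voltage,
                 sensitivity_per_mT = sensitivity_per_mT,
                 noise_rms_field = noise_rms_field),
            class = "acquisition_config")
}

#' Field-to-voltage conversion through the signal chain
#'
#' `V = bias * sensitivity(per tesla) * B * preamp_gain * post_gain`.
#' With the defaults (1 V bias, 2.5 %/mT, total gain 10 000) a 2.2 uT field
#' maps to 0.55 V. `voltage_to_field` is its exact inverse.
#'
#' @param B field in tesla (vectorized).
#' @param acq an [acquisition_config()].
#' @return voltage in volts.
#' @export
field_to_voltage <- function(B, acq) {
  acq$bias_voltage * (acq$sensitivity_per_mT * 1e3) * B *
    acq$preamp_gain * acq$post_gain
}

#' @rdname field_to_voltage
#' @param V voltage in volts (vectorized).
#' @export
voltage_to_field <- function(V, acq) {
  V / (acq$bias_voltage * acq$sensitivity_per_mT * 1e3 *
         acq$preamp_gain * acq$post_gain)
}

# Single-bead peak amplitude as a function of height, tabulated once on a
# log grid and interpolated; used to prune events that cannot approach the
# detection threshold when simulating dense bead backgrounds.
.unit_peak_interp <- function(bead, sensor, h_range) {
  hs <- exp(seq(log(h_range[1]), log(h_range[2]), length.out = 60))
  one <- make_object("bead", 1, bead)
  amps <- vapply(hs, function(h) peak_amplitude(one, h, sensor), numeric(1))
  stats::approxfun(log(hs), log(amps), rule = 2)
}

#' Simulate a voltage trace from an event stream
#'
#' Each object crosses the sensor along y at the mean flow speed at its
#' drawn height; its sensor-averaged signal is evaluated at every sample
#' time inside a window around the crossing, converted to volts and
#' superposed. The clean trace is then optionally low-pass filtered
#' (4th-order Butterworth, zero-phase) and Gaussian noise at the configured
#' field-equivalent RMS is added. With a fixed `seed` the trace is
#' reproducible sample for sample.
#'
#' @param events a `gmr_sample` from [generate_sample()], or any data.frame
#'   with columns `kind`, `n_beads`, `t_arrival_s`, `height_m`, `offset_m`
#'   and optional list-column `object`.
#' @param acq an [acquisition_config()].
#' @param sensor a [sensor_geometry()].
#' @param channel a [channel_geometry()].
#' @param duration_s trace length in seconds; defaults to the event stream's
#'   duration attribute.
#' @param noise add Gaussian noise (default `TRUE`).
#' @param lowpass apply the low-pass filter (default `TRUE`).
#' @param seed optional integer seed for the noise.
#' @param bead a [bead_magnetics()] used for canonical aggregate events.
#' @param amplitude_floor in tesla: events whose estimated peak field falls
#'   below this are skipped (0, the default, simulates everything). An upper
#'   bound estimate is used so no near-threshold event is dropped.
#' @return an object of class `gmr_trace`.
#' @export
simulate_trace <- function(events, acq, sensor, channel, duration_s = NULL,
                           noise = TRUE, lowpass = TRUE, seed = NULL,
                           bead = NULL, amplitude_floor = 0) {
  stopifnot(inherits(acq, "acquisition_config"),
            inherits(sensor, "sensor_geometry"),
            inherits(channel, "channel_geometry"))
  if (is.null(duration_s)) duration_s <- attr(events, "duration_s")
  if (is.null(duration_s)) stop("'duration_s' missing and not an event attribute")
  if (is.null(bead)) bead <- attr(events, "bead")
  if (is.null(bead)) bead <- bead_magnetics()
  if (!is.null(seed)) set.seed(seed)
  fs <- acq$sample_rate
  v <- mean_transit_speed(channel)
  if (v / fs > channel$spacer + sensor$width_l / 2)
    warning("transit is faster than the sampling can resolve: fewer than ",
            "one sample per pulse lobe at the lowest transit heights")
  n <- as.integer(round(duration_s * fs))
  x <- numeric(n)
  nev <- if (is.null(events)) 0L else nrow(events)
  unit_peak <- NULL
  if (amplitude_floor > 0 && nev > 0) {
    hmax <- channel$spacer + channel$height + 1e-6
    unit_peak <- .unit_peak_interp(bead, sensor, c(0.2e-6, hmax))
  }
  for (i in seq_len(nev)) {
    h <- events$height_m[i]
    obj <- if (!is.null(events$object)) events$object[[i]] else NULL
    if (is.null(obj) && !is.null(unit_peak)) {
      # upper bound: saturation moment, beads as close as the cell radius
      h_lo <- max(h - 3e-6, 0.2e-6)
      est <- events$n_beads[i] * exp(unit_peak(log(h_lo))) *
        bead$moment_saturation / bead$moment_operating
      if (est < amplitude_floor) next
    }
    if (is.null(obj)) obj <- make_object(
      if (events$kind[i] == "cell") "aggregate" else events$kind[i],
      events$n_beads[i], bead)
    extent <- max(abs(obj$offsets))
    span <- sensor$width_l / 2 + 6 * (h + extent) + 5e-6
    t0 <- events$t_arrival_s[i]
    i0 <- max(1L, as.integer(ceiling((t0 - span / v) * fs)) + 1L)
    i1 <- min(n, as.integer(floor((t0 + span / v) * fs)) + 1L)
    if (i1 < i0) next
    tt <- (seq.int(i0, i1) - 1L) / fs
    ys <- (tt - t0) * v
    disp <- cbind(rep(events$offset_m[i], length(ys)), ys)
    x[i0:i1] <- x[i0:i1] +
      field_to_voltage(object_signal(obj, disp, h, sensor), acq)
  }
  if (lowpass && n > 12L) {
    bf <- signal::butter(4, acq$filter_cutoff / (fs / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  if (noise && acq$noise_rms_field > 0) {
    x <- x + stats::rnorm(n, 0, field_to_voltage(acq$noise_rms_field, acq))
  }
  structure(list(samples = x, sample_rate = fs, acquisition = acq,
                 duration_s = duration_s, n_events = nev),
            class = "gmr_trace")
}

#' Construct a trace from raw samples
#'
#' @param samples numeric vector of voltages.
#' @param acq an [acquisition_config()].
#' @return a `gmr_trace`.
#' @export
gmr_trace <- function(samples, acq) {
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), sample_rate = acq$sample_rate,
                 acquisition = acq,
                 duration_s = length(samples) / acq$sample_rate,
                 n_events = NA_integer_),
            class = "gmr_trace")
}

#' @export
print.gmr_trace <- function(x, ...) {
  cat(sprintf("gmr trace: %d samples at %.0f kHz (%.3g s), sd %.3g V\n",
              length(x$samples), x$sample_rate / 1e3, x$duration_s,
              stats::sd(x$samples)))
  invisible(x)
}

#' @export
plot.gmr_trace <- function(x, t_range = NULL, ...) {
  t <- (seq_along(x$samples) - 1L) / x$sample_rate
  keep <- if (is.null(t_range)) TRUE else t >= t_range[1] & t <= t_range[2]
  graphics::plot(t[keep], x$samples[keep], type = "l",
                 xlab = "time (s)", ylab = "voltage (V)", ...)
  invisible(x)
}

#' Inject random telegraph noise into a trace
#'
#' Adds a two-state (0 / `amplitude_V`) offset whose transitions are Poisson
#' with the given switching rate, emulating the random telegraph noise some
#' sensor configurations exhibit. Useful to exercise the detector's symmetry
#' criterion, which exists to discriminate transits from exactly this
#' artifact.
#'
#' @param trace a `gmr_trace`.
#' @param rate_hz mean number of state switches per second.
#' @param amplitude_V offset of the high state, volts.
#' @param seed optional integer seed.
#' @return the trace with the telegraph component added.
#' @export
add_telegraph_noise <- function(trace, rate_hz, amplitude_V, seed = NULL) {
  stopifnot(inherits(trace, "gmr_trace"), rate_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(trace$samples)
  dur <- n / trace$sample_rate
  n_switch <- stats::rpois(1, rate_hz * dur)
  if (n_switch > 0) {
    at <- sort(ceiling(stats::runif(n_switch) * n))
    state <- numeric(n)
    level <- 0
    bounds <- c(at, n + 1L)
    pos <- 1L
    for (i in seq_along(bounds)) {
      hi <- bounds[i] - 1L
      if (hi >= pos) state[pos:hi] <- level
      level <- amplitude_V - level
      pos <- bounds[i]
    }
    trace$samples <- trace$samples + state
  }
  trace
}

.trace_header_keys <- c("sample_rate_hz", "bias_v", "sensitivity_per_mT",
                        "preamp_gain", "post_gain", "filter_cutoff_hz",
                        "noise_rms_T")

#' Write / read a voltage trace
#'
#' CSV with a `#`-prefixed metadata header (`key = value` lines for the
#' acquisition parameters) followed by a single `voltage_V` column. The
#' round trip is exact for the metadata and preserves samples to better
#' than 1e-12 relative (full double precision is written).
#'
#' @param trace a `gmr_trace`.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `gmr_trace`.
#' @export
write_trace <- function(trace, path) {
  acq <- trace$acquisition
  vals <- c(acq$sample_rate, acq$bias_voltage, acq$sensitivity_per_mT,
            acq$preamp_gain, acq$post_gain, acq$filter_cutoff,
            acq$noise_rms_field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s = %.17g", .trace_header_keys, vals), con)
  writeLines("voltage_V", con)
  if (length(trace$samples))
    writeLines(sprintf("%.17g", trace$samples), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    parts <- strsplit(kv, "\\s*=\\s*")[[1]]
    if (length(parts) == 2) meta[[parts[1]]] <- as.numeric(parts[2])
  }
  missing <- setdiff(.trace_header_keys, names(meta))
  if (length(missing))
    stop("trace format error: missing metadata key(s): ",
         paste(missing, collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0 || body[1] != "voltage_V")
    stop("trace format error: missing 'voltage_V' column header")
  samples <- if (length(body) > 1) as.numeric(body[-1]) else numeric(0)
  if (anyNA(samples))
    stop("trace format error: non-numeric sample values")
  acq <- acquisition_config(sample_rate = meta$sample_rate_hz,
                            preamp_gain = meta$preamp_gain,
                            post_gain = meta$post_gain,
                            filter_cutoff = meta$filter_cutoff_hz,
                            bias_voltage = meta$bias_v,
                            sensitivity_per_mT = meta$sensitivity_per_mT,
                            noise_rms_field = meta$noise_rms_T)
  gmr_trace(samples, acq)
}
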