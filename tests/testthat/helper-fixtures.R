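# Shared fixtures: the reference instrument and small hand-built signals.

default_sensor <- function() sensor_geometry()
default_bead <- function() bead_magnetics()
default_channel <- function() channel_geometry()
default_acq <- function() acquisition_config()

# detector at the pooled 2.2 uT threshold expressed in volts
default_detector <- function(acq = default_acq(), k = -1) {
  detector_config(field_to_voltage(2.2e-6, acq), direction_k = k)
}

# Clean antisymmetric bipolar pulse (negative lobe first for k = -1):
# derivative-of-Gaussian shape with lobe peaks `half_width` samples apart.
bipolar_pulse <- function(n, center, half_width, amplitude, sign = -1) {
  i <- seq_len(n)
  u <- (i - center) / (half_width / 2)
  sign * amplitude * u * exp(0.5 - u^2 / 2)
}

# random dipole state inside the channel above the sensor
random_dipole <- function(moment = bead_magnetics()$moment_operating) {
  dipole_state(c(runif(1, -80e-6, 80e-6), runif(1, -20e-6, 20e-6),
                 runif(1, 1e-6, 30e-6)),
               moment = moment,
               theta = runif(1, 0, pi / 2), psi = runif(1, 0, 2 * pi))
}

# single-event stream in the shape generate_sample() produces
one_event <- function(object, t_arrival, height, offset = 0) {
  ev <- data.frame(object_id = 1L, kind = object$kind,
                   n_beads = object$n_beads, t_arrival_s = t_arrival,
                   height_m = height, offset_m = offset)
  ev$object <- list(object)
  ev
}
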