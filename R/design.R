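# Chip-design analysis: how high above the sensor an object of a given bead
# load remains detectable, and what a separation (spacer) layer does to the
# detectable fractions of labeled cells versus bead aggregates.

#' Maximum detectable transit height for an N-bead object
#'
#' Bisects the peak transit amplitude of a co-located N-bead object
#' (vertical moments at the operating moment) against the sensor
#' detectivity. Returns 0 with attribute `undetectable = TRUE` when the
#' object stays below detectivity even at the minimum height.
#'
#' @param n_beads number of beads.
#' @param detectivity smallest detectable field, tesla; defaults to the
#'   sensor's.
#' @param bead a [bead_magnetics()].
#' @param sensor a [sensor_geometry()].
#' @param tol bisection tolerance in meters (default 0.05 um).
#' @param h_min,h_max search bracket in meters.
#' @return height in meters.
#' @export
#' @examples
#' detectable_height(7)  # about 7 um at 2.2 uT detectivity
detectable_height <- function(n_beads, detectivity = NULL,
                              bead = bead_magnetics(),
                              sensor = sensor_geometry(), tol = 0.05e-6,
                              h_min = 0.2e-6, h_max = 200e-6) {
  stopifnot(n_beads >= 1)
  if (is.null(detectivity)) detectivity <- sensor$detectivity
  stopifnot(detectivity > 0)
  one <- make_object("bead", 1, bead)
  f <- function(h) n_beads * peak_amplitude(one, h, sensor) - detectivity
  if (f(h_min) <= 0) {
    out <- 0
    attr(out, "undetectable") <- TRUE
    return(out)
  }
  if (f(h_max) > 0)
    stop("object still detectable at h_max = ", h_max, " m; widen bracket")
  stats::uniroot(f, c(h_min, h_max), tol = tol)$root
}

#' Smallest detectable bead load at a given height
#'
#' Inverse of [detectable_height()]: the smallest number of co-located
#' beads whose peak transit amplitude reaches detectivity at the given
#' height. The aggregate signal is exactly linear in the bead count, so the
#' answer is a ceiling of a single-bead ratio.
#'
#' @param height transit height in meters.
#' @inheritParams detectable_height
#' @return integer bead count (at least 1).
#' @export
min_beads_detectable <- function(height, detectivity = NULL,
                                 bead = bead_magnetics(),
                                 sensor = sensor_geometry()) {
  stopifnot(height > 0)
  if (is.null(detectivity)) detectivity <- sensor$detectivity
  one <- make_object("bead", 1, bead)
  a1 <- peak_amplitude(one, height, sensor)
  n <- ceiling(detectivity / a1)
  # guard the boundary against floating-point rounding
  if ((n - 1) * a1 >= detectivity) n <- n - 1
  max(1L, as.integer(n))
}

#' Detectability curve: maximum height versus bead load
#'
#' @param n_grid integer vector of bead counts.
#' @inheritParams detectable_height
#' @return a `data.frame` of class `detectability_curve` with columns
#'   `n_beads` and `max_height_m` (non-decreasing in `n_beads`).
#' @export
detectability_curve <- function(n_grid = 1:100, detectivity = NULL,
                                bead = bead_magnetics(),
                                sensor = sensor_geometry()) {
  if (is.null(detectivity)) detectivity <- sensor$detectivity
  h <- vapply(n_grid, detectable_height, numeric(1),
              detectivity = detectivity, bead = bead, sensor = sensor)
  out <- data.frame(n_beads = as.integer(n_grid), max_height_m = h)
  attr(out, "detectivity") <- detectivity
  class(out) <- c("detectability_curve", "data.frame")
  out
}

#' @export
plot.detectability_curve <- function(x, ...) {
  graphics::plot(x$n_beads, x$max_height_m * 1e6, type = "l",
                 xlab = "beads per object",
                 ylab = "maximum detectable height (um)", ...)
  invisible(x)
}

#' Cell/aggregate discrimination for a spacer thickness
#'
#' For every bead load `n`, the fraction of the transit-height range
#' `[spacer, spacer + channel height]` at which an `n`-bead object is
#' detectable is computed from the detectability curve; averaging those
#' fractions over the beads-per-cell and aggregate-size distributions gives
#' the detectable population fractions. Heights are assumed uniform, and
#' cells are inverted with the co-located (worst-case) geometry.
#'
#' @param cell_dist beads-per-cell `size_distribution`.
#' @param aggregate_dist aggregate-size `size_distribution`.
#' @param spacer separation-layer thickness in meters.
#' @param channel a [channel_geometry()] (its own `spacer` is ignored in
#'   favor of the `spacer` argument).
#' @inheritParams detectable_height
#' @return an object of class `discrimination_report`.
#' @export
discrimination_fractions <- function(cell_dist = beads_per_cell_distribution(),
                                     aggregate_dist = aggregate_size_distribution(),
                                     spacer = 6e-6,
                                     channel = channel_geometry(),
                                     detectivity = NULL,
                                     bead = bead_magnetics(),
                                     sensor = sensor_geometry()) {
  stopifnot(spacer >= 0)
  if (is.null(detectivity)) detectivity <- sensor$detectivity
  ns <- sort(unique(c(cell_dist$n[cell_dist$prob > 1e-12],
                      aggregate_dist$n[aggregate_dist$prob > 1e-12])))
  ns <- ns[ns >= 1]
  hmax <- vapply(ns, detectable_height, numeric(1),
                 detectivity = detectivity, bead = bead, sensor = sensor)
  frac_h <- pmin(pmax((hmax - spacer) / channel$height, 0), 1)
  lookup <- stats::setNames(frac_h, ns)
  weight <- function(dist) {
    f <- ifelse(dist$n >= 1, lookup[as.character(dist$n)], 0)
    f[is.na(f)] <- 0
    sum(dist$prob * f)
  }
  structure(list(spacer = spacer,
                 fraction_cells_detectable = weight(cell_dist),
                 fraction_aggregates_detectable = weight(aggregate_dist),
                 detectivity = detectivity),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf(paste0("spacer %.1f um at detectivity %.2g uT: ",
                     "%.1f%% of cells, %.2f%% of aggregates detectable\n"),
              x$spacer * 1e6, x$detectivity * 1e6,
              100 * x$fraction_cells_detectable,
              100 * x$fraction_aggregates_detectable))
  invisible(x)
}
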