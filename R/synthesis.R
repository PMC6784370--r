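# Synthetic-sample generation: calibrated size distributions for bead
# aggregates and beads-per-cell labeling, object construction, and Poisson
# arrival streams through the microfluidic channel.

#' Bead-aggregate size distribution
#'
#' Zero-truncated geometric distribution over the number of beads per
#' aggregate in the commercial suspension. By default the parameter is
#' calibrated so that 93% of objects carry fewer than 7 beads, the anchor
#' measured for MyOne beads; the second reported anchor (99% below 15 beads)
#' then follows to within a percent.
#'
#' @param p geometric parameter in (0, 1); if `NULL` (default) it is
#'   calibrated from `anchor_lt7`.
#' @param anchor_lt7 target for `P(n < 7)` used in calibration.
#' @param max_n truncation point of the probability table.
#' @return an object of class `size_distribution`: a probability table over
#'   `n >= 1` with the family, parameters and mean attached.
#' @export
#' @examples
#' d <- aggregate_size_distribution()
#' sum(d$prob[d$n < 7])  # 0.93 by construction
aggregate_size_distribution <- function(p = NULL, anchor_lt7 = 0.93,
                                        max_n = 100L) {
  if (is.null(p)) {
    if (anchor_lt7 <= 0 || anchor_lt7 >= 1)
      stop("calibration error: anchor P(n < 7) must lie in (0, 1)")
    # P(n <= 6) = 1 - (1 - p)^6 for the zero-truncated geometric
    p <- 1 - (1 - anchor_lt7)^(1 / 6)
  }
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)")
  n <- seq_len(max_n)
  prob <- p * (1 - p)^(n - 1)
  prob <- prob / sum(prob)
  structure(list(n = n, prob = prob, family = "zero-truncated geometric",
                 params = list(p = p), mean = sum(n * prob)),
            class = "size_distribution")
}

#' Beads-per-cell labeling distribution
#'
#' Negative-binomial distribution over the number of beads bound per cell.
#' The mean is the measured average load (roughly 50 beads per NS1 cell for
#' the reference system); the dispersion is calibrated, unless given, so that
#' 98% of cells carry more than 7 beads, the measured labeling anchor.
#'
#' @param mean mean number of beads per cell.
#' @param dispersion negative-binomial size parameter; `Inf` gives a Poisson.
#'   If `NULL` (default) it is calibrated from `anchor_gt7`.
#' @param anchor_gt7 target for `P(n > 7)` used in calibration.
#' @param max_n truncation point of the probability table.
#' @return an object of class `size_distribution` over `n >= 0`.
#' @export
beads_per_cell_distribution <- function(mean = 50, dispersion = NULL,
                                        anchor_gt7 = 0.98, max_n = 400L) {
  stopifnot(mean > 0)
  if (is.null(dispersion)) {
    if (anchor_gt7 <= 0 || anchor_gt7 >= 1)
      stop("calibration error: anchor P(n > 7) must lie in (0, 1)")
    target <- 1 - anchor_gt7          # P(n <= 7)
    f <- function(r) stats::pnbinom(7, size = r, mu = mean) - target
    if (f(1e-3) < 0 || f(1e3) > 0)
      stop("calibration error: anchor P(n > 7) = ", anchor_gt7,
           " unreachable at mean ", mean)
    dispersion <- stats::uniroot(f, c(1e-3, 1e3), tol = 1e-10)$root
  }
  n <- 0:max_n
  prob <- if (is.infinite(dispersion)) stats::dpois(n, mean) else
    stats::dnbinom(n, size = dispersion, mu = mean)
  prob <- prob / sum(prob)
  structure(list(n = n, prob = prob, family = "negative binomial",
                 params = list(mu = mean, size = dispersion),
                 mean = sum(n * prob)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("%s size distribution on [%d, %d], mean %.2f\n",
              x$family, min(x$n), max(x$n), x$mean))
  str(x$params, give.head = FALSE)
  invisible(x)
}

#' Draw sizes from a probability table
#'
#' @param dist a `size_distribution`.
#' @param n number of draws.
#' @return integer vector of sizes.
#' @export
draw_sizes <- function(dist, n) {
  stopifnot(inherits(dist, "size_distribution"))
  sample(dist$n, n, replace = TRUE, prob = dist$prob)
}

# Tilt-angle cap: per-bead theta is uniform on [0, theta_max] with theta_max
# chosen so E[cos theta] = sin(theta_max)/theta_max equals the ratio of the
# operating to the saturation moment, enforcing the measured magnetization
# in expectation.
.theta_max_for <- function(ratio) {
  stopifnot(ratio > 0, ratio < 1)
  stats::uniroot(function(x) sin(x) / x - ratio, c(1e-9, pi),
                 tol = 1e-12)$root
}

#' Construct a magnetic object
#'
#' Builds the bead-level description of a detectable object. Aggregates (and
#' single beads) are co-located vertical dipoles at the operating moment, so
#' their signal is exactly `n_beads` times a single bead's. Cells are spheres
#' with beads placed uniformly at random on the surface; each bead carries
#' the saturation moment tilted by a random angle drawn so that the mean
#' vertical magnetization matches the measured operating moment.
#'
#' @param kind `"bead"`, `"aggregate"` or `"cell"`.
#' @param n_beads number of beads (`"bead"` forces 1).
#' @param bead a [bead_magnetics()].
#' @param cell_diameter cell diameter in meters (cells only; default 6 um,
#'   the NS1 average).
#' @return an object of class `magnetic_object`.
#' @export
#' @examples
#' set.seed(1)
#' make_object("cell", 10, bead_magnetics())
make_object <- function(kind = c("bead", "aggregate", "cell"), n_beads,
                        bead = bead_magnetics(), cell_diameter = 6e-6) {
  kind <- match.arg(kind)
  if (kind == "bead") n_beads <- 1L
  n_beads <- as.integer(n_beads)
  if (n_beads < 1) stop("'n_beads' must be at least 1")
  if (kind == "cell") {
    u <- matrix(stats::rnorm(3 * n_beads), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    offsets <- u * cell_diameter / 2
    tmax <- .theta_max_for(bead$moment_operating / bead$moment_saturation)
    theta <- stats::runif(n_beads, 0, tmax)
    psi <- stats::runif(n_beads, 0, 2 * pi)
    moment <- rep(bead$moment_saturation, n_beads)
    colocated <- FALSE
  } else {
    offsets <- matrix(0, nrow = n_beads, ncol = 3)
    theta <- rep(0, n_beads)
    psi <- rep(0, n_beads)
    moment <- rep(bead$moment_operating, n_beads)
    cell_diameter <- NA_real_
    colocated <- TRUE
  }
  structure(list(kind = kind, n_beads = n_beads, offsets = offsets,
                 theta = theta, psi = psi, moment = moment,
                 cell_diameter = cell_diameter, colocated = colocated),
            class = "magnetic_object")
}

#' @export
print.magnetic_object <- function(x, ...) {
  cat(sprintf("magnetic object: %s, %d bead(s)\n", x$kind, x$n_beads))
  invisible(x)
}

#' Sample composition
#'
#' Concentrations and size distributions describing what flows through the
#' channel: labeled cells at `cells_per_mL` plus free beads at `beads_per_mL`
#' (default 2e7 beads/mL, the assay's fixed labeling concentration). Free
#' beads are emitted as aggregates with sizes drawn from the aggregate
#' distribution, reflecting the clustering of the commercial suspension.
#' Negative samples are represented as bead-only compositions.
#'
#' @param cells_per_mL labeled-cell concentration, objects/mL.
#' @param beads_per_mL free-bead concentration, beads/mL.
#' @param cell_dist beads-per-cell `size_distribution`
#'   (default [beads_per_cell_distribution()]).
#' @param aggregate_dist aggregate-size `size_distribution`
#'   (default [aggregate_size_distribution()]).
#' @param label sample label carried into manifests.
#' @return an object of class `sample_composition`.
#' @export
sample_composition <- function(cells_per_mL = 0, beads_per_mL = 2e7,
                               cell_dist = NULL, aggregate_dist = NULL,
                               label = "sample") {
  if (cells_per_mL < 0 || beads_per_mL < 0)
    stop("concentrations must be non-negative")
  if (is.null(cell_dist)) cell_dist <- beads_per_cell_distribution()
  if (is.null(aggregate_dist)) aggregate_dist <- aggregate_size_distribution()
  structure(list(cells_per_mL = cells_per_mL, beads_per_mL = beads_per_mL,
                 cell_dist = cell_dist, aggregate_dist = aggregate_dist,
                 label = label, positive = cells_per_mL > 0),
            class = "sample_composition")
}

#' Microfluidic channel geometry
#'
#' @param height channel height, meters (default 25 um).
#' @param width channel width, meters (default 100 um).
#' @param spacer separation-layer thickness between sensor and channel
#'   floor, meters (default 6 um); objects transit at heights in
#'   `[spacer, spacer + height]`.
#' @param flow_mL_min volume flow rate, mL/min (default 1/30: 1 mL in 30 min).
#' @return an object of class `channel_geometry`.
#' @export
channel_geometry <- function(height = 25e-6, width = 100e-6, spacer = 6e-6,
                             flow_mL_min = 1 / 30) {
  stopifnot(height > 0, width > 0, spacer >= 0, flow_mL_min > 0)
  structure(list(height = height, width = width, spacer = spacer,
                 flow_mL_min = flow_mL_min),
            class = "channel_geometry")
}

#' Mean transit speed through the channel
#'
#' Plug-flow speed: volume rate divided by the channel cross-section
#' (about 0.22 m/s for the defaults).
#'
#' @param channel a [channel_geometry()].
#' @return speed in m/s.
#' @export
mean_transit_speed <- function(channel) {
  (channel$flow_mL_min * 1e-6 / 60) / (channel$height * channel$width)
}

#' Generate a synthetic sample event stream
#'
#' Draws the magnetic objects that transit the sensor during `duration_s`
#' seconds of flow. Arrivals are Poisson with rate concentration times
#' volume rate, independently per object class; transit heights are uniform
#' over the open channel `[spacer, spacer + height]`; cells with zero bound
#' beads produce no object. The returned event table is deterministic given
#' `seed`.
#'
#' @param composition a [sample_composition()].
#' @param channel a [channel_geometry()].
#' @param duration_s flow duration in seconds.
#' @param bead a [bead_magnetics()].
#' @param seed optional integer seed.
#' @param materialize which event rows carry a full [magnetic_object()] in
#'   the `object` list-column: `"cells"` (default; aggregates are canonical
#'   co-located objects reconstructed from `n_beads` on demand), `"all"`, or
#'   `"none"`.
#' @param lateral_jitter if `TRUE`, transit offsets along the sensor long
#'   axis are uniform over the channel width; default is centered transits.
#' @return a `data.frame` of class `gmr_sample` with columns `object_id`,
#'   `kind`, `n_beads`, `t_arrival_s`, `height_m`, `offset_m` and list-column
#'   `object`, ordered by arrival time. The composition, channel, duration
#'   and equivalent volume are attached as attributes.
#' @export
generate_sample <- function(composition, channel, duration_s,
                            bead = bead_magnetics(), seed = NULL,
                            materialize = c("cells", "all", "none"),
                            lateral_jitter = FALSE) {
  stopifnot(inherits(composition, "sample_composition"),
            inherits(channel, "channel_geometry"), duration_s > 0)
  materialize <- match.arg(materialize)
  if (!is.null(seed)) set.seed(seed)
  volume_mL <- channel$flow_mL_min * duration_s / 60

  n_cells <- stats::rpois(1, composition$cells_per_mL * volume_mL)
  cell_sizes <- if (n_cells > 0) draw_sizes(composition$cell_dist, n_cells)
                else integer(0)
  cell_sizes <- cell_sizes[cell_sizes > 0]  # unlabeled cells are invisible

  agg_rate <- composition$beads_per_mL / composition$aggregate_dist$mean
  n_agg <- stats::rpois(1, agg_rate * volume_mL)
  agg_sizes <- if (n_agg > 0) draw_sizes(composition$aggregate_dist, n_agg)
               else integer(0)

  kind <- c(rep("cell", length(cell_sizes)), rep("aggregate", length(agg_sizes)))
  n_beads <- c(cell_sizes, agg_sizes)
  n_tot <- length(n_beads)
  ev <- data.frame(
    object_id = seq_len(n_tot),
    kind = kind,
    n_beads = as.integer(n_beads),
    t_arrival_s = stats::runif(n_tot, 0, duration_s),
    height_m = stats::runif(n_tot, channel$spacer,
                            channel$spacer + channel$height),
    offset_m = if (lateral_jitter)
      stats::runif(n_tot, -channel$width / 2, channel$width / 2)
    else rep(0, n_tot),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$t_arrival_s), , drop = FALSE]
  ev$object_id <- seq_len(n_tot)
  rownames(ev) <- NULL
  objects <- vector("list", n_tot)
  if (materialize != "none") {
    for (i in seq_len(n_tot)) {
      if (ev$kind[i] == "cell" || materialize == "all")
        objects[[i]] <- make_object(ev$kind[i], ev$n_beads[i], bead)
    }
  }
  ev$object <- objects
  attr(ev, "composition") <- composition
  attr(ev, "channel") <- channel
  attr(ev, "duration_s") <- duration_s
  attr(ev, "volume_mL") <- volume_mL
  attr(ev, "bead") <- bead
  class(ev) <- c("gmr_sample", "data.frame")
  ev
}

#' Write / read a sample manifest
#'
#' Plain TSV with one row per object: `object_id`, `kind`, `n_beads`,
#' `t_arrival_s`, `height_um`. Bead-level geometry is not serialized; reading
#' a manifest back yields canonical (co-located) objects only.
#'
#' @param sample a `gmr_sample`.
#' @param path file path.
#' @return `write_sample_manifest` returns `path` invisibly;
#'   `read_sample_manifest` returns a `data.frame`.
#' @export
write_sample_manifest <- function(sample, path) {
  df <- data.frame(object_id = sample$object_id, kind = sample$kind,
                   n_beads = sample$n_beads,
                   t_arrival_s = sprintf("%.9f", sample$t_arrival_s),
                   height_um = sprintf("%.6f", sample$height_m * 1e6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_manifest
#' @export
read_sample_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @export
print.gmr_sample <- function(x, ...) {
  cat(sprintf("gmr sample: %d objects in %.3g s (%.3g mL): %d cells, %d aggregates\n",
              nrow(x), attr(x, "duration_s"), attr(x, "volume_mL"),
              sum(x$kind == "cell"), sum(x$kind == "aggregate")))
  invisible(x)
}
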