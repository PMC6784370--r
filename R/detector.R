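# Rule-based bipolar peak detector. Every sample exceeding the voltage
# threshold seeds a local search whose window grows until both extrema sit
# well inside it; candidates are then validated on bipolarity, orientation,
# width and symmetry, and overlapping detections are merged.

#' Detector configuration
#'
#' Parameters of the peak identification and validation rules. A candidate
#' is accepted when (in this order) it is bipolar (both extrema exceed
#' `bipolar_fraction * v_threshold` in magnitude, with opposite signs), has
#' the configured orientation (`direction_k * (i_max - i_min) < 0`), a width
#' compatible with the flow speed (`width_min` to `width_max`), and is
#' sufficiently symmetric (`|V_max + V_min| / |V_max - V_min| <
#' symmetry_max`), the last criterion discriminating transits from random
#' telegraph noise.
#'
#' @param v_threshold detection threshold in volts.
#' @param direction_k +1 or -1, the expected lobe order; -1 matches the
#'   simulator's default transit direction (negative lobe first).
#' @param width_min,width_max accepted peak-to-peak widths, seconds
#'   (defaults 25 us and 2.5 ms).
#' @param bipolar_fraction fraction of `v_threshold` both lobes must reach
#'   (default 1/3).
#' @param symmetry_max bound on the symmetry statistic (default 0.4).
#' @param grow_step window growth per side per iteration, samples (15).
#' @param edge_margin required distance of both extrema from the window
#'   edges, samples (20).
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(v_threshold, direction_k = -1,
                            width_min = 25e-6, width_max = 2.5e-3,
                            bipolar_fraction = 1 / 3, symmetry_max = 0.4,
                            grow_step = 15L, edge_margin = 20L) {
  stopifnot(v_threshold > 0, direction_k %in% c(-1, 1),
            width_min < width_max, bipolar_fraction > 0,
            bipolar_fraction < 1, symmetry_max > 0,
            grow_step >= 1, edge_margin >= 1)
  structure(list(v_threshold = v_threshold, direction_k = direction_k,
                 width_min = width_min, width_max = width_max,
                 bipolar_fraction = bipolar_fraction,
                 symmetry_max = symmetry_max,
                 grow_step = as.integer(grow_step),
                 edge_margin = as.integer(edge_margin)),
            class = "detector_config")
}

#' Locate the extrema around a threshold crossing
#'
#' Starting from a window of `edge_margin` samples around the seed, the
#' window is grown by `grow_step` samples per side until both the maximum
#' and the minimum lie at least `edge_margin` samples from both window
#' edges. The search is abandoned (unterminated) when the window reaches
#' four times the maximum accepted width or the trace boundaries pin an
#' extremum to an edge, as happens on drifts and ramps.
#'
#' @param trace a `gmr_trace`.
#' @param seed_index sample index whose magnitude exceeds the threshold.
#' @param cfg a [detector_config()].
#' @return list with `i_min`, `i_max`, `V_min`, `V_max`, `terminated`.
#' @export
refine_extrema <- function(trace, seed_index, cfg) {
  x <- trace$samples
  n <- length(x)
  stopifnot(seed_index >= 1, seed_index <= n)
  cap <- ceiling(4 * cfg$width_max * trace$sample_rate)
  lo <- max(1L, seed_index - cfg$edge_margin)
  hi <- min(n, seed_index + cfg$edge_margin)
  repeat {
    w <- x[lo:hi]
    i_max <- lo - 1L + which.max(w)
    i_min <- lo - 1L + which.min(w)
    inside <- function(i) (i - lo) >= cfg$edge_margin &&
      (hi - i) >= cfg$edge_margin
    if (inside(i_max) && inside(i_min)) {
      return(list(i_min = i_min, i_max = i_max,
                  V_min = x[i_min], V_max = x[i_max], terminated = TRUE))
    }
    if ((hi - lo + 1L) >= cap || (lo == 1L && hi == n)) {
      return(list(i_min = i_min, i_max = i_max,
                  V_min = x[i_min], V_max = x[i_max], terminated = FALSE))
    }
    lo <- max(1L, lo - cfg$grow_step)
    hi <- min(n, hi + cfg$grow_step)
  }
}

#' Validate a refined candidate
#'
#' Applies the four acceptance criteria in order and records the first
#' failure; an unterminated extremum search is rejected outright.
#'
#' @param candidate output of [refine_extrema()].
#' @param cfg a [detector_config()].
#' @param sample_rate sampling rate in Hz, used to convert widths.
#' @return one-row `data.frame` with the candidate's geometry, the symmetry
#'   statistic, `accepted` and `rejection_reason` (`NA` when accepted).
#' @export
validate_candidate <- function(candidate, cfg, sample_rate) {
  V_min <- candidate$V_min; V_max <- candidate$V_max
  width <- abs(candidate$i_max - candidate$i_min) / sample_rate
  symmetry <- if (V_max == V_min) Inf else
    abs(V_max + V_min) / abs(V_max - V_min)
  reason <- NA_character_
  if (!isTRUE(candidate$terminated)) {
    reason <- "unterminated_search"
  } else if (!(V_max > 0 && V_min < 0 &&
               abs(V_min) > cfg$bipolar_fraction * cfg$v_threshold &&
               abs(V_max) > cfg$bipolar_fraction * cfg$v_threshold)) {
    reason <- "bipolarity"
  } else if (!(cfg$direction_k * (candidate$i_max - candidate$i_min) < 0)) {
    reason <- "orientation"
  } else if (width < cfg$width_min || width > cfg$width_max) {
    reason <- "width"
  } else if (!(symmetry < cfg$symmetry_max)) {
    reason <- "symmetry"
  }
  data.frame(i_min = candidate$i_min, i_max = candidate$i_max,
             V_min = V_min, V_max = V_max, width_s = width,
             symmetry = symmetry, accepted = is.na(reason),
             rejection_reason = reason, stringsAsFactors = FALSE)
}

#' Detect validated bipolar events in a trace
#'
#' Scans every sample whose magnitude exceeds the threshold, refines the
#' local extrema around it, validates the candidate, and merges detections
#' whose extremum intervals coincide or overlap by at least half the
#' shorter interval, keeping the larger peak-to-peak amplitude. Accepted
#' and rejected candidates are merged separately, so an overlapping noise
#' artifact cannot displace a validated transit (which keeps the accepted
#' count monotone in the threshold); rejected candidates duplicating an
#' accepted detection are dropped. The event list is deterministic for a
#' given trace and configuration and sorted by position.
#'
#' @param trace a `gmr_trace`.
#' @param cfg a [detector_config()].
#' @param acq an [acquisition_config()] used to express amplitudes as
#'   fields; defaults to the trace's own.
#' @return a `data.frame` of class `gmr_events`: one row per retained
#'   candidate with `event_id`, extremum indices and voltages, `t_min_s`,
#'   `width_s`, `symmetry`, `amplitude_T` (peak magnitude as field),
#'   `accepted` and `rejection_reason`.
#' @export
detect_events <- function(trace, cfg, acq = NULL) {
  stopifnot(inherits(trace, "gmr_trace"), inherits(cfg, "detector_config"))
  if (is.null(acq)) acq <- trace$acquisition
  x <- trace$samples
  empty <- data.frame(event_id = integer(0), i_min = integer(0),
                      i_max = integer(0), t_min_s = numeric(0),
                      V_min = numeric(0), V_max = numeric(0),
                      width_s = numeric(0), symmetry = numeric(0),
                      amplitude_T = numeric(0), accepted = logical(0),
                      rejection_reason = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("gmr_events", "data.frame")
  if (length(x) == 0) return(empty)
  seeds <- which(abs(x) > cfg$v_threshold)
  if (length(seeds) == 0) return(empty)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cands <- vector("list", length(seeds))
  k <- 0L
  for (s in seeds) {
    cand <- refine_extrema(trace, s, cfg)
    key <- paste(cand$i_min, cand$i_max, cand$terminated)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    k <- k + 1L
    cands[[k]] <- cand
  }
  rows <- lapply(cands[seq_len(k)], validate_candidate, cfg = cfg,
                 sample_rate = trace$sample_rate)
  ev <- do.call(rbind, rows)
  # Deduplicate by interval overlap, preferring the larger excursion.
  # Accepted and rejected candidates are merged separately so that a noise
  # artifact sharing an excursion with a validated transit cannot shadow
  # it; rejected candidates duplicating an accepted detection are dropped.
  dedup <- function(sub) {
    if (nrow(sub) < 2) return(sub)
    lo <- pmin(sub$i_min, sub$i_max); hi <- pmax(sub$i_min, sub$i_max)
    amp <- sub$V_max - sub$V_min
    ord <- order(lo, hi)
    sub <- sub[ord, , drop = FALSE]
    lo <- lo[ord]; hi <- hi[ord]; amp <- amp[ord]
    keep <- logical(nrow(sub))
    cur <- 0L
    for (i in seq_len(nrow(sub))) {
      if (cur == 0L) { cur <- i; keep[i] <- TRUE; next }
      ovl <- min(hi[cur], hi[i]) - max(lo[cur], lo[i]) + 1L
      shorter <- min(hi[cur] - lo[cur], hi[i] - lo[i]) + 1L
      if (ovl >= 0.5 * shorter) {
        if (amp[i] > amp[cur]) { keep[cur] <- FALSE; keep[i] <- TRUE; cur <- i }
      } else {
        cur <- i; keep[i] <- TRUE
      }
    }
    sub[keep, , drop = FALSE]
  }
  acc <- dedup(ev[ev$accepted, , drop = FALSE])
  rej <- dedup(ev[!ev$accepted, , drop = FALSE])
  if (nrow(acc) && nrow(rej)) {
    alo <- pmin(acc$i_min, acc$i_max); ahi <- pmax(acc$i_min, acc$i_max)
    rlo <- pmin(rej$i_min, rej$i_max); rhi <- pmax(rej$i_min, rej$i_max)
    dup <- vapply(seq_len(nrow(rej)), function(i) {
      ovl <- pmin(ahi, rhi[i]) - pmax(alo, rlo[i]) + 1L
      shorter <- pmin(ahi - alo, rhi[i] - rlo[i]) + 1L
      any(ovl >= 0.5 * shorter)
    }, logical(1))
    rej <- rej[!dup, , drop = FALSE]
  }
  ev <- rbind(acc, rej)
  ev <- ev[order(pmin(ev$i_min, ev$i_max)), , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))
  ev$t_min_s <- (ev$i_min - 1L) / trace$sample_rate
  ev$amplitude_T <- voltage_to_field(pmax(abs(ev$V_max), abs(ev$V_min)), acq)
  ev <- ev[, c("event_id", "i_min", "i_max", "t_min_s", "V_min", "V_max",
               "width_s", "symmetry", "amplitude_T", "accepted",
               "rejection_reason")]
  rownames(ev) <- NULL
  class(ev) <- c("gmr_events", "data.frame")
  ev
}

#' @export
print.gmr_events <- function(x, ...) {
  cat(sprintf("gmr events: %d candidate(s), %d accepted\n",
              nrow(x), sum(x$accepted)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
summary.gmr_events <- function(object, ...) {
  acc <- object[object$accepted, , drop = FALSE]
  list(n_candidates = nrow(object), n_accepted = nrow(acc),
       rejection_reasons = table(object$rejection_reason, useNA = "no"),
       amplitude_uT = if (nrow(acc)) summary(acc$amplitude_T * 1e6) else NULL)
}

#' Write / read a detected-event table
#'
#' TSV with one row per candidate: `event_id`, `i_min`, `i_max`, `t_min_s`,
#' `V_min_V`, `V_max_V`, `width_s`, `symmetry`, `amplitude_uT`, `accepted`,
#' `rejection_reason`.
#'
#' @param events a `gmr_events`.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  df <- data.frame(event_id = events$event_id, i_min = events$i_min,
                   i_max = events$i_max, t_min_s = events$t_min_s,
                   V_min_V = events$V_min, V_max_V = events$V_max,
                   width_s = events$width_s, symmetry = events$symmetry,
                   amplitude_uT = events$amplitude_T * 1e6,
                   accepted = events$accepted,
                   rejection_reason = events$rejection_reason)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
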