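# Campaign orchestration: reproducible multi-sample runs through the full
# generate -> trace -> detect -> count pipeline, seed fan-out, plain-text
# configs, and the consolidated reference-number report.

#' Fan a campaign seed out to per-task child seeds
#'
#' A single campaign seed deterministically yields one child seed per task,
#' so any sample of a campaign can be re-run in isolation.
#'
#' @param seed integer campaign seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Read a key-value configuration file
#'
#' Plain-text `section.key = value` lines (`#` comments allowed), e.g.
#' `sensor.length_um = 120`. Returns a nested list keyed by section.
#'
#' @param path file path.
#' @return nested named list; values are numeric where possible.
#' @export
read_gmr_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s*=\\s*")[[1]]
    if (length(parts) != 2)
      stop("config validation error: cannot parse line: ", ln)
    keys <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) val <- parts[2]
    if (length(keys) == 2) {
      out[[keys[1]]][[keys[2]]] <- val
    } else {
      out[[parts[1]]] <- val
    }
  }
  out
}

#' Build component objects from a parsed config
#'
#' Maps the conventional config keys (`sensor.length_um`, `sensor.width_um`,
#' `sensor.detectivity_uT`, `bead.moment_sat_emu`, `bead.moment_op_emu`,
#' `bead.diameter_um`, `channel.*`, `acquisition.*`) onto package
#' constructors, using constructor defaults for absent keys.
#'
#' @param config a nested list from [read_gmr_config()].
#' @return list with `sensor`, `bead`, `channel`, `acquisition`.
#' @export
config_components <- function(config) {
  g <- function(section, key, default) {
    v <- config[[section]][[key]]
    if (is.null(v)) default else v
  }
  sensor <- sensor_geometry(
    length_L = g("sensor", "length_um", 120) * 1e-6,
    width_l = g("sensor", "width_um", 4) * 1e-6,
    detectivity = g("sensor", "detectivity_uT", 2.2) * 1e-6)
  bead <- bead_magnetics(
    diameter = g("bead", "diameter_um", 1) * 1e-6,
    moment_sat_emu = g("bead", "moment_sat_emu", 2.1e-11),
    moment_op_emu = g("bead", "moment_op_emu", 1.6e-11))
  channel <- channel_geometry(
    height = g("channel", "height_um", 25) * 1e-6,
    width = g("channel", "width_um", 100) * 1e-6,
    spacer = g("channel", "spacer_um", 6) * 1e-6,
    flow_mL_min = g("channel", "flow_mL_min", 1 / 30))
  acq <- acquisition_config(
    sample_rate = g("acquisition", "sample_rate_hz", 200e3),
    preamp_gain = g("acquisition", "preamp_gain", 500),
    post_gain = g("acquisition", "post_gain", 20),
    filter_cutoff = g("acquisition", "filter_cutoff_hz", 15e3),
    bias_voltage = g("acquisition", "bias_v", 1),
    sensitivity_per_mT = g("acquisition", "sensitivity_per_mT", 0.025),
    noise_rms_field = g("acquisition", "noise_rms_uT", 2.2 / 3) * 1e-6)
  list(sensor = sensor, bead = bead, channel = channel, acquisition = acq)
}

#' Run a simulation campaign over a list of compositions
#'
#' For each composition: generate the event stream, synthesize the trace,
#' detect events, and count accepted events whose field amplitude reaches
#' the pooled analysis cutoff, normalized to counts/mL. Deterministic for a
#' given seed (one child seed per sample). When `out_dir` is given, traces,
#' event tables, manifests and a checksum manifest are written there.
#'
#' @param compositions list of [sample_composition()] objects.
#' @param duration_s simulated flow duration per sample, seconds.
#' @param seed campaign seed.
#' @param sensor,bead,channel,acq component objects (defaults mirror the
#'   reference instrument).
#' @param detector a [detector_config()]; default threshold is the voltage
#'   image of the sensor detectivity.
#' @param amplitude_cutoff pooled analysis cutoff in tesla (default the
#'   sensor detectivity): only accepted events at or above it are counted.
#' @param noise,lowpass passed to [simulate_trace()].
#' @param amplitude_floor passed to [simulate_trace()]; a sensible value
#'   for dense bead backgrounds is a quarter of the detectivity.
#' @param out_dir optional output directory for artifacts.
#' @return a `data.frame` of class `gmr_campaign`: one row per sample with
#'   `label`, `cells_per_mL`, `volume_mL`, `n_objects`, `n_accepted`,
#'   `counts_per_mL` and the child `seed`.
#' @export
run_campaign <- function(compositions, duration_s, seed,
                         sensor = sensor_geometry(),
                         bead = bead_magnetics(),
                         channel = channel_geometry(),
                         acq = acquisition_config(),
                         detector = NULL,
                         amplitude_cutoff = NULL,
                         noise = TRUE, lowpass = TRUE,
                         amplitude_floor = 0, out_dir = NULL) {
  if (!length(compositions)) {
    out <- data.frame(label = character(0), cells_per_mL = numeric(0),
                      volume_mL = numeric(0), n_objects = integer(0),
                      n_accepted = integer(0), counts_per_mL = numeric(0),
                      seed = integer(0))
    class(out) <- c("gmr_campaign", "data.frame")
    return(out)
  }
  bad <- !vapply(compositions, inherits, logical(1), "sample_composition")
  if (any(bad))
    stop("config validation error: compositions ",
         paste(which(bad), collapse = ", "), " are not sample_composition")
  if (is.null(amplitude_cutoff)) amplitude_cutoff <- sensor$detectivity
  if (is.null(detector))
    detector <- detector_config(field_to_voltage(sensor$detectivity, acq))
  seeds <- child_seeds(seed, length(compositions))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  written <- character(0)
  rows <- vector("list", length(compositions))
  for (i in seq_along(compositions)) {
    comp <- compositions[[i]]
    ev <- generate_sample(comp, channel, duration_s, bead, seed = seeds[i])
    tr <- simulate_trace(ev, acq, sensor, channel, noise = noise,
                         lowpass = lowpass, seed = seeds[i] + 1L,
                         amplitude_floor = amplitude_floor)
    det <- detect_events(tr, detector, acq)
    hit <- det$accepted & det$amplitude_T >= amplitude_cutoff
    vol <- attr(ev, "volume_mL")
    rows[[i]] <- data.frame(label = comp$label,
                            cells_per_mL = comp$cells_per_mL,
                            volume_mL = vol, n_objects = nrow(ev),
                            n_accepted = sum(hit),
                            counts_per_mL = normalize_counts(sum(hit), vol),
                            seed = seeds[i], stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      slug <- gsub("[^A-Za-z0-9]+", "_", comp$label)
      p1 <- file.path(out_dir, paste0(slug, "_trace.csv"))
      p2 <- file.path(out_dir, paste0(slug, "_events.tsv"))
      p3 <- file.path(out_dir, paste0(slug, "_manifest.tsv"))
      write_trace(tr, p1); write_events(det, p2)
      write_sample_manifest(ev, p3)
      written <- c(written, p1, p2, p3)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    p4 <- file.path(out_dir, "summary.tsv")
    utils::write.table(out, p4, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p4)
    manifest <- data.frame(file = basename(written),
                           md5 = unname(tools::md5sum(written)))
    utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  attr(out, "seed") <- seed
  class(out) <- c("gmr_campaign", "data.frame")
  out
}

#' Recompute the headline reference numbers
#'
#' Consolidated self-check: the per-sample summary of the packaged count
#' matrix, the negative-control threshold chain, the LOD bracket, the
#' dipole scaling ratios (height decade, bead-count ratio, spacer-window
#' ratio) and the 7-bead detectable height, each compared against its
#' published value at the printed rounding.
#'
#' @param sensor,bead component objects.
#' @return an object of class `gmr_reproduction`; its `checks` element is a
#'   `data.frame` with `check`, `value`, `reference`, `pass`.
#' @export
reproduce_paper_numbers <- function(sensor = sensor_geometry(),
                                    bead = bead_magnetics()) {
  tab <- count_table()
  smry <- summarize_table(tab)
  printed_mean <- c(12000, 5000, 1900, 560, 530, 540, 480, 1100)
  printed_sd <- c(1800, 970, 610, 66, 270, 260, 150, 820)
  table_pass <- signif(smry$mean_per_mL, 2) == printed_mean &
    signif(smry$sd_per_mL, 2) == printed_sd

  neg <- tab$count_per_mL[tab$sample_label == "beads only / anti-CD138"]
  thr <- detection_count_threshold(neg)
  lod <- classify_and_bracket_lod(tab, thr)

  d1 <- dipole_state(c(0, 0, 1e-6), bead$moment_operating)
  b1 <- point_dipole_field(d1, c(0, 0, 0))
  d10 <- dipole_state(c(0, 0, 10e-6), bead$moment_operating)
  b10 <- point_dipole_field(d10, c(0, 0, 0))
  height_ratio <- sqrt(sum(b1^2)) / sqrt(sum(b10^2))
  bead_ratio <- sqrt(sum(point_dipole_field(d1, c(0, 0, 0), 100)^2)) /
    sqrt(sum(b1^2))
  d7 <- dipole_state(c(0, 0, 7e-6), bead$moment_operating)
  d16 <- dipole_state(c(0, 0, 16e-6), bead$moment_operating)
  spacer_ratio <- sqrt(sum(point_dipole_field(d7, c(0, 0, 0))^2)) /
    sqrt(sum(point_dipole_field(d16, c(0, 0, 0))^2))

  h7 <- detectable_height(7, sensor$detectivity, bead, sensor)

  checks <- data.frame(
    check = c("negative mean (counts/mL)", "negative SD (counts/mL)",
              "count threshold (counts/mL)", "LOD bracket low (cells/mL)",
              "LOD bracket high (cells/mL)", "field ratio 1 um vs 10 um",
              "field ratio 100 vs 1 beads", "field ratio 7 um vs 16 um",
              "7-bead detectable height (um)"),
    value = c(signif(thr$negative_mean, 2), signif(thr$negative_sd, 2),
              signif(thr$count_threshold, 2), lod$lod_bracket[1],
              lod$lod_bracket[2], height_ratio, bead_ratio,
              round(spacer_ratio), round(h7 * 1e6)),
    reference = c(1100, 820, 3600, 1e4, 3e4, 1000, 100, 12, 6),
    stringsAsFactors = FALSE)
  checks$pass <- abs(checks$value - checks$reference) <=
    c(0, 0, 0, 0, 0, 1e-9, 1e-9, 0, 1)
  structure(list(table_summary = smry, table_pass = table_pass,
                 threshold = thr, lod = lod, checks = checks),
            class = "gmr_reproduction")
}

#' @export
print.gmr_reproduction <- function(x, ...) {
  cat("Count-matrix summary (mean +/- population SD, counts/mL):\n")
  s <- x$table_summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-26s %8.3g +/- %8.3g   [%s]\n", s$sample_label[i],
                s$mean_per_mL[i], s$sd_per_mL[i],
                if (x$table_pass[i]) "ok" else "MISMATCH"))
  cat("\nReference checks:\n")
  c <- x$checks
  for (i in seq_len(nrow(c)))
    cat(sprintf("  %-32s %10.4g  (ref %8.4g)  [%s]\n", c$check[i],
                c$value[i], c$reference[i],
                if (c$pass[i]) "ok" else "MISMATCH"))
  invisible(x)
}
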