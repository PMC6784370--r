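# Assay counting statistics: per-mL normalization, the negative-control
# count threshold that declares a sample positive, limit-of-detection
# bracketing, and the blank-based LOD/LOQ conventions of plate assays.
# Population standard deviations (divisor n) are used throughout: that is
# the convention under which the packaged reference count matrix reproduces
# its published summary column.

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Normalize an event count to counts per milliliter
#'
#' @param event_count number of events (vectorized).
#' @param volume_mL sample volume actually flowed, mL.
#' @return counts per mL.
#' @export
normalize_counts <- function(event_count, volume_mL) {
  if (any(volume_mL <= 0)) stop("'volume_mL' must be positive")
  event_count / volume_mL
}

#' Negative-control detection count threshold
#'
#' Mean of the replicate counts of the worst negative control plus three
#' times their population standard deviation: a sample whose mean count
#' exceeds this is declared positive.
#'
#' @param negative_counts numeric vector of counts/mL, length at least 2.
#' @return an object of class `threshold_result` with `negative_mean`,
#'   `negative_sd` and `count_threshold`.
#' @export
#' @examples
#' detection_count_threshold(c(1665, 375, 2213, 310))  # about 3.6e3
detection_count_threshold <- function(negative_counts) {
  if (length(negative_counts) < 2)
    stop("at least 2 negative replicate counts are required")
  m <- mean(negative_counts)
  s <- .pop_sd(negative_counts)
  structure(list(negative_mean = m, negative_sd = s,
                 count_threshold = m + 3 * s),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("negative mean %.3g +/- %.3g counts/mL -> threshold %.3g counts/mL\n",
              x$negative_mean, x$negative_sd, x$count_threshold))
  invisible(x)
}

#' Count table of replicate per-mL counts
#'
#' Long-format table with one row per replicate measurement. The packaged
#' reference matrix (loaded when `data` is omitted) holds the published
#' per-mL counts of five positive NS1 dilutions and three negative controls
#' measured over seven chip experiments.
#'
#' @param data a `data.frame` with columns `sample_label`, `class`
#'   (`"positive"`/`"negative"`), `cells_per_mL` (NA for controls),
#'   `antibody`, `count_per_mL`; omitted: the packaged matrix is read.
#' @return the validated `data.frame` with class `count_table`.
#' @export
count_table <- function(data = NULL) {
  if (is.null(data)) {
    path <- system.file("extdata", "table2_counts.tsv", package = "gmrflow",
                        mustWork = TRUE)
    data <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("sample_label", "class", "cells_per_mL", "antibody", "count_per_mL")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("count table missing column(s): ", paste(missing, collapse = ", "))
  if (any(data$count_per_mL < 0)) stop("counts must be non-negative")
  if (!any(data$class == "negative"))
    stop("count table needs at least one negative row for thresholding")
  class(data) <- c("count_table", "data.frame")
  data
}

#' Per-sample mean and population SD
#'
#' @param table a [count_table()].
#' @return a `data.frame` with one row per sample (in first-appearance
#'   order): `sample_label`, `class`, `cells_per_mL`, `n_replicates`,
#'   `mean_per_mL`, `sd_per_mL`.
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "count_table"), nrow(table) > 0)
  labs <- unique(table$sample_label)
  rows <- lapply(labs, function(lab) {
    sub <- table[table$sample_label == lab, , drop = FALSE]
    data.frame(sample_label = lab, class = sub$class[1],
               cells_per_mL = sub$cells_per_mL[1],
               n_replicates = nrow(sub),
               mean_per_mL = mean(sub$count_per_mL),
               sd_per_mL = .pop_sd(sub$count_per_mL),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify samples and bracket the limit of detection
#'
#' A sample is declared positive when its mean count exceeds the count
#' threshold. The LOD bracket is the interval between the highest cell
#' concentration still declared negative and the lowest declared positive.
#'
#' @param table a [count_table()]; positive rows must carry nominal
#'   concentrations.
#' @param threshold counts/mL, or a `threshold_result`.
#' @return list with `verdicts` (the summary table plus a `positive`
#'   column), `lod_bracket` (length-2 concentration interval, `NA` sides
#'   where unbounded) and `open_bracket` (`TRUE` when no positive sample
#'   exceeds the threshold).
#' @export
classify_and_bracket_lod <- function(table, threshold) {
  if (inherits(threshold, "threshold_result"))
    threshold <- threshold$count_threshold
  smry <- summarize_table(table)
  smry$positive <- smry$mean_per_mL > threshold
  pos <- smry[smry$class == "positive" & !is.na(smry$cells_per_mL), ,
              drop = FALSE]
  if (!nrow(pos)) stop("no positive rows with nominal concentrations")
  below <- pos$cells_per_mL[!pos$positive]
  above <- pos$cells_per_mL[pos$positive]
  open <- length(above) == 0
  bracket <- c(if (length(below)) max(below) else NA_real_,
               if (length(above)) min(above) else NA_real_)
  list(verdicts = smry, lod_bracket = bracket, open_bracket = open,
       count_threshold = threshold)
}

#' Blank-based LOD and LOQ signals
#'
#' Plate-assay conventions: the limit of detection is the blank mean plus
#' 3 standard deviations, the limit of quantification the blank mean plus
#' 10; population SD, as elsewhere in the package.
#'
#' @param blank_values numeric vector of blank measurements, length >= 2.
#' @return named numeric `c(lod = , loq = )` on the blank signal scale.
#' @export
blank_based_lod_loq <- function(blank_values) {
  if (length(blank_values) < 2)
    stop("at least 2 blank measurements are required")
  m <- mean(blank_values)
  s <- .pop_sd(blank_values)
  c(lod = m + 3 * s, loq = m + 10 * s)
}
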