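#' Quality-control configuration for the analysis-ready cell set
#'
#' @param lower_depth_threshold A fixed positive depth, or `"auto"`: the
#'   threshold becomes the smallest observed depth in the batch that is at
#'   least `auto_floor`. The automatic rule is a reproducible stand-in for
#'   choosing a per-batch cutoff by inspecting the depth distribution.
#' @param auto_floor Floor for the automatic rule (reads).
#' @param upper_rule_multiplier Multiplier `k` of the upper-depth rule.
#' @param upper_rule_variant `"Q3_TIMES_K"` (default): exclude cells with
#'   depth above `k * Q3`, the literal reading of a cutoff at `k` times
#'   the upper boundary of the interquartile range; or `"TUKEY_FENCE"`:
#'   exclude above `Q3 + k * (Q3 - Q1)`.
#' @param quartile_method Quantile type passed to [stats::quantile()];
#'   default 7, linear interpolation between order statistics.
#' @param negative_control_max_depth A plate whose negative-control well
#'   exceeds this depth is flagged as contaminated and dropped entirely.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(lower_depth_threshold = "auto", auto_floor = 200,
                      upper_rule_multiplier = 1.5,
                      upper_rule_variant = c("Q3_TIMES_K", "TUKEY_FENCE"),
                      quartile_method = 7,
                      negative_control_max_depth = 10) {
  upper_rule_variant <- match.arg(upper_rule_variant)
  if (!identical(lower_depth_threshold, "auto")) {
    stopifnot(is.numeric(lower_depth_threshold), lower_depth_threshold > 0)
  }
  stopifnot(upper_rule_multiplier > 0, negative_control_max_depth >= 0)
  structure(list(lower_depth_threshold = lower_depth_threshold,
                 auto_floor = auto_floor,
                 upper_rule_multiplier = upper_rule_multiplier,
                 upper_rule_variant = upper_rule_variant,
                 quartile_method = quartile_method,
                 negative_control_max_depth = negative_control_max_depth),
            class = "qc_config")
}

#' Lower read-depth threshold for a sequencing batch
#'
#' Cells with read depth strictly below the returned threshold are to be
#' excluded. With a fixed configuration value the threshold is that value;
#' with `"auto"` it is the smallest observed depth that is at least the
#' configured floor, so the retained minimum is the first depth clearing
#' the floor.
#'
#' @param depths Per-cell read depths of one batch.
#' @param config A [qc_config()].
#' @return The numeric threshold.
#' @export
lower_depth_threshold <- function(depths, config = qc_config()) {
  if (length(depths) == 0) stop("empty batch")
  if (identical(config$lower_depth_threshold, "auto")) {
    above <- depths[depths >= config$auto_floor]
    if (length(above) == 0) return(config$auto_floor)
    min(above)
  } else {
    config$lower_depth_threshold
  }
}

#' High-depth (suspected doublet) exclusion
#'
#' Flags cells whose read depth is anomalously high for the batch — the
#' signature of a well that received more than one cell. Under
#' `Q3_TIMES_K`, depth strictly above `k * Q3` is excluded; under
#' `TUKEY_FENCE`, above `Q3 + k * (Q3 - Q1)`. Quartiles use the declared
#' quantile convention. With fewer than 4 depths no exclusion is made and
#' a warning is raised.
#'
#' @inheritParams lower_depth_threshold
#' @return Logical vector, `TRUE` where the cell is excluded.
#' @export
upper_depth_exclusion <- function(depths, config = qc_config()) {
  if (length(depths) < 4) {
    warning("fewer than 4 depths: upper-depth rule not applied")
    return(rep(FALSE, length(depths)))
  }
  q <- quantile(depths, c(0.25, 0.75), type = config$quartile_method,
                names = FALSE)
  cutoff <- switch(config$upper_rule_variant,
    Q3_TIMES_K = config$upper_rule_multiplier * q[2],
    TUKEY_FENCE = q[2] + config$upper_rule_multiplier * (q[2] - q[1]))
  depths > cutoff
}

#' Flag plates with contaminated negative controls
#'
#' A plate is excluded when its (single, cell-free) negative-control well
#' shows read depth above `negative_control_max_depth`: reads there mean
#' template reached a well that should have none.
#'
#' @param controls data.frame with columns `plate_id` and `depth`, one row
#'   per plate's negative control.
#' @param config A [qc_config()].
#' @return Character vector of excluded plate ids.
#' @export
flag_contaminated_plates <- function(controls, config = qc_config()) {
  if (anyDuplicated(controls$plate_id) || any(is.na(controls$depth)))
    stop("expected exactly one negative control per plate")
  controls$plate_id[controls$depth > config$negative_control_max_depth]
}

#' Apply all quality filters and build the QC report
#'
#' Runs, in order: negative-control plate exclusion, then per-batch lower
#' and upper read-depth filters on cell wells. The depth thresholds are
#' computed per batch (`batch` column if present, otherwise one batch)
#' from the cell wells of plates that survived control screening.
#'
#' @param counts Allele-count table with columns `plate_id`, `well_id`,
#'   `is_control`, `depth` (as produced by [simulate_cohort()] or from
#'   [count_plate()] merged with a plate map); a `batch` column is
#'   honoured if present.
#' @param config A [qc_config()].
#' @return A list of class `qc_result`: `retained` (rows of `counts`
#'   passing all filters, controls removed), `report` (per-plate
#'   bookkeeping plus thresholds and the retained-depth summary), and
#'   `excluded_plates`.
#' @export
apply_qc <- function(counts, config = qc_config()) {
  stopifnot(all(c("plate_id", "well_id", "is_control", "depth") %in%
                  names(counts)))
  had_batch <- "batch" %in% names(counts)
  if (!had_batch) counts$batch <- "batch1"

  controls <- counts[counts$is_control, c("plate_id", "depth")]
  if (!setequal(controls$plate_id, unique(counts$plate_id)))
    stop("every plate must carry exactly one negative control")
  bad_plates <- flag_contaminated_plates(controls, config)

  cells <- counts[!counts$is_control & !(counts$plate_id %in% bad_plates), ,
                  drop = FALSE]
  keep <- rep(TRUE, nrow(cells))
  low <- high <- rep(FALSE, nrow(cells))
  thresholds <- list()
  for (b in unique(cells$batch)) {
    sel <- cells$batch == b
    thr <- lower_depth_threshold(cells$depth[sel], config)
    low[sel] <- cells$depth[sel] < thr
    high[sel] <- upper_depth_exclusion(cells$depth[sel], config)
    thresholds[[b]] <- thr
  }
  keep <- !low & !high
  retained <- cells[keep, , drop = FALSE]
  if (!had_batch) retained$batch <- NULL

  per_plate <- do.call(rbind, lapply(unique(counts$plate_id), function(p) {
    in_p <- !counts$is_control & counts$plate_id == p
    if (p %in% bad_plates) {
      data.frame(plate_id = p, n_in = sum(in_p), n_low_depth = NA_integer_,
                 n_high_depth_excluded = NA_integer_, n_retained = 0L,
                 plate_excluded = TRUE, reason = "negative-control contamination")
    } else {
      cp <- cells$plate_id == p
      data.frame(plate_id = p, n_in = sum(in_p), n_low_depth = sum(low[cp]),
                 n_high_depth_excluded = sum(high[cp]),
                 n_retained = sum(keep[cp]), plate_excluded = FALSE,
                 reason = "")
    }
  }))

  d <- retained$depth
  depth_summary <- if (length(d)) {
    q <- quantile(d, c(0.25, 0.75), type = config$quartile_method,
                  names = FALSE)
    list(n = length(d), median = median(d), iqr = q, range = range(d))
  } else list(n = 0L)

  structure(list(retained = retained,
                 report = list(per_plate = per_plate,
                               lower_thresholds = thresholds,
                               upper_rule = config$upper_rule_variant,
                               upper_rule_multiplier = config$upper_rule_multiplier,
                               quartile_method = config$quartile_method,
                               depth_summary = depth_summary),
                 excluded_plates = bad_plates),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("QC result:", sum(r$per_plate$n_in), "cells in,",
      nrow(x$retained), "retained;",
      length(x$excluded_plates), "plate(s) excluded\n")
  if (x$report$depth_summary$n > 0) {
    s <- x$report$depth_summary
    cat(sprintf("retained read depth: median %s (IQR = %s, %s; range = %s, %s)\n",
                format(s$median), format(s$iqr[1]), format(s$iqr[2]),
                format(s$range[1]), format(s$range[2])))
  }
  invisible(x)
}
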