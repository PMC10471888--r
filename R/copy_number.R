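#' Fit a qPCR standard curve
#'
#' Ordinary least squares of threshold cycle (Ct) on log10 template
#' copies across a plasmid dilution series (typically six 10-fold
#' dilutions). A 100%-efficient assay has slope \eqn{-\log_2 10 \approx
#' -3.3219}. The curve is flagged when the fit falls outside the
#' configured QC bounds (defaults: \eqn{R^2 > 0.9992} and slope within
#' \eqn{[-3.449, -3.264]}).
#'
#' @param copies Known copies per reaction at each dilution (> 0).
#' @param ct Observed Ct values (same length).
#' @param r2_min,slope_range QC bounds.
#' @return An object of class `standard_curve`: `slope`, `intercept`
#'   (Ct at 1 copy), `r_squared`, `qc_pass`, `qc_reason`.
#' @export
fit_standard_curve <- function(copies, ct, r2_min = 0.9992,
                               slope_range = c(-3.449, -3.264)) {
  if (length(copies) < 3 || length(ct) != length(copies))
    stop("need at least 3 dilution points with matching Ct values")
  if (any(copies <= 0)) stop("copies must be > 0")
  fit <- lm(ct ~ log10(copies))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  # suppressWarnings: summary.lm warns on an exactly collinear (perfect)
  # fit, which is a legitimate noise-free standard curve here
  r2 <- if (var(ct) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  reason <- character(0)
  if (!is.finite(slope) || slope >= 0 || slope < slope_range[1] ||
      slope > slope_range[2])
    reason <- c(reason, sprintf("slope %.4f outside [%.3f, %.3f]", slope,
                                slope_range[1], slope_range[2]))
  if (r2 < r2_min)
    reason <- c(reason, sprintf("R^2 %.5f below %.5f", r2, r2_min))
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 qc_pass = length(reason) == 0,
                 qc_reason = paste(reason, collapse = "; ")),
            class = "standard_curve")
}

#' Absolute template copies per cell from a mean Ct
#'
#' Inverts the standard curve, `copies_in_reaction =
#' 10^((mean_ct - intercept) / slope)`, then divides by the number of
#' sorted cells and the fraction of the cell lysate present in the
#' reaction: `copies_per_cell = copies_in_reaction / (n_cells *
#' volume_factor)`.
#'
#' @param mean_ct Mean threshold cycle of the sample.
#' @param curve A [fit_standard_curve()] result.
#' @param n_cells Cells sorted into the sample (>= 1).
#' @param volume_factor Fraction of the total lysate used per reaction
#'   (default 1/25: a 1:5 lysate dilution of which one fifth is loaded).
#' @return Copies per cell.
#' @export
quantify <- function(mean_ct, curve, n_cells, volume_factor = 1 / 25) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  if (volume_factor <= 0) stop("volume_factor must be > 0")
  copies_in_reaction <- 10^((mean_ct - curve$intercept) / curve$slope)
  copies_in_reaction / (n_cells * volume_factor)
}

#' Normalize a copy-number estimate across plates
#'
#' `normalized = (absolute / on_plate_control) * mean_control`, which
#' removes plate-to-plate efficiency differences by expressing every
#' sample relative to the control DNA run on its own plate.
#'
#' @param absolute Absolute copies per cell of the sample.
#' @param on_plate_control The same quantity for the plate's control DNA.
#' @param mean_control Mean control copy number across plates.
#' @return Normalized copies per cell.
#' @export
normalize_plate <- function(absolute, on_plate_control, mean_control) {
  if (any(on_plate_control <= 0) || any(mean_control <= 0))
    stop("control copy numbers must be > 0")
  (absolute / on_plate_control) * mean_control
}

#' Apply replicate-consistency exclusions to qPCR samples
#'
#' Per sample: an optional within-triplicate outlier step drops one
#' replicate when its removal brings the replicate SD below the SD
#' cutoff and it deviates from the other two by more than 3 times their
#' spread; then the sample is excluded if the (remaining) replicate SD
#' exceeds `sd_max` (default 0.3) or the mean Ct exceeds `ct_max`
#' (default 30). Fewer than 2 usable replicates also excludes the
#' sample.
#'
#' @param cts A matrix or data.frame of replicate Ct values (rows =
#'   samples) or a list of numeric vectors.
#' @param sd_max,ct_max Exclusion cutoffs.
#' @param drop_outliers Apply the within-triplicate outlier rule?
#' @return A data.frame: `mean_ct`, `ct_sd`, `n_replicates_used`,
#'   `outlier_dropped`, `excluded`, `reason`.
#' @export
apply_ct_exclusions <- function(cts, sd_max = 0.3, ct_max = 30,
                                drop_outliers = TRUE) {
  if (is.matrix(cts) || is.data.frame(cts))
    cts <- lapply(seq_len(nrow(cts)), function(i) as.numeric(cts[i, ]))
  res <- lapply(cts, function(x) {
    x <- x[is.finite(x)]
    dropped <- FALSE
    if (drop_outliers && length(x) == 3 && sd(x) > sd_max) {
      for (i in 1:3) {
        rest <- x[-i]
        if (sd(rest) < sd_max &&
            abs(x[i] - mean(rest)) > 3 * max(diff(range(rest)), .Machine$double.eps)) {
          x <- rest; dropped <- TRUE; break
        }
      }
    }
    if (length(x) < 2)
      return(data.frame(mean_ct = NA_real_, ct_sd = NA_real_,
                        n_replicates_used = length(x),
                        outlier_dropped = dropped, excluded = TRUE,
                        reason = "fewer than 2 usable replicates"))
    m <- mean(x); s <- sd(x)
    reason <- character(0)
    if (s > sd_max) reason <- c(reason, sprintf("Ct SD %.3f > %.2f", s, sd_max))
    if (m > ct_max) reason <- c(reason, sprintf("mean Ct %.2f > %g", m, ct_max))
    data.frame(mean_ct = m, ct_sd = s, n_replicates_used = length(x),
               outlier_dropped = dropped, excluded = length(reason) > 0,
               reason = paste(reason, collapse = "; "))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Quantify a whole qPCR plate with exclusions and normalization
#'
#' Convenience wrapper: applies [apply_ct_exclusions()], fits the plate's
#' standard curve, converts retained samples to absolute copies per cell
#' with [quantify()], and (when a control sample is marked) computes
#' plate-normalized values with [normalize_plate()].
#'
#' @param samples data.frame with columns `sample_id`, replicate columns
#'   `ct1`, `ct2`, `ct3`, `n_cells`, and optionally a logical
#'   `is_control`.
#' @param standards data.frame with columns `copies` and `ct`.
#' @param mean_control Cross-plate mean control copy number; defaults to
#'   this plate's control value (making the control map to itself).
#' @inheritParams quantify
#' @return A list: `curve`, `samples` (input plus `mean_ct`, `ct_sd`,
#'   `excluded`, `reason`, `copies_per_cell`, `normalized_copies_per_cell`).
#' @export
quantify_plate <- function(samples, standards, volume_factor = 1 / 25,
                           mean_control = NULL) {
  curve <- fit_standard_curve(standards$copies, standards$ct)
  excl <- apply_ct_exclusions(samples[, c("ct1", "ct2", "ct3")])
  out <- cbind(samples, excl)
  out$copies_per_cell <- NA_real_
  ok <- !out$excluded
  out$copies_per_cell[ok] <- quantify(out$mean_ct[ok], curve,
                                      out$n_cells[ok], volume_factor)
  out$normalized_copies_per_cell <- NA_real_
  if ("is_control" %in% names(out) && any(out$is_control & ok)) {
    ctrl <- out$copies_per_cell[out$is_control & ok][1]
    if (is.null(mean_control)) mean_control <- ctrl
    out$normalized_copies_per_cell[ok] <-
      normalize_plate(out$copies_per_cell[ok], ctrl, mean_control)
  }
  list(curve = curve, samples = out)
}
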