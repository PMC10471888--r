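#' Describe one sorted cell subset and its true heteroplasmy distribution
#'
#' A subset is a (subject, cell type) combination with a known number of
#' sorted cells and a ground-truth spike-and-slab heteroplasmy law: with
#' probability `pi_true` a cell belongs to the near-zero "spike"
#' (a normal with mean `mu_true` and sd `sigma_true` truncated to (0,1),
#' or exactly 0 when `spike = "hard_zero"`), otherwise to the "slab"
#' spanning (0,1).
#'
#' @param subject_id,cell_type Labels.
#' @param n_cells Number of cells sorted for this subset.
#' @param pi_true Spike weight in \[0,1\].
#' @param mu_true Spike mean in \[0, 0.2\].
#' @param sigma_true Spike standard deviation (> 0).
#' @param slab Slab descriptor: `slab_uniform()` (default) or
#'   `slab_beta(shape1, shape2)`.
#' @param spike `"truncnorm"` (default; matches the inference model) or
#'   `"hard_zero"` (spike cells have heteroplasmy exactly 0, emulating
#'   complete clearance of the variant).
#' @return An object of class `subset_truth`.
#' @export
subset_truth <- function(subject_id, cell_type, n_cells, pi_true,
                         mu_true = 0.02, sigma_true = 0.05,
                         slab = slab_uniform(),
                         spike = c("truncnorm", "hard_zero")) {
  spike <- match.arg(spike)
  stopifnot(n_cells >= 1, n_cells == round(n_cells))
  if (pi_true < 0 || pi_true > 1) stop("pi_true must lie in [0,1]")
  if (mu_true < 0 || mu_true > 0.2) stop("mu_true must lie in [0, 0.2]")
  if (sigma_true <= 0) stop("sigma_true must be > 0")
  structure(list(subject_id = as.character(subject_id),
                 cell_type = as.character(cell_type),
                 n_cells = as.integer(n_cells), pi_true = pi_true,
                 mu_true = mu_true, sigma_true = sigma_true,
                 slab = slab, spike = spike),
            class = "subset_truth")
}

#' Slab (background) heteroplasmy distributions on (0,1)
#'
#' @param shape1,shape2 Beta shape parameters.
#' @return A slab descriptor list.
#' @export
slab_uniform <- function() structure(list(type = "uniform"), class = "hetmix_slab")

#' @rdname slab_uniform
#' @export
slab_beta <- function(shape1, shape2) {
  stopifnot(shape1 > 0, shape2 > 0)
  structure(list(type = "beta", shape1 = shape1, shape2 = shape2),
            class = "hetmix_slab")
}

#' Sequencing assay description for the synthetic generator
#'
#' Defaults emulate the kind of plate-based single-cell amplicon assay the
#' pipeline targets: per-cell read depth log-normal with median 1,146 and
#' central 99% range close to \[200, 7,000\], truncated below at one read;
#' a low per-base miscall rate; occasional doublet wells at roughly twice
#' the depth; cell-free negative-control wells with near-zero ambient
#' counts, except on contaminated plates where the control looks like a
#' cell.
#'
#' @param depth_law,negative_control_depth_law,low_depth_law Depth-law
#'   descriptors, see [depth_law()].
#' @param error_rate Per-base miscall probability in \[0, 0.05\].
#' @param doublet_rate Probability that a well receives two cells.
#' @param low_depth_rate Probability that a (singlet) cell well amplifies
#'   poorly and draws its depth from `low_depth_law`; these wells are the
#'   planted targets of the lower read-depth filter.
#' @param contaminated_plate_rate Probability that a plate's negative
#'   control well is contaminated.
#' @param base_quality_law Phred base-quality descriptor for emitted FASTQ:
#'   `list(type = "fixed", q = 38)` or
#'   `list(type = "discrete", q = ..., prob = ...)`.
#' @param reverse_prob Probability a read is emitted in reverse-complement
#'   orientation.
#' @return An object of class `sequencing_spec`.
#' @export
sequencing_spec <- function(depth_law = NULL,
                            error_rate = 0.005,
                            doublet_rate = 0.02,
                            low_depth_rate = 0,
                            low_depth_law = NULL,
                            contaminated_plate_rate = 0.05,
                            negative_control_depth_law = NULL,
                            base_quality_law = list(type = "fixed", q = 38L),
                            reverse_prob = 0.5) {
  if (is.null(depth_law))
    depth_law <- hetmix::depth_law("lognormal", meanlog = log(1146),
                                   sdlog = 0.69, min = 1)
  if (is.null(low_depth_law))
    low_depth_law <- hetmix::depth_law("uniform_int", min = 10, max = 50)
  if (is.null(negative_control_depth_law))
    negative_control_depth_law <- hetmix::depth_law("poisson", lambda = 2)
  for (p in c(error_rate, doublet_rate, low_depth_rate,
              contaminated_plate_rate, reverse_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0,1]")
  if (error_rate > 0.05) stop("error_rate above 0.05 is not supported")
  structure(list(depth_law = depth_law, error_rate = error_rate,
                 doublet_rate = doublet_rate, low_depth_rate = low_depth_rate,
                 low_depth_law = low_depth_law,
                 contaminated_plate_rate = contaminated_plate_rate,
                 negative_control_depth_law = negative_control_depth_law,
                 base_quality_law = base_quality_law,
                 reverse_prob = reverse_prob),
            class = "sequencing_spec")
}

#' Read-depth law descriptors
#'
#' @param type One of `"lognormal"` (rounded, truncated below at `min`),
#'   `"poisson"`, `"uniform_int"`, `"fixed"`.
#' @param ... Parameters of the law (`meanlog`/`sdlog`/`min`, `lambda`,
#'   `min`/`max`, or `value`).
#' @return A depth-law descriptor.
#' @export
depth_law <- function(type = c("lognormal", "poisson", "uniform_int", "fixed"),
                      ...) {
  type <- match.arg(type)
  structure(c(list(type = type), list(...)), class = "hetmix_depth_law")
}

draw_depth <- function(law, n) {
  switch(law$type,
    lognormal = pmax(law$min %||% 1L,
                     as.integer(round(rlnorm(n, law$meanlog, law$sdlog)))),
    poisson = rpois(n, law$lambda),
    uniform_int = as.integer(law$min + floor(runif(n) * (law$max - law$min + 1L))),
    fixed = rep(as.integer(law$value), n),
    stop("unknown depth law: ", law$type))
}

# Inverse-CDF draw from normal(mu, sigma) truncated to (0, 1).
rtruncnorm01 <- function(n, mu, sigma) {
  lo <- pnorm(0, mu, sigma)
  hi <- pnorm(1, mu, sigma)
  qnorm(lo + runif(n) * (hi - lo), mu, sigma)
}

#' Draw true per-cell heteroplasmy values from a subset's spike-and-slab law
#'
#' With probability `pi_true` the cell is a spike cell (truncated-normal
#' draw near zero, or exactly 0 for a hard-zero spike); otherwise a slab
#' draw on (0,1).
#'
#' @param truth A [subset_truth()].
#' @param n Number of cells to draw.
#' @return Numeric vector of heteroplasmy values in \[0,1\].
#' @export
draw_cell_heteroplasmy <- function(truth, n = 1) {
  stopifnot(inherits(truth, "subset_truth"))
  in_spike <- runif(n) < truth$pi_true
  h <- numeric(n)
  n_sp <- sum(in_spike)
  if (n_sp > 0) {
    h[in_spike] <- if (truth$spike == "hard_zero") 0 else
      rtruncnorm01(n_sp, truth$mu_true, truth$sigma_true)
  }
  n_sl <- n - n_sp
  if (n_sl > 0) {
    h[!in_spike] <- switch(truth$slab$type,
      uniform = runif(n_sl),
      beta = rbeta(n_sl, truth$slab$shape1, truth$slab$shape2))
  }
  h
}

#' Simulate sequencing allele counts for given heteroplasmy values
#'
#' Depth is drawn from the spec's depth law (unless supplied); the variant
#' (G) read count is binomial with success probability
#' `h * (1 - e) + (1 - h) * e`, folding the per-base miscall rate `e` into
#' the observed allele fraction; the reference (A) count is the remainder.
#'
#' @param h Heteroplasmy values in \[0,1\] (one per well).
#' @param spec A [sequencing_spec()].
#' @param depth Optional fixed depths (recycled to `length(h)`).
#' @return A data.frame with columns `depth`, `ref_count`, `alt_count`.
#' @export
simulate_counts <- function(h, spec = sequencing_spec(), depth = NULL) {
  stopifnot(all(h >= 0 & h <= 1))
  n <- length(h)
  depth <- if (is.null(depth)) draw_depth(spec$depth_law, n)
           else as.integer(rep_len(depth, n))
  e <- spec$error_rate
  alt <- rbinom(n, depth, h * (1 - e) + (1 - h) * e)
  data.frame(depth = depth, ref_count = depth - alt, alt_count = alt)
}

#' Generate well barcodes with guaranteed pairwise separation
#'
#' Random DNA barcodes with pairwise Hamming distance at least `min_dist`,
#' so exact-match demultiplexing is unambiguous even with isolated miscalls.
#'
#' @param n Number of barcodes.
#' @param width Barcode length in bases.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return Character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n = 96, width = 8, min_dist = 3) {
  bases <- c("A", "C", "G", "T")
  codes <- character(0)
  mat <- matrix(character(0), nrow = width, ncol = 0)
  tries <- 0
  while (length(codes) < n) {
    tries <- tries + 1
    if (tries > 100000) stop("cannot place ", n, " barcodes at width ", width)
    cand <- sample(bases, width, replace = TRUE)
    if (ncol(mat) == 0 || all(colSums(mat != cand) >= min_dist)) {
      mat <- cbind(mat, cand)
      codes <- c(codes, paste(cand, collapse = ""))
    }
  }
  codes
}

well_ids_96 <- function() {
  paste0(rep(LETTERS[1:8], each = 12),
         sprintf("%02d", rep(1:12, times = 8)))
}

#' Lay out a synthetic cohort on 96-well sort plates with full ground truth
#'
#' Cells of each subset are sorted onto plates of their own (one sort gate
#' per plate), at most 95 cells per plate plus exactly one cell-free
#' negative-control well at a random position. Doublet wells receive two
#' independent cells and carry the sum of their depths and counts.
#' Contaminated plates give their negative control a cell-like depth and a
#' random heteroplasmy. Every planted value is recorded in the returned
#' truth table, so downstream filters have exact expected outcomes.
#'
#' @param cohort A list of [subset_truth()] objects.
#' @param spec A [sequencing_spec()].
#' @param seed Integer seed; the layout and all counts are deterministic
#'   given the seed.
#' @param max_plates Optional plate budget; exceeding it is an error.
#' @return A list with `plates` (plate map: plate_id, well_id, barcode,
#'   content) and `truth` (one row per well with all planted values and
#'   simulated counts).
#' @export
build_plates <- function(cohort, spec = sequencing_spec(), seed = NULL,
                         max_plates = NULL) {
  if (inherits(cohort, "subset_truth")) cohort <- list(cohort)
  stopifnot(all(vapply(cohort, inherits, TRUE, "subset_truth")))
  if (!is.null(seed)) set.seed(seed)

  barcodes <- generate_barcodes(96)
  wells <- well_ids_96()
  n_plates_per <- vapply(cohort, function(s) ceiling(s$n_cells / 95), 1)
  if (!is.null(max_plates) && sum(n_plates_per) > max_plates)
    stop("cohort needs ", sum(n_plates_per), " plates but max_plates = ",
         max_plates, call. = FALSE)

  plate_no <- 0
  plate_rows <- list()
  truth_rows <- list()
  for (s in cohort) {
    h_all <- draw_cell_heteroplasmy(s, s$n_cells)
    idx <- split(seq_len(s$n_cells),
                 ceiling(seq_len(s$n_cells) / 95))
    for (chunk in idx) {
      plate_no <- plate_no + 1
      pid <- sprintf("P%03d", plate_no)
      ctrl_pos <- sample(96, 1)
      cell_wells <- setdiff(seq_len(96), ctrl_pos)[seq_along(chunk)]
      contaminated <- runif(1) < spec$contaminated_plate_rate

      n_c <- length(chunk)
      doublet <- runif(n_c) < spec$doublet_rate
      low_depth <- !doublet & (runif(n_c) < spec$low_depth_rate)
      h1 <- h_all[chunk]
      h2 <- rep(NA_real_, n_c)
      if (any(doublet)) h2[doublet] <- draw_cell_heteroplasmy(s, sum(doublet))

      depth1 <- draw_depth(spec$depth_law, n_c)
      if (any(low_depth))
        depth1[low_depth] <- draw_depth(spec$low_depth_law, sum(low_depth))
      e <- spec$error_rate
      alt1 <- rbinom(n_c, depth1, h1 * (1 - e) + (1 - h1) * e)
      depth2 <- alt2 <- integer(n_c)
      if (any(doublet)) {
        nd <- sum(doublet)
        depth2[doublet] <- draw_depth(spec$depth_law, nd)
        alt2[doublet] <- rbinom(nd, depth2[doublet],
                                h2[doublet] * (1 - e) + (1 - h2[doublet]) * e)
      }
      depth <- depth1 + depth2
      alt <- alt1 + alt2

      # negative-control well
      if (contaminated) {
        c_depth <- draw_depth(spec$depth_law, 1)
        c_h <- runif(1)
        c_alt <- rbinom(1, c_depth, c_h * (1 - e) + (1 - c_h) * e)
      } else {
        c_depth <- draw_depth(spec$negative_control_depth_law, 1)
        c_h <- NA_real_
        c_alt <- rbinom(1, c_depth, e)
      }

      ord <- order(c(cell_wells, ctrl_pos))
      pr <- data.frame(plate_id = pid,
                       well_id = wells[c(cell_wells, ctrl_pos)],
                       barcode = barcodes[c(cell_wells, ctrl_pos)],
                       content = c(rep("cell", n_c), "negative_control"))[ord, ]
      tr <- data.frame(plate_id = pid,
                       well_id = wells[c(cell_wells, ctrl_pos)],
                       barcode = barcodes[c(cell_wells, ctrl_pos)],
                       subject_id = c(rep(s$subject_id, n_c), NA),
                       cell_type = c(rep(s$cell_type, n_c), NA),
                       is_control = c(rep(FALSE, n_c), TRUE),
                       plate_contaminated = contaminated,
                       doublet = c(doublet, FALSE),
                       low_depth = c(low_depth, FALSE),
                       h1 = c(h1, c_h), h2 = c(h2, NA),
                       depth = c(depth, c_depth),
                       ref_count = c(depth - alt, c_depth - c_alt),
                       alt_count = c(alt, c_alt))[ord, ]
      tr$vaf <- ifelse(tr$depth > 0, tr$alt_count / tr$depth, NA_real_)
      rownames(pr) <- rownames(tr) <- NULL
      plate_rows[[plate_no]] <- pr
      truth_rows[[plate_no]] <- tr
    }
  }
  list(plates = do.call(rbind, plate_rows),
       truth = do.call(rbind, truth_rows))
}

#' Simulate a full synthetic cohort (plates plus analysis-ready counts)
#'
#' Convenience wrapper around [build_plates()] that also returns the
#' per-well allele-count table in the layout the QC and inference stages
#' consume.
#'
#' @inheritParams build_plates
#' @return A list with `plates`, `truth` and `counts` (an allele-count
#'   table: plate_id, well_id, subject_id, cell_type, is_control,
#'   ref_count, alt_count, depth, vaf).
#' @export
simulate_cohort <- function(cohort, spec = sequencing_spec(), seed = NULL) {
  res <- build_plates(cohort, spec, seed = seed)
  cols <- c("plate_id", "well_id", "subject_id", "cell_type", "is_control",
            "ref_count", "alt_count", "depth", "vaf")
  res$counts <- res$truth[, cols]
  res
}
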