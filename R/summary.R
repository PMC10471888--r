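#' Equal-tailed credible interval from posterior draws
#'
#' Quantiles at `(1 - level)/2` and `1 - (1 - level)/2` under the
#' declared quantile convention (type 7, linear interpolation, by
#' default). A highest-posterior-density variant is available because the
#' point mass at zero can make equal-tailed intervals conservative there.
#'
#' @param draws Numeric draws (or a `hetmix_fit`, whose pi draws are
#'   used).
#' @param level Credibility level in (0,1).
#' @param method `"equal_tailed"` (default) or `"hpd"`.
#' @param quantile_type Quantile type for the equal-tailed method.
#' @return Numeric `c(low, high)`.
#' @export
credible_interval <- function(draws, level = 0.95,
                              method = c("equal_tailed", "hpd"),
                              quantile_type = 7) {
  method <- match.arg(method)
  if (inherits(draws, "hetmix_fit")) draws <- pi_draws(draws)
  if (level <= 0 || level >= 1) stop("level must lie in (0,1)")
  if (length(draws) < 100) stop("need at least 100 draws")
  if (method == "equal_tailed") {
    quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
             type = quantile_type, names = FALSE)
  } else {
    x <- sort(draws)
    n <- length(x)
    k <- max(1, floor(level * n))
    i <- which.min(x[seq_len(n - k + 1) + k - 1] - x[seq_len(n - k + 1)])
    c(x[i], x[i + k - 1])
  }
}

#' Posterior peak estimates (modes), including the point mass at zero
#'
#' Finds the modes of the posterior of the spike weight: the point mass
#' at \eqn{\pi = 0} is reported as a mode whenever the posterior no-spike
#' probability exceeds `mass_threshold`; continuous modes are local
#' maxima, above a prominence threshold, of a Gaussian kernel density
#' estimate reflected at both boundaries of \[0,1\]. Multiple modes
#' indicate a bi-/multimodal posterior.
#'
#' @param draws Numeric pi draws, or a `hetmix_fit`.
#' @param mass_threshold Minimum posterior probability of `pi = 0` for
#'   the zero mode to be reported.
#' @param bw Kernel bandwidth rule or value, as in [stats::density()].
#' @param prominence Minimum density height of a reported continuous
#'   mode, as a fraction of the global density maximum.
#' @param n_grid Evaluation grid size on \[0,1\].
#' @return An object of class `hetmix_peaks`: `modes` (sorted),
#'   `heights` (density heights; `NA` for the zero point mass),
#'   `p_zero`, `bw`.
#' @export
peak_estimates <- function(draws, mass_threshold = 0.05, bw = "nrd0",
                           prominence = 0.1, n_grid = 512) {
  p_zero <- NA_real_
  if (inherits(draws, "hetmix_fit")) {
    p_zero <- draws$p_no_spike
    draws <- pi_draws(draws)
  }
  if (length(draws) < 1000) stop("need at least 1,000 draws")
  if (is.na(p_zero)) p_zero <- mean(draws == 0)
  cont <- draws[draws > 0]

  modes <- numeric(0); heights <- numeric(0); bw_used <- NA_real_
  if (length(cont) >= 10 && stats::sd(cont) > 0) {
    # reflect at 0 and 1 to correct boundary bias, then keep [0,1]
    aug <- c(cont, -cont, 2 - cont)
    den <- density(aug, bw = bw, n = n_grid, from = 0, to = 1)
    fy <- 3 * den$y
    bw_used <- den$bw
    loc <- which(diff(sign(diff(fy))) < 0) + 1
    # boundary grid points can be modes too
    if (fy[1] > fy[2]) loc <- c(1, loc)
    if (fy[n_grid] > fy[n_grid - 1]) loc <- c(loc, n_grid)
    keep <- fy[loc] >= prominence * max(fy)
    modes <- den$x[loc[keep]]
    heights <- fy[loc[keep]]
  } else if (length(cont) > 0) {
    modes <- median(cont); heights <- NA_real_
  }
  if (p_zero > mass_threshold) {
    modes <- c(0, modes); heights <- c(NA_real_, heights)
  }
  ord <- order(modes)
  structure(list(modes = modes[ord], heights = heights[ord],
                 p_zero = p_zero, bw = bw_used), class = "hetmix_peaks")
}

#' Primary peak of a posterior
#'
#' The single best "peak estimate": the continuous mode of greatest
#' density height, or 0 when the posterior puts a majority of its mass on
#' no spike.
#'
#' @inheritParams peak_estimates
#' @return A single numeric mode.
#' @export
primary_peak <- function(draws, ...) {
  pk <- if (inherits(draws, "hetmix_peaks")) draws else peak_estimates(draws, ...)
  if (pk$p_zero > 0.5 || length(pk$modes) == 0) return(0)
  finite <- which(is.finite(pk$heights))
  if (length(finite) == 0) return(pk$modes[1])
  pk$modes[finite[which.max(pk$heights[finite])]]
}

#' @export
print.hetmix_peaks <- function(x, ...) {
  cat("Posterior peaks:", paste(sprintf("%.3f", x$modes), collapse = ", "),
      sprintf("(P(pi = 0) = %.3f)\n", x$p_zero))
  invisible(x)
}

#' Compare the spike proportions of two cell subsets
#'
#' Forms posterior draws of the difference \eqn{\pi_A - \pi_B} by pairing
#' the two groups' draw sequences in stored iteration order (chains are
#' independent, so any fixed pairing is valid; the scheme is recorded),
#' truncating to the shorter sequence. The difference is "significant"
#' when zero lies outside its equal-tailed credible interval at `level`.
#'
#' @param draws_a,draws_b Numeric pi draws or `hetmix_fit` objects.
#' @param level Credibility level.
#' @param pairing `"iteration"` (default) or `"permute"` (random
#'   re-pairing, for sensitivity analysis).
#' @param seed Seed used when `pairing = "permute"`.
#' @return An object of class `hetmix_comparison`: `ci_low`, `ci_high`,
#'   `significant`, `mean_diff`, `n_pairs`, `pairing`.
#' @export
compare_pair <- function(draws_a, draws_b, level = 0.95,
                         pairing = c("iteration", "permute"), seed = 1) {
  pairing <- match.arg(pairing)
  if (inherits(draws_a, "hetmix_fit")) draws_a <- pi_draws(draws_a)
  if (inherits(draws_b, "hetmix_fit")) draws_b <- pi_draws(draws_b)
  if (length(draws_a) < 1000 || length(draws_b) < 1000)
    stop("need at least 1,000 draws per group")
  n <- min(length(draws_a), length(draws_b))
  a <- draws_a[seq_len(n)]
  b <- draws_b[seq_len(n)]
  if (pairing == "permute") {
    set.seed(seed)
    b <- b[sample.int(n)]
  }
  d <- a - b
  ci <- quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  structure(list(ci_low = ci[1], ci_high = ci[2],
                 significant = ci[1] > 0 || ci[2] < 0,
                 mean_diff = mean(d), level = level, n_pairs = n,
                 pairing = pairing), class = "hetmix_comparison")
}

#' @export
print.hetmix_comparison <- function(x, ...) {
  cat(sprintf("Difference in pi: mean %.3f, %g%% CrI [%.3f, %.3f] -> %s\n",
              x$mean_diff, 100 * x$level, x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Ordered peak estimates with within-group pairwise comparisons
#'
#' Produces the standard report for a maturity gradient: per cell type
#' (in the declared order) the posterior peak estimates of the
#' near-zero-cell proportion, and pairwise credible-interval comparisons
#' restricted to declared cell-type groups (e.g. within the CD4 and CD8
#' compartments).
#'
#' @param fits Named list of `hetmix_fit` objects (or numeric pi-draw
#'   vectors), keyed by cell type.
#' @param order Character vector giving the maturity order of the cell
#'   types; every name in `fits` must appear.
#' @param groups Named list of character vectors defining within-group
#'   comparison sets; defaults to one group containing everything.
#' @param level Credibility level for the comparisons.
#' @param ... Passed to [peak_estimates()].
#' @return A list of class `hetmix_gradient`: `peaks` (data.frame:
#'   cell_type, primary_peak, modes, p_zero), `comparisons` (data.frame:
#'   group, type_a, type_b, mean_diff, ci_low, ci_high, significant),
#'   `n_comparisons`.
#' @export
gradient_report <- function(fits, order, groups = NULL, level = 0.95, ...) {
  if (length(fits) < 1 || is.null(names(fits))) stop("fits must be named")
  unknown <- setdiff(names(fits), order)
  if (length(unknown))
    stop("cell types not in declared order: ", paste(unknown, collapse = ", "))
  order <- order[order %in% names(fits)]
  if (is.null(groups)) groups <- list(all = order)
  for (g in groups)
    if (length(bad <- setdiff(g, names(fits))))
      stop("unknown cell type label in groups: ", paste(bad, collapse = ", "))

  pk <- lapply(fits[order], peak_estimates, ...)
  peaks <- data.frame(cell_type = order,
                      primary_peak = vapply(pk, primary_peak, 0),
                      modes = vapply(pk, function(p)
                        paste(sprintf("%.3f", p$modes), collapse = ";"), ""),
                      p_zero = vapply(pk, function(p) p$p_zero, 0))
  rownames(peaks) <- NULL

  comp <- list()
  for (gname in names(groups)) {
    g <- intersect(order, groups[[gname]])
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
      cc <- compare_pair(fits[[g[i]]], fits[[g[j]]], level = level)
      comp[[length(comp) + 1]] <-
        data.frame(group = gname, type_a = g[i], type_b = g[j],
                   mean_diff = cc$mean_diff, ci_low = cc$ci_low,
                   ci_high = cc$ci_high, significant = cc$significant)
    }
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    data.frame(group = character(0), type_a = character(0),
               type_b = character(0), mean_diff = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               significant = logical(0))
  structure(list(peaks = peaks, comparisons = comparisons,
                 n_comparisons = nrow(comparisons), level = level),
            class = "hetmix_gradient")
}

#' @export
print.hetmix_gradient <- function(x, ...) {
  cat("Peak estimates along the declared order:\n")
  print(x$peaks, row.names = FALSE)
  if (x$n_comparisons > 0) {
    cat(sprintf("\n%d pairwise comparison(s) at %g%% credibility (unadjusted):\n",
                x$n_comparisons, 100 * x$level))
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
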