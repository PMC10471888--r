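#' Simulation studies validating the mixture inference pipeline
#'
#' These functions run the package's standard self-validation studies on
#' synthetic cohorts with known ground truth: sampler-versus-quadrature
#' agreement, parameter recovery and credible-interval coverage at the
#' typical subset size of 91 cells, calibration of the pairwise
#' significance rule under null and separated spike weights, and
#' end-to-end recovery of a planted maturity gradient. Every study is
#' deterministic given `seed`.
#'
#' @param seed Master seed; all dataset and chain seeds derive from it.
#' @param spike_mu,spike_sigma Ground-truth spike parameters used by the
#'   generators.
#' @name validation-studies
NULL

truth_for <- function(pi_true, n_cells, spike_mu, spike_sigma) {
  subset_truth("V", "cells", n_cells, pi_true = pi_true,
               mu_true = spike_mu, sigma_true = spike_sigma)
}

#' @describeIn validation-studies Compare MCMC posteriors with the
#'   deterministic quadrature oracle on small datasets. Returns one row
#'   per dataset: absolute differences in the posterior mean of pi and in
#'   P(no spike), and the largest CDF discrepancy over the deciles of pi.
#' @param datasets data.frame with columns `n` and `pi_true`, one row per
#'   dataset.
#' @export
validate_oracle_equivalence <- function(seed = 1,
                                        datasets = data.frame(
                                          n = c(10, 30, 90, 30, 90),
                                          pi_true = c(0.5, 0.5, 0.2, 0.8, 0.5)),
                                        spike_mu = 0.02, spike_sigma = 0.05) {
  deciles <- seq(0.1, 0.9, by = 0.1)
  out <- lapply(seq_len(nrow(datasets)), function(k) {
    set.seed(derive_seed(seed, 10 + k))
    tr <- truth_for(datasets$pi_true[k], datasets$n[k], spike_mu, spike_sigma)
    y <- draw_cell_heteroplasmy(tr, datasets$n[k])
    fit <- fit_mcmc(y, seed = derive_seed(seed, 40 + k))
    orc <- grid_posterior(y)
    p <- pi_draws(fit)
    cdf_gap <- max(abs(vapply(deciles, function(q) mean(p <= q), 0) -
                         orc$cdf_pi(deciles)))
    data.frame(n = datasets$n[k], pi_true = datasets$pi_true[k],
               e_pi_mcmc = mean(p), e_pi_oracle = orc$e_pi,
               d_e_pi = abs(mean(p) - orc$e_pi),
               d_p_no_spike = abs(fit$p_no_spike - orc$p_no_spike),
               max_cdf_gap = cdf_gap)
  })
  do.call(rbind, out)
}

#' @describeIn validation-studies Parameter recovery at n = 91 cells:
#'   datasets with true pi cycling through `pi_values`; reports 95%
#'   credible-interval coverage of the truth and the RMSE of the
#'   posterior mean.
#' @param n_datasets Number of datasets.
#' @param n_cells Cells per dataset.
#' @param pi_values True spike weights, recycled across datasets.
#' @export
validate_recovery <- function(seed = 1, n_datasets = 20, n_cells = 91,
                              pi_values = c(0, 0.2, 0.5, 0.8),
                              spike_mu = 0.02, spike_sigma = 0.05) {
  pis <- rep_len(pi_values, n_datasets)
  rows <- lapply(seq_len(n_datasets), function(k) {
    set.seed(derive_seed(seed, 100 + k))
    y <- draw_cell_heteroplasmy(truth_for(pis[k], n_cells, spike_mu,
                                          spike_sigma), n_cells)
    fit <- fit_mcmc(y, seed = derive_seed(seed, 150 + k))
    ci <- credible_interval(fit, 0.95)
    data.frame(pi_true = pis[k], e_pi = mean(pi_draws(fit)),
               ci_low = ci[1], ci_high = ci[2],
               covered = pis[k] >= ci[1] & pis[k] <= ci[2])
  })
  tab <- do.call(rbind, rows)
  list(table = tab, n_covered = sum(tab$covered),
       coverage = mean(tab$covered),
       rmse = sqrt(mean((tab$e_pi - tab$pi_true)^2)))
}

compare_one_pair <- function(seed, k, offset, pi_a, pi_b, n_cells,
                             spike_mu, spike_sigma) {
  set.seed(derive_seed(seed, offset + 2 * k))
  ya <- draw_cell_heteroplasmy(truth_for(pi_a, n_cells, spike_mu,
                                         spike_sigma), n_cells)
  set.seed(derive_seed(seed, offset + 2 * k + 1))
  yb <- draw_cell_heteroplasmy(truth_for(pi_b, n_cells, spike_mu,
                                         spike_sigma), n_cells)
  fa <- fit_mcmc(ya, seed = derive_seed(seed, offset + 1000 + 2 * k))
  fb <- fit_mcmc(yb, seed = derive_seed(seed, offset + 1000 + 2 * k + 1))
  compare_pair(fa, fb)$significant
}

#' @describeIn validation-studies Calibration of the credible-interval
#'   significance rule: pairs of independent cohorts with identical
#'   (`pi_null`) or well-separated (`pi_sep`) spike weights; reports how
#'   often each is declared significant.
#' @param n_pairs Pairs per condition.
#' @param pi_null Common spike weight of the null pairs.
#' @param pi_sep Two spike weights of the separated pairs.
#' @export
validate_calibration <- function(seed = 1, n_pairs = 20, n_cells = 91,
                                 pi_null = 0.4, pi_sep = c(0.1, 0.6),
                                 spike_mu = 0.02, spike_sigma = 0.05) {
  null_sig <- vapply(seq_len(n_pairs), function(k)
    compare_one_pair(seed, k, 200, pi_null, pi_null, n_cells,
                     spike_mu, spike_sigma), TRUE)
  sep_sig <- vapply(seq_len(n_pairs), function(k)
    compare_one_pair(seed, k, 400, pi_sep[1], pi_sep[2], n_cells,
                     spike_mu, spike_sigma), TRUE)
  list(n_pairs = n_pairs,
       null_significant = sum(null_sig),
       separated_significant = sum(sep_sig))
}

#' @describeIn validation-studies End-to-end gradient recovery: per
#'   subject, three cell types with the spike weight increasing along the
#'   maturity order (`pi_gradient`); reports how many subjects reproduce
#'   the planted ordering of primary peak estimates and how the
#'   within-group significance bars fall relative to the planted
#'   differences.
#' @param n_subjects Number of synthetic subjects.
#' @param pi_gradient Named true spike weights along the maturity order.
#' @export
validate_gradient <- function(seed = 1, n_subjects = 10, n_cells = 91,
                              pi_gradient = c(naive = 0.10, CM = 0.45,
                                              EM = 0.80),
                              spike_mu = 0.02, spike_sigma = 0.05) {
  order <- names(pi_gradient)
  rows <- lapply(seq_len(n_subjects), function(s) {
    fits <- list()
    for (j in seq_along(pi_gradient)) {
      set.seed(derive_seed(seed, 600 + 10 * s + j))
      y <- draw_cell_heteroplasmy(truth_for(pi_gradient[j], n_cells,
                                            spike_mu, spike_sigma), n_cells)
      fits[[order[j]]] <- fit_mcmc(y, seed = derive_seed(seed,
                                                         800 + 10 * s + j))
    }
    rep_s <- gradient_report(fits, order = order,
                             groups = list(T = order))
    peaks <- rep_s$peaks$primary_peak
    comp <- rep_s$comparisons
    comp$planted_diff <- abs(pi_gradient[comp$type_a] -
                               pi_gradient[comp$type_b])
    data.frame(subject = s,
               ordering_recovered = all(diff(peaks) > 0),
               n_significant = sum(comp$significant),
               bars_only_large = !any(comp$significant &
                                        comp$planted_diff < 0.3),
               extreme_pair_significant =
                 comp$significant[comp$planted_diff ==
                                    max(comp$planted_diff)][1])
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       n_ordering_recovered = sum(tab$ordering_recovered),
       all_bars_across_large_diffs = all(tab$bars_only_large),
       n_extreme_pair_significant = sum(tab$extreme_pair_significant))
}
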