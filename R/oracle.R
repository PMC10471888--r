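#' Deterministic quadrature posterior for the spike-and-slab mixture
#'
#' Independent validation oracle for [fit_mcmc()] on small datasets: dense
#' midpoint quadrature over \eqn{(\pi, \mu, \sigma)} with prior-quantile
#' grids (so every node carries equal prior weight), computing
#' \deqn{P(s=0 \mid Y) = \tfrac12 \cdot 1 \big/ \big[\tfrac12 +
#'   \tfrac12\,\bar L\big],}
#' where \eqn{\bar L} is the prior-averaged marginal (allocation-summed)
#' likelihood and the slab-only likelihood is identically 1, together with
#' the continuous part of the posterior of \eqn{\pi} and the marginals of
#' \eqn{\mu} and \eqn{\sigma} given a spike. Everything is deterministic.
#'
#' @param y Heteroplasmy values in (0,1) (use `depth` to offset exact 0/1
#'   as in [fit_mcmc()]).
#' @param spec A [mixture_model_spec()].
#' @param n_pi,n_mu,n_sigma Grid resolutions (guideline: `length(y)` up to
#'   ~200 and grids up to ~200 each).
#' @param depth Optional per-cell read depths for boundary offsetting.
#' @param check_refinement If `TRUE`, recompute at doubled resolution and
#'   error if \eqn{P(s=0 \mid Y)} moves by more than `refine_tol`.
#' @param refine_tol Tolerance for the refinement self-check.
#' @return An object of class `hetmix_oracle`: `p_no_spike`, `e_pi`
#'   (posterior mean of pi including the point mass), `e_pi_spike`
#'   (mean given a spike), `pi_grid`/`pi_weight` (normalised continuous
#'   weights summing to 1), `cdf_pi` (function), `mu_grid`/`mu_weight`,
#'   `sigma_grid`/`sigma_weight`.
#' @export
grid_posterior <- function(y, spec = mixture_model_spec(), n_pi = 101,
                           n_mu = 61, n_sigma = 61, depth = NULL,
                           check_refinement = FALSE, refine_tol = 1e-4) {
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop("y must be finite and in [0,1]")
  y <- nudge_boundaries(y, depth)$y

  res <- grid_posterior_core(y, spec, n_pi, n_mu, n_sigma)
  if (check_refinement) {
    res2 <- grid_posterior_core(y, spec, 2 * n_pi, 2 * n_mu, 2 * n_sigma)
    if (abs(res2$p_no_spike - res$p_no_spike) > refine_tol)
      stop(sprintf(
        "grid too coarse: P(s=0) moved by %.2e on refinement (tol %.1e)",
        abs(res2$p_no_spike - res$p_no_spike), refine_tol))
  }
  res
}

grid_posterior_core <- function(y, spec, n_pi, n_mu, n_sigma) {
  # equal-prior-weight midpoint grids
  pi_grid <- (seq_len(n_pi) - 0.5) / n_pi
  mu_grid <- spec$mu_max * (seq_len(n_mu) - 0.5) / n_mu
  sigma_grid <- stats::qexp((seq_len(n_sigma) - 0.5) / n_sigma,
                            rate = spec$sigma_rate)
  pair_mu <- rep(mu_grid, times = n_sigma)
  pair_sigma <- rep(sigma_grid, each = n_mu)

  if (length(y) == 0) {
    ll <- matrix(0, n_pi, n_mu * n_sigma)
  } else {
    ll <- grid_loglik_cpp(as.numeric(y), pi_grid, pair_mu, pair_sigma)
  }
  M <- max(ll)
  el <- exp(ll - M)                     # n_pi x (n_mu*n_sigma)
  lbar_log <- M + log(mean(el))         # log prior-mean likelihood
  # P(s=0|Y) = 0.5 / (0.5 + 0.5 * Lbar), computed stably in logs
  p_s0 <- 1 / (1 + exp(lbar_log))

  w_pi <- rowMeans(el); w_pi <- w_pi / sum(w_pi)
  w_pair <- colMeans(el); w_pair <- w_pair / sum(w_pair)
  w_pair_m <- matrix(w_pair, n_mu, n_sigma)   # (mu, sigma) layout
  w_mu <- rowSums(w_pair_m)
  w_sigma <- colSums(w_pair_m)

  e_pi_spike <- sum(pi_grid * w_pi)
  e_pi <- (1 - p_s0) * e_pi_spike
  cdf_pi <- function(q) {
    p_s0 + (1 - p_s0) * vapply(q, function(qq) sum(w_pi[pi_grid <= qq]), 0)
  }
  structure(list(p_no_spike = p_s0, e_pi = e_pi, e_pi_spike = e_pi_spike,
                 pi_grid = pi_grid, pi_weight = w_pi, cdf_pi = cdf_pi,
                 mu_grid = mu_grid, mu_weight = as.numeric(w_mu),
                 sigma_grid = sigma_grid, sigma_weight = as.numeric(w_sigma),
                 n_pi = n_pi, n_mu = n_mu, n_sigma = n_sigma),
            class = "hetmix_oracle")
}

#' @export
print.hetmix_oracle <- function(x, ...) {
  cat(sprintf("Quadrature posterior (grid %d x %d x %d):\n",
              x$n_pi, x$n_mu, x$n_sigma))
  cat(sprintf("  P(no spike | Y) = %.4f   E[pi | Y] = %.4f\n",
              x$p_no_spike, x$e_pi))
  invisible(x)
}
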