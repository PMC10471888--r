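#' Spike-and-slab mixture model specification
#'
#' The per-cell heteroplasmy model for one cell subset:
#' \deqn{Y \sim \pi\,N_{01}(\mu, \sigma^2) + (1-\pi)\,U(0,1), \qquad
#'       \pi \sim \pi_0\,\delta_0 + (1-\pi_0)\,U(0,1),}
#' where \eqn{N_{01}} is a normal truncated to (0,1) (the near-zero
#' "spike"), the slab is uniform, and \eqn{\delta_0} is a point mass at
#' \eqn{\pi = 0} so that \eqn{\pi_0} is the probability of no spike.
#' Priors: \eqn{\mu \sim U(0, 0.2)}, \eqn{\sigma \sim Exp(5)},
#' \eqn{\pi_0 \sim U(0,1)}. The uniform \eqn{\pi_0} prior is integrated
#' out analytically, giving prior spike probability 1/2.
#'
#' @param mu_max Upper bound of the uniform prior on the spike mean.
#' @param sigma_rate Rate of the exponential prior on the spike sd.
#' @return An object of class `mixture_model_spec`.
#' @export
mixture_model_spec <- function(mu_max = 0.2, sigma_rate = 5) {
  stopifnot(mu_max > 0, mu_max <= 1, sigma_rate > 0)
  structure(list(mu_max = mu_max, sigma_rate = sigma_rate),
            class = "mixture_model_spec")
}

#' Density of the truncated-normal spike component
#'
#' \eqn{f(y) = \phi((y-\mu)/\sigma) / (\sigma [\Phi((1-\mu)/\sigma) -
#' \Phi(-\mu/\sigma)])} for \eqn{y \in (0,1)}, 0 outside.
#'
#' @param y Evaluation points.
#' @param mu,sigma Spike mean and sd (`sigma > 0`).
#' @param log Return log density?
#' @return Numeric vector of (log) densities.
#' @export
spike_density <- function(y, mu, sigma, log = FALSE) {
  if (sigma <= 0) stop("sigma must be > 0")
  ld <- spike_logdens_cpp(as.numeric(y), mu, sigma)
  if (log) ld else exp(ld)
}

#' Marginal (allocation-summed) log likelihood of the mixture
#'
#' \eqn{\sum_i \log[\pi f(y_i; \mu, \sigma) + (1-\pi)]}; the slab density
#' is 1 on (0,1). Identical, by summation over the latent per-cell
#' allocation, to the complete-data likelihood with allocations summed
#' out.
#'
#' @param y Heteroplasmy values, all in (0,1).
#' @param pi Spike weight in \[0,1\].
#' @inheritParams spike_density
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(y, pi, mu, sigma) {
  if (pi < 0 || pi > 1) stop("pi must lie in [0,1]")
  if (sigma <= 0) stop("sigma must be > 0")
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly in (0,1)")
  # per-cell logsumexp of {log pi + log f(y), log(1 - pi)}: stable when the
  # spike density underflows or pi sits at a boundary
  lsp <- log(pi) + spike_logdens_cpp(as.numeric(y), mu, sigma)
  lsl <- rep(log(1 - pi), length(y))
  m <- pmax(lsp, lsl)
  sum(ifelse(is.infinite(m) & m < 0, -Inf,
             m + log(exp(lsp - m) + exp(lsl - m))))
}

# Map boundary VAFs into the open interval by half a read:
# 0 -> 1/(2 depth), 1 -> 1 - 1/(2 depth). Both mixture components have
# support (0,1), so exact 0/1 (possible from finite counts) must be nudged.
nudge_boundaries <- function(y, depth = NULL) {
  at_b <- y <= 0 | y >= 1
  if (!any(at_b)) return(list(y = y, n_nudged = 0L))
  if (is.null(depth))
    stop("boundary VAF values (0 or 1) present: supply per-cell read depths ",
         "so they can be offset by 1/(2*depth)")
  depth <- rep_len(depth, length(y))
  eps <- 1 / (2 * depth)
  y[y <= 0] <- eps[y <= 0]
  y[y >= 1] <- 1 - eps[y >= 1]
  list(y = y, n_nudged = sum(at_b))
}

#' Fit the spike-and-slab mixture by trans-model MCMC
#'
#' A purpose-built Gibbs/Metropolis sampler targeting the exact posterior,
#' including the point mass at \eqn{\pi = 0}. Each sweep performs (i) a
#' trans-model birth/death move between the no-spike and spike states
#' whose acceptance ratio uses the marginal (allocation-summed)
#' likelihood, with parameters proposed from their priors; (ii) latent
#' allocation updates \eqn{z_i \mid \pi, \mu, \sigma}; (iii) a conjugate
#' draw \eqn{\pi \mid z \sim Beta(n_{spike}+1, n_{slab}+1)}; (iv)
#' Metropolis updates of \eqn{\mu} (random walk reflected at \[0, 0.2\])
#' and \eqn{\sigma} (random walk on the log scale). Multiple chains are
#' run from independent prior draws and screened with a split-chain
#' potential-scale-reduction diagnostic on \eqn{\pi}.
#'
#' @param y Per-cell heteroplasmy values in \[0,1\] (proportions, not
#'   percent). Exact 0/1 values are offset into the open interval by
#'   `1/(2 * depth)`.
#' @param spec A [mixture_model_spec()].
#' @param n_iter,burn_in,thin Iterations per chain, burn-in discarded,
#'   thinning interval.
#' @param n_chains Number of independent chains.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param depth Optional per-cell read depths (required if `y` touches 0
#'   or 1).
#' @param mu_prop_sd,log_sigma_prop_sd Metropolis proposal scales.
#' @return An object of class `hetmix_fit`: `draws` (data.frame with
#'   columns chain, s, pi, mu, sigma), `p_no_spike` (posterior
#'   \eqn{P(s=0\mid Y)} estimate), acceptance rates, `rhat_pi`, and the
#'   call parameters.
#' @export
fit_mcmc <- function(y, spec = mixture_model_spec(), n_iter = 30000,
                     burn_in = 10000, thin = 4, n_chains = 4, seed = 1,
                     depth = NULL, mu_prop_sd = 0.02,
                     log_sigma_prop_sd = 0.4) {
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop("y must be finite and in [0,1]")
  stopifnot(n_iter > burn_in, thin >= 1, n_chains >= 1)
  nb <- nudge_boundaries(y, depth)
  y <- nb$y

  chains <- vector("list", n_chains)
  acc <- matrix(NA_real_, n_chains, 3,
                dimnames = list(NULL, c("mu", "sigma", "trans")))
  for (ch in seq_len(n_chains)) {
    set.seed(derive_seed(seed, ch))
    r <- mixture_mcmc_cpp(y, as.integer(n_iter), as.integer(burn_in),
                          as.integer(thin), spec$mu_max, spec$sigma_rate,
                          mu_prop_sd, log_sigma_prop_sd)
    chains[[ch]] <- data.frame(chain = ch, s = r$s, pi = r$pi, mu = r$mu,
                               sigma = r$sigma)
    acc[ch, ] <- c(r$accept_mu, r$accept_sigma, r$accept_trans)
  }
  draws <- do.call(rbind, chains)

  rhat <- split_rhat(matrix(draws$pi, ncol = n_chains))
  if (is.finite(rhat) && rhat > 1.05)
    warning(sprintf("split-chain R-hat on pi is %.3f (> 1.05): ", rhat),
            "chains may not have converged", call. = FALSE)

  structure(list(draws = draws, p_no_spike = mean(draws$s == 0),
                 acceptance = colMeans(acc), rhat_pi = rhat,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, seed = seed, n_cells = length(y),
                 n_boundary_nudged = nb$n_nudged, spec = spec),
            class = "hetmix_fit")
}

# Split-chain potential scale reduction factor (each chain halved).
split_rhat <- function(mat) {
  halves <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    n <- nrow(mat) %/% 2
    cbind(mat[seq_len(n), j], mat[n + seq_len(n), j])
  }))
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Extract posterior draws of the spike weight
#'
#' @param fit A `hetmix_fit`.
#' @return Numeric vector of pi draws (pooled over chains, in stored
#'   order).
#' @export
pi_draws <- function(fit) {
  stopifnot(inherits(fit, "hetmix_fit"))
  fit$draws$pi
}

#' @export
print.hetmix_fit <- function(x, ...) {
  cat(sprintf("Spike-and-slab mixture fit: %d cells, %d chains x %d draws\n",
              x$n_cells, x$n_chains, nrow(x$draws) / x$n_chains))
  cat(sprintf("  E[pi | Y] = %.3f   P(no spike | Y) = %.3f   R-hat(pi) = %.3f\n",
              mean(x$draws$pi), x$p_no_spike, x$rhat_pi))
  ci <- quantile(x$draws$pi, c(0.025, 0.975), names = FALSE)
  cat(sprintf("  95%% CrI for pi: [%.3f, %.3f]\n", ci[1], ci[2]))
  invisible(x)
}
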