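test_that("spike density is a proper density on (0,1)", {
  # normalisation for a grid of (mu, sigma)
  for (mu in c(0.02, 0.1)) for (sigma in c(0.01, 0.2)) {
    z <- integrate(spike_density, 0, 1, mu = mu, sigma = sigma,
                   rel.tol = 1e-10)$value
    expect_lt(abs(z - 1), 1e-8)
  }
  # huge sigma: flat over the interval
  f <- spike_density(seq(0.01, 0.99, by = 0.01), 0.5, 1e6)
  expect_lt(max(abs(f - 1)), 1e-3)
  # zero outside the support
  expect_equal(spike_density(c(-0.1, 0, 1, 1.1), 0.1, 0.05), rep(0, 4))
  expect_error(spike_density(0.5, 0.1, 0), "sigma")
})

test_that("spike density matches direct quadrature of the restricted normal", {
  mu <- 0.05; sigma <- 0.1; y <- 0.02
  z <- integrate(function(x) dnorm(x, mu, sigma), 0, 1, rel.tol = 1e-12)$value
  expect_equal(spike_density(y, mu, sigma), dnorm(y, mu, sigma) / z,
               tolerance = 1e-10)
})

test_that("marginal log likelihood reduces correctly at the extremes", {
  set.seed(41)
  y <- runif(20)
  expect_equal(log_likelihood(y, 0, 0.1, 0.05), 0)   # slab density is 1
  y_far <- rep(0.9, 5)
  expect_equal(log_likelihood(y_far, 1, 0.02, 0.01),
               sum(spike_density(y_far, 0.02, 0.01, log = TRUE)))
  expect_error(log_likelihood(c(0.5, 1.2), 0.5, 0.1, 0.05), "\\(0,1\\)")
})

test_that("allocation-summed likelihood equals its two-term logsumexp form", {
  set.seed(42)
  for (rep in 1:20) {
    y <- runif(15)
    pi <- runif(1); mu <- runif(1, 0, 0.2); sigma <- rexp(1, 5)
    direct <- log_likelihood(y, pi, mu, sigma)
    lsp <- log(pi) + spike_density(y, mu, sigma, log = TRUE)
    lsl <- rep(log(1 - pi), length(y))
    m <- pmax(lsp, lsl)
    summed <- sum(m + log(exp(lsp - m) + exp(lsl - m)))
    expect_equal(direct, summed, tolerance = 1e-12)
  }
})

test_that("with no data the sampler reproduces the prior", {
  fit <- fit_mcmc(numeric(0), seed = 43, n_chains = 2)
  d <- fit$draws
  # prior spike probability is 1/2 after integrating out pi0
  expect_lt(abs(fit$p_no_spike - 0.5), 0.02)
  # mu ~ U(0, 0.2): mean 0.1, range inside [0, 0.2]
  expect_lt(abs(mean(d$mu) - 0.1), 0.005)
  expect_true(all(d$mu >= 0 & d$mu <= 0.2))
  # pi | s = 1 uniform on (0,1)
  ks <- suppressWarnings(ks.test(d$pi[d$s == 1], "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  # sigma ~ Exp(5)
  expect_lt(abs(mean(d$sigma) - 0.2), 0.01)
})

test_that("the point mass is exact: s = 0 if and only if pi = 0", {
  set.seed(44)
  y <- runif(30)
  fit <- fit_mcmc(y, seed = 45, n_chains = 2)
  expect_true(all((fit$draws$s == 0) == (fit$draws$pi == 0)))
  expect_gt(sum(fit$draws$s == 0), 0)
  expect_gt(sum(fit$draws$s == 1), 0)
})

test_that("quadrature posterior is exact with no data and stable under
          refinement", {
  orc <- grid_posterior(numeric(0))
  expect_equal(orc$p_no_spike, 0.5)
  expect_equal(orc$e_pi, 0.25, tolerance = 1e-6)  # (1/2) * E[U(0,1)]

  set.seed(46)
  tr <- subset_truth("S", "x", 30, pi_true = 0.5)
  y <- draw_cell_heteroplasmy(tr, 30)
  expect_no_error(grid_posterior(y, n_pi = 51, n_mu = 31, n_sigma = 31,
                                 check_refinement = TRUE, refine_tol = 1e-3))
})

test_that("quadrature posterior agrees with a brute-force MC integrator", {
  set.seed(47)
  tr <- subset_truth("S", "x", 20, pi_true = 0.5)
  y <- draw_cell_heteroplasmy(tr, 20)
  orc <- grid_posterior(y)
  mc <- mc_posterior(y, n_draws = 4e5, seed = 48)
  expect_lt(abs(orc$p_no_spike - mc$p_s0), 3 * mc$se_p_s0 + 1e-4)
  expect_lt(abs(orc$e_pi_spike - mc$e_pi_spike),
            3 * mc$se_e_pi_spike + 1e-4)
})

test_that("MCMC matches the quadrature oracle on a spiked dataset", {
  set.seed(49)
  tr <- subset_truth("S", "x", 30, pi_true = 0.5, mu_true = 0.02,
                     sigma_true = 0.05)
  y <- draw_cell_heteroplasmy(tr, 30)
  fit <- fit_mcmc(y, seed = 50)
  orc <- grid_posterior(y)
  expect_lt(abs(mean(pi_draws(fit)) - orc$e_pi), 0.02)
  expect_lt(abs(fit$p_no_spike - orc$p_no_spike), 0.03)
})

test_that("slab-only data concentrates pi near zero, as the oracle says", {
  set.seed(51)
  y <- runif(50, 0.3, 0.9)
  fit <- fit_mcmc(y, seed = 52)
  orc <- grid_posterior(y)
  expect_lt(abs(mean(pi_draws(fit) < 0.2) - orc$cdf_pi(0.2)), 0.03)
  expect_gt(mean(pi_draws(fit) < 0.2), 0.8)
})

test_that("adding a cell below the spike mean raises the posterior mean of pi", {
  for (seed in 53:55) {
    set.seed(seed)
    tr <- subset_truth("S", "x", 12, pi_true = 0.5)
    y <- draw_cell_heteroplasmy(tr, 12)
    base <- grid_posterior(y, n_mu = 41, n_sigma = 41)
    more <- grid_posterior(c(y, 0.005), n_mu = 41, n_sigma = 41)
    expect_gte(more$e_pi, base$e_pi)
  }
})

test_that("boundary VAFs are offset by half a read before fitting", {
  y <- c(0, 0.4, 1)
  expect_error(fit_mcmc(y, seed = 56), "depth")
  fit <- fit_mcmc(y, seed = 56, depth = c(100, 100, 50), n_iter = 2000,
                  burn_in = 500, n_chains = 1)
  expect_equal(fit$n_boundary_nudged, 2L)
  expect_error(fit_mcmc(c(0.5, NA), seed = 57), "finite")
  expect_error(fit_mcmc(c(0.5, 1.4), seed = 57), "finite|\\[0,1\\]")
})
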