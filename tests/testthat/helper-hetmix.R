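# Shared helpers: independent oracles and small fixtures built in code.

# Truncated-normal CDF on (0,1) by numerical integration (independent of the
# package's closed-form spike density).
truncnorm01_cdf_quad <- function(q, mu, sigma) {
  z <- integrate(function(x) dnorm(x, mu, sigma), 0, 1)$value
  integrate(function(x) dnorm(x, mu, sigma), 0, q)$value / z
}

# Brute-force Monte-Carlo posterior integrator: importance weights from
# prior draws of (pi, mu, sigma). Returns estimates and rough standard
# errors (delta method on the weighted means).
mc_posterior <- function(y, n_draws = 2e5, mu_max = 0.2, sigma_rate = 5,
                         seed = 1) {
  set.seed(seed)
  pi_s <- runif(n_draws)
  mu_s <- runif(n_draws, 0, mu_max)
  sig_s <- rexp(n_draws, sigma_rate)
  zc <- pnorm(1, mu_s, sig_s) - pnorm(0, mu_s, sig_s)
  ll <- 0
  for (yi in y) ll <- ll + log(pi_s * dnorm(yi, mu_s, sig_s) / zc + (1 - pi_s))
  w <- exp(ll - max(ll))
  lbar <- mean(w) * exp(max(ll))
  p_s0 <- 0.5 / (0.5 + 0.5 * lbar)
  e_pi_spike <- sum(pi_s * w) / sum(w)
  # SEs: lbar via iid mean; e_pi_spike via ratio-estimator linearisation
  se_lbar <- sd(w) / sqrt(n_draws) * exp(max(ll))
  se_p_s0 <- 0.5 * se_lbar / (0.5 + 0.5 * lbar)^2
  infl <- w * (pi_s - e_pi_spike) / mean(w)
  se_e_pi_spike <- sd(infl) / sqrt(n_draws)
  list(p_s0 = p_s0, e_pi = (1 - p_s0) * e_pi_spike,
       e_pi_spike = e_pi_spike, se_p_s0 = se_p_s0,
       se_e_pi_spike = se_e_pi_spike)
}

# Draw from an oracle posterior of pi (point mass at 0 plus gridded
# continuous part), for forming difference intervals.
sample_oracle_pi <- function(orc, m = 20000) {
  s0 <- runif(m) < orc$p_no_spike
  x <- numeric(m)
  if (any(!s0)) {
    idx <- sample.int(length(orc$pi_grid), sum(!s0), replace = TRUE,
                      prob = orc$pi_weight)
    x[!s0] <- orc$pi_grid[idx]
  }
  x
}

# A fixed 41-base amplicon template with the reference A at 0-based
# offset 20.
test_template <- function() {
  set.seed(424242)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
                collapse = "")
  substr(tmpl, 21, 21) <- "A"
  tmpl
}

# One truth row shaped like build_plates() output, for emit_fastq tests.
manual_truth_row <- function(plate_id = "P001", well_id = "A01",
                             barcode = "ACGTACGT", ref = 0L, alt = 0L) {
  data.frame(plate_id = plate_id, well_id = well_id, barcode = barcode,
             subject_id = "S1", cell_type = "naive", is_control = FALSE,
             plate_contaminated = FALSE, doublet = FALSE, low_depth = FALSE,
             h1 = NA_real_, h2 = NA_real_, depth = ref + alt,
             ref_count = ref, alt_count = alt,
             vaf = if (ref + alt > 0) alt / (ref + alt) else NA_real_)
}
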