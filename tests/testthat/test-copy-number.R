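test_that("a perfect-efficiency dilution series is recovered exactly", {
  copies <- 10^(6:1)               # six 10-fold dilutions
  ct <- 40 - log2(10) * log10(copies)   # Ct drops log2(10) per decade
  curve <- fit_standard_curve(copies, ct)
  expect_equal(curve$slope, -log2(10), tolerance = 1e-6)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_true(curve$qc_pass)
})

test_that("flat or out-of-range curves raise the QC flag", {
  copies <- 10^(6:1)
  flat <- fit_standard_curve(copies, rep(25, 6))
  expect_false(flat$qc_pass)
  expect_match(flat$qc_reason, "slope")
  steep <- fit_standard_curve(copies, 40 - 4 * log10(copies))
  expect_false(steep$qc_pass)
  expect_error(fit_standard_curve(c(10, 100), c(30, 27)), "3 dilution")
  expect_error(fit_standard_curve(c(0, 10, 100), c(33, 30, 27)), "> 0")
})

test_that("noisy curve matches the closed-form least-squares solution", {
  set.seed(71)
  copies <- 10^(6:1)
  x <- log10(copies)
  ct <- 38 - 3.35 * x + rnorm(6, 0, 0.1)
  curve <- fit_standard_curve(copies, ct, slope_range = c(-4, -3))
  slope_hat <- sum((x - mean(x)) * (ct - mean(ct))) / sum((x - mean(x))^2)
  intercept_hat <- mean(ct) - slope_hat * mean(x)
  expect_equal(curve$slope, slope_hat, tolerance = 1e-10)
  expect_equal(curve$intercept, intercept_hat, tolerance = 1e-10)
})

test_that("quantification inverts the curve", {
  copies <- 10^(6:1)
  curve <- fit_standard_curve(copies, 40 - log2(10) * log10(copies))
  # one copy in the reaction at Ct = intercept
  expect_equal(quantify(curve$intercept, curve, n_cells = 1,
                        volume_factor = 1), 1, tolerance = 1e-9)
  expect_equal(quantify(curve$intercept + curve$slope, curve, 1, 1), 10,
               tolerance = 1e-9)
  expect_error(quantify(25, curve, 0), "n_cells")
})

test_that("noise-free plates round-trip planted copy numbers", {
  copies <- 10^(6:1)
  curve <- fit_standard_curve(copies, 40 - log2(10) * log10(copies))
  planted <- c(120, 530, 2100)
  n_cells <- c(100, 250, 500)
  vf <- 1 / 25
  ct <- curve$intercept + curve$slope * log10(planted * n_cells * vf)
  rec <- quantify(ct, curve, n_cells, vf)
  expect_equal(rec, planted, tolerance = 1e-9)
})

test_that("plate normalization has its identity and equivariance properties", {
  expect_equal(normalize_plate(100, 100, 150), 150)  # control maps to mean
  expect_equal(normalize_plate(200, 100, 150), 300)
  expect_equal(normalize_plate(7 * 200, 7 * 100, 150), 300)  # scale-free
  expect_error(normalize_plate(10, 0, 100), "> 0")
  # planted plate effects cancel after normalization
  true_cn <- 300
  plate_eff <- c(0.8, 1.0, 1.3)
  absolute <- true_cn * plate_eff
  control <- 150 * plate_eff
  norm <- normalize_plate(absolute, control, 150)
  expect_true(all(abs(norm - 2 * 150) < 1e-9))
})

test_that("replicate exclusions reproduce hand-evaluated flags", {
  expect_false(apply_ct_exclusions(rbind(c(25.0, 25.1, 25.2)))$excluded)
  expect_true(apply_ct_exclusions(rbind(c(31, 31, 31)))$excluded)
  out <- apply_ct_exclusions(rbind(c(25.0, 25.1, 27.5)))
  expect_true(out$outlier_dropped)
  expect_false(out$excluded)
  expect_equal(out$n_replicates_used, 2)
  expect_equal(out$mean_ct, 25.05)
})

test_that("exclusion rules match a hand-worked ten-sample fixture", {
  cts <- rbind(
    c(24.0, 24.1, 24.0),   # keep: sd 0.06
    c(29.9, 29.9, 30.0),   # keep: mean 29.93 < 30
    c(30.1, 30.0, 30.2),   # drop: mean 30.1 > 30
    c(25.0, 25.5, 26.0),   # drop: sd 0.5, no single outlier rescues it
    c(22.0, 22.1, 25.0),   # keep after dropping 25.0
    c(28.0, 28.0, 28.0),   # keep: sd 0
    c(35.0, 35.1, 35.0),   # drop: mean > 30
    c(20.0, 24.0, 28.0),   # drop: sd 4, symmetric, no outlier
    c(26.0, 26.2, 26.1),   # keep
    c(27.0, 27.1, 32.0))   # keep after dropping 32.0
  out <- apply_ct_exclusions(cts)
  expect_equal(out$excluded,
               c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                 FALSE, FALSE))
  expect_equal(out$outlier_dropped,
               c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, TRUE))
  # idempotence on the survivors (their replicates are already consistent)
  keep <- !out$excluded & !out$outlier_dropped
  again <- apply_ct_exclusions(cts[keep, , drop = FALSE])
  expect_false(any(again$excluded))
})

test_that("quantify_plate ties exclusions, curve and normalization together", {
  copies <- 10^(6:1)
  standards <- data.frame(copies = copies,
                          ct = 40 - log2(10) * log10(copies))
  curve <- fit_standard_curve(standards$copies, standards$ct)
  planted <- c(control = 150, a = 300, b = 75)
  n_cells <- c(200, 100, 400)
  ct0 <- curve$intercept + curve$slope * log10(planted * n_cells / 25)
  samples <- data.frame(sample_id = names(planted),
                        ct1 = ct0, ct2 = ct0, ct3 = ct0,
                        n_cells = n_cells,
                        is_control = c(TRUE, FALSE, FALSE))
  res <- quantify_plate(samples, standards, mean_control = 150)
  expect_equal(res$samples$copies_per_cell, unname(planted),
               tolerance = 1e-9)
  # control equals the cross-plate mean, so normalization is the identity
  expect_equal(res$samples$normalized_copies_per_cell, unname(planted),
               tolerance = 1e-9)
})
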