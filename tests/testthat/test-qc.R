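test_that("fixed and automatic lower depth thresholds behave as declared", {
  cfg <- qc_config(lower_depth_threshold = 200)
  expect_equal(lower_depth_threshold(c(150, 201, 1000), cfg), 200)
  d <- c(150, 201, 1000)
  expect_equal(d[d >= 200], c(201, 1000))

  auto <- qc_config(lower_depth_threshold = "auto", auto_floor = 200)
  # all depths above the floor: the smallest observed one is the threshold
  expect_equal(lower_depth_threshold(c(250, 300, 900), auto), 250)
  # mixed: threshold is the smallest depth clearing the floor
  expect_equal(lower_depth_threshold(c(40, 201, 1000), auto), 201)
  expect_error(lower_depth_threshold(numeric(0), auto), "empty")
})

test_that("upper-depth rule matches hand-computed quantiles", {
  # degenerate IQR: all equal depths, Q3 = d, nothing above 1.5 d
  expect_false(any(upper_depth_exclusion(rep(500, 10), qc_config())))

  # {100, 200, 300, 400, 10000}, type-7 quartiles: Q1 = 200, Q3 = 400.
  # Q3_TIMES_K cutoff 1.5 * 400 = 600; TUKEY cutoff 400 + 1.5 * 200 = 700.
  d <- c(100, 200, 300, 400, 10000)
  ex1 <- upper_depth_exclusion(d, qc_config(upper_rule_variant = "Q3_TIMES_K"))
  expect_equal(which(ex1), 5L)
  ex2 <- upper_depth_exclusion(d, qc_config(upper_rule_variant = "TUKEY_FENCE"))
  expect_equal(which(ex2), 5L)
  # a depth between the two cutoffs separates the variants
  d2 <- c(100, 200, 300, 400, 650)
  expect_true(upper_depth_exclusion(d2, qc_config())[5])
  expect_false(upper_depth_exclusion(
    d2, qc_config(upper_rule_variant = "TUKEY_FENCE"))[5])

  expect_warning(res <- upper_depth_exclusion(c(1, 2, 3), qc_config()),
                 "fewer than 4")
  expect_false(any(res))
})

test_that("negative-control screening flags only contaminated plates", {
  cfg <- qc_config(negative_control_max_depth = 10)
  controls <- data.frame(plate_id = c("P1", "P2", "P3"),
                         depth = c(0, 1000, 10))
  expect_equal(flag_contaminated_plates(controls, cfg), "P2")
  expect_error(flag_contaminated_plates(
    data.frame(plate_id = c("P1", "P1"), depth = c(0, 0)), cfg), "one negative")
})

test_that("planted low-depth wells, doublets and contaminated plates are
          excluded exactly", {
  subs <- lapply(1:6, function(i)
    subset_truth(paste0("S", i), "naive", 90, pi_true = 0.4))
  spec <- sequencing_spec(
    depth_law = depth_law("lognormal", meanlog = log(1146), sdlog = 0.05),
    doublet_rate = 0.05, low_depth_rate = 0.1,
    contaminated_plate_rate = 0.3, error_rate = 0)
  sim <- simulate_cohort(subs, spec, seed = 31)
  qc <- apply_qc(sim$counts, qc_config(lower_depth_threshold = 200))

  cells <- sim$truth[!sim$truth$is_control, ]
  planted_bad <- cells$plate_contaminated | cells$doublet | cells$low_depth
  expect_gt(sum(cells$doublet), 0)
  expect_gt(sum(cells$low_depth), 0)
  expect_gt(length(qc$excluded_plates), 0)
  key <- function(df) paste(df$plate_id, df$well_id)
  expect_setequal(key(qc$retained), key(cells)[!planted_bad])
  expect_setequal(qc$excluded_plates,
                  unique(cells$plate_id[cells$plate_contaminated]))
})

test_that("QC bookkeeping sums and the report carries the depth summary", {
  subs <- list(subset_truth("S1", "naive", 120, pi_true = 0.4))
  spec <- sequencing_spec(contaminated_plate_rate = 0, low_depth_rate = 0.05)
  sim <- simulate_cohort(subs, spec, seed = 32)
  qc <- apply_qc(sim$counts, qc_config(lower_depth_threshold = 200))
  pp <- qc$report$per_plate
  expect_equal(sum(pp$n_retained), nrow(qc$retained))
  ok <- !pp$plate_excluded
  expect_equal(pp$n_in[ok],
               pp$n_low_depth[ok] + pp$n_high_depth_excluded[ok] +
                 pp$n_retained[ok])
  s <- qc$report$depth_summary
  expect_equal(s$n, nrow(qc$retained))
  expect_equal(s$median, median(qc$retained$depth))
  expect_true(s$iqr[1] <= s$median && s$median <= s$iqr[2])
})

test_that("filters are monotone and idempotent", {
  subs <- list(subset_truth("S1", "naive", 150, pi_true = 0.4))
  spec <- sequencing_spec(
    depth_law = depth_law("lognormal", meanlog = log(1146), sdlog = 0.1),
    contaminated_plate_rate = 0, low_depth_rate = 0.1, doublet_rate = 0.05)
  sim <- simulate_cohort(subs, spec, seed = 33)

  r1 <- apply_qc(sim$counts, qc_config(lower_depth_threshold = 100))$retained
  r2 <- apply_qc(sim$counts, qc_config(lower_depth_threshold = 400))$retained
  key <- function(df) paste(df$plate_id, df$well_id)
  expect_true(all(key(r2) %in% key(r1)))   # raising the bar only removes
  expect_true(all(key(r1) %in% key(sim$counts)))

  # idempotence: re-running on the survivors (plus their controls) changes
  # nothing (fixed thresholds, already-filtered depths)
  cfg <- qc_config(lower_depth_threshold = 100)
  ctrl <- sim$counts[sim$counts$is_control &
                       sim$counts$plate_id %in% unique(r1$plate_id), ]
  again <- apply_qc(rbind(r1, ctrl), cfg)$retained
  expect_setequal(key(again), key(r1))
})
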