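test_that("reads are assigned by exact prefix in either orientation", {
  bc <- data.frame(well_id = c("A01", "A02"),
                   barcode = c("ACGTACGT", "TTTTCCCC"))
  fwd <- "ACGTACGTGGGAAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  res <- demultiplex(c(fwd, rc, "GGGGGGGGGGGGGG"), bc)
  expect_equal(res$n_assigned, 2)
  expect_equal(res$n_unassigned, 1)
  expect_equal(res$n_total, 3)
  expect_equal(res$reads$well_id, c("A01", "A01"))
  # the reverse-complement read is re-oriented to the template strand
  expect_equal(res$reads$seq[2], fwd)
  expect_true(res$reads$reverse_matched[2])
})

test_that("duplicate barcodes are a configuration error", {
  bc <- data.frame(well_id = c("A01", "A02"),
                   barcode = c("ACGTACGT", "ACGTACGT"))
  expect_error(demultiplex("ACGTACGTAAA", bc), "duplicate")
  expect_error(demultiplex("ACGT", bc[0, ]), "empty")
})

test_that("quality strings follow re-oriented reads", {
  bc <- data.frame(well_id = "A01", barcode = "ACGT")
  fwd <- "ACGTAG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  res <- demultiplex(rc, bc, quals = "IIHGFE")
  expect_equal(res$reads$seq, fwd)
  expect_equal(res$reads$qual, "EFGHII")
})

test_that("allele counting applies the per-base quality cutoff", {
  tmpl_reads <- function(base, n, qchar) {
    list(seq = rep(paste0("ACGT", base, "GG"), n),
         qual = rep(strrep(qchar, 7), n))
  }
  # 70 G + 30 A, all Q40 ('I' = Phred 40)
  r <- tmpl_reads("G", 70, "I")
  a <- tmpl_reads("A", 30, "I")
  cc <- count_alleles(c(r$seq, a$seq), c(r$qual, a$qual),
                      target_offset = 0, barcode_width = 4)
  expect_equal(cc$alt_count, 70)
  expect_equal(cc$ref_count, 30)
  expect_equal(cc$n_discarded_low_quality, 0)

  # 10 G at Q20 ('5') + 10 A at Q40: the Q20 bases are discarded
  g20 <- tmpl_reads("G", 10, "5")
  a40 <- tmpl_reads("A", 10, "I")
  cc <- count_alleles(c(g20$seq, a40$seq), c(g20$qual, a40$qual),
                      target_offset = 0, barcode_width = 4)
  expect_equal(cc$alt_count, 0)
  expect_equal(cc$ref_count, 10)
  expect_equal(cc$n_discarded_low_quality, 10)

  # non-A/G bases and short reads are discarded, not miscounted
  cc <- count_alleles(c("ACGTCGG", "ACG"), c(strrep("I", 7), "III"),
                      target_offset = 0, barcode_width = 4)
  expect_equal(cc$depth, 0)
  expect_equal(cc$n_discarded_low_quality, 2)
})

test_that("heteroplasmy is the alt fraction and is scale-free", {
  expect_equal(heteroplasmy(30, 70), 0.7)
  expect_equal(heteroplasmy(100, 0), 0)
  expect_equal(heteroplasmy(1, 2), 2 / 3)
  expect_equal(heteroplasmy(10 * 1, 10 * 2), heteroplasmy(1, 2))
  expect_error(heteroplasmy(0, 0), "zero depth")
  expect_error(heteroplasmy(-1, 2), "negative")
})

test_that("emitted reads carry the planted allele at the target offset", {
  tr <- manual_truth_row(ref = 0L, alt = 10L)
  spec <- sequencing_spec(error_rate = 0, reverse_prob = 0)
  dir <- withr::local_tempdir()
  paths <- emit_fastq(tr, test_template(), 20, spec, dir, seed = 21)
  fq <- read_fastq(paths[["P001"]])
  expect_length(fq$seq, 10)
  expect_true(all(substr(fq$seq, 8 + 21, 8 + 21) == "G"))
  expect_true(all(startsWith(fq$seq, "ACGTACGT")))
})

test_that("emit_fastq validates the template", {
  tr <- manual_truth_row(ref = 1L, alt = 1L)
  dir <- withr::local_tempdir()
  expect_error(emit_fastq(tr, "CCCCC", 2, sequencing_spec(), dir), "reference base")
  expect_error(emit_fastq(tr, "CCACC", 9, sequencing_spec(), dir), "offset")
})

test_that("read orientation is symmetric at reverse_prob = 0.5", {
  tr <- manual_truth_row(ref = 5000L, alt = 5000L)
  spec <- sequencing_spec(error_rate = 0, reverse_prob = 0.5)
  dir <- withr::local_tempdir()
  paths <- emit_fastq(tr, test_template(), 20, spec, dir, seed = 22)
  fq <- read_fastq(paths[["P001"]])
  bc <- data.frame(well_id = "A01", barcode = "ACGTACGT")
  dm <- demultiplex(fq, bc)
  expect_equal(dm$n_unassigned, 0)
  frac_rc <- mean(dm$reads$reverse_matched)
  expect_lt(abs(frac_rc - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("error-free FASTQ round trip recovers planted counts exactly", {
  subs <- list(subset_truth("S1", "naive", 40, pi_true = 0.3),
               subset_truth("S1", "EM", 40, pi_true = 0.8))
  spec <- sequencing_spec(depth_law = depth_law("uniform_int", min = 50,
                                                max = 200),
                          error_rate = 0, doublet_rate = 0.05,
                          contaminated_plate_rate = 0.5)
  sim <- simulate_cohort(subs, spec, seed = 23)
  dir <- withr::local_tempdir()
  paths <- emit_fastq(sim, test_template(), 20, spec, dir, seed = 24)
  for (pid in names(paths)) {
    bc <- sim$plates[sim$plates$plate_id == pid, c("well_id", "barcode")]
    dm <- demultiplex(read_fastq(paths[[pid]]), bc)
    expect_equal(dm$n_unassigned, 0)
    cp <- count_plate(dm, bc, 20, 8)
    tr <- sim$truth[sim$truth$plate_id == pid, ]
    m <- merge(tr, cp, by = "well_id")
    expect_equal(m$ref_count.y, m$ref_count.x)
    expect_equal(m$alt_count.y, m$alt_count.x)
    nz <- m$depth.y > 0
    expect_equal(heteroplasmy(m$ref_count.y[nz], m$alt_count.y[nz]),
                 m$vaf[nz])
  }
})

test_that("flank sequencing errors do not disturb target-base counts", {
  tr <- manual_truth_row(ref = 300L, alt = 700L)
  spec <- sequencing_spec(error_rate = 0.02, reverse_prob = 0.5)
  dir <- withr::local_tempdir()
  paths <- emit_fastq(tr, test_template(), 20, spec, dir, seed = 25)
  bc <- data.frame(well_id = "A01", barcode = "ACGTACGT")
  dm <- demultiplex(read_fastq(paths[["P001"]]), bc)
  expect_equal(dm$n_unassigned, 0)
  cc <- count_alleles(dm$reads$seq, dm$reads$qual, 20, 8)
  expect_equal(cc$alt_count, 700)
  expect_equal(cc$ref_count, 300)
})
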