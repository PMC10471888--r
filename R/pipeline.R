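#' Pipeline configuration
#'
#' Bundles every stage's settings and the master seed. All randomness in
#' [run_pipeline()] flows from `seed` through fixed per-stage
#' derivations, so a config plus a seed fully determines every output.
#'
#' The default cohort is a single-subject T-cell maturity panel (naive,
#' CM, EM; 91 cells each — the typical subset size of plate-based
#' single-cell sorts) with the spike weight increasing along the
#' gradient (0.10, 0.45, 0.80).
#'
#' @param cohort List of [subset_truth()] objects.
#' @param spec A [sequencing_spec()].
#' @param qc A [qc_config()].
#' @param model A [mixture_model_spec()].
#' @param use_fastq Route the synthetic data through FASTQ emission,
#'   demultiplexing and allele counting (`TRUE`) or feed the simulated
#'   counts directly to QC (`FALSE`, default).
#' @param template,target_offset Amplicon template and 0-based target
#'   offset (required when `use_fastq = TRUE`).
#' @param min_base_quality Per-base Phred cutoff for allele counting.
#' @param order,groups Cell-type maturity order and comparison groups for
#'   [gradient_report()].
#' @param n_iter,burn_in,thin,n_chains MCMC settings per group fit.
#' @param level Credibility level for comparisons.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, spec = sequencing_spec(),
                            qc = qc_config(), model = mixture_model_spec(),
                            use_fastq = FALSE, template = NULL,
                            target_offset = NULL, min_base_quality = 28,
                            order = c("naive", "CM", "EM", "TEMRA"),
                            groups = NULL, n_iter = 30000, burn_in = 10000,
                            thin = 4, n_chains = 4, level = 0.95, seed = 1) {
  if (is.null(cohort)) {
    pis <- c(naive = 0.10, CM = 0.45, EM = 0.80)
    cohort <- lapply(names(pis), function(ct)
      subset_truth("S1", ct, n_cells = 91, pi_true = pis[[ct]]))
  }
  if (use_fastq && (is.null(template) || is.null(target_offset)))
    stop("use_fastq = TRUE requires template and target_offset")
  structure(list(cohort = cohort, spec = spec, qc = qc, model = model,
                 use_fastq = use_fastq, template = template,
                 target_offset = target_offset,
                 min_base_quality = min_base_quality, order = order,
                 groups = groups, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, n_chains = n_chains, level = level,
                 seed = seed),
            class = "pipeline_config")
}

pipe_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a tab-separated table
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate (or ingest) -> demultiplex -> QC -> per-subset
#' mixture fits -> gradient comparisons, writing tables and a JSON
#' manifest (seeds, parameters, per-file MD5 hashes) to `out_dir`.
#' Identical config and seed produce byte-identical tables and manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param counts Optional pre-computed allele-count table (columns as in
#'   [simulate_cohort()]'s `counts`); skips the simulation/demux stages.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list: `counts`, `qc`, `fits` (nested by subject),
#'   `reports` (per-subject `hetmix_gradient`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir, counts = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_fn <- if (quiet) function(...) invisible() else pipe_log
  written <- character(0)

  # --- stage 1: simulate or ingest ---------------------------------------
  if (is.null(counts)) {
    log_fn("simulate", sprintf("%d subset(s), master seed %d",
                               length(config$cohort), config$seed))
    sim <- simulate_cohort(config$cohort, config$spec,
                           seed = derive_seed(config$seed, 1))
    written["truth"] <- write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
    written["plate_map"] <- write_tsv(sim$plates,
                                      file.path(out_dir, "plate_map.tsv"))
    if (config$use_fastq) {
      # --- stage 2: FASTQ emission, demultiplex, allele counting ---------
      log_fn("demux", "emitting and demultiplexing per-plate FASTQ")
      fq_dir <- file.path(out_dir, "fastq")
      paths <- emit_fastq(sim, config$template, config$target_offset,
                          config$spec, fq_dir,
                          seed = derive_seed(config$seed, 2))
      bw <- nchar(sim$plates$barcode[1])
      counts <- do.call(rbind, lapply(names(paths), function(pid) {
        bc <- sim$plates[sim$plates$plate_id == pid,
                         c("well_id", "barcode")]
        dm <- demultiplex(read_fastq(paths[[pid]]), bc)
        cp <- count_plate(dm, bc, config$target_offset, bw,
                          config$min_base_quality)
        cbind(plate_id = pid, cp)
      }))
      meta <- sim$truth[, c("plate_id", "well_id", "subject_id", "cell_type",
                            "is_control")]
      counts <- merge(meta, counts, by = c("plate_id", "well_id"),
                      sort = FALSE)
      counts <- counts[order(counts$plate_id, counts$well_id), ]
      counts$vaf <- ifelse(counts$depth > 0,
                           counts$alt_count / counts$depth, NA_real_)
      rownames(counts) <- NULL
    } else {
      counts <- sim$counts
    }
  } else {
    log_fn("ingest", sprintf("%d wells supplied", nrow(counts)))
  }
  written["counts"] <- write_tsv(counts, file.path(out_dir, "counts.tsv"))

  # --- stage 3: QC --------------------------------------------------------
  qc <- apply_qc(counts, config$qc)
  log_fn("qc", sprintf("%d/%d cells retained; %d plate(s) excluded",
                       nrow(qc$retained),
                       sum(!counts$is_control), length(qc$excluded_plates)))
  written["retained"] <- write_tsv(qc$retained,
                                   file.path(out_dir, "retained.tsv"))
  jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written["qc_report"] <- file.path(out_dir, "qc_report.json")

  # --- stage 4: per-subset mixture fits ----------------------------------
  ret <- qc$retained
  groups_tab <- unique(ret[, c("subject_id", "cell_type")])
  groups_tab <- groups_tab[order(groups_tab$subject_id,
                                 match(groups_tab$cell_type, config$order)), ]
  fits <- list(); fit_rows <- list()
  for (k in seq_len(nrow(groups_tab))) {
    su <- groups_tab$subject_id[k]; ct <- groups_tab$cell_type[k]
    sel <- ret$subject_id == su & ret$cell_type == ct
    y <- ret$vaf[sel]
    fit <- fit_mcmc(y, config$model, n_iter = config$n_iter,
                    burn_in = config$burn_in, thin = config$thin,
                    n_chains = config$n_chains,
                    seed = derive_seed(config$seed, 100 + k),
                    depth = ret$depth[sel])
    fits[[su]][[ct]] <- fit
    ci <- credible_interval(fit, level = config$level)
    fit_rows[[k]] <- data.frame(subject_id = su, cell_type = ct,
                                n_cells = sum(sel),
                                e_pi = mean(pi_draws(fit)),
                                ci_low = ci[1], ci_high = ci[2],
                                p_no_spike = fit$p_no_spike,
                                rhat_pi = fit$rhat_pi)
    log_fn("fit", sprintf("%s/%s: n=%d, E[pi|Y]=%.3f", su, ct, sum(sel),
                          mean(pi_draws(fit))))
  }
  fit_summary <- do.call(rbind, fit_rows)
  written["fit_summary"] <- write_tsv(fit_summary,
                                      file.path(out_dir, "fit_summary.tsv"))

  # --- stage 5: gradient comparisons -------------------------------------
  reports <- list(); comp_rows <- list(); peak_rows <- list()
  for (su in names(fits)) {
    rep_s <- gradient_report(fits[[su]], order = config$order,
                             groups = config$groups, level = config$level)
    reports[[su]] <- rep_s
    peak_rows[[su]] <- cbind(subject_id = su, rep_s$peaks)
    if (nrow(rep_s$comparisons))
      comp_rows[[su]] <- cbind(subject_id = su, rep_s$comparisons)
  }
  written["peaks"] <- write_tsv(do.call(rbind, peak_rows),
                                file.path(out_dir, "peaks.tsv"))
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame()
  written["comparisons"] <- write_tsv(comparisons,
                                      file.path(out_dir, "comparisons.tsv"))

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("hetmix")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 1),
                       fastq = derive_seed(config$seed, 2)),
    parameters = list(use_fastq = config$use_fastq,
                      n_iter = config$n_iter, burn_in = config$burn_in,
                      thin = config$thin, n_chains = config$n_chains,
                      level = config$level, order = config$order,
                      min_base_quality = config$min_base_quality),
    files = lapply(written, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_fn("done", sprintf("outputs in %s", out_dir))

  invisible(list(counts = counts, qc = qc, fits = fits, reports = reports,
                 fit_summary = fit_summary, comparisons = comparisons,
                 manifest = manifest))
}
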