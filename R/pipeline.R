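# End-to-end orchestration: validated run configuration, the staged
# pipeline (read -> transform -> preprocess -> nucleus pipeline ->
# assignment -> DP4), per-stage reports and a run log.

#' Validated run configuration
#'
#' @param h_data,c_data paths to raw 1H/13C data (Bruker directory or
#'   JCAMP-DX file); NULL skips the nucleus.
#' @param shift_tables named list: per candidate id, a list with entries
#'   `"1H"`/`"13C"` of shift-table paths, or `CandidateShifts` objects.
#' @param structure_file optional MOL/SDF path for methyl/labile/proton
#'   counts.
#' @param solvent solvent label.
#' @param total_protons,labile_protons,n_carbons molecule totals (derived
#'   from `structure_file` when given).
#' @param error_models list with `"1H"`/`"13C"` [error_model()]s.
#' @param external_factors list with `"1H"`/`"13C"` scaling pairs.
#' @param output_dir directory for reports (NULL disables writing).
#' @param seed RNG seed for any stochastic step.
#' @param verbose print stage log lines as they happen.
#' @param ... rejected: unknown keys are configuration errors.
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(h_data = NULL, c_data = NULL, shift_tables = list(),
                       structure_file = NULL, solvent = "chloroform",
                       total_protons = NULL, labile_protons = 0L,
                       n_carbons = NULL,
                       error_models = list(`1H` = default_error_model("1H"),
                                           `13C` = default_error_model("13C")),
                       external_factors = list(`1H` = c(1, 0),
                                               `13C` = c(1, 0)),
                       output_dir = NULL, seed = 1L, verbose = FALSE, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  if (is.null(h_data) && is.null(c_data))
    stop("at least one of h_data / c_data is required")
  for (p in c(h_data, c_data, structure_file)) {
    if (!is.null(p) && !file.exists(p) && !dir.exists(p))
      stop("configured path does not exist: ", p)
  }
  if (!length(shift_tables))
    stop("at least one candidate shift table is required")
  structure(list(h_data = h_data, c_data = c_data,
                 shift_tables = shift_tables,
                 structure_file = structure_file, solvent = solvent,
                 total_protons = total_protons,
                 labile_protons = labile_protons, n_carbons = n_carbons,
                 error_models = error_models,
                 external_factors = external_factors,
                 output_dir = output_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "RunConfig")
}

read_raw_any <- function(path) {
  if (dir.exists(path)) read_bruker(path) else read_jcamp(path)
}

#' Run the full pipeline
#'
#' Executes, per configured nucleus: raw-data reading, Fourier transform,
#' noise estimation, phasing, baseline correction, the nucleus-specific
#' peak pipeline, candidate assignment, and finally the DP4 ranking.
#' Writes per-stage reports (JSON + TSV) and a decision log to
#' `output_dir` when configured.
#'
#' @param config a [run_config()].
#' @return list with `dp4` (a `DP4Result`), `assignments` (per candidate,
#'   per nucleus), `proton` / `carbon` stage outputs, and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  set.seed(config$seed)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    if (config$verbose) message(msg)
    log <<- c(log, msg)
  }

  struct <- NULL
  total_protons <- config$total_protons
  labile_protons <- config$labile_protons
  n_carbons <- config$n_carbons
  if (!is.null(config$structure_file)) {
    struct <- read_structure(config$structure_file)
    total_protons <- struct$n_protons
    labile_protons <- struct$n_labile
    n_carbons <- struct$n_carbons
    say("structure: %d H (%d labile), %d C, %d methyl group(s)",
        total_protons, labile_protons, n_carbons,
        length(struct$methyl_groups))
  }

  proton_out <- NULL
  if (!is.null(config$h_data)) {
    fid <- read_raw_any(config$h_data)
    sp <- if (inherits(fid, "RawFID")) fourier_transform(fid) else fid
    proton_out <- process_proton(sp, total_protons = total_protons,
                                 labile_protons = labile_protons,
                                 solvent = config$solvent)
    say("1H: phi0 %.1f deg, phi1 %.1f deg; %d multiplet(s); solvent shift %+.3f ppm; n = %s protons",
        proton_out$phase$phi0 * 180 / pi, proton_out$phase$phi1 * 180 / pi,
        length(proton_out$multiplets), proton_out$solvent_shift,
        as.character(proton_out$n_protons))
  }

  carbon_out <- NULL
  if (!is.null(config$c_data)) {
    fid <- read_raw_any(config$c_data)
    sp <- if (inherits(fid, "RawFID")) fourier_transform(fid) else fid
    sp <- estimate_noise(sp)
    regions <- classify_signal_regions(sp, sp$noise_sigma)
    ph <- phase_correct(sp, regions)
    sp <- baseline_correct(ph$spectrum, regions)
    sp <- estimate_noise(sp)
    pk <- pick_peaks_iterative(sp)
    if (is.null(n_carbons))
      stop("n_carbons (or structure_file) required for a 13C run")
    pk <- group_amplitudes_and_weight(pk, n_carbons)
    carbon_out <- list(spectrum = sp, peaks = pk, phase = ph$phase)
    say("13C: phi0 %.1f deg; %d peak(s) in %d amplitude group(s)",
        ph$phase$phi0 * 180 / pi, nrow(pk), max(c(pk$group, 0L)))
  }

  # assignment per candidate, per nucleus
  ids <- names(config$shift_tables)
  if (is.null(ids)) stop("shift_tables must be a named list")
  errors <- list()
  assignments <- list()
  for (id in ids) {
    entry <- config$shift_tables[[id]]
    errs <- list()
    asg <- list()
    if (!is.null(proton_out) && !is.null(entry[["1H"]])) {
      cand <- entry[["1H"]]
      if (is.character(cand))
        cand <- read_shift_table(cand, candidate_id = id, nucleus = "1H")
      if (!is.null(struct)) cand <- annotate_from_structure(cand, struct)
      a <- assign_protons(cand, proton_out$multiplets,
                          model = config$error_models[["1H"]],
                          external_factors = config$external_factors[["1H"]])
      asg[["1H"]] <- a
      errs[["1H"]] <- a$table$error
    }
    if (!is.null(carbon_out) && !is.null(entry[["13C"]])) {
      cand <- entry[["13C"]]
      if (is.character(cand))
        cand <- read_shift_table(cand, candidate_id = id, nucleus = "13C")
      a <- assign_carbons(cand, carbon_out$peaks,
                          model = config$error_models[["13C"]],
                          external_factors = config$external_factors[["13C"]])
      asg[["13C"]] <- a
      errs[["13C"]] <- a$table$error
    }
    if (!length(errs))
      stop("candidate ", id, " has no shifts for any processed nucleus")
    errors[[id]] <- errs
    assignments[[id]] <- asg
    say("assigned candidate %s (%s)", id, paste(names(errs), collapse = "+"))
  }

  result <- dp4(errors, models = config$error_models)
  best <- result$candidate[which.max(result$dp4)]
  say("DP4: best candidate %s (%.1f%%)", best,
      100 * max(result$dp4))

  out <- list(dp4 = result, assignments = assignments,
              proton = proton_out, carbon = carbon_out, log = log)
  if (!is.null(config$output_dir)) write_reports(out, config$output_dir)
  out
}

write_reports <- function(out, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.data.frame(out$dp4),
                       file.path(output_dir, "dp4.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(as.data.frame(out$dp4), file.path(output_dir, "dp4.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$proton)) {
    mt <- multiplet_table(out$proton$multiplets)
    write.table(mt, file.path(output_dir, "multiplets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(mt, file.path(output_dir, "multiplets.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$carbon)) {
    write.table(out$carbon$peaks, file.path(output_dir, "carbon_peaks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (id in names(out$assignments)) {
    for (nuc in names(out$assignments[[id]])) {
      tab <- out$assignments[[id]][[nuc]]$table
      write.table(tab, file.path(output_dir,
                                 sprintf("assignment_%s_%s.tsv", id, nuc)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  writeLines(out$log, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' Run the simulation/property suite
#'
#' Recomputes the package's recovery and oracle-equivalence metrics on
#' freshly generated synthetic data and returns a machine-readable summary
#' (the same quantities the acceptance script reports).
#'
#' @param seed RNG seed.
#' @param n_phase,n_pipeline,n_bic,n_endtoend,n_hungarian replicate counts
#'   per property (reduced sizes for quick runs).
#' @param output_path optional JSON output path.
#' @return data.frame with columns `metric`, `value`, `n`.
#' @export
run_simulation_suite <- function(seed = 1L, n_phase = 20L, n_pipeline = 10L,
                                 n_bic = 10L, n_endtoend = 20L,
                                 n_hungarian = 200L, output_path = NULL) {
  res <- list(
    hungarian_oracle_agreement_pct =
      list(value = 100 * hungarian_oracle_check(seed, n_hungarian),
           n = n_hungarian),
    phase_recovery_rate_pct =
      list(value = 100 * phase_recovery_rate(seed + 1L, n_phase),
           n = n_phase))
  pipe <- proton_recovery_rates(seed + 2L, n_pipeline)
  res$multiplet_center_recovery_pct <- list(value = 100 * pipe$center_rate,
                                            n = n_pipeline)
  res$proton_count_accuracy_pct <- list(value = 100 * pipe$count_rate,
                                        n = n_pipeline)
  res$bic_prune_success_pct <- list(value = 100 * bic_prune_rate(seed + 3L, n_bic),
                                    n = n_bic)
  res$dp4_top1_recovery_pct <- list(value = 100 * dp4_recovery_rate(seed + 4L,
                                                                    n_endtoend),
                                    n = n_endtoend)
  tab <- data.frame(metric = names(res),
                    value = vapply(res, function(r) r$value, numeric(1)),
                    n = vapply(res, function(r) r$n, numeric(1)),
                    row.names = NULL)
  if (!is.null(output_path))
    jsonlite::write_json(tab, output_path, auto_unbox = TRUE, digits = NA)
  tab
}
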