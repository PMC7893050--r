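#' Run the full titration-analysis pipeline in memory
#'
#' Wires the stages together for one synthetic experiment:
#' simulate replicate forward/reverse curves, compute charge excess, fit the
#' ligand spectrum by LPM per replicate (forward run), bin the fitted sites
#' into functional-group classes, aggregate replicates into a summary, and
#' run the QC comparisons (forward vs reverse per replicate; measured vs
#' modeled per fit).
#'
#' The forward run is used for fitting; the reverse run serves as the
#' hysteresis control, mirroring how agreement is checked before inversion.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param grid A \code{\link{pka_grid}}.
#' @param scheme A \code{\link{functional_group_scheme}}.
#' @param resample Passed to \code{\link{fit_lpm}}.
#' @return A list with elements \code{curves}, \code{series} (charge-excess
#'   per curve), \code{fits} (per replicate), \code{class_totals} (per
#'   replicate, mol/g), \code{summary} (a
#'   \code{\link{aggregate_replicates}} table), \code{report} (rendered
#'   table) and \code{qc} (list of agreement reports).
#' @examples
#' \donttest{
#' res <- run_titration_pipeline(preset_specs()[["minimal"]])
#' res$report
#' }
#' @export
run_titration_pipeline <- function(spec, grid = pka_grid(),
                                   scheme = functional_group_scheme(),
                                   resample = TRUE) {
  stop_unless(is_synthetic_spec(spec), "spec must be a synthetic_spec")
  curves <- simulate_titration(spec)
  series <- lapply(curves, charge_excess)

  fits <- list(); totals <- list(); qc <- list()
  for (r in seq_len(spec$n_replicates)) {
    fw <- series[[sprintf("rep%d_forward", r)]]
    rv <- series[[sprintf("rep%d_reverse", r)]]
    qc[[sprintf("rep%d_forward_vs_reverse", r)]] <-
      compare_series(fw, rv, grid)
    fit <- fit_lpm(fw, grid, resample = resample)
    fits[[sprintf("rep%d", r)]] <- fit
    qc[[sprintf("rep%d_measured_vs_modeled", r)]] <-
      measured_vs_modeled(fw, fit$spectrum)
    totals[[sprintf("rep%d", r)]] <- bin_functional_groups(fit$spectrum, scheme)
  }
  summary <- aggregate_replicates(totals)
  report <- render_table1_report(stats::setNames(list(summary), spec$sample_id),
                                 scheme)
  list(curves = curves, series = series, fits = fits,
       class_totals = totals, summary = summary, report = report, qc = qc)
}

#' Simulate an experiment and write its files
#'
#' Writes the titration CSV (\code{curves.csv}) and the ground-truth sidecar
#' (\code{truth.json}) for a synthetic experiment into a directory.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional seed overriding \code{spec$seed}.
#' @return Invisible list with the written paths.
#' @export
simulate_to_files <- function(spec, out_dir, seed = NULL) {
  stop_unless(is_synthetic_spec(spec), "spec must be a synthetic_spec")
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- simulate_titration(spec)
  curves_path <- file.path(out_dir, "curves.csv")
  truth_path <- file.path(out_dir, "truth.json")
  write_titration_csv(curves, curves_path)
  write_truth_json(spec, truth_path)
  invisible(list(curves = curves_path, truth = truth_path))
}

#' Fit every curve in a titration CSV and write spectra + QC
#'
#' Reads a titration CSV, computes charge excess per curve, fits the LPM
#' spectrum for each, and writes per-curve spectrum TSVs
#' (\code{spectrum_<sample>_rep<k>_<direction>.tsv}), a diagnostics JSON and
#' a QC JSON (forward-vs-reverse agreement per replicate where both
#' directions are present, measured-vs-modeled agreement per curve).
#'
#' @param curves_path Path to a titration CSV.
#' @param out_dir Output directory (created if missing).
#' @param config A \code{\link{vessel_config}}.
#' @param grid A \code{\link{pka_grid}}.
#' @param resample Passed to \code{\link{fit_lpm}}.
#' @return Invisible list of \code{lpm_fit} objects keyed like the curves.
#' @export
fit_curves_file <- function(curves_path, out_dir,
                            config, grid = pka_grid(), resample = TRUE) {
  curves <- read_titration_curves(curves_path, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  series <- lapply(curves, charge_excess)
  fits <- list(); diagnostics <- list(); qc <- list()
  for (nm in names(curves)) {
    fit <- fit_lpm(series[[nm]], grid, resample = resample)
    fits[[nm]] <- fit
    write_spectrum_tsv(fit$spectrum,
                       file.path(out_dir, sprintf("spectrum_%s.tsv", nm)))
    d <- fit$diagnostics
    diagnostics[[nm]] <- list(objective_value = d$objective_value,
                              rmse = d$rmse,
                              n_active_sites = d$n_active_sites,
                              solver_status = d$solver_status,
                              n_points = d$n_points)
    mvm <- measured_vs_modeled(series[[nm]], fit$spectrum)
    qc[[paste0(nm, "_measured_vs_modeled")]] <- unclass(mvm)
  }
  pairs <- unique(sub("_(forward|reverse)$", "", names(curves)))
  for (p in pairs) {
    fw <- series[[paste0(p, "_forward")]]
    rv <- series[[paste0(p, "_reverse")]]
    if (!is.null(fw) && !is.null(rv)) {
      qc[[paste0(p, "_forward_vs_reverse")]] <-
        unclass(compare_series(fw, rv, grid))
    }
  }
  write_json_report(diagnostics, file.path(out_dir, "diagnostics.json"))
  write_json_report(qc, file.path(out_dir, "qc.json"))
  invisible(fits)
}

#' Summarize fitted spectra into a functional-group table
#'
#' Reads per-curve spectrum TSVs written by \code{\link{fit_curves_file}},
#' pools each forward-run spectrum into functional-group class totals,
#' aggregates replicates per sample and writes a summary TSV plus a
#' human-readable fixed-width report.
#'
#' @param spectra_dir Directory containing \code{spectrum_*.tsv} files.
#' @param out_path Output TSV path; a \code{.txt} report is written next to
#'   it.
#' @param scheme A \code{\link{functional_group_scheme}}.
#' @return Invisible rendered report data.frame.
#' @export
summarize_spectra_files <- function(spectra_dir, out_path,
                                    scheme = functional_group_scheme()) {
  files <- sort(list.files(spectra_dir, pattern = "^spectrum_.*_forward\\.tsv$",
                           full.names = TRUE))
  stop_unless(length(files) >= 1, "no forward-run spectrum TSVs found")
  meta <- sub("^spectrum_(.*)_rep(.*)_forward\\.tsv$", "\\1|\\2",
              basename(files))
  sample <- sub("\\|.*$", "", meta)
  summaries <- list()
  for (s in unique(sample)) {
    totals <- lapply(files[sample == s], function(f)
      bin_functional_groups(read_spectrum_tsv(f), scheme))
    summaries[[s]] <- aggregate_replicates(totals)
  }
  report <- render_table1_report(summaries, scheme)
  utils::write.table(report, out_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  txt <- file.path(dirname(out_path),
                   sub("\\.[^.]*$", ".txt", basename(out_path)))
  writeLines(utils::capture.output(print(report)), txt, useBytes = FALSE)
  invisible(report)
}
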