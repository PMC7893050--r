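# File formats: titration CSV, spectrum TSV, JSON sidecars.
# All numeric output uses 6 significant digits so that repeated runs with the
# same seed produce byte-identical files.

fmt6 <- function(x) formatC(x, digits = 6, format = "g")

#' Write titration curves to CSV
#'
#' One row per titration point, columns
#' \code{sample_id,replicate_id,direction,acid_volume_L,base_volume_L,pH};
#' UTF-8, '.' decimal separator, numerics at 6 significant digits.
#'
#' @param curves A \code{\link{titration_curve}} or list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_titration_csv <- function(curves, path) {
  if (is_titration_curve(curves)) curves <- list(curves)
  stop_unless(length(curves) >= 1 && all(vapply(curves, is_titration_curve,
                                                logical(1))),
              "curves must be titration_curve objects")
  rows <- lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, replicate_id = cv$replicate_id,
               direction = cv$direction,
               acid_volume_L = fmt6(cv$points$acid_volume_L),
               base_volume_L = fmt6(cv$points$base_volume_L),
               pH = fmt6(cv$points$pH),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read titration curves from CSV
#'
#' Parses the dialect written by \code{\link{write_titration_csv}} and
#' validates every row; a malformed row aborts with a message naming its
#' line number. Rows are grouped into one curve per (sample, replicate,
#' direction), in order of first appearance.
#'
#' @param path CSV file path.
#' @param config The \code{\link{vessel_config}} the curves were measured
#'   under (the CSV stores volumes and pH only).
#' @return Named list of \code{\link{titration_curve}} objects.
#' @export
read_titration_curves <- function(path, config) {
  stop_unless(file.exists(path), sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "replicate_id", "direction",
            "acid_volume_L", "base_volume_L", "pH")
  stop_unless(all(need %in% names(tab)),
              sprintf("CSV must have columns: %s", paste(need, collapse = ",")))
  if (nrow(tab) == 0) stop("empty titration file", call. = FALSE)
  num <- function(col) suppressWarnings(as.numeric(tab[[col]]))
  va <- num("acid_volume_L"); vb <- num("base_volume_L"); ph <- num("pH")
  bad <- which(!is.finite(va) | !is.finite(vb) | !is.finite(ph) |
                 va < 0 | vb < 0 | ph <= 0 | ph >= 14 |
                 !tab$direction %in% c("forward", "reverse"))
  if (length(bad)) {
    stop(sprintf("malformed titration row at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)   # +1 for the header
  }
  key <- paste(tab$sample_id, tab$replicate_id, tab$direction, sep = "|")
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    cv <- titration_curve(tab$sample_id[sel][1], tab$replicate_id[sel][1],
                          tab$direction[sel][1], config,
                          data.frame(acid_volume_L = va[sel],
                                     base_volume_L = vb[sel],
                                     pH = ph[sel]))
    out[[sprintf("%s_rep%s_%s", cv$sample_id, cv$replicate_id,
                 cv$direction)]] <- cv
  }
  out
}

#' Write a fitted ligand spectrum to TSV
#'
#' Columns \code{pKa} and \code{L_T_mmol_per_g}; the intercept is stored on
#' a leading comment line \code{# intercept_S_mmol_per_g=<value>}.
#'
#' @param spectrum A \code{\link{ligand_spectrum}} (mol/g; written as
#'   mmol/g).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stop_unless(is_ligand_spectrum(spectrum), "spectrum must be a ligand_spectrum")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# intercept_S_mmol_per_g=%s", fmt6(spectrum$S * 1e3)), con)
  writeLines("pKa\tL_T_mmol_per_g", con)
  writeLines(sprintf("%s\t%s", fmt6(spectrum$sites$pKa),
                     fmt6(spectrum$sites$L_T * 1e3)), con)
  invisible(path)
}

#' Read a ligand spectrum from TSV
#'
#' @param path File written by \code{\link{write_spectrum_tsv}}.
#' @return A \code{\link{ligand_spectrum}} (converted back to mol/g).
#' @export
read_spectrum_tsv <- function(path) {
  stop_unless(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  sline <- grep("^# intercept_S_mmol_per_g=", lines, value = TRUE)
  S <- if (length(sline)) as.numeric(sub("^# intercept_S_mmol_per_g=", "",
                                         sline[1])) / 1e3 else 0
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  ligand_spectrum(tab$pKa, tab$L_T_mmol_per_g / 1e3, S = S)
}

#' Write the ground truth of a synthetic experiment to JSON
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param path Output path for the \code{truth.json} sidecar.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(spec, path) {
  stop_unless(is_synthetic_spec(spec), "spec must be a synthetic_spec")
  obj <- list(
    sample_id = spec$sample_id,
    truth = list(pKa = spec$truth$sites$pKa,
                 L_T_mol_per_g = spec$truth$sites$L_T,
                 S_mol_per_g = spec$truth$S),
    config = unclass(spec$config),
    noise = spec$noise,
    n_replicates = spec$n_replicates,
    seed = spec$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_json_report <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
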