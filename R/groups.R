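#' Functional-group classification scheme
#'
#' pKa-range classes used to pool fitted ligand sites into chemically
#' interpretable groups. The default follows the standard assignment for
#' microbial surface ligands: carboxyl 3--5.8, phosphoryl 6--8, amine 8--9,
#' hydroxyl 9--10.
#'
#' Boundary convention: a class covers [lo, hi) when its upper bound is
#' shared with the next class's lower bound; where a gap follows (or for the
#' last class) the upper bound is included. So a grid site at pKa 5.8 is
#' carboxyl, 6.0 phosphoryl, 8.0 amine, 9.0 hydroxyl and 10.0 hydroxyl.
#'
#' @param classes A data.frame with columns \code{name}, \code{lo},
#'   \code{hi}, ordered by increasing \code{lo}. Ranges must not overlap
#'   under the boundary convention.
#' @return An object of class \code{functional_group_scheme}.
#' @export
functional_group_scheme <- function(classes = NULL) {
  if (is.null(classes)) {
    classes <- data.frame(
      name = c("carboxyl", "phosphoryl", "amine", "hydroxyl"),
      lo = c(3, 6, 8, 9),
      hi = c(5.8, 8, 9, 10),
      stringsAsFactors = FALSE)
  }
  stop_unless(is.data.frame(classes) &&
                all(c("name", "lo", "hi") %in% names(classes)),
              "classes must have columns name, lo, hi")
  classes <- classes[order(classes$lo), , drop = FALSE]
  rownames(classes) <- NULL
  stop_unless(all(classes$lo < classes$hi), "each class needs lo < hi")
  if (nrow(classes) > 1) {
    stop_unless(all(classes$hi[-nrow(classes)] <= classes$lo[-1] + 1e-9),
                "class pKa ranges overlap")
  }
  stop_unless(!anyDuplicated(classes$name), "class names must be unique")
  structure(classes, class = c("functional_group_scheme", "data.frame"))
}

is_fg_scheme <- function(x) inherits(x, "functional_group_scheme")

# class index for each pKa under the boundary convention; NA = unassigned
assign_class <- function(pKa, scheme, tol = 1e-9) {
  k <- nrow(scheme)
  # upper bound closed when no class starts exactly at hi (gap or last class)
  hi_closed <- c(if (k > 1) abs(scheme$hi[-k] - scheme$lo[-1]) > tol, TRUE)
  idx <- rep(NA_integer_, length(pKa))
  for (i in seq_len(k)) {
    inside <- pKa >= scheme$lo[i] - tol &
      (pKa < scheme$hi[i] - tol | (hi_closed[i] & pKa <= scheme$hi[i] + tol))
    idx[is.na(idx) & inside] <- i
  }
  idx
}

#' Pool fitted ligand sites into functional-group classes
#'
#' Sums the site concentrations of a ligand spectrum over the pKa ranges of
#' a classification scheme. Every site is assigned to at most one class;
#' sites falling in no class are accumulated under \code{"unassigned"}, so
#' the class totals plus the unassigned total always reproduce the
#' spectrum's total L_T exactly.
#'
#' @param spectrum A \code{\link{ligand_spectrum}}.
#' @param scheme A \code{\link{functional_group_scheme}}.
#' @return Named numeric vector: one total per class (in the spectrum's
#'   units, mol/g for fitted spectra) plus \code{unassigned}.
#' @examples
#' sp <- ligand_spectrum(c(4.2, 5.6, 8.4), c(0.05, 0.06, 0.2))
#' bin_functional_groups(sp)
#' @export
bin_functional_groups <- function(spectrum, scheme = functional_group_scheme()) {
  stop_unless(is_ligand_spectrum(spectrum), "spectrum must be a ligand_spectrum")
  scheme <- functional_group_scheme(as.data.frame(scheme))  # re-validate
  idx <- assign_class(spectrum$sites$pKa, scheme)
  out <- c(stats::setNames(rep(0, nrow(scheme)), scheme$name), unassigned = 0)
  for (j in seq_along(idx)) {
    k <- if (is.na(idx[j])) length(out) else idx[j]
    out[k] <- out[k] + spectrum$sites$L_T[j]
  }
  out
}

#' Aggregate replicate functional-group totals
#'
#' Combines per-replicate class totals (from \code{\link{bin_functional_groups}})
#' into per-class mean and sample standard deviation (n - 1 denominator),
#' the statistics used for triplicate titrations. With a single replicate
#' the standard deviation is reported as NA.
#'
#' @param per_replicate_totals A list of named numeric vectors with
#'   identical names (one vector per replicate).
#' @return An object of class \code{functional_group_summary}: a data.frame
#'   with columns \code{class}, \code{mean}, \code{sd}, \code{n_replicates},
#'   carrying the per-replicate matrix as attribute \code{"replicates"}.
#' @examples
#' aggregate_replicates(list(c(carboxyl = 0.2), c(carboxyl = 0.4),
#'                           c(carboxyl = 0.6)))
#' @export
aggregate_replicates <- function(per_replicate_totals) {
  stop_unless(is.list(per_replicate_totals) && length(per_replicate_totals) >= 1,
              "need at least one replicate")
  nms <- names(per_replicate_totals[[1]])
  stop_unless(!is.null(nms) && all(nzchar(nms)), "replicate totals must be named")
  same <- vapply(per_replicate_totals, function(x) identical(names(x), nms),
                 logical(1))
  stop_unless(all(same), "replicates carry inconsistent class sets")
  mat <- do.call(rbind, per_replicate_totals)   # replicates x classes
  n <- nrow(mat)
  out <- data.frame(
    class = nms,
    mean = colMeans(mat),
    sd = if (n > 1) apply(mat, 2, stats::sd) else NA_real_,
    n_replicates = n,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "replicates") <- mat
  class(out) <- c("functional_group_summary", "data.frame")
  out
}

#' Render a functional-group summary table
#'
#' Produces the standard reporting layout for EPS functional-group
#' concentrations: one row per class with its pKa range and one
#' "Average L_T (mMol/g EPS)" column per sample, each cell formatted
#' \code{mean +/- sd} to three decimals.
#'
#' @param summaries Named list of \code{\link{aggregate_replicates}} outputs,
#'   one per sample (names become column labels, in input order).
#' @param scheme The \code{\link{functional_group_scheme}} supplying the
#'   printed pKa ranges.
#' @param input_units Units of the summary values: \code{"mol_per_g"}
#'   (default; values are multiplied by 1000 for display) or
#'   \code{"mmol_per_g"} (displayed as-is).
#' @return A data.frame of class \code{fg_report}: columns
#'   \code{Functional Group}, \code{pKa Range}, then one character column of
#'   \code{mean ± sd} per sample. Classes absent from a summary render
#'   as \code{0.000 ± 0.000}; an NA sd renders as \code{NA}.
#' @export
render_table1_report <- function(summaries, scheme = functional_group_scheme(),
                                 input_units = c("mol_per_g", "mmol_per_g")) {
  input_units <- match.arg(input_units)
  stop_unless(is.list(summaries) && length(summaries) >= 1,
              "need at least one summary")
  if (is.null(names(summaries)))
    names(summaries) <- paste("sample", seq_along(summaries))
  mult <- if (input_units == "mol_per_g") 1e3 else 1
  fmt <- function(x) formatC(x, digits = 3, format = "f")

  classes <- scheme$name
  out <- data.frame(
    `Functional Group` = tools_title_case(classes),
    `pKa Range` = paste0(format_num(scheme$lo), "–", format_num(scheme$hi)),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(summaries)) {
    s <- summaries[[nm]]
    stop_unless(inherits(s, "functional_group_summary"),
                "summaries must come from aggregate_replicates()")
    cell <- character(length(classes))
    for (i in seq_along(classes)) {
      row <- s[s$class == classes[i], , drop = FALSE]
      if (nrow(row) == 0) {
        cell[i] <- paste0(fmt(0), " ± ", fmt(0))
      } else {
        sdtxt <- if (is.na(row$sd)) "NA" else fmt(row$sd * mult)
        cell[i] <- paste0(fmt(row$mean * mult), " ± ", sdtxt)
      }
    }
    out[[paste0(nm, " Average L_T (mMol/g EPS)")]] <- cell
  }
  class(out) <- c("fg_report", "data.frame")
  out
}

#' @export
print.fg_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, right = FALSE)
  invisible(x)
}

tools_title_case <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

format_num <- function(x) {
  sub("\\.?0+$", "", formatC(x, digits = 6, format = "f"))
}
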