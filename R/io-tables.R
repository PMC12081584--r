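#' Read a binding-energy component table
#'
#' CSV with columns `condition`, `cluster`, `dG_solv`, `dG_coul`, `dG_nonelec`
#' and optionally `dG_b`, all energies in kJ/mol. One row per
#' cluster-representative complex.
#'
#' @param path path to the CSV file.
#' @return A data frame of energy components (kJ/mol), class `energy_table`.
#' @export
read_energy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("condition", "cluster", "dG_solv", "dG_coul", "dG_nonelec")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(c("dG_solv", "dG_coul", "dG_nonelec", "dG_b"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   col, bad[1], df[[col]][bad[1]]))
    df[[col]] <- v
  }
  class(df) <- c("energy_table", "data.frame")
  df
}

#' Write a results table as CSV
#'
#' @param rows a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one labelled solvation energy value from a plain-text file
#'
#' Accepts files like `dG_solv_kJ: 251`, `dG_solv_kcal: 2.0`, or a bare
#' number (interpreted per `unit`). Values declared (or defaulting to)
#' kcal/mol are converted to kJ/mol with the factor 4.184.
#'
#' @param path path to the text file.
#' @param unit unit assumed for values whose label does not declare one:
#'   `"kJ"` (default) or `"kcal"`.
#' @return A single solvation energy in kJ/mol.
#' @export
read_solvation_component <- function(path, unit = c("kJ", "kcal")) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no energy value found in ", path)
  hits <- regmatches(lines, regexec(
    "^\\s*(?:([A-Za-z_0-9]+)\\s*[:=])?\\s*(-?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*$",
    lines))
  hits <- Filter(function(h) length(h) == 3, hits)
  if (length(hits) == 0) stop("no energy value found in ", path)
  if (length(hits) > 1) stop("ambiguous: multiple energy values in ", path)
  label <- hits[[1]][2]
  value <- as.numeric(hits[[1]][3])
  u <- if (grepl("kcal", label, ignore.case = TRUE)) "kcal"
       else if (grepl("kj", label, ignore.case = TRUE)) "kJ"
       else unit
  if (u == "kcal") value * 4.184 else value
}
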