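#' Titration series tibbles
#'
#' A titration series is a tibble describing one ligand's concentration
#' ladder against a fixed protein concentration, with columns:
#'
#' * `conc_mol_per_l` — ligand concentration (mol/L); exactly one row must
#'   have `conc_mol_per_l == 0` (it defines the unquenched intensity F0) and
#'   the remaining concentrations must be strictly positive and strictly
#'   increasing;
#' * `intensity` — fluorescence intensity (arbitrary units), all `> 0`;
#' * `ligand_id` (optional) — compound identifier, a single value per series;
#' * `scan` (optional) — list-column of full emission scans, one per row,
#'   each a tibble with `wavelength_nm` and `intensity`.
#'
#' `check_titration()` validates the contract and returns the data invisibly;
#' `titration_f0()` extracts the unquenched intensity.
#'
#' @param data A titration tibble as described above.
#' @return `check_titration()`: `data`, invisibly. `titration_f0()`: the
#'   intensity at zero ligand concentration.
#' @name titration
NULL

#' @rdname titration
#' @export
check_titration <- function(data) {
  if (!is.data.frame(data) || !all(c("conc_mol_per_l", "intensity") %in% names(data))) {
    fq_abort("A titration series needs columns `conc_mol_per_l` and `intensity`.", "validation")
  }
  conc <- data$conc_mol_per_l
  if (anyNA(conc) || anyNA(data$intensity)) {
    fq_abort("Titration concentrations and intensities must be non-missing.", "validation")
  }
  if (sum(conc == 0) != 1L) {
    fq_abort("A titration series must contain exactly one C = 0 point (it defines F0).",
             "validation")
  }
  pos <- conc[conc != 0]
  if (any(pos <= 0) || any(diff(pos) <= 0)) {
    fq_abort("Nonzero concentrations must be strictly positive and strictly increasing.",
             "validation")
  }
  if (any(data$intensity <= 0)) {
    fq_abort("All fluorescence intensities must be > 0.", "validation")
  }
  if ("ligand_id" %in% names(data) && length(unique(data$ligand_id)) > 1L) {
    fq_abort("A single titration series must describe a single ligand_id.", "validation")
  }
  invisible(data)
}

#' @rdname titration
#' @export
titration_f0 <- function(data) {
  check_titration(data)
  data$intensity[data$conc_mol_per_l == 0]
}

#' Read titration series from CSV
#'
#' Scalar mode expects columns `ligand_id,conc_mol_per_L,intensity`; scan mode
#' (long format) expects `ligand_id,conc_mol_per_L,wavelength_nm,intensity`,
#' in which case the per-concentration scans are nested into a `scan`
#' list-column and the scalar `intensity` is the scan maximum. Column name
#' matching is case-insensitive for the concentration column. Lines starting
#' with `#` are skipped.
#'
#' @param path Path to a CSV file (header required).
#' @return A tibble with one row per (ligand, concentration), columns
#'   `ligand_id`, `conc_mol_per_l`, `intensity` and, in scan mode, `scan`.
#'   Multiple ligands may be present; split with [dplyr::group_split()] before
#'   fitting.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) fq_abort(sprintf("File not found: %s", path), "format")
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  names(df)[tolower(names(df)) == "conc_mol_per_l"] <- "conc_mol_per_l"
  need <- c("ligand_id", "conc_mol_per_l", "intensity")
  if (!all(need %in% names(df))) {
    fq_abort(sprintf(
      "Titration CSV must have columns %s (got: %s).",
      paste(need, collapse = ", "), paste(names(df), collapse = ", ")
    ), "format")
  }
  if ("wavelength_nm" %in% names(df)) {
    df <- df |>
      dplyr::group_by(.data$ligand_id, .data$conc_mol_per_l) |>
      dplyr::arrange(.data$wavelength_nm, .by_group = TRUE) |>
      tidyr::nest(scan = c("wavelength_nm", "intensity")) |>
      dplyr::ungroup() |>
      dplyr::mutate(intensity = purrr::map_dbl(.data$scan, ~ max(.x$intensity))) |>
      dplyr::relocate("ligand_id", "conc_mol_per_l", "intensity", "scan")
  }
  dplyr::arrange(df, .data$ligand_id, .data$conc_mol_per_l)
}

#' Write titration series to CSV
#'
#' Inverse of [read_titration()]. When a `scan` list-column is present the
#' long (scan-mode) layout is written; otherwise the scalar layout.
#'
#' @param data A titration tibble (one or more ligands).
#' @param path Output file path.
#' @param metadata Optional named list written as `# name: value` comment
#'   lines before the header (e.g. the generator seed).
#' @return `path`, invisibly.
#' @export
write_titration <- function(data, path, metadata = NULL) {
  if (!"ligand_id" %in% names(data)) data$ligand_id <- "ligand"
  if ("scan" %in% names(data)) {
    out <- data |>
      dplyr::select("ligand_id", "conc_mol_per_l", "scan") |>
      tidyr::unnest("scan") |>
      dplyr::select("ligand_id", "conc_mol_per_l", "wavelength_nm", "intensity")
  } else {
    out <- dplyr::select(data, "ligand_id", "conc_mol_per_l", "intensity")
  }
  header <- character(0)
  if (!is.null(metadata)) {
    header <- sprintf("# %s: %s", names(metadata), vapply(metadata, format, ""))
  }
  body <- strsplit(readr::format_csv(out), "\n", fixed = TRUE)[[1]]
  writeLines(c(header, body), path)
  invisible(path)
}
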