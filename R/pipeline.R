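#' Full per-compound quenching analysis
#'
#' Runs the complete analysis for one ligand's titration: the modified
#' Stern-Volmer fit (quenching constants), mechanism classification against
#' the diffusion limit, the double-logarithmic binding fit (KA and site
#' number), and — when full emission scans are present — the emission-maximum
#' shift. Fit errors are re-raised with the ligand attached for context.
#'
#' @param data A titration tibble for a single ligand.
#' @param tau0 Unquenched lifetime (s); default `1e-8`.
#' @param meta Optional one-row data frame of compound metadata (columns
#'   `ligand_id`, `family`, `chain_class`, `perfluorinated_carbon_count`,
#'   as in [pfas_compounds()]).
#' @param kq_threshold Static/dynamic classification threshold, L/(mol s);
#'   default `2.0e10`.
#' @return A one-row tibble with the fitted constants (`slope_sv`,
#'   `intercept_sv`, `r_squared_sv`, `fa`, `ksv_prime`, `kq`, `mechanism`,
#'   `n_sites`, `lg_ka`, `ka`, `r_squared_lb`, `peak_shift_nm`), any
#'   metadata columns, and list-columns `sv_fit`/`lb_fit` holding the full
#'   fit objects.
#' @export
run_compound_analysis <- function(data, tau0 = 1e-8, meta = NULL,
                                  kq_threshold = 2.0e10) {
  check_titration(data)
  ligand <- if ("ligand_id" %in% names(data)) data$ligand_id[1] else "(unnamed ligand)"
  with_ligand_context <- function(expr) {
    tryCatch(expr, fq_error = function(e) {
      fq_abort(sprintf("[%s] %s", ligand, conditionMessage(e)),
               class = sub("^fq_error_", "", class(e)[1]))
    })
  }
  sv <- with_ligand_context(fit_modified_stern_volmer(data, tau0 = tau0))
  lb <- with_ligand_context(fit_lineweaver_burk(data))
  shift <- if ("scan" %in% names(data)) peak_shift(data) else NA_real_
  row <- tibble::tibble(
    ligand_id = ligand,
    slope_sv = sv$slope, intercept_sv = sv$intercept, r_squared_sv = sv$r_squared,
    fa = sv$fa, ksv_prime = sv$ksv_prime, tau0 = sv$tau0, kq = sv$kq,
    mechanism = classify_quenching(sv$kq, kq_threshold),
    n_sites = lb$n_sites, lg_ka = lb$lg_ka, ka = lb$ka, r_squared_lb = lb$r_squared,
    peak_shift_nm = shift,
    sv_fit = list(sv), lb_fit = list(lb)
  )
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    extra <- setdiff(names(meta), "ligand_id")
    row <- dplyr::bind_cols(row, meta[1, extra, drop = FALSE])
  }
  row
}

#' Cross-compound comparison report
#'
#' Ranks fitted binding constants across compounds, evaluates declared
#' ordering assertions, and summarises `lg KA` by compound family and chain
#' class (aggregation is on the log scale so one strong binder does not
#' dominate the mean).
#'
#' @param rows A tibble of per-compound results, one row each, as produced
#'   by [run_compound_analysis()] (requires at least `ligand_id` and `ka`).
#' @param expected_orderings Optional character vector of assertions of the
#'   form `"PFOS > PFHxS > PFOA"`; each adjacent pair is checked on the
#'   fitted `ka`.
#' @return An object of class `comparison_report`: a list with `rows` (input
#'   rows plus `rank_ka`, ranked by decreasing `ka`, ties broken
#'   alphabetically by `ligand_id`), `group_means` (mean `lg_ka` by `family`
#'   and by `chain_class` when those columns exist), and `assertions`
#'   (tibble of assertion/pass). [tidy()] returns the ranked rows.
#' @export
compare_compounds <- function(rows, expected_orderings = NULL) {
  if (!is.data.frame(rows) || nrow(rows) < 2L) {
    fq_abort("At least 2 compound rows are required for a comparison.", "validation")
  }
  if (!all(c("ligand_id", "ka") %in% names(rows))) {
    fq_abort("Comparison rows need `ligand_id` and `ka` columns.", "validation")
  }
  if (anyDuplicated(rows$ligand_id)) {
    fq_abort(sprintf("Duplicate ligand_id in comparison rows: %s.",
                     paste(unique(rows$ligand_id[duplicated(rows$ligand_id)]),
                           collapse = ", ")), "validation")
  }
  if (!"lg_ka" %in% names(rows)) rows$lg_ka <- log10(rows$ka)
  ranked <- rows |>
    dplyr::arrange(dplyr::desc(.data$ka), .data$ligand_id) |>
    dplyr::mutate(rank_ka = dplyr::row_number())

  group_means <- list()
  for (g in intersect(c("family", "chain_class"), names(rows))) {
    group_means[[g]] <- ranked |>
      dplyr::group_by(.data[[g]]) |>
      dplyr::summarise(mean_lg_ka = mean(.data$lg_ka), n = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$mean_lg_ka))
  }

  assertions <- tibble::tibble(assertion = character(0), pass = logical(0))
  if (!is.null(expected_orderings)) {
    ka <- stats::setNames(rows$ka, rows$ligand_id)
    assertions <- purrr::map_dfr(expected_orderings, function(a) {
      ids <- trimws(strsplit(a, ">", fixed = TRUE)[[1]])
      if (length(ids) < 2L || !all(ids %in% names(ka))) {
        fq_abort(sprintf("Cannot evaluate ordering assertion '%s': unknown ligand_id.", a),
                 "validation")
      }
      tibble::tibble(assertion = a, pass = all(diff(ka[ids]) < 0))
    })
  }

  structure(
    list(rows = ranked, group_means = group_means, assertions = assertions,
         docking_concordance = NULL),
    class = "comparison_report"
  )
}

#' Attach a docking summary and compute rank concordance
#'
#' Joins an externally computed docking table (e.g. Autodock Vina output
#' summarised per ligand) onto a comparison report and computes the Spearman
#' rank correlation (midranks on ties) between the fitted binding constant
#' `ka` and the docking affinity `-binding_energy`, over the matched
#' compounds. With fewer than 2 matches the concordance is reported as `NA`.
#'
#' @param report A [compare_compounds()] report.
#' @param docking A data frame with columns `ligand_id`,
#'   `binding_energy_kcal_mol` (kcal/mol, negative = favourable) and
#'   optionally `hydrogen_bonds`, `residues` (see [reference_docking()]).
#'   Records whose `ligand_id` does not appear in the report are dropped
#'   with a warning.
#' @return The report with docking columns joined onto `rows` and
#'   `docking_concordance` set.
#' @export
merge_docking <- function(report, docking) {
  stopifnot(inherits(report, "comparison_report"))
  if (!is.data.frame(docking) ||
      !all(c("ligand_id", "binding_energy_kcal_mol") %in% names(docking))) {
    fq_abort("`docking` needs columns `ligand_id` and `binding_energy_kcal_mol`.",
             "validation")
  }
  if ("hydrogen_bonds" %in% names(docking) &&
      any(docking$hydrogen_bonds < 0, na.rm = TRUE)) {
    fq_abort("`hydrogen_bonds` must be >= 0.", "validation")
  }
  unmatched <- setdiff(docking$ligand_id, report$rows$ligand_id)
  if (length(unmatched) > 0) {
    fq_warn(sprintf("Docking record(s) dropped (no matching compound row): %s.",
                    paste(unmatched, collapse = ", ")), "unmatched_docking")
    docking <- docking[!docking$ligand_id %in% unmatched, , drop = FALSE]
  }
  report$rows <- dplyr::left_join(report$rows, tibble::as_tibble(docking),
                                  by = "ligand_id")
  matched <- !is.na(report$rows$binding_energy_kcal_mol)
  report$docking_concordance <- if (sum(matched) >= 2L) {
    stats::cor(report$rows$ka[matched],
               -report$rows$binding_energy_kcal_mol[matched],
               method = "spearman")
  } else {
    NA_real_
  }
  report
}

#' Read a docking summary CSV
#'
#' Expects columns `ligand_id,binding_energy_kcal_mol,hydrogen_bonds,residues`.
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_docking <- function(path) {
  if (!file.exists(path)) fq_abort(sprintf("File not found: %s", path), "format")
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("ligand_id", "binding_energy_kcal_mol")
  if (!all(need %in% names(df))) {
    fq_abort(sprintf("Docking CSV must have columns %s.", paste(need, collapse = ", ")),
             "format")
  }
  df
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d compounds\n", nrow(x$rows)))
  cols <- intersect(c("rank_ka", "ligand_id", "ka", "n_sites", "kq", "mechanism"),
                    names(x$rows))
  print(x$rows[, cols])
  if (nrow(x$assertions) > 0) {
    cat(sprintf("assertions passed: %d/%d\n", sum(x$assertions$pass), nrow(x$assertions)))
  }
  if (!is.null(x$docking_concordance)) {
    cat(sprintf("KA vs docking affinity Spearman concordance: %.3f\n",
                x$docking_concordance))
  }
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) {
  x$rows
}

#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    n_compounds = nrow(x$rows),
    n_static = sum(x$rows$mechanism == "static"),
    n_assertions_passed = sum(x$assertions$pass),
    n_assertions = nrow(x$assertions),
    docking_concordance = x$docking_concordance %||% NA_real_
  )
}

#' Bar chart of fitted binding constants
#'
#' @param object A [compare_compounds()] report.
#' @param ... Unused.
#' @return A ggplot object (compounds ordered by rank, log10 KA scale).
#' @export
autoplot.comparison_report <- function(object, ...) {
  d <- dplyr::mutate(object$rows,
                     ligand_id = stats::reorder(.data$ligand_id, -.data$rank_ka))
  ggplot2::ggplot(d, ggplot2::aes(.data$ligand_id, .data$ka)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "KA (L/mol, log scale)") +
    ggplot2::theme_minimal()
}

#' Write report tables to disk
#'
#' Serialises a comparison report as one JSON file (everything) plus TSV
#' tables: the quenching table (fitted equation, R^2, Kq, mechanism), the
#' binding table (fitted equation, R^2, KA, n) and the ranked comparison.
#' Displayed constants follow the field's reporting precision (Kq to 3
#' significant figures, KA to 4 decimals); the JSON keeps full precision.
#'
#' @param report A [compare_compounds()] report.
#' @param dir Output directory (created if needed).
#' @param run_info Optional named list (seed, parameters, ...) stored in the
#'   JSON header together with the package version.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, run_info = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- report$rows
  quench_tbl <- tibble::tibble(
    ligand_id = rows$ligand_id,
    fitted_equation = sprintf("y = %.7gx + %.4g", rows$slope_sv, rows$intercept_sv),
    r_squared = round(rows$r_squared_sv, 4),
    kq = signif(rows$kq, 3),
    mechanism = rows$mechanism
  )
  bind_tbl <- tibble::tibble(
    ligand_id = rows$ligand_id,
    fitted_equation = sprintf("y = %.4gx + %.4g", rows$n_sites, rows$lg_ka),
    r_squared = round(rows$r_squared_lb, 4),
    ka = round(rows$ka, 4),
    n_sites = rows$n_sites
  )
  comp_cols <- intersect(
    c("rank_ka", "ligand_id", "family", "chain_class", "ka", "lg_ka", "n_sites",
      "kq", "mechanism", "peak_shift_nm", "binding_energy_kcal_mol"),
    names(rows)
  )
  readr::write_tsv(quench_tbl, file.path(dir, "quenching_constants.tsv"))
  readr::write_tsv(bind_tbl, file.path(dir, "binding_constants.tsv"))
  readr::write_tsv(rows[, comp_cols], file.path(dir, "comparison.tsv"))
  payload <- list(
    package = "fluorquench",
    version = as.character(utils::packageVersion("fluorquench")),
    run_info = run_info,
    rows = rows[, setdiff(names(rows), c("sv_fit", "lb_fit"))],
    group_means = report$group_means,
    assertions = report$assertions,
    docking_concordance = report$docking_concordance
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
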