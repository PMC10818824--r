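#' Detect fluorescence peaks in an EEM
#'
#' Finds strict local maxima of the intensity matrix (a cell greater than all
#' of its up-to-8 neighbours), excluding the first-order Rayleigh scatter band
#' `|excitation - emission| <= ridge_halfwidth_nm`, and keeping only maxima
#' with intensity at least `min_prominence` times the global maximum of the
#' matrix. Protein EEMs such as human serum albumin typically show two such
#' peaks: a polypeptide-backbone peak and the tryptophan/tyrosine peak.
#'
#' @param x An [eem()] object.
#' @param ridge_halfwidth_nm Half-width (nm) of the excluded scatter band
#'   around the diagonal; default 10 nm (two 5-nm grid steps).
#' @param min_prominence Minimum peak intensity as a fraction of the global
#'   matrix maximum, in (0, 1); default 0.05.
#' @return A tibble with columns `excitation_nm`, `emission_nm`, `intensity`
#'   and `kind = "fluorescence"`, sorted by decreasing intensity (ties broken
#'   by lower excitation then lower emission). Zero rows when no peak
#'   qualifies.
#' @examples
#' e <- simulate_eem(hsa_eem_config(baseline_sigma = 0, seed = 1))
#' detect_fluorescence_peaks(e)
#' @export
detect_fluorescence_peaks <- function(x, ridge_halfwidth_nm = 10, min_prominence = 0.05) {
  stopifnot(inherits(x, "eem"))
  check_number(ridge_halfwidth_nm, "ridge_halfwidth_nm")
  if (ridge_halfwidth_nm < 0) fq_abort("`ridge_halfwidth_nm` must be >= 0.", "domain")
  check_number(min_prominence, "min_prominence")
  if (min_prominence <= 0 || min_prominence >= 1) {
    fq_abort("`min_prominence` must lie strictly between 0 and 1.", "domain")
  }
  m <- x$intensity
  nr <- nrow(m)
  nc <- ncol(m)
  if (nr == 0L || nc == 0L) fq_abort("EEM intensity matrix is empty.", "validation")

  # strict 8-neighbourhood local maxima via shifted comparisons; borders
  # compare only against neighbours that exist
  is_max <- matrix(TRUE, nr, nc)
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0), ]
  for (k in seq_len(nrow(shifts))) {
    di <- shifts$di[k]; dj <- shifts$dj[k]
    ri <- seq_len(nr); rj <- seq_len(nc)
    ri_src <- ri[ri + di >= 1 & ri + di <= nr]
    rj_src <- rj[rj + dj >= 1 & rj + dj <= nc]
    cmp <- m[ri_src, rj_src, drop = FALSE] > m[ri_src + di, rj_src + dj, drop = FALSE]
    sub <- is_max[ri_src, rj_src, drop = FALSE] & cmp
    is_max[ri_src, rj_src] <- sub
  }

  band <- abs(outer(x$excitation_nm, x$emission_nm, "-")) <= ridge_halfwidth_nm
  keep <- is_max & !band & (m >= min_prominence * max(m))
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble::tibble(
    excitation_nm = x$excitation_nm[idx[, 1]],
    emission_nm = x$emission_nm[idx[, 2]],
    intensity = m[idx],
    kind = rep("fluorescence", nrow(idx))
  )
  dplyr::arrange(out, dplyr::desc(.data$intensity), .data$excitation_nm, .data$emission_nm)
}

#' Locate the first-order Rayleigh scatter ridge
#'
#' Returns the maximum-intensity cell inside the elastic-scatter band
#' `|excitation - emission| <= ridge_halfwidth_nm`. The ridge grows with
#' solute particle size, so its maximum is tracked alongside the fluorescence
#' peaks when a ligand is added.
#'
#' @inheritParams detect_fluorescence_peaks
#' @return A one-row tibble with columns `excitation_nm`, `emission_nm`,
#'   `intensity` and `kind = "rayleigh_first_order"`. Ties are broken toward
#'   lower excitation, then lower emission.
#' @export
locate_rayleigh_ridge <- function(x, ridge_halfwidth_nm = 10) {
  stopifnot(inherits(x, "eem"))
  check_number(ridge_halfwidth_nm, "ridge_halfwidth_nm")
  band <- abs(outer(x$excitation_nm, x$emission_nm, "-")) <= ridge_halfwidth_nm
  if (!any(band)) {
    fq_abort("Excitation and emission grids do not overlap within the scatter band.", "domain")
  }
  idx <- which(band, arr.ind = TRUE)
  vals <- x$intensity[band]
  ord <- order(-vals, idx[, 1], idx[, 2])
  best <- ord[1]
  tibble::tibble(
    excitation_nm = x$excitation_nm[idx[best, 1]],
    emission_nm = x$emission_nm[idx[best, 2]],
    intensity = vals[best],
    kind = "rayleigh_first_order"
  )
}

# validate an emission scan tibble: wavelength_nm strictly increasing uniform
# step, >= 3 points, intensities >= 0
check_scan <- function(scan, what = "scan") {
  if (!is.data.frame(scan) || !all(c("wavelength_nm", "intensity") %in% names(scan))) {
    fq_abort(sprintf("%s must be a data frame with columns wavelength_nm and intensity.", what),
             "validation")
  }
  if (nrow(scan) < 3L) {
    fq_abort(sprintf("%s must have >= 3 grid points.", what), "validation")
  }
  check_grid(scan$wavelength_nm, paste0(what, "$wavelength_nm"))
  if (anyNA(scan$intensity) || any(scan$intensity < 0)) {
    fq_abort(sprintf("%s intensities must be non-missing and >= 0.", what), "validation")
  }
  invisible(scan)
}

#' Emission maximum of a scan
#'
#' @param scan A data frame with columns `wavelength_nm` (strictly increasing,
#'   uniform step, at least 3 points) and `intensity` (`>= 0`).
#' @return A one-row tibble with columns `emission_nm` and `intensity`: the
#'   wavelength of the global intensity maximum, ties broken toward the
#'   shorter wavelength. A perfectly flat scan returns the shortest
#'   wavelength with a warning.
#' @export
emission_maximum <- function(scan) {
  check_scan(scan)
  if (length(unique(scan$intensity)) == 1L) {
    fq_warn("All intensities equal; emission maximum defaults to the shortest wavelength.",
            "flat_scan")
  }
  i <- which.max(scan$intensity) # first hit = shortest wavelength on ties
  tibble::tibble(emission_nm = scan$wavelength_nm[i], intensity = scan$intensity[i])
}

#' Emission-maximum shift across a titration
#'
#' Signed shift (nm) of the emission maximum between the zero-quencher scan
#' and the scan at the highest quencher concentration. A negative value is a
#' blue shift, the signature of a less polar fluorophore microenvironment
#' upon ligand binding.
#'
#' @param data A titration tibble (see [fit_modified_stern_volmer()]) with a
#'   `scan` list-column holding one emission scan per concentration.
#' @return A single number: `emission_maximum(scan at max C) -
#'   emission_maximum(scan at C = 0)`, in nm.
#' @export
peak_shift <- function(data) {
  check_titration(data)
  if (!"scan" %in% names(data) || !is.list(data$scan)) {
    fq_abort(paste(
      "This series carries scalar intensities only (no `scan` list-column);",
      "peak_shift needs full emission scans. Use the scalar pipeline",
      "(fit_modified_stern_volmer / fit_lineweaver_burk) instead."
    ), "capability")
  }
  s0 <- data$scan[[which(data$conc_mol_per_l == 0)]]
  s1 <- data$scan[[which.max(data$conc_mol_per_l)]]
  if (is.null(s0) || is.null(s1)) {
    fq_abort("Scans must be present at C = 0 and at the largest concentration.", "capability")
  }
  emission_maximum(s1)$emission_nm - emission_maximum(s0)$emission_nm
}
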