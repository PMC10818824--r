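#' Excitation-emission matrix (EEM) objects
#'
#' An `eem` is a fluorescence landscape: intensity measured on a rectangular
#' grid of excitation wavelengths (rows) by emission wavelengths (columns).
#' Both wavelength grids must be strictly increasing with a uniform step, and
#' intensities must be non-negative.
#'
#' @param excitation_nm Numeric vector of excitation wavelengths (nm),
#'   strictly increasing, uniform step.
#' @param emission_nm Numeric vector of emission wavelengths (nm), strictly
#'   increasing, uniform step.
#' @param intensity Numeric matrix of fluorescence intensities (arbitrary
#'   units), dimensions `length(excitation_nm)` x `length(emission_nm)`,
#'   all values `>= 0`.
#'
#' @return An object of class `eem`: a list with elements `excitation_nm`,
#'   `emission_nm` and `intensity`.
#' @examples
#' e <- eem(c(200, 205, 210), c(270, 275, 280), matrix(0, 3, 3))
#' e
#' @export
eem <- function(excitation_nm, emission_nm, intensity) {
  check_grid(excitation_nm, "excitation_nm")
  check_grid(emission_nm, "emission_nm")
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    fq_abort("`intensity` must be a numeric matrix.", "validation")
  }
  if (!identical(dim(intensity), c(length(excitation_nm), length(emission_nm)))) {
    fq_abort(
      sprintf(
        "`intensity` must be %d x %d (excitation x emission); got %d x %d.",
        length(excitation_nm), length(emission_nm), nrow(intensity), ncol(intensity)
      ),
      "validation"
    )
  }
  if (anyNA(intensity) || any(intensity < 0)) {
    fq_abort("All EEM intensities must be non-missing and >= 0.", "validation")
  }
  structure(
    list(
      excitation_nm = as.numeric(excitation_nm),
      emission_nm = as.numeric(emission_nm),
      intensity = unname(intensity)
    ),
    class = "eem"
  )
}

# strictly increasing, uniform step, >= 2 points
check_grid <- function(grid, name) {
  if (!is.numeric(grid) || length(grid) < 2L || anyNA(grid)) {
    fq_abort(sprintf("`%s` must be a numeric grid with >= 2 points.", name), "format")
  }
  steps <- diff(grid)
  if (any(steps <= 0)) {
    fq_abort(
      sprintf("`%s` must be strictly increasing (violation at position %d).",
              name, which(steps <= 0)[1] + 1L),
      "format"
    )
  }
  if (max(steps) - min(steps) > 1e-8 * max(steps)) {
    fq_abort(
      sprintf("`%s` must have a uniform step (irregular step at position %d).",
              name, which.max(abs(steps - steps[1])) + 1L),
      "format"
    )
  }
  invisible(grid)
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf(
    "<eem> %d x %d grid | excitation %g-%g nm | emission %g-%g nm | max intensity %.4g\n",
    length(x$excitation_nm), length(x$emission_nm),
    min(x$excitation_nm), max(x$excitation_nm),
    min(x$emission_nm), max(x$emission_nm),
    max(x$intensity)
  ))
  invisible(x)
}

#' @export
as.data.frame.eem <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' Convert an EEM to a long tibble
#'
#' @param x An [eem()] object.
#' @param ... Unused.
#' @return A tibble with columns `excitation_nm`, `emission_nm`, `intensity`,
#'   one row per grid cell.
#' @exportS3Method tibble::as_tibble
as_tibble.eem <- function(x, ...) {
  tibble::tibble(
    excitation_nm = rep(x$excitation_nm, times = length(x$emission_nm)),
    emission_nm = rep(x$emission_nm, each = length(x$excitation_nm)),
    intensity = as.vector(x$intensity)
  )
}

#' Read an EEM from a CSV grid
#'
#' Expects the documented grid layout: row 1 holds the emission wavelengths
#' (cell 1,1 blank or arbitrary), column 1 holds the excitation wavelengths,
#' and the body holds intensities. Decimal separator is always the dot,
#' independent of locale; lines starting with `#` (metadata headers written by
#' [write_eem()]) are skipped.
#'
#' @param path Path to a CSV file.
#' @return An [eem()] object.
#' @seealso [write_eem()]
#' @export
read_eem <- function(path) {
  if (!file.exists(path)) {
    fq_abort(sprintf("File not found: %s", path), "format")
  }
  raw <- utils::read.csv(path, header = FALSE, comment.char = "#",
                         colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    fq_abort("EEM CSV must have at least 2 rows and 2 columns.", "format")
  }
  num <- function(v, where) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad) > 0 || anyNA(out)) {
      fq_abort(sprintf("Non-numeric value in %s of EEM CSV.", where), "format")
    }
    out
  }
  emission <- num(unlist(raw[1, -1], use.names = FALSE), "header row (emission grid)")
  excitation <- num(raw[-1, 1], "first column (excitation grid)")
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  intensity <- matrix(num(body, "intensity body"), nrow = length(excitation))
  eem(excitation, emission, intensity)
}

#' Write an EEM to a CSV grid
#'
#' Inverse of [read_eem()]; the round trip is lossless (values are written
#' with 17 significant digits). An optional metadata header is written as
#' `#`-prefixed comment lines.
#'
#' @param x An [eem()] object.
#' @param path Output file path.
#' @param metadata Optional named list written as `# name: value` header lines
#'   (e.g. the generator seed).
#' @return `path`, invisibly.
#' @export
write_eem <- function(x, path, metadata = NULL) {
  stopifnot(inherits(x, "eem"))
  fmt <- function(v) sprintf("%.17g", v)
  lines <- character(0)
  if (!is.null(metadata)) {
    lines <- sprintf("# %s: %s", names(metadata), vapply(metadata, format, ""))
  }
  lines <- c(lines, paste(c("", fmt(x$emission_nm)), collapse = ","))
  for (i in seq_along(x$excitation_nm)) {
    lines <- c(lines, paste(c(fmt(x$excitation_nm[i]), fmt(x$intensity[i, ])), collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Heatmap of an EEM
#'
#' @param object An [eem()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eem <- function(object, ...) {
  tibble::as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$emission_nm, .data$excitation_nm,
                                 fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "emission (nm)", y = "excitation (nm)") +
    ggplot2::theme_minimal()
}
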