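#' Fit the modified Stern-Volmer quenching model
#'
#' Fluorescence quenching of a protein by a ligand at concentration C is
#' analysed on modified Stern-Volmer coordinates: the transformed response
#' `y = F0/(F0 - F)` is regressed on `x = 1/C`, so that
#' `y = 1/(Ksv' fa) * (1/C) + 1/fa`. The intercept gives the accessible
#' fluorophore fraction `fa = 1/intercept`, the slope and intercept give the
#' effective quenching constant `Ksv' = intercept/slope` (L/mol), and the
#' bimolecular quenching rate constant is `Kq = Ksv'/tau0`.
#'
#' The C = 0 point only defines F0 (1/C is undefined there), and points with
#' `F >= F0` carry no quench signal on these coordinates; both are excluded
#' from the regression, the latter with a warning. An accessible fraction
#' above 1 is algebraically possible on noisy intercepts and is reported
#' as-is with a warning rather than constrained.
#'
#' @param data A titration tibble; see [check_titration()] for the contract.
#' @param tau0 Unquenched fluorophore lifetime in seconds; default `1e-8` s,
#'   the customary average fluorescence lifetime of biomolecules.
#' @return An object of class `sv_fit`. Use [glance()] for a one-row summary
#'   (slope, intercept, R^2, `fa`, `ksv_prime`, `kq`, ...), [tidy()] for
#'   term-level output and [autoplot()] for the diagnostic plot.
#' @examples
#' ser <- simulate_titration_sv(titration_sim_config(
#'   model = "modified_sv", f0 = 1000, fa = 0.8, ksv = 1500,
#'   noise_sigma = 0, seed = 1
#' ))
#' glance(fit_modified_stern_volmer(ser))
#' @export
fit_modified_stern_volmer <- function(data, tau0 = 1e-8) {
  check_titration(data)
  check_number(tau0, "tau0", positive = TRUE)
  f0 <- titration_f0(data)
  pts <- data[data$conc_mol_per_l > 0, , drop = FALSE]
  usable <- pts$intensity < f0
  if (any(!usable)) {
    fq_warn(sprintf(
      "%d point(s) with F >= F0 excluded from the modified Stern-Volmer fit (C = %s).",
      sum(!usable), paste(signif(pts$conc_mol_per_l[!usable], 4), collapse = ", ")
    ), "points_dropped")
  }
  kept <- pts[usable, , drop = FALSE]
  if (nrow(kept) < 3L) {
    fq_abort(sprintf(
      "Only %d usable point(s) (C > 0 and F < F0); at least 3 are required.", nrow(kept)
    ), "insufficient_data")
  }
  line <- ols_line(1 / kept$conc_mol_per_l, f0 / (f0 - kept$intensity))
  if (line$slope <= 0 || line$intercept <= 0) {
    fq_abort(sprintf(
      "Fitted slope (%.4g) and intercept (%.4g) must both be positive; the quenching model is violated.",
      line$slope, line$intercept
    ), "fit_invalid")
  }
  con <- derive_sv_constants(line$slope, line$intercept, tau0)
  out <- structure(
    list(
      ligand_id = if ("ligand_id" %in% names(data)) data$ligand_id[1] else NA_character_,
      slope = line$slope,
      intercept = line$intercept,
      r_squared = line$r_squared,
      fa = con$fa,
      ksv_prime = con$ksv_prime,
      tau0 = tau0,
      kq = con$kq,
      n_points_used = line$n_points,
      n_points_dropped = sum(!usable),
      f0 = f0,
      points = tibble::tibble(
        conc_mol_per_l = kept$conc_mol_per_l,
        inv_conc = 1 / kept$conc_mol_per_l,
        f0_over_df = f0 / (f0 - kept$intensity)
      )
    ),
    class = "sv_fit"
  )
  # construction-time algebraic consistency checks
  stopifnot(
    abs(out$kq * out$tau0 * out$slope - out$intercept) <= 1e-9 * abs(out$intercept),
    abs(out$fa * out$intercept - 1) <= 1e-9
  )
  out
}

#' Derive quenching constants from a modified Stern-Volmer line
#'
#' @param slope Fitted slope on `F0/(F0-F)` vs `1/C` coordinates (mol/L).
#' @param intercept Fitted intercept (dimensionless).
#' @param tau0 Unquenched lifetime (s); default `1e-8`.
#' @return A one-row tibble with `fa` (accessible fraction, `1/intercept`),
#'   `ksv_prime` (L/mol, `intercept/slope`) and `kq` (L/(mol s),
#'   `ksv_prime/tau0`).
#' @examples
#' derive_sv_constants(0.0005035, 0.635) # Kq ~ 1.26e11 L/(mol s)
#' @export
derive_sv_constants <- function(slope, intercept, tau0 = 1e-8) {
  check_number(slope, "slope", positive = TRUE)
  check_number(intercept, "intercept", positive = TRUE)
  check_number(tau0, "tau0", positive = TRUE)
  fa <- 1 / intercept
  if (fa > 1) {
    fq_warn(sprintf(
      "Accessible fraction fa = %.4g exceeds 1; reported unconstrained.", fa
    ), "fa_above_one")
  }
  ksv_prime <- intercept / slope
  tibble::tibble(fa = fa, ksv_prime = ksv_prime, kq = ksv_prime / tau0)
}

#' Fit the double-logarithmic (Lineweaver-Burk style) binding isotherm
#'
#' For independent binding of a small molecule to a set of equivalent sites,
#' `lg((F0 - F)/F) = lg KA + n lg C`: a straight line on double-logarithmic
#' coordinates whose slope is the apparent number of binding sites `n` and
#' whose intercept is `lg KA`, the base-10 log of the binding constant.
#' Point exclusion follows [fit_modified_stern_volmer()].
#'
#' @inheritParams fit_modified_stern_volmer
#' @return An object of class `lb_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods; `glance()` reports `n_sites`, `lg_ka`,
#'   `ka = 10^lg_ka` (nominal L/mol) and `r_squared`.
#' @examples
#' ser <- simulate_titration_lb(titration_sim_config(
#'   model = "lineweaver_burk", f0 = 1000, ka = 394.639, n_sites = 0.8694,
#'   noise_sigma = 0, seed = 1
#' ))
#' glance(fit_lineweaver_burk(ser))
#' @export
fit_lineweaver_burk <- function(data) {
  check_titration(data)
  f0 <- titration_f0(data)
  pts <- data[data$conc_mol_per_l > 0, , drop = FALSE]
  usable <- pts$intensity < f0
  if (any(!usable)) {
    fq_warn(sprintf(
      "%d point(s) with F >= F0 excluded from the double-log binding fit (C = %s).",
      sum(!usable), paste(signif(pts$conc_mol_per_l[!usable], 4), collapse = ", ")
    ), "points_dropped")
  }
  kept <- pts[usable, , drop = FALSE]
  if (nrow(kept) < 3L) {
    fq_abort(sprintf(
      "Only %d usable point(s) (C > 0 and F < F0); at least 3 are required.", nrow(kept)
    ), "insufficient_data")
  }
  line <- ols_line(log10(kept$conc_mol_per_l),
                   log10((f0 - kept$intensity) / kept$intensity))
  out <- structure(
    list(
      ligand_id = if ("ligand_id" %in% names(data)) data$ligand_id[1] else NA_character_,
      n_sites = line$slope,
      lg_ka = line$intercept,
      ka = 10^line$intercept,
      r_squared = line$r_squared,
      n_points_used = line$n_points,
      n_points_dropped = sum(!usable),
      f0 = f0,
      points = tibble::tibble(
        conc_mol_per_l = kept$conc_mol_per_l,
        lg_conc = log10(kept$conc_mol_per_l),
        lg_df_over_f = log10((f0 - kept$intensity) / kept$intensity)
      )
    ),
    class = "lb_fit"
  )
  stopifnot(abs(out$ka - 10^out$lg_ka) <= 1e-12 * out$ka)
  out
}

#' Classify the quenching mechanism from the bimolecular rate constant
#'
#' Diffusion-limited collisional (dynamic) quenching of biopolymers cannot
#' exceed a maximum scatter-collision rate constant of about
#' `2.0e10 L/(mol s)`; a fitted `Kq` strictly above that limit indicates
#' ground-state complex formation, i.e. static quenching.
#'
#' @param kq Bimolecular quenching rate constant(s), L/(mol s), all `> 0`.
#' @param threshold Diffusion-limit threshold, L/(mol s); default `2.0e10`.
#' @return A character vector: `"static"` where `kq > threshold` (strict),
#'   else `"dynamic_consistent"`.
#' @examples
#' classify_quenching(c(1.26e11, 2e10, 1e9))
#' @export
classify_quenching <- function(kq, threshold = 2.0e10) {
  if (!is.numeric(kq) || length(kq) == 0 || anyNA(kq) || any(kq <= 0)) {
    fq_abort("`kq` must be positive and non-missing.", "domain")
  }
  check_number(threshold, "threshold", positive = TRUE)
  ifelse(kq > threshold, "static", "dynamic_consistent")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("<sv_fit> %s\n", if (is.na(x$ligand_id)) "(unnamed ligand)" else x$ligand_id))
  cat(sprintf("  y = %.6g x + %.6g   (R^2 = %.4f, n = %d, dropped = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points_used, x$n_points_dropped))
  cat(sprintf("  fa = %.4g | Ksv' = %.4g L/mol | Kq = %.3g L/(mol s) [tau0 = %g s]\n",
              x$fa, x$ksv_prime, x$kq, x$tau0))
  invisible(x)
}

#' @export
print.lb_fit <- function(x, ...) {
  cat(sprintf("<lb_fit> %s\n", if (is.na(x$ligand_id)) "(unnamed ligand)" else x$ligand_id))
  cat(sprintf("  y = %.6g x + %.6g   (R^2 = %.4f, n = %d, dropped = %d)\n",
              x$n_sites, x$lg_ka, x$r_squared, x$n_points_used, x$n_points_dropped))
  cat(sprintf("  KA = %.4f L/mol | n = %.4f binding sites\n", x$ka, x$n_sites))
  invisible(x)
}

#' @export
tidy.sv_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept)
  )
}

#' @export
tidy.lb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n_sites", "lg_ka"),
    estimate = c(x$n_sites, x$lg_ka)
  )
}

#' @export
glance.sv_fit <- function(x, ...) {
  tibble::tibble(
    ligand_id = x$ligand_id,
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    fa = x$fa, ksv_prime = x$ksv_prime, tau0 = x$tau0, kq = x$kq,
    mechanism = classify_quenching(x$kq),
    n_points_used = x$n_points_used, n_points_dropped = x$n_points_dropped
  )
}

#' @export
glance.lb_fit <- function(x, ...) {
  tibble::tibble(
    ligand_id = x$ligand_id,
    n_sites = x$n_sites, lg_ka = x$lg_ka, ka = x$ka, r_squared = x$r_squared,
    n_points_used = x$n_points_used, n_points_dropped = x$n_points_dropped
  )
}

#' @export
autoplot.sv_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$inv_conc, .data$f0_over_df)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "1/C (L/mol)", y = expression(F[0] / (F[0] - F)),
      title = object$ligand_id,
      subtitle = sprintf("y = %.4gx + %.4g, R² = %.4f",
                         object$slope, object$intercept, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lb_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$lg_conc, .data$lg_df_over_f)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$n_sites, intercept = object$lg_ka,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "lg C", y = expression(lg((F[0] - F) / F)),
      title = object$ligand_id,
      subtitle = sprintf("KA = %.4f, n = %.4f, R² = %.4f",
                         object$ka, object$n_sites, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
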