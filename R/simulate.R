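#' Concentrations after volume mixing
#'
#' Final molar concentrations when `v_protein` mL of protein stock is mixed
#' with `v_ligand` mL of ligand stock: `c = stock * v / (v_protein +
#' v_ligand)` for each species. This converts the volume ratios a titration
#' protocol states (e.g. protein:ligand 5:0, 5:1, 5:5, ...) into the molar
#' ladders the fits consume.
#'
#' @param v_protein,v_ligand Volumes mixed (mL), `>= 0`, not both zero;
#'   `v_ligand` may be a vector.
#' @param stock_protein,stock_ligand Stock concentrations (mol/L), `> 0`.
#' @return A tibble with columns `v_protein`, `v_ligand`,
#'   `protein_mol_per_l` and `ligand_mol_per_l`.
#' @examples
#' mixing_concentrations(5, c(0, 1, 5), 1e-3, 1e-3)
#' @export
mixing_concentrations <- function(v_protein, v_ligand,
                                  stock_protein = 1e-3, stock_ligand = 1e-3) {
  check_number(v_protein, "v_protein")
  check_number(stock_protein, "stock_protein", positive = TRUE)
  check_number(stock_ligand, "stock_ligand", positive = TRUE)
  if (!is.numeric(v_ligand) || anyNA(v_ligand) || any(v_ligand < 0) || v_protein < 0) {
    fq_abort("Volumes must be non-negative numbers.", "domain")
  }
  total <- v_protein + v_ligand
  if (any(total == 0)) {
    fq_abort("Total mixed volume must be > 0.", "domain")
  }
  tibble::tibble(
    v_protein = v_protein,
    v_ligand = v_ligand,
    protein_mol_per_l = stock_protein * v_protein / total,
    ligand_mol_per_l = stock_ligand * v_ligand / total
  )
}

#' Default ligand concentration ladder
#'
#' The molar ligand concentrations obtained by mixing 5 mL of protein stock
#' with 0, 1, 5, 10, 15, 20 and 30 mL of ligand stock, both stocks at
#' `1e-3` mol/L — the protein:ligand volume ratios 5:0 through 5:30 of a
#' standard quenching titration. The first entry is 0 (defines F0).
#'
#' @param stock_mol_per_l Common stock concentration (mol/L); default `1e-3`.
#' @return Numeric vector of 7 ligand concentrations (mol/L), starting at 0,
#'   strictly increasing.
#' @export
default_conc_ladder <- function(stock_mol_per_l = 1e-3) {
  mixing_concentrations(5, c(0, 1, 5, 10, 15, 20, 30),
                        stock_protein = stock_mol_per_l,
                        stock_ligand = stock_mol_per_l)$ligand_mol_per_l
}

#' Titration simulation configuration
#'
#' @param model `"modified_sv"` (accessible-fraction static quenching:
#'   `F(C) = F0 (1 - fa Ksv C / (1 + Ksv C))`) or `"lineweaver_burk"`
#'   (equivalent-sites isotherm: `F(C) = F0 / (1 + KA C^n)`).
#' @param f0 Unquenched intensity, `> 0`.
#' @param fa,ksv Accessible fraction and quenching constant (L/mol); required
#'   for `model = "modified_sv"`, both `> 0`.
#' @param ka,n_sites Binding constant (nominal L/mol) and site number;
#'   required for `model = "lineweaver_burk"`, both `> 0`.
#' @param conc_ladder Ligand concentrations (mol/L), starting at 0 then
#'   strictly increasing; default [default_conc_ladder()].
#' @param noise_sigma Relative standard deviation of the seeded Gaussian
#'   noise, `>= 0`; default 0.01 (the true instrument noise is not known, so
#'   the default is a nominal 1 percent).
#' @param noise_type `"multiplicative"` (`F * (1 + eps)`, fluorescence
#'   shot/gain approximation, the default) or `"additive"`
#'   (`F + F0 * eps`).
#' @param seed Integer RNG seed; every generator is a deterministic function
#'   of its configuration including the seed.
#' @param ligand_id Label written into the generated series.
#' @return A validated list of class `titration_sim_config`.
#' @export
titration_sim_config <- function(model = c("modified_sv", "lineweaver_burk"),
                                 f0 = 1000, fa = NULL, ksv = NULL,
                                 ka = NULL, n_sites = NULL,
                                 conc_ladder = default_conc_ladder(),
                                 noise_sigma = 0.01,
                                 noise_type = c("multiplicative", "additive"),
                                 seed, ligand_id = "synthetic") {
  model <- match.arg(model)
  noise_type <- match.arg(noise_type)
  check_number(f0, "f0", positive = TRUE)
  if (model == "modified_sv") {
    check_number(fa %||% NA_real_, "fa", positive = TRUE)
    check_number(ksv %||% NA_real_, "ksv", positive = TRUE)
  } else {
    check_number(ka %||% NA_real_, "ka", positive = TRUE)
    check_number(n_sites %||% NA_real_, "n_sites", positive = TRUE)
  }
  if (!is.numeric(conc_ladder) || length(conc_ladder) < 2L ||
      conc_ladder[1] != 0 || any(diff(conc_ladder) <= 0)) {
    fq_abort("`conc_ladder` must start at 0 and then be strictly increasing.", "config")
  }
  check_number(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) fq_abort("`noise_sigma` must be >= 0.", "config")
  if (missing(seed)) fq_abort("`seed` is required: generators are seed-deterministic.", "config")
  check_number(seed, "seed")
  structure(
    list(model = model, f0 = f0, fa = fa, ksv = ksv, ka = ka, n_sites = n_sites,
         conc_ladder = as.numeric(conc_ladder), noise_sigma = noise_sigma,
         noise_type = noise_type, seed = as.integer(seed), ligand_id = ligand_id),
    class = "titration_sim_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private, seeded RNG stream; global RNG state untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

apply_noise <- function(f_mean, config) {
  if (config$noise_sigma == 0) return(f_mean)
  with_seed(config$seed, {
    eps <- stats::rnorm(length(f_mean), 0, config$noise_sigma)
    f <- switch(config$noise_type,
      multiplicative = f_mean * (1 + eps),
      additive = f_mean + config$f0 * eps
    )
    # fluorescence readouts are positive; floor far below signal level
    pmax(f, 1e-9 * config$f0)
  })
}

#' Simulate a titration under the modified Stern-Volmer model
#'
#' Noiseless mean `F(C) = F0 (1 - fa Ksv C / (1 + Ksv C))` for `C > 0` and
#' `F(0) = F0`, then seeded noise per the configuration. With
#' `noise_sigma = 0` the transformed points satisfy the modified
#' Stern-Volmer line exactly, so fitting recovers `(fa, Ksv)` to numerical
#' precision.
#'
#' @param config A [titration_sim_config()] with `model = "modified_sv"`.
#' @return A titration tibble (`ligand_id`, `conc_mol_per_l`, `intensity`)
#'   with the configuration attached as attribute `"sim_config"`.
#' @export
simulate_titration_sv <- function(config) {
  stopifnot(inherits(config, "titration_sim_config"))
  if (config$model != "modified_sv") {
    fq_abort('`config$model` must be "modified_sv" for simulate_titration_sv().', "config")
  }
  cc <- config$conc_ladder
  quench <- config$fa * config$ksv * cc / (1 + config$ksv * cc)
  if (any(quench >= 1)) {
    fq_abort(paste(
      "fa * Ksv * C / (1 + Ksv C) >= 1 at some ladder point: the mean intensity",
      "would be non-positive. Reduce fa, Ksv or the top concentration."
    ), "config")
  }
  f_mean <- config$f0 * (1 - quench)
  out <- tibble::tibble(
    ligand_id = config$ligand_id,
    conc_mol_per_l = cc,
    intensity = apply_noise(f_mean, config)
  )
  attr(out, "sim_config") <- config
  check_titration(out)
  out
}

#' Simulate a titration under the equivalent-sites binding isotherm
#'
#' Noiseless mean `F(C) = F0 / (1 + KA C^n)` for `C > 0` and `F(0) = F0`,
#' then seeded noise. With `noise_sigma = 0`, `lg((F0-F)/F) = lg KA +
#' n lg C` holds exactly and [fit_lineweaver_burk()] recovers `(KA, n)` to
#' numerical precision.
#'
#' @param config A [titration_sim_config()] with `model = "lineweaver_burk"`.
#' @inherit simulate_titration_sv return
#' @export
simulate_titration_lb <- function(config) {
  stopifnot(inherits(config, "titration_sim_config"))
  if (config$model != "lineweaver_burk") {
    fq_abort('`config$model` must be "lineweaver_burk" for simulate_titration_lb().', "config")
  }
  cc <- config$conc_ladder
  f_mean <- ifelse(cc == 0, config$f0,
                   config$f0 / (1 + config$ka * cc^config$n_sites))
  out <- tibble::tibble(
    ligand_id = config$ligand_id,
    conc_mol_per_l = cc,
    intensity = apply_noise(f_mean, config)
  )
  attr(out, "sim_config") <- config
  check_titration(out)
  out
}

#' Simulate a titration with full emission scans
#'
#' Builds the scalar series for the configured model, then attaches one
#' Gaussian emission scan per concentration. Each scan has peak height equal
#' to that point's intensity and centre
#' `peak0_nm + peak_shift_total_nm * (1 - F/F0) / (1 - F_top/F0)`, where
#' `F/F0` uses the noiseless means and `F_top` is the mean at the highest
#' concentration — i.e. the emission maximum moves linearly in the quenched
#' fraction, from `peak0_nm` at C = 0 to `peak0_nm + peak_shift_total_nm` at
#' the top of the ladder (default 335 nm shifting blue to 310 nm).
#'
#' @param config A [titration_sim_config()].
#' @param peak0_nm Emission maximum at C = 0 (nm); default 335.
#' @param peak_shift_total_nm Total signed shift at the top concentration
#'   (nm); default -25 (blue shift).
#' @param peak_width_nm Gaussian sigma of each scan (nm), `> 0`; default 20.
#' @param emission_grid_nm Scan wavelength grid; default 285-430 nm in 5-nm
#'   steps.
#' @return A titration tibble with an additional `scan` list-column; the
#'   scalar `intensity` equals each scan's maximum (centres are snapped to
#'   the sampling grid, so the sampled and true maxima coincide).
#' @export
simulate_titration_scans <- function(config, peak0_nm = 335,
                                     peak_shift_total_nm = -25,
                                     peak_width_nm = 20,
                                     emission_grid_nm = seq(285, 430, by = 5)) {
  stopifnot(inherits(config, "titration_sim_config"))
  check_number(peak0_nm, "peak0_nm", positive = TRUE)
  check_number(peak_shift_total_nm, "peak_shift_total_nm")
  check_number(peak_width_nm, "peak_width_nm")
  if (peak_width_nm <= 0) fq_abort("`peak_width_nm` must be > 0.", "domain")
  check_grid(emission_grid_nm, "emission_grid_nm")

  base <- if (config$model == "modified_sv") {
    simulate_titration_sv(config)
  } else {
    simulate_titration_lb(config)
  }
  noiseless <- titration_sim_config(
    model = config$model, f0 = config$f0, fa = config$fa, ksv = config$ksv,
    ka = config$ka, n_sites = config$n_sites, conc_ladder = config$conc_ladder,
    noise_sigma = 0, seed = config$seed, ligand_id = config$ligand_id
  )
  f_mean <- if (config$model == "modified_sv") {
    simulate_titration_sv(noiseless)$intensity
  } else {
    simulate_titration_lb(noiseless)$intensity
  }
  q_frac <- 1 - f_mean / config$f0
  q_top <- q_frac[which.max(config$conc_ladder)]
  if (q_top <= 0) {
    centers <- rep(peak0_nm, length(q_frac))
  } else {
    centers <- peak0_nm + peak_shift_total_nm * q_frac / q_top
  }
  # centres snap to the sampling grid (the instrument reads at grid steps),
  # so each scan's sampled maximum equals its peak height exactly
  centers <- vapply(centers, function(ctr) {
    emission_grid_nm[which.min(abs(emission_grid_nm - ctr))]
  }, 0)
  scans <- purrr::map2(base$intensity, centers, function(height, ctr) {
    tibble::tibble(
      wavelength_nm = emission_grid_nm,
      intensity = height * exp(-(emission_grid_nm - ctr)^2 / (2 * peak_width_nm^2))
    )
  })
  out <- dplyr::mutate(base, scan = scans)
  attr(out, "sim_config") <- config
  check_titration(out)
  out
}

#' EEM simulation configuration
#'
#' @param peaks Data frame of fluorescence peaks with columns `ex_center_nm`,
#'   `em_center_nm`, `amplitude` (`>= 0`), `width_ex_nm`, `width_em_nm`
#'   (Gaussian sigmas, `> 0`).
#' @param rayleigh_amplitude Peak amplitude of the first-order Rayleigh
#'   scatter ridge along the `ex = em` diagonal, `>= 0`.
#' @param rayleigh_width_nm Gaussian sigma of the ridge across the diagonal
#'   (nm), `> 0`.
#' @param rayleigh_center_nm Wavelength at which the ridge amplitude peaks
#'   along the diagonal (nm).
#' @param rayleigh_along_width_nm Gaussian sigma of the ridge profile along
#'   the diagonal (nm), `> 0`.
#' @param baseline_sigma Standard deviation of the non-negative (clipped at
#'   zero) additive Gaussian baseline noise, `>= 0`.
#' @param excitation_grid_nm,emission_grid_nm Wavelength grids; defaults
#'   200-340 nm and 270-460 nm in 5-nm steps.
#' @param seed Integer RNG seed.
#' @return A validated list of class `eem_sim_config`.
#' @seealso [hsa_eem_config()] for the serum-albumin preset.
#' @export
eem_sim_config <- function(peaks, rayleigh_amplitude = 0, rayleigh_width_nm = 8,
                           rayleigh_center_nm = 290, rayleigh_along_width_nm = 30,
                           baseline_sigma = 0,
                           excitation_grid_nm = seq(200, 340, by = 5),
                           emission_grid_nm = seq(270, 460, by = 5),
                           seed) {
  need <- c("ex_center_nm", "em_center_nm", "amplitude", "width_ex_nm", "width_em_nm")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks))) {
    fq_abort(sprintf("`peaks` must be a data frame with columns %s.",
                     paste(need, collapse = ", ")), "config")
  }
  if (any(peaks$amplitude < 0) || any(peaks$width_ex_nm <= 0) || any(peaks$width_em_nm <= 0)) {
    fq_abort("Peak amplitudes must be >= 0 and widths > 0.", "config")
  }
  if (rayleigh_amplitude < 0) fq_abort("`rayleigh_amplitude` must be >= 0.", "config")
  check_number(rayleigh_width_nm, "rayleigh_width_nm", positive = TRUE)
  check_number(rayleigh_along_width_nm, "rayleigh_along_width_nm", positive = TRUE)
  if (baseline_sigma < 0) fq_abort("`baseline_sigma` must be >= 0.", "config")
  check_grid(excitation_grid_nm, "excitation_grid_nm")
  check_grid(emission_grid_nm, "emission_grid_nm")
  if (missing(seed)) fq_abort("`seed` is required: generators are seed-deterministic.", "config")
  structure(
    list(peaks = tibble::as_tibble(peaks),
         rayleigh_amplitude = rayleigh_amplitude,
         rayleigh_width_nm = rayleigh_width_nm,
         rayleigh_center_nm = rayleigh_center_nm,
         rayleigh_along_width_nm = rayleigh_along_width_nm,
         baseline_sigma = baseline_sigma,
         excitation_grid_nm = as.numeric(excitation_grid_nm),
         emission_grid_nm = as.numeric(emission_grid_nm),
         seed = as.integer(seed)),
    class = "eem_sim_config"
  )
}

#' Serum-albumin-like EEM preset
#'
#' Two fluorescence peaks — the polypeptide-backbone peak at excitation
#' 235 nm / emission 325 nm (amplitude 362.3) and the tryptophan/tyrosine
#' peak at excitation 280 nm / emission 335 nm (amplitude 1803) — plus a
#' first-order Rayleigh ridge peaking at 290 nm with amplitude 1058, on the
#' standard 200-340 x 270-460 nm grids. Gaussian widths (sigma 8 nm in
#' excitation, 12 nm in emission, ridge cross-width 8 nm) are narrow enough
#' that the three intensities are separable on the 5-nm grid.
#'
#' @param baseline_sigma,seed Passed to [eem_sim_config()].
#' @return An `eem_sim_config`.
#' @export
hsa_eem_config <- function(baseline_sigma = 0, seed = 1) {
  eem_sim_config(
    peaks = tibble::tibble(
      ex_center_nm = c(235, 280),
      em_center_nm = c(325, 335),
      amplitude = c(362.3, 1803),
      width_ex_nm = c(8, 8),
      width_em_nm = c(12, 12)
    ),
    rayleigh_amplitude = 1058,
    rayleigh_width_nm = 8,
    rayleigh_center_nm = 290,
    rayleigh_along_width_nm = 30,
    baseline_sigma = baseline_sigma,
    seed = seed
  )
}

#' Simulate an excitation-emission matrix
#'
#' Sum of separable Gaussian fluorescence peaks plus a Gaussian first-order
#' Rayleigh ridge along the `ex = em` diagonal (with its own amplitude
#' profile along the diagonal), plus non-negative clipped Gaussian baseline
#' noise, seeded.
#'
#' @param config An [eem_sim_config()].
#' @return An [eem()] object with the configuration attached as attribute
#'   `"sim_config"`.
#' @export
simulate_eem <- function(config) {
  stopifnot(inherits(config, "eem_sim_config"))
  ex <- config$excitation_grid_nm
  em <- config$emission_grid_nm
  m <- matrix(0, length(ex), length(em))
  for (i in seq_len(nrow(config$peaks))) {
    p <- config$peaks[i, ]
    m <- m + p$amplitude *
      outer(exp(-(ex - p$ex_center_nm)^2 / (2 * p$width_ex_nm^2)),
            exp(-(em - p$em_center_nm)^2 / (2 * p$width_em_nm^2)))
  }
  if (config$rayleigh_amplitude > 0) {
    cross <- outer(ex, em, "-")
    along <- outer(ex, em, "+") / 2 - config$rayleigh_center_nm
    m <- m + config$rayleigh_amplitude *
      exp(-cross^2 / (2 * config$rayleigh_width_nm^2)) *
      exp(-along^2 / (2 * config$rayleigh_along_width_nm^2))
  }
  if (config$baseline_sigma > 0) {
    noise <- with_seed(config$seed,
                       stats::rnorm(length(m), 0, config$baseline_sigma))
    m <- m + pmax(noise, 0)
  }
  out <- eem(ex, em, m)
  attr(out, "sim_config") <- config
  out
}
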