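#' Compound metadata for the ten reference PFAS ligands
#'
#' The ten per- and polyfluoroalkyl substances of the published HSA
#' quenching study this package's reference tables come from: three legacy
#' long-chain compounds (PFOA, PFOS, PFHxS), three short-chain alternatives
#' (PFPrS, PFBS, PFBA) and four novel alternatives (9Cl-PF3ONS,
#' 11Cl-PF3OUdS, HFPO-DA, NaDONA).
#'
#' @return A tibble with columns `ligand_id`, `family` (PFSA, PFCA,
#'   Cl-PFESA or ether-PFCA), `chain_class` (legacy_long, short_alternative
#'   or novel_alternative) and `perfluorinated_carbon_count`.
#' @export
pfas_compounds <- function() {
  tibble::tribble(
    ~ligand_id,      ~family,      ~chain_class,          ~perfluorinated_carbon_count,
    "PFOA",          "PFCA",       "legacy_long",         7L,
    "PFOS",          "PFSA",       "legacy_long",         8L,
    "PFHxS",         "PFSA",       "legacy_long",         6L,
    "PFPrS",         "PFSA",       "short_alternative",   3L,
    "PFBS",          "PFSA",       "short_alternative",   4L,
    "PFBA",          "PFCA",       "short_alternative",   3L,
    "9Cl-PF3ONS",    "Cl-PFESA",   "novel_alternative",   8L,
    "11Cl-PF3OUdS",  "Cl-PFESA",   "novel_alternative",   10L,
    "HFPO-DA",       "ether-PFCA", "novel_alternative",   5L,
    "NaDONA",        "ether-PFCA", "novel_alternative",   7L
  )
}

#' Published modified Stern-Volmer coefficients
#'
#' Literature-reported fitted lines `y = slope * (1/C) + intercept` on
#' modified Stern-Volmer coordinates for the ten reference PFAS-HSA
#' titrations, with the reported R^2 and bimolecular quenching rate constant
#' (3 significant figures, tau0 = 1e-8 s).
#'
#' @return A tibble with columns `ligand_id`, `slope`, `intercept`,
#'   `r_squared`, `kq_reported`.
#' @export
reference_quenching_fits <- function() {
  tibble::tribble(
    ~ligand_id,      ~slope,    ~intercept, ~r_squared, ~kq_reported,
    "PFOA",          0.0005035, 0.635,      0.9996,     1.26e11,
    "PFOS",          0.0007969, 0.2456,     0.9977,     3.08e10,
    "PFHxS",         0.0005641, 0.4741,     0.9946,     8.40e10,
    "PFPrS",         0.0004813, 0.7054,     0.9977,     1.47e11,
    "PFBS",          0.0005327, 0.6013,     0.9989,     1.13e11,
    "PFBA",          0.0003302, 0.9979,     0.9985,     3.02e11,
    "9Cl-PF3ONS",    0.0006538, 0.7081,     0.9948,     1.08e11,
    "11Cl-PF3OUdS",  0.0005285, 0.6068,     0.9956,     1.15e11,
    "HFPO-DA",       0.0005095, 0.8051,     0.9945,     1.58e11,
    "NaDONA",        0.0005118, 0.6743,     0.9994,     1.32e11
  )
}

#' Published double-logarithmic binding coefficients
#'
#' Literature-reported fitted lines `y = n * lg C + lg KA` on
#' double-logarithmic binding coordinates for the ten reference PFAS-HSA
#' titrations, with the reported R^2, binding constant and site number.
#'
#' @return A tibble with columns `ligand_id`, `n_sites` (slope), `lg_ka`
#'   (intercept), `r_squared`, `ka_reported`.
#' @export
reference_binding_fits <- function() {
  tibble::tribble(
    ~ligand_id,      ~n_sites, ~lg_ka, ~r_squared, ~ka_reported,
    "PFOA",          0.6811,   2.0143, 0.9991,     103.3475,
    "PFOS",          0.8694,   2.5962, 0.9896,     394.639,
    "PFHxS",         0.7328,   2.1985, 0.9754,     157.9429,
    "PFPrS",         0.6487,   1.9001, 0.9939,     79.4511,
    "PFBS",          0.6986,   2.0663, 0.9931,     116.4930,
    "PFBA",          0.4692,   1.3089, 0.9792,     20.3657,
    "9Cl-PF3ONS",    0.7240,   2.0686, 0.9952,     117.112,
    "11Cl-PF3OUdS",  0.7102,   2.1059, 0.9966,     127.6145,
    "HFPO-DA",       0.6214,   1.7708, 0.9794,     58.9929,
    "NaDONA",        0.6718,   1.9689, 0.9982,     93.0894
  )
}

#' Published docking summary for the ten reference ligands
#'
#' Literature-reported Autodock Vina binding energies (kcal/mol, more
#' negative = more favourable), hydrogen-bond counts and contact residues
#' for the same ten PFAS docked against HSA. This table is ingested for rank
#' concordance only; the package never runs docking.
#'
#' @return A tibble with columns `ligand_id`, `binding_energy_kcal_mol`,
#'   `hydrogen_bonds`, `residues`.
#' @export
reference_docking <- function() {
  tibble::tribble(
    ~ligand_id,      ~binding_energy_kcal_mol, ~hydrogen_bonds, ~residues,
    "PFOA",          -7.6,                     1L,              "MET548",
    "PFOS",          -8.3,                     1L,              "ASN405",
    "PFHxS",         -7.5,                     2L,              "ASN405, TYR401",
    "PFBA",          -6.2,                     4L,              "ARG117",
    "PFBS",          -6.4,                     1L,              "LYS137",
    "PFPrS",         -6.2,                     2L,              "LEU14, ASN18",
    "NaDONA",        -7.3,                     1L,              "LEU155",
    "HFPO-DA",       -7.0,                     1L,              "SER287",
    "9Cl-PF3ONS",    -7.8,                     4L,              "ARG410, ALA406",
    "11Cl-PF3OUdS",  -7.9,                     3L,              "ARG410"
  )
}

#' Noiseless series reproducing a published fitted line
#'
#' Construct synthetic titrations whose transformed coordinates lie exactly
#' on a reported fitted line, so that re-fitting reproduces the published
#' constants: `series_from_sv_line()` inverts the modified Stern-Volmer
#' line (fa = 1/intercept, Ksv = intercept/slope) and
#' `series_from_lb_line()` inverts the double-logarithmic line
#' (KA = 10^intercept, n = slope).
#'
#' @param slope,intercept Reported line coefficients on the respective
#'   transformed coordinates.
#' @param f0 Unquenched intensity for the reconstruction; default 1000.
#' @param conc_ladder Concentration ladder (mol/L, first entry 0); default
#'   [default_conc_ladder()].
#' @param ligand_id Label for the generated series.
#' @return A titration tibble (see [check_titration()]).
#' @name series_from_line
NULL

#' @rdname series_from_line
#' @export
series_from_sv_line <- function(slope, intercept, f0 = 1000,
                                conc_ladder = default_conc_ladder(),
                                ligand_id = "synthetic") {
  cfg <- titration_sim_config(
    model = "modified_sv", f0 = f0,
    fa = 1 / intercept, ksv = intercept / slope,
    conc_ladder = conc_ladder, noise_sigma = 0, seed = 0L,
    ligand_id = ligand_id
  )
  simulate_titration_sv(cfg)
}

#' @rdname series_from_line
#' @export
series_from_lb_line <- function(slope, intercept, f0 = 1000,
                                conc_ladder = default_conc_ladder(),
                                ligand_id = "synthetic") {
  cfg <- titration_sim_config(
    model = "lineweaver_burk", f0 = f0,
    ka = 10^intercept, n_sites = slope,
    conc_ladder = conc_ladder, noise_sigma = 0, seed = 0L,
    ligand_id = ligand_id
  )
  simulate_titration_lb(cfg)
}
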