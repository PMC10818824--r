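test_that("mixing_concentrations follows volume dilution", {
  expect_equal(mixing_concentrations(5, 0, 1e-3, 1e-3)$ligand_mol_per_l, 0)
  expect_equal(mixing_concentrations(5, 0, 1e-3, 1e-3)$protein_mol_per_l, 1e-3)
  half <- mixing_concentrations(5, 5, 1e-3, 1e-3)
  expect_equal(half$protein_mol_per_l, 5e-4)
  expect_equal(half$ligand_mol_per_l, 5e-4)
  # 5 mL + 1 mL: hand arithmetic 1e-3 * 5/6 and 1e-3 * 1/6
  one <- mixing_concentrations(5, 1, 1e-3, 1e-3)
  expect_equal(one$protein_mol_per_l, 1e-3 * 5 / 6, tolerance = 1e-12)
  expect_equal(one$ligand_mol_per_l, 1e-3 * 1 / 6, tolerance = 1e-12)
  expect_error(mixing_concentrations(0, 0, 1e-3, 1e-3), class = "fq_error_domain")
})

test_that("the default ladder derives from the 5:0..5:30 volume ratios", {
  ladder <- default_conc_ladder()
  vols <- c(0, 1, 5, 10, 15, 20, 30)
  expect_equal(ladder, 1e-3 * vols / (5 + vols), tolerance = 1e-12)
  expect_equal(ladder[1], 0)
  expect_true(all(diff(ladder) > 0))
  expect_length(ladder, 7)
})

test_that("generators are deterministic in their seed and respect invariants", {
  cfg <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = 0.8,
                              ksv = 1500, noise_sigma = 0.05, seed = 11)
  expect_identical(simulate_titration_sv(cfg)$intensity,
                   simulate_titration_sv(cfg)$intensity)
  cfg2 <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = 0.8,
                               ksv = 1500, noise_sigma = 0.05, seed = 12)
  expect_false(identical(simulate_titration_sv(cfg)$intensity,
                         simulate_titration_sv(cfg2)$intensity))
  # generated output always passes the titration contract
  for (s in 1:10) {
    c3 <- titration_sim_config(model = "lineweaver_burk", f0 = 500, ka = 50,
                               n_sites = 0.6, noise_sigma = 0.1, seed = s)
    expect_silent(check_titration(simulate_titration_lb(c3)))
  }
  e1 <- simulate_eem(hsa_eem_config(baseline_sigma = 10, seed = 4))
  e2 <- simulate_eem(hsa_eem_config(baseline_sigma = 10, seed = 4))
  expect_identical(e1$intensity, e2$intensity)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(simulate_titration_sv(titration_sim_config(
    model = "modified_sv", f0 = 1000, fa = 0.5, ksv = 800,
    noise_sigma = 0.02, seed = 77
  )))
  expect_identical(rnorm(1), before)
})

test_that("null-effect configurations behave as limits", {
  # fa -> 0: no quenching, F = F0 everywhere (fa must stay > 0; use tiny)
  cfg <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = 1e-12,
                              ksv = 1500, noise_sigma = 0, seed = 1)
  expect_equal(simulate_titration_sv(cfg)$intensity, rep(1000, 7), tolerance = 1e-9)
  # ka -> 0: no binding
  cfg <- titration_sim_config(model = "lineweaver_burk", f0 = 1000, ka = 1e-12,
                              n_sites = 1, noise_sigma = 0, seed = 1)
  expect_equal(simulate_titration_lb(cfg)$intensity, rep(1000, 7), tolerance = 1e-9)
  # half-saturation: ka = 1, n = 1, C = 1 gives F0/2
  cfg <- titration_sim_config(model = "lineweaver_burk", f0 = 1000, ka = 1,
                              n_sites = 1, conc_ladder = c(0, 0.5, 1, 2),
                              noise_sigma = 0, seed = 1)
  ser <- simulate_titration_lb(cfg)
  expect_equal(ser$intensity[ser$conc_mol_per_l == 1], 500)
})

test_that("over-quenched configurations raise a config error", {
  cfg <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = 1.5,
                              ksv = 1e5, noise_sigma = 0, seed = 1)
  expect_error(simulate_titration_sv(cfg), class = "fq_error_config")
  expect_error(
    titration_sim_config(model = "modified_sv", f0 = 1000, fa = 0.8, ksv = 1500,
                         conc_ladder = c(1e-4, 2e-4), noise_sigma = 0, seed = 1),
    class = "fq_error_config"
  ) # ladder must start at 0
  expect_error(
    titration_sim_config(model = "modified_sv", f0 = 1000, fa = 0.8, ksv = 1500,
                         noise_sigma = 0),
    class = "fq_error_config"
  ) # seed is mandatory
})

test_that("scan series are self-consistent and carry the configured blue shift", {
  cfg <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = 0.8,
                              ksv = 1500, noise_sigma = 0, seed = 9)
  ser <- simulate_titration_scans(cfg)
  expect_true("scan" %in% names(ser))
  expect_equal(ser$intensity, purrr::map_dbl(ser$scan, ~ max(.x$intensity)))
  expect_equal(peak_shift(ser), -25)
  expect_error(simulate_titration_scans(cfg, peak_width_nm = 0),
               class = "fq_error_domain")
  # C = 0 scan is centred at the unshifted emission maximum
  s0 <- ser$scan[[which(ser$conc_mol_per_l == 0)]]
  expect_equal(emission_maximum(s0)$emission_nm, 335)
})

test_that("zero-amplitude EEM configs give a zero matrix", {
  cfg <- eem_sim_config(
    peaks = tibble::tibble(ex_center_nm = 280, em_center_nm = 335, amplitude = 0,
                           width_ex_nm = 10, width_em_nm = 10),
    rayleigh_amplitude = 0, baseline_sigma = 0, seed = 1
  )
  expect_true(all(simulate_eem(cfg)$intensity == 0))
})

test_that("titration CSV round trip preserves scalar and scan layouts", {
  cfg <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = 0.8,
                              ksv = 1500, noise_sigma = 0.02, seed = 21,
                              ligand_id = "PFOA")
  ser <- simulate_titration_sv(cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  write_titration(ser, p, metadata = list(seed = 21))
  back <- read_titration(p)
  expect_equal(back$conc_mol_per_l, ser$conc_mol_per_l)
  expect_equal(back$intensity, ser$intensity)
  expect_equal(back$ligand_id, ser$ligand_id)

  scans <- simulate_titration_scans(cfg)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_titration(scans, p2)
  back2 <- read_titration(p2)
  expect_true("scan" %in% names(back2))
  expect_equal(back2$intensity, scans$intensity)
  expect_equal(back2$scan[[3]]$intensity, scans$scan[[3]]$intensity)
  expect_equal(peak_shift(back2), peak_shift(scans))
})
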