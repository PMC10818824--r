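# Constants quoted below are the published fitted lines for the ten PFAS-HSA
# titrations shipped in reference_quenching_fits()/reference_binding_fits().

test_that("derive_sv_constants reproduces published Kq values", {
  # long-chain PFOS line
  got <- suppressWarnings(derive_sv_constants(0.0007969, 0.2456, tau0 = 1e-8))
  expect_equal(signif(got$kq, 3), 3.08e10)
  # short-chain PFBA line
  got <- suppressWarnings(derive_sv_constants(0.0003302, 0.9979, tau0 = 1e-8))
  expect_equal(signif(got$kq, 3), 3.02e11)
  # identity case
  expect_equal(unlist(derive_sv_constants(1, 1, 1)), c(fa = 1, ksv_prime = 1, kq = 1))
  expect_error(derive_sv_constants(-1, 1, 1), class = "fq_error_domain")
  expect_warning(derive_sv_constants(0.0005, 0.635), class = "fq_warning_fa_above_one")
})

test_that("modified Stern-Volmer fit on a line-exact series recovers the published Kq", {
  ser <- series_from_sv_line(0.0005035, 0.635, ligand_id = "PFOA")
  fit <- suppressWarnings(fit_modified_stern_volmer(ser, tau0 = 1e-8))
  expect_equal(signif(fit$kq, 3), 1.26e11)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # algebraic invariants asserted at construction hold
  expect_equal(fit$kq * fit$tau0 * fit$slope, fit$intercept, tolerance = 1e-9)
  expect_equal(fit$fa * fit$intercept, 1, tolerance = 1e-9)
})

test_that("flat quenching signal (zero slope) is a fit-invalid error", {
  f0 <- 1000
  ser <- tibble::tibble(
    conc_mol_per_l = c(0, 2e-4, 4e-4, 6e-4),
    intensity = c(f0, f0 / 2, f0 / 2, f0 / 2) # y = F0/(F0-F) constant at 2
  )
  expect_error(fit_modified_stern_volmer(ser), class = "fq_error_fit_invalid")
})

test_that("noiseless simulate -> fit round trips are exact to 1e-9 relative", {
  cfg <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = 0.8,
                              ksv = 1500, noise_sigma = 0, seed = 7)
  fit <- fit_modified_stern_volmer(simulate_titration_sv(cfg))
  expect_equal(fit$fa, 0.8, tolerance = 1e-9)
  expect_equal(fit$ksv_prime, 1500, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  cfg_lb <- titration_sim_config(model = "lineweaver_burk", f0 = 1000, ka = 150,
                                 n_sites = 0.7, noise_sigma = 0, seed = 3)
  fit_lb <- fit_lineweaver_burk(simulate_titration_lb(cfg_lb))
  expect_equal(fit_lb$ka, 150, tolerance = 1e-9)
  expect_equal(fit_lb$n_sites, 0.7, tolerance = 1e-9)
  expect_equal(fit_lb$r_squared, 1, tolerance = 1e-12)
})

test_that("double-log fit reproduces the published PFOS binding constants", {
  ser <- series_from_lb_line(0.8694, 2.5962, ligand_id = "PFOS")
  fit <- fit_lineweaver_burk(ser)
  expect_equal(fit$ka, 394.639, tolerance = 1e-5)
  expect_equal(fit$n_sites, 0.8694, tolerance = 1e-9)
  expect_equal(fit$ka, 10^fit$lg_ka, tolerance = 1e-12)
})

test_that("a unit-constant isotherm gives ka = 1 and one site", {
  f0 <- 1000
  cc <- c(0.5, 1, 2, 4) # (F0-F)/F = C exactly
  ser <- tibble::tibble(conc_mol_per_l = c(0, cc), intensity = c(f0, f0 / (1 + cc)))
  fit <- fit_lineweaver_burk(ser)
  expect_equal(fit$ka, 1, tolerance = 1e-12)
  expect_equal(fit$n_sites, 1, tolerance = 1e-12)
})

test_that("points with F >= F0 are dropped with a warning; too few points error", {
  f0 <- 1000
  cc <- default_conc_ladder()[-1]
  f <- f0 / (1 + 150 * cc^0.7)
  f[1] <- f0 * 1.01 # no quench signal at the lowest rung
  ser <- tibble::tibble(conc_mol_per_l = c(0, cc), intensity = c(f0, f))
  expect_warning(fit <- fit_lineweaver_burk(ser), class = "fq_warning_points_dropped")
  expect_equal(fit$n_points_dropped, 1)
  expect_equal(fit$n_points_used, length(cc) - 1)

  tiny <- tibble::tibble(conc_mol_per_l = c(0, 1e-4, 2e-4),
                         intensity = c(f0, 900, 1100))
  expect_warning(
    expect_error(fit_modified_stern_volmer(tiny), class = "fq_error_insufficient_data"),
    class = "fq_warning_points_dropped"
  )
})

test_that("quenching mechanism classification is strict at the diffusion limit", {
  expect_equal(classify_quenching(1.26e11), "static")
  expect_equal(classify_quenching(2.0e10), "dynamic_consistent") # boundary, strict
  expect_equal(classify_quenching(1e9), "dynamic_consistent")
  expect_equal(classify_quenching(c(3e10, 1e10)), c("static", "dynamic_consistent"))
  expect_error(classify_quenching(-1), class = "fq_error_domain")
})

test_that("simulated static-quenching intensities decrease monotonically in C", {
  for (seed in 1:5) {
    fa <- runif(1, 0.3, 0.95)
    ksv <- runif(1, 200, 2000)
    cfg <- titration_sim_config(model = "modified_sv", f0 = 1000, fa = fa,
                                ksv = ksv, noise_sigma = 0, seed = seed)
    ser <- simulate_titration_sv(cfg)
    expect_true(all(diff(ser$intensity) < 0))
    fit <- fit_modified_stern_volmer(ser)
    expect_gt(fit$slope, 0)
    expect_gt(fit$intercept, 0)
  }
})

test_that("log-scale binding-constant recovery is accurate under 1 percent noise", {
  errs <- vapply(1:100, function(s) {
    cfg <- titration_sim_config(model = "lineweaver_burk", f0 = 1000, ka = 150,
                                n_sites = 0.7, noise_sigma = 0.01, seed = s)
    fit <- fit_lineweaver_burk(simulate_titration_lb(cfg))
    abs(fit$lg_ka - log10(150)) / log10(150)
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("tidy/glance expose the fitted constants", {
  ser <- series_from_lb_line(0.6811, 2.0143, ligand_id = "PFOA")
  g <- glance(fit_lineweaver_burk(ser))
  expect_equal(g$ligand_id, "PFOA")
  expect_equal(round(g$ka, 4), 103.3475)
  sv <- suppressWarnings(fit_modified_stern_volmer(series_from_sv_line(0.0005035, 0.635)))
  expect_equal(tidy(sv)$term, c("slope", "intercept"))
  expect_equal(glance(sv)$mechanism, "static")
})
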