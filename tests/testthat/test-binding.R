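test_that("two-species bound concentration matches algebra and oracle", {
  # no protein -> no complex
  expect_identical(bound_direct(0, 11e-9, 1.2e-9), 0)
  # P0 = L0 = Kd = c has the closed algebraic solution c(3 - sqrt(5))/2
  for (c0 in c(1e-9, 1e-6, 1e-3)) {
    expect_equal(bound_direct(c0, c0, c0), c0 * (3 - sqrt(5)) / 2,
                 tolerance = 1e-12)
  }
  # direct-titration composition vs the iterative mass-balance oracle
  pl <- bound_direct(200e-9, 11e-9, 1.2e-9)
  expect_equal(pl, oracle_bound_direct(200e-9, 11e-9, 1.2e-9),
               tolerance = 1e-10)
  expect_true(pl <= min(200e-9, 11e-9) && pl >= 0)
  expect_error(bound_direct(-1e-9, 1e-9, 1e-9), "must be >= 0")
})

test_that("competitive bound concentration reduces, obeys symmetry, and matches the root-solve oracle", {
  base <- binding_system(P0 = 30e-9, L0 = 10e-9, B0 = 0, KdL = 1.2e-9,
                         KdB = 19e-9)
  expect_identical(bound_competitive(base), bound_direct(30e-9, 10e-9, 1.2e-9))
  # identical ligands partition equally
  sym <- binding_system(P0 = 30e-9, L0 = 10e-9, B0 = 10e-9, KdL = 1.2e-9,
                        KdB = 1.2e-9)
  expect_equal(bound_competitive(sym), bound_competitor(sym),
               tolerance = 1e-10)
  # assay composition with a 19 nM competitor at 1 uM
  sys <- binding_system(P0 = 30e-9, L0 = 10e-9, B0 = 1e-6, KdL = 1.2e-9,
                        KdB = 19e-9)
  expect_equal(bound_competitive(sys),
               oracle_bound_competitive(30e-9, 10e-9, 1e-6, 1.2e-9, 19e-9),
               tolerance = 1e-8)
  expect_error(bound_competitive(binding_system(P0 = NaN)), "finite")
})

test_that("competitive solution matches the oracle across a random parameter grid", {
  set.seed(101)
  worst <- 0
  for (i in 1:2000) {
    p <- 10^runif(5, -12, -2)
    a <- bound_competitive(binding_system(p[1], p[2], p[3], p[4], p[5]))
    b <- oracle_bound_competitive(p[1], p[2], p[3], p[4], p[5])
    rel <- if (b > 0) abs(a / b - 1) else abs(a - b)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-8)
})

test_that("bound concentration is monotone in each binding parameter", {
  pl_at <- function(P0 = 30e-9, B0 = 1e-7, KdL = 1.2e-9, KdB = 19e-9) {
    bound_competitive(binding_system(P0, 10e-9, B0, KdL, KdB))
  }
  b_grid <- 10^seq(-9, -3, length.out = 25)
  expect_true(all(diff(vapply(b_grid, function(b) pl_at(B0 = b), 0)) < 0))
  k_grid <- 10^seq(-10, -6, length.out = 25)
  expect_true(all(diff(vapply(k_grid, function(k) pl_at(KdL = k), 0)) < 0))
  p_grid <- 10^seq(-9, -6, length.out = 25)
  expect_true(all(diff(vapply(p_grid, function(p) pl_at(P0 = p), 0)) > 0))
  # limits: saturating competitor abolishes the labeled complex; an
  # infinitely weak competitor restores the two-species value
  expect_lt(pl_at(B0 = 1), 1e-4 * pl_at(B0 = 0))
  expect_equal(bound_competitive(binding_system(30e-9, 10e-9, 1e-6, 1.2e-9,
                                                Inf)),
               bound_direct(30e-9, 10e-9, 1.2e-9), tolerance = 1e-12)
})

test_that("anisotropy signal interpolates between calibration end points", {
  cal <- anisotropy_calibration(60, 120, q = 1)
  expect_identical(anisotropy_signal(0, cal), 60)
  expect_identical(anisotropy_signal(1, cal), 120)
  expect_identical(anisotropy_signal(0.5, cal), 90)
  # q weights the bound state by its brightness
  cal2 <- anisotropy_calibration(60, 120, q = 2)
  expect_equal(anisotropy_signal(0.5, cal2), (2 * 0.5 * 120 + 0.5 * 60) / 1.5)
  expect_error(anisotropy_signal(1.2, cal), "\\[0, 1\\]")
  expect_error(anisotropy_calibration(120, 60), "exceed")
})

test_that("direct-titration fitting recovers the probe dissociation constant", {
  gen <- generate_fp_titration(binding_system(L0 = 11e-9, KdL = 1.2e-9),
                               sigma_mP = 0, seed = 1, varied = "protein")
  fit <- fit_direct_kd(gen$series, L0 = 11e-9, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(fit$estimate, 1.2e-9, tolerance = 1e-6)
  # flat series never converges
  flat <- gen$series
  flat$anisotropy_mP <- 60
  ffit <- fit_direct_kd(flat, 11e-9, n_boot = 0)
  expect_false(ffit$converged)
  expect_true("no_signal_change" %in% ffit$flags)
})

test_that("noisy direct titrations recover the constant within 20% in at least 95 of 100 seeds", {
  # direct-titration design rule: keep the probe at or below its Kd so the
  # isotherm shape (not the stoichiometric break) carries the information;
  # a probe far above Kd caps the attainable precision below this target
  hits <- 0L
  for (s in 1:100) {
    gen <- generate_fp_titration(binding_system(L0 = 1e-9, KdL = 1.2e-9),
                                 sigma_mP = 2, seed = s, varied = "protein",
                                 doses = 50e-9 / 2^(0:11))
    fit <- fit_direct_kd(gen$series, L0 = 1e-9, n_boot = 0)
    if (isTRUE(fit$converged) && abs(fit$estimate / 1.2e-9 - 1) <= 0.2) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("competition fitting recovers constants across the affinity ladder", {
  for (kd in c(63e-6, 1.26e-6, 158e-9, 19e-9)) {
    gen <- generate_fp_titration(binding_system(KdB = kd), sigma_mP = 0,
                                 seed = 1)
    fit <- fit_competition_kd(gen$series, binding_system(), n_boot = 0)
    expect_true(fit$converged)
    expect_equal(fit$estimate, kd, tolerance = 1e-4)
  }
})

test_that("undisplaceable series is reported as a lower bound, not an estimate", {
  gen <- generate_fp_titration(binding_system(KdB = 1), sigma_mP = 2, seed = 1)
  fit <- fit_competition_kd(gen$series, binding_system(), n_boot = 0)
  expect_false(fit$converged)
  expect_true("too_weak_to_measure" %in% fit$flags)
  expect_equal(fit$estimate, 0.1) # top of the search range
})

test_that("total-fluorescence excursions are flagged but never corrected", {
  gen <- generate_fp_titration(binding_system(KdB = 19e-9), sigma_mP = 0,
                               seed = 1)
  s <- gen$series
  s$total_fluorescence <- 1000
  s$total_fluorescence[3] <- 1500 # 50% excursion on one point
  fit <- fit_competition_kd(s, binding_system(), n_boot = 0)
  expect_true(any(grepl("total_fluorescence_artifact", fit$flags)))
  expect_equal(fit$estimate, 19e-9, tolerance = 1e-6) # data untouched
})

test_that("bootstrap interval brackets the estimate and covers the truth on a well-behaved series", {
  gen <- generate_fp_titration(binding_system(KdB = 19e-9), sigma_mP = 2,
                               seed = 11)
  fit <- fit_competition_kd(gen$series, binding_system(), n_boot = 200,
                            boot_seed = 1)
  expect_true(fit$ci[1] <= fit$estimate && fit$estimate <= fit$ci[2])
  expect_true(fit$ci[1] < 19e-9 * 1.5 && fit$ci[2] > 19e-9 * 0.5)
})

test_that("fitted IC50 of a competition curve exceeds the true constant under ligand depletion", {
  # with P0, L0 non-negligible against KdL, half-displacement needs more
  # competitor than KdB (depletion shifts the apparent potency)
  sys <- binding_system(P0 = 30e-9, L0 = 10e-9, KdL = 1.2e-9, KdB = 19e-9)
  cal <- anisotropy_calibration()
  doses <- 10^seq(-10, -4, length.out = 200)
  mp <- sapply(doses, function(b) {
    s <- binding_system(sys$P0, sys$L0, b, sys$KdL, sys$KdB)
    anisotropy_signal(bound_competitive(s) / sys$L0, cal)
  })
  half <- (max(mp) + min(mp)) / 2
  ic50 <- doses[which.min(abs(mp - half))]
  expect_gt(ic50, sys$KdB)
})
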