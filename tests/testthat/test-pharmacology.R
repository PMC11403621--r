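test_that("viability normalization anchors blank at 0 and vehicle at 1", {
  veh <- c(1050, 1100, 1150)
  expect_equal(normalize_viability(mean(veh), 100, veh), 1)
  expect_equal(normalize_viability(100, 100, veh), 0)
  expect_equal(normalize_viability(600, 100, veh), 0.5)
  expect_error(normalize_viability(500, 1000, c(900, 950, 980)), "assay failure")
  expect_error(normalize_viability(500, 100, c(900, 950)), ">= 3 vehicle")
})

test_that("4PL fitting recovers exact curves and refuses degenerate input", {
  d <- c(0, 1e-9 * 2^(0:9))
  y <- oracle_pl4(d, bottom = 0, top = 1, mid = 1e-6, slope = 1)
  fit <- fit_4pl(d, y)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 1e-6, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_lte(fit$bottom, fit$top) # canonical orientation
  # ascending curves fit equally well (negative canonical slope)
  y2 <- oracle_pl4(d, bottom = 5, top = 95, mid = 4e-8, slope = -1.3)
  fit2 <- fit_4pl(d, y2)
  expect_equal(fit2$ec50, 4e-8, tolerance = 1e-5)
  # constant responses never converge; two points are an error
  expect_false(fit_4pl(d, rep(1, length(d)))$converged)
  expect_error(fit_4pl(c(0, 1e-6), c(1, 0)), "insufficient data")
})

test_that("4PL fit is invariant to point order and equivariant to dose scaling", {
  d <- 1e-9 * 2^(0:8)
  set.seed(3)
  y <- oracle_pl4(d, 0.05, 0.98, 2e-8, 1.4) + rnorm(9, 0, 0.01)
  fit <- fit_4pl(d, y)
  perm <- sample(length(d))
  fit_p <- fit_4pl(d[perm], y[perm])
  expect_equal(fit_p$ec50, fit$ec50, tolerance = 1e-6)
  fit_s <- fit_4pl(d * 1000, y)
  expect_equal(fit_s$ec50, 1000 * fit$ec50, tolerance = 1e-6)
})

test_that("Bliss surface follows the independence formula", {
  # single 3x3 grid built by hand: Ea = Eb = 0.5 at the top doses
  inh <- matrix(c(0, 0.5, 0.5,
                  0.5, 0.75, 0.75,
                  0.5, 0.75, 0.75), 3, 3, byrow = TRUE)
  g <- bliss_analysis(checkerboard_grid(c(0, 1, 2), c(0, 1, 2), inh))
  expect_equal(g$expected[2, 2], 0.75)
  expect_equal(g$score[2, 2], 0)
  # a zero single-agent row leaves the expectation at the other agent
  inh2 <- matrix(0, 3, 3)
  inh2[1, ] <- c(0, 0.3, 0.6) # agent B alone
  g2 <- bliss_analysis(checkerboard_grid(c(0, 1, 2), c(0, 1, 2), inh2))
  expect_equal(g2$expected[2, ], c(0, 0.3, 0.6))
  # clamping flags small excursions, larger ones error
  inh3 <- inh; inh3[2, 2] <- 1.03
  expect_identical(bliss_analysis(checkerboard_grid(c(0, 1, 2), c(0, 1, 2),
                                                    inh3))$flags,
                   "inhibition_clamped")
  inh4 <- inh; inh4[2, 2] <- 1.2
  expect_error(bliss_analysis(checkerboard_grid(c(0, 1, 2), c(0, 1, 2), inh4)),
               "clampable")
})

test_that("Bliss scores vanish on multiplicative-survival data and expose a constructed bump", {
  null <- generate_checkerboard(sigma = 0)
  b <- bliss_analysis(null$grid)
  expect_lt(max(abs(b$score)), 1e-12)
  expect_true(all(b$expected >= 0 & b$expected <= 1))
  bumped <- generate_checkerboard(bump = list(value = 0.1, rows = 4:5,
                                              cols = 4:5), sigma = 0)
  bb <- bliss_analysis(bumped$grid)
  expect_equal(mean(bb$score[4:5, 4:5]), 0.1, tolerance = 1e-12)
  expect_lt(max(abs(bb$score[-(4:5), ])), 1e-12)
  expect_equal(bb$summary$max_window_mean, 0.1, tolerance = 1e-12)
})

test_that("ligand efficiency follows the 1.4 pKd per heavy atom convention", {
  le <- ligand_efficiency(19e-9, 33)
  expect_identical(le$rounded, 0.33)
  expect_equal(le$value, 1.4 * (-log10(19e-9)) / 33)
  expect_identical(ligand_efficiency(1, 20)$rounded, 0)
  expect_identical(ligand_efficiency(1, 20)$flag, "nonpositive")
  expect_identical(ligand_efficiency(1e-6, 25)$value, 1.4 * 6 / 25)
  # exact thermodynamic convention at 300 K agrees with -RT ln Kd / HA
  th <- ligand_efficiency(1e-6, 25, convention = "thermodynamic",
                          temperature = 300)
  expect_equal(th$value, -1.98720425864083e-3 * 300 * log(1e-6) / 25)
  # strictly decreasing in Kd and heavy atoms
  expect_gt(ligand_efficiency(1e-9, 30)$value, ligand_efficiency(1e-8, 30)$value)
  expect_gt(ligand_efficiency(1e-9, 30)$value, ligand_efficiency(1e-9, 31)$value)
})

test_that("selectivity ratios carry lower-bound semantics", {
  expect_equal(selectivity_ratio(10e-9, 3e-6)$ratio, 300)
  expect_equal(selectivity_ratio(5e-8, 5e-8)$ratio, 1)
  bound <- selectivity_ratio(19e-9, 20e-6, off_is_lower_bound = TRUE)
  expect_true(bound$is_lower_bound)
  expect_identical(bound$label, ">1052")
})

test_that("tumor volume uses the geometric-mean radius and is permutation invariant", {
  expect_equal(tumor_volume(2, 2, 2), 4 / 3 * pi, tolerance = 1e-12)
  expect_equal(tumor_volume(1, 2, 4), 4 / 3 * pi, tolerance = 1e-12) # gmean 2
  set.seed(8)
  d <- runif(3, 1, 10)
  expect_equal(tumor_volume(d[1], d[2], d[3]),
               4 / 3 * pi * (prod(d)^(1 / 3) / 2)^3, tolerance = 1e-12)
  expect_equal(tumor_volume(d[3], d[1], d[2]), tumor_volume(d[1], d[2], d[3]))
  expect_error(tumor_volume(0, 1, 2), "positive")
})

test_that("free-drug arithmetic is a plain fraction", {
  expect_equal(free_concentration(10e-6, 0.54), 5.4e-6)
  expect_identical(free_concentration(3e-6, 1), 3e-6)
  expect_identical(free_concentration(3e-6, 0), 0)
  expect_error(free_concentration(1e-6, 1.2), "\\[0, 1\\]")
})
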