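# The imaging tests build small fields in code (discs and capsules on a
# flat baseline) so every expected quantity is known by construction.

make_blank <- function(n = 120, level = 0) matrix(level, n, n)

test_that("background estimation is robust to sparse bright objects", {
  expect_warning(b0 <- estimate_background(make_blank(50, 0)), "constant-zero")
  expect_identical(b0, 0)
  expect_identical(estimate_background(make_blank(50, 3.5)), 3.5)
  # known baseline + <5% bright pixels + noise
  set.seed(4)
  img <- matrix(rnorm(200 * 200, 0.02, 0.002), 200)
  img[sample(length(img), 0.04 * length(img))] <- 5
  expect_equal(estimate_background(img), 0.02, tolerance = 0.05 * 5)
})

test_that("nucleus segmentation finds exactly the constructed nuclei", {
  n <- 150
  img <- make_blank(n, 0.01)
  # blank field
  labels0 <- segment_nuclei(img, pixel_size = 0.65)
  expect_identical(max(labels0), 0L)
  # two disjoint bright discs above 100x background
  for (ctr in list(c(40, 40), c(100, 100))) {
    px <- mitopharm:::disc_pixels(ctr[1], ctr[2], 7, n)
    img[px] <- 2
  }
  labels <- segment_nuclei(img, pixel_size = 0.65)
  expect_identical(max(labels), 2L)
  # area filter removes a tiny speck and a huge blob (both clear of the
  # two nuclei so no components merge)
  img[mitopharm:::disc_pixels(130, 20, 1.5, n)] <- 2   # ~3 um^2
  img[mitopharm:::disc_pixels(40, 120, 25, n)] <- 2    # ~830 um^2
  labels2 <- segment_nuclei(img, pixel_size = 0.65)
  expect_identical(max(labels2), 2L)
})

test_that("generated fields segment to the ground-truth cell count", {
  spec <- plate_spec()
  gen <- mitopharm:::with_seed(21, mitopharm:::generate_well_fields(spec, "C3", 0))
  f <- gen$fields[[1]]
  labels <- segment_nuclei(f$dna, pixel_size = spec$pixel_size)
  expect_identical(max(labels), spec$cells_per_field)
  mit <- classify_mitotic(labels, f$marker)
  truth <- gen$truth[gen$truth$field == 1, ]
  expect_identical(sum(mit), sum(truth$mitotic))
})

test_that("mitotic classification follows marker positivity", {
  n <- 150
  dna <- make_blank(n, 0.01)
  marker <- make_blank(n, 0.001)
  a <- mitopharm:::disc_pixels(40, 40, 7, n)
  b <- mitopharm:::disc_pixels(100, 100, 7, n)
  dna[a] <- 2; dna[b] <- 2
  labels <- segment_nuclei(dna, pixel_size = 0.65)
  expect_identical(classify_mitotic(labels, marker), c(FALSE, FALSE))
  marker[a] <- 1 # ~1000x background on one nucleus
  flags <- classify_mitotic(labels, marker)
  expect_identical(sum(flags), 1L)
  expect_identical(classify_mitotic(matrix(0L, n, n), marker), logical(0))
})

test_that("top-hat spindle mask isolates fine structure", {
  # constant image: top-hat is zero everywhere, mask empty
  n <- 160
  img <- make_blank(n, 0.5)
  nuc <- mitopharm:::disc_pixels(80, 80, 7, n)
  expect_length(spindle_mask(img, nuc, 0.65), 0)
  # a thin bright line much narrower than the 25 um element (and far above
  # 100x the baseline) is passed
  img2 <- make_blank(n, 0.001)
  line <- mitopharm:::capsule_pixels(80, 80, 10, 2, 0.5, n)
  img2[line] <- 1
  mask <- spindle_mask(img2, nuc, 0.65)
  expect_gte(length(intersect(mask, line)) / length(line), 0.95)
  # rendered spindle recovers its footprint with Jaccard >= 0.5
  spec <- plate_spec()
  set.seed(9)
  px <- spec$pixel_size
  marker <- make_blank(280, spec$background)
  body <- mitopharm:::disc_pixels(140, 140, spec$cell_radius_um / px, 280)
  cap <- mitopharm:::capsule_pixels(140, 140, spec$spindle_length_um / px / 2,
                                    spec$spindle_halfwidth_um / px, 1.1, 280)
  marker[body] <- marker[body] + spec$marker_diffuse
  marker[cap] <- marker[cap] + spec$marker_spindle
  marker <- pmax(marker + rnorm(280^2, 0, spec$noise_sd), 0)
  dim(marker) <- c(280, 280)
  nuc2 <- mitopharm:::disc_pixels(140, 140, spec$nucleus_radius_um / px, 280)
  m <- spindle_mask(marker, nuc2, px)
  jac <- length(intersect(m, cap)) / length(union(m, cap))
  expect_gte(jac, 0.5)
})

test_that("cell scoring averages the readout over the mask", {
  img <- make_blank(20, 0)
  img[c(3, 7)] <- c(10, 30)
  sc <- score_cells(img, list(c(3, 7)), "spindle")
  expect_identical(sc$mean_intensity, 20)
  sc2 <- score_cells(make_blank(20, 4.2), list(1:5, 10:12), "whole-nucleus")
  expect_identical(sc2$mean_intensity, c(4.2, 4.2))
  expect_error(score_cells(img, list(integer(0))), "empty mask")
  expect_error(score_cells(img, list(c(1, 4000))), "shape mismatch")
})

test_that("plate threshold takes the top of the darkest decile", {
  expect_identical(plate_threshold(1:100, 0.10)$threshold, 10L)
  # all-equal controls: threshold c, strict 'below' scores nothing positive
  thr <- plate_threshold(rep(7, 50), 0.10)
  expect_identical(thr$threshold, 7)
  ws <- well_mislocalization(rep(7, 50), thr, min_cells = 10)
  expect_identical(ws$percent, 0)
  # random sample equals the brute-force sort-and-select oracle
  set.seed(12)
  x <- runif(137)
  k <- ceiling(0.1 * length(x))
  expect_identical(plate_threshold(x, 0.10)$threshold, sort(x)[k])
  expect_error(plate_threshold(1:5, 0.10), "reject the plate")
})

test_that("well scores count strictly-below cells and flag degenerate wells", {
  expect_identical(well_mislocalization(c(5, 6, 7), 4, min_cells = 2)$percent, 0)
  ws <- well_mislocalization(c(1, 2, 3, rep(10, 7)), 5, min_cells = 5)
  expect_identical(ws$percent, 30)
  expect_identical(ws$n_below, 3L)
  low <- well_mislocalization(c(1, 10), 5, min_cells = 20)
  expect_identical(low$flags, "low_count")
  none <- well_mislocalization(numeric(0), 5)
  expect_true(is.na(none$percent) && none$flags == "no_mitotic_cells")
})

test_that("scoring is deterministic and equivariant under intensity scaling", {
  spec <- plate_spec(fields_per_well = 2L)
  gen <- mitopharm:::with_seed(31, mitopharm:::generate_well_fields(spec, "D4", 0.3))
  s1 <- mitopharm:::score_fields(gen$fields, hcs_config())
  s2 <- mitopharm:::score_fields(gen$fields, hcs_config())
  expect_identical(s1, s2)
  # multiply every channel by a constant: identical cells, scaled means
  scaled <- lapply(gen$fields, function(f) {
    field_image(f$dna * 7, f$marker * 7, f$readout * 7, f$pixel_size,
                f$well, f$field)
  })
  s3 <- mitopharm:::score_fields(scaled, hcs_config())
  expect_identical(s3$cells[c("well", "field", "label", "mask_px")],
                   s1$cells[c("well", "field", "label", "mask_px")])
  expect_equal(s3$cells$mean_intensity, 7 * s1$cells$mean_intensity,
               tolerance = 1e-12)
})

test_that("untreated wells score at the decile false-positive floor", {
  spec <- plate_spec()
  map <- vehicle_plate_map(c("B2", "B3", "B4", "B5", "B6", "B7"))
  res <- simulate_and_score_plate(spec, map, misloc_curve(5e-8), seed = 17)
  frac <- mean(res$cells$mean_intensity < res$threshold$threshold)
  n <- nrow(res$cells)
  expect_lt(abs(frac - 0.10), 1.96 * sqrt(0.1 * 0.9 / n) + 1 / n)
})

test_that("well scores increase with the mislocalization probability", {
  spec <- plate_spec(fields_per_well = 6L)
  pcts <- vapply(c(0, 0.5, 1), function(p) {
    gen <- mitopharm:::with_seed(53, mitopharm:::generate_well_fields(spec, "E5", p))
    sc <- mitopharm:::score_fields(gen$fields, hcs_config())
    truth <- gen$truth
    # score against a fixed threshold from an untreated reference well
    ref <- mitopharm:::with_seed(54, mitopharm:::generate_well_fields(spec, "E6", 0))
    ctl <- mitopharm:::score_fields(ref$fields, hcs_config())
    thr <- plate_threshold(ctl$cells$mean_intensity, 0.10)
    well_mislocalization(sc$cells$mean_intensity, thr, min_cells = 5)$percent
  }, numeric(1))
  expect_true(all(diff(pcts) > 0))
  expect_lt(pcts[1], 25)
  expect_gt(pcts[3], 90)
})

test_that("the whole-nucleus variant scores over nucleus masks", {
  spec <- plate_spec(fields_per_well = 2L)
  gen <- mitopharm:::with_seed(71, mitopharm:::generate_well_fields(spec, "F4", 0))
  cfg <- hcs_config(mask_kind = "whole-nucleus")
  sc <- mitopharm:::score_fields(gen$fields, cfg)
  expect_true(all(sc$cells$mask_kind == "whole-nucleus"))
  # masks are the segmented nuclei themselves: area within the filter range
  areas_um2 <- sc$cells$mask_px * spec$pixel_size^2
  expect_true(all(areas_um2 >= 30 & areas_um2 <= 600))
  # spindle-variant masks on the same fields are smaller, finer structures
  sp <- mitopharm:::score_fields(gen$fields, hcs_config())
  expect_lt(median(sp$cells$mask_px), median(sc$cells$mask_px))
})

test_that("plate scoring from TIFF files reproduces in-memory scoring", {
  spec <- plate_spec(fields_per_well = 2L, cells_per_field = 8L)
  map <- vehicle_plate_map(c("B2", "B3", "B4"))
  mem <- generate_plate(spec, map, misloc_curve(5e-8), seed = 5)
  cfg <- hcs_config(min_control_cells = 5, min_well_cells = 2)
  res_mem <- score_plate(mem, map, cfg)
  td <- withr::local_tempdir()
  generate_plate(spec, map, misloc_curve(5e-8), seed = 5, out_dir = td)
  res_disk <- score_plate(td, map, cfg)
  expect_equal(res_disk$well_scores$percent, res_mem$well_scores$percent,
               tolerance = 1e-5)
  expect_identical(res_disk$well_scores$n_mitotic, res_mem$well_scores$n_mitotic)
})
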