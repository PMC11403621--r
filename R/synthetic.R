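# Seeded generators for every input the analysis stages consume, each
# returning its data together with a ground-truth record so parameter
# recovery can be tested without any external data.

#' Simulate a fluorescence-polarization titration
#'
#' Generates a triplicate titration series from the exact equilibrium model:
#' either a competition series (competitor varied at fixed assay
#' composition) or a direct series (protein varied into the labeled probe).
#' Gaussian read noise of `sigma_mP` is added per replicate observation.
#'
#' @param sys A [binding_system()]; for competition series its `P0`, `L0`,
#'   `KdL`, `KdB` define the assay and the true competitor constant; for
#'   direct series `L0` and `KdL` are used.
#' @param cal An [anisotropy_calibration()].
#' @param doses Varied-species concentrations (molar). Default: 12
#'   concentrations, 3-fold serial dilution from 100 uM (competition) or
#'   200 nM (direct).
#' @param sigma_mP Gaussian noise standard deviation (mP, default 2).
#' @param seed RNG seed.
#' @param n_replicates Replicates per concentration (default 3).
#' @param varied `"competitor"` or `"protein"`.
#' @return List with `series` (data frame `concentration_molar`,
#'   `anisotropy_mP`, `replicate`) and `truth` (all generating parameters).
#' @export
generate_fp_titration <- function(sys = binding_system(KdB = 19e-9),
                                  cal = anisotropy_calibration(),
                                  doses = NULL, sigma_mP = 2, seed = 1L,
                                  n_replicates = 3L,
                                  varied = c("competitor", "protein")) {
  varied <- match.arg(varied)
  stopifnot(inherits(sys, "binding_system"), inherits(cal, "anisotropy_calibration"))
  stopifnot_scalar(sigma_mP, "sigma_mP", nonneg = TRUE)
  if (is.null(doses)) {
    doses <- if (varied == "competitor") 1e-4 / 3^(0:11) else 200e-9 / 2^(0:11)
  }
  model <- if (varied == "competitor") {
    competition_model_mp(doses, sys$P0, sys$L0, sys$KdL, sys$KdB,
                         cal$r_free, cal$r_bound, cal$q)
  } else {
    direct_model_mp(doses, sys$L0, sys$KdL, cal$r_free, cal$r_bound, cal$q)
  }
  series <- data.frame(
    concentration_molar = rep(doses, each = n_replicates),
    anisotropy_mP = rep(model, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(doses)))
  if (sigma_mP > 0) {
    series$anisotropy_mP <- series$anisotropy_mP +
      with_seed(seed, rnorm(nrow(series), 0, sigma_mP))
  }
  truth <- list(generator = "fp_titration", seed = seed, varied = varied,
                sys = unclass(sys), cal = unclass(cal),
                sigma_mP = sigma_mP, doses = doses,
                n_replicates = n_replicates)
  list(series = series, truth = truth)
}

#' Specification of a synthetic imaging plate
#'
#' Geometry, cell counts, and intensity levels of the synthetic 96-well
#' high-content plate. The defaults yield approximately 100 mitotic cells
#' per triplicate well (12 fields/well, ~10 cells/field, 28% mitotic).
#' Intensities are arbitrary units in `[0, 1]`; read noise is Gaussian with
#' standard deviation 2% of the nucleus intensity, and images are clamped
#' at 0.
#'
#' @param fields_per_well Fields imaged per well (default 12).
#' @param cells_per_field Cells placed per field (default 10).
#' @param mitotic_fraction Fraction of cells that are mitotic (default 0.28).
#' @param pixel_size Micrometers per pixel (default 0.65).
#' @param image_size Field side in pixels (default 280).
#' @param nucleus_radius_um Nucleus disc radius (default 4.5).
#' @param cell_radius_um Mitotic cell-body disc radius; must exceed half the
#'   top-hat kernel so the diffuse body is removed by the opening (default
#'   15).
#' @param spindle_length_um,spindle_halfwidth_um Capsule geometry of the
#'   rendered spindle (defaults 8 and 1.5).
#' @param background Baseline intensity added to all channels (default
#'   0.008).
#' @param nucleus_intensity DNA-channel nucleus level (default 0.3).
#' @param marker_diffuse Marker-channel diffuse cell-body level of mitotic
#'   cells (default 0.3).
#' @param marker_spindle Marker-channel spindle level added on the capsule
#'   (default 0.6).
#' @param readout_on On-spindle readout level (localized kinase, default
#'   0.45).
#' @param readout_off Diffuse readout level of a mislocalized cell (default
#'   0.05).
#' @param noise_sd Gaussian read noise; default 2% of `nucleus_intensity`.
#' @return A list of class `plate_spec`.
#' @export
plate_spec <- function(fields_per_well = 12L,
                       cells_per_field = 10L,
                       mitotic_fraction = 0.28,
                       pixel_size = 0.65,
                       image_size = 280L,
                       nucleus_radius_um = 4.5,
                       cell_radius_um = 15,
                       spindle_length_um = 8,
                       spindle_halfwidth_um = 1.5,
                       background = 0.008,
                       nucleus_intensity = 0.3,
                       marker_diffuse = 0.3,
                       marker_spindle = 0.6,
                       readout_on = 0.45,
                       readout_off = 0.05,
                       noise_sd = NULL) {
  spec <- list(fields_per_well = as.integer(fields_per_well),
               cells_per_field = as.integer(cells_per_field),
               mitotic_fraction = mitotic_fraction,
               pixel_size = pixel_size,
               image_size = as.integer(image_size),
               nucleus_radius_um = nucleus_radius_um,
               cell_radius_um = cell_radius_um,
               spindle_length_um = spindle_length_um,
               spindle_halfwidth_um = spindle_halfwidth_um,
               background = background,
               nucleus_intensity = nucleus_intensity,
               marker_diffuse = marker_diffuse,
               marker_spindle = marker_spindle,
               readout_on = readout_on,
               readout_off = readout_off,
               noise_sd = noise_sd %||% (0.02 * nucleus_intensity))
  class(spec) <- "plate_spec"
  spec
}

# indices of a filled disc at (cx, cy) radius r (pixels) in an n x n matrix
disc_pixels <- function(cx, cy, r, n) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(n, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(n, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  keep <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  (gy[keep] - 1L) * n + gx[keep]
}

# indices of a capsule (segment of half-length hl at angle theta, dilated to
# half-width hw) centred at (cx, cy)
capsule_pixels <- function(cx, cy, hl, hw, theta, n) {
  ext <- hl + hw + 1
  x0 <- max(1L, floor(cx - ext)); x1 <- min(n, ceiling(cx + ext))
  y0 <- max(1L, floor(cy - ext)); y1 <- min(n, ceiling(cy + ext))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  ux <- cos(theta); uy <- sin(theta)
  # distance from each pixel to the central segment
  t <- pmin(pmax((gx - cx) * ux + (gy - cy) * uy, -hl), hl)
  dx <- gx - (cx + t * ux); dy <- gy - (cy + t * uy)
  keep <- dx^2 + dy^2 <= hw^2
  (gy[keep] - 1L) * n + gx[keep]
}

# place k centres with minimum pairwise distance `sep` inside [margin, n-margin]
place_centers <- function(k, n, margin, sep, max_tries = 4000L) {
  xs <- numeric(k); ys <- numeric(k)
  placed <- 0L
  for (i in seq_len(max_tries)) {
    x <- runif(1, margin, n - margin); y <- runif(1, margin, n - margin)
    if (placed == 0L ||
        all((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 >= sep^2)) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      if (placed == k) return(cbind(xs, ys))
    }
  }
  stop("infeasible packing: too many cells for the field", call. = FALSE)
}

# Generate the fields of one well. Consumes the current RNG stream.
generate_well_fields <- function(spec, well, p_misloc) {
  n <- spec$image_size
  px <- spec$pixel_size
  r_nuc <- spec$nucleus_radius_um / px
  r_cell <- spec$cell_radius_um / px
  hl <- spec$spindle_length_um / px / 2
  hw <- spec$spindle_halfwidth_um / px
  margin <- r_cell + 3
  sep <- 2 * r_cell + 2
  fields <- vector("list", spec$fields_per_well)
  truth <- vector("list", spec$fields_per_well)
  for (fi in seq_len(spec$fields_per_well)) {
    centers <- place_centers(spec$cells_per_field, n, margin, sep)
    mitotic <- runif(spec$cells_per_field) < spec$mitotic_fraction
    misloc <- mitotic & (runif(spec$cells_per_field) < p_misloc)
    dna <- matrix(spec$background, n, n)
    marker <- matrix(spec$background, n, n)
    readout <- matrix(spec$background, n, n)
    for (ci in seq_len(spec$cells_per_field)) {
      cx <- centers[ci, 1]; cy <- centers[ci, 2]
      nuc <- disc_pixels(cx, cy, r_nuc, n)
      dna[nuc] <- dna[nuc] + spec$nucleus_intensity
      if (mitotic[ci]) {
        body <- disc_pixels(cx, cy, r_cell, n)
        marker[body] <- marker[body] + spec$marker_diffuse
        theta <- runif(1, 0, pi)
        cap <- capsule_pixels(cx, cy, hl, hw, theta, n)
        marker[cap] <- marker[cap] + spec$marker_spindle
        if (misloc[ci]) {
          readout[body] <- readout[body] + spec$readout_off
        } else {
          readout[cap] <- readout[cap] + spec$readout_on
        }
      }
    }
    if (spec$noise_sd > 0) {
      dna <- dna + rnorm(n * n, 0, spec$noise_sd)
      marker <- marker + rnorm(n * n, 0, spec$noise_sd)
      readout <- readout + rnorm(n * n, 0, spec$noise_sd)
    }
    dna <- pmax(dna, 0); marker <- pmax(marker, 0); readout <- pmax(readout, 0)
    dim(dna) <- dim(marker) <- dim(readout) <- c(n, n)
    fields[[fi]] <- field_image(dna, marker, readout, px, well, fi)
    truth[[fi]] <- data.frame(well = well, field = fi,
                              cell = seq_len(spec$cells_per_field),
                              x = centers[, 1], y = centers[, 2],
                              mitotic = mitotic, mislocalized = misloc,
                              stringsAsFactors = FALSE)
  }
  list(fields = fields, truth = do.call(rbind, truth))
}

# deterministic per-well seed derived from the plate seed
well_seed <- function(seed, idx) {
  (as.integer(seed) + 7919L * as.integer(idx)) %% 2147483647L
}

# mislocalization probability at a dose, from the ground-truth 4PL
misloc_probability <- function(dose, curve) {
  pl4(dose, curve$p_max, curve$p_min, curve$ec50, curve$slope %||% 1)
}

#' Ground-truth mislocalization dose-response curve
#'
#' Per-cell probability that the readout is displaced from the spindle,
#' following a four-parameter logistic in dose.
#'
#' @param ec50 Midpoint dose (molar).
#' @param slope Hill slope (default 1).
#' @param p_min Probability at zero dose (default 0).
#' @param p_max Probability at saturating dose (default 0.95).
#' @return A list of class `misloc_curve`.
#' @export
misloc_curve <- function(ec50, slope = 1, p_min = 0, p_max = 0.95) {
  stopifnot_scalar(ec50, "ec50", positive = TRUE)
  structure(list(ec50 = ec50, slope = slope, p_min = p_min, p_max = p_max),
            class = "misloc_curve")
}

#' Generate a synthetic high-content plate
#'
#' Renders every non-blank well of a plate map as `fields_per_well`
#' three-channel fields: nuclei placed without overlap, mitotic cells
#' carrying a diffuse marker-positive cell body with an elongated spindle
#' capsule, and the readout channel placed on the spindle footprint or —
#' with the dose-dependent mislocalization probability — diffusely across
#' the cell body. Per-cell ground-truth labels are recorded. Each well uses
#' a seed derived deterministically from `seed` and the well index, so
#' identical calls are byte-identical and wells can be regenerated
#' independently (see [simulate_and_score_plate()]).
#'
#' @param spec A [plate_spec()].
#' @param plate_map Plate map data frame (`well`, `compound`, `dose_molar`,
#'   `role`); blank wells are not rendered.
#' @param curve A [misloc_curve()] mapping dose to mislocalization
#'   probability.
#' @param seed Plate RNG seed.
#' @param out_dir If non-`NULL`, fields are written as 32-bit single-channel
#'   TIFFs named `{plate_name}_{well}_{field}_{channel}.tif` plus a
#'   `ground_truth.json` manifest, and file paths replace in-memory images.
#' @param plate_name Name used in file names (default `"plate1"`).
#' @return An object of class `synthetic_plate`: `wells` (named list of
#'   [field_image()] lists, or `NULL` when written to disk), `truth`
#'   (generator parameters, per-well seeds, per-cell labels), `plate_map`,
#'   `spec`, and `dir` when written.
#' @export
generate_plate <- function(spec, plate_map, curve, seed = 1L,
                           out_dir = NULL, plate_name = "plate1") {
  stopifnot(inherits(spec, "plate_spec"), inherits(curve, "misloc_curve"))
  plate_map <- validate_plate_map(plate_map)
  active <- plate_map[plate_map$role != "blank", , drop = FALSE]
  wells <- list()
  cell_truth <- list()
  seeds <- integer(nrow(active))
  for (i in seq_len(nrow(active))) {
    w <- active$well[i]
    dose <- active$dose_molar[i]
    p <- if (active$role[i] == "vehicle") curve$p_min else misloc_probability(dose, curve)
    seeds[i] <- well_seed(seed, match(w, plate_map$well))
    gen <- with_seed(seeds[i], generate_well_fields(spec, w, p))
    cell_truth[[i]] <- cbind(gen$truth, dose_molar = dose,
                             p_mislocalized = p)
    if (is.null(out_dir)) {
      wells[[w]] <- gen$fields
    } else {
      write_well_tiffs(gen$fields, out_dir, plate_name)
    }
  }
  truth <- list(generator = "plate", seed = seed,
                well_seeds = setNames(seeds, active$well),
                curve = unclass(curve), spec = unclass(spec),
                cells = do.call(rbind, cell_truth))
  if (!is.null(out_dir)) {
    manifest <- truth
    manifest$cells <- NULL # per-cell table stays in the R object
    jsonlite::write_json(manifest,
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(plate_map, file.path(out_dir, "plate_map.csv"),
              row.names = FALSE)
  }
  structure(list(wells = if (is.null(out_dir)) wells else NULL,
                 truth = truth, plate_map = plate_map, spec = spec,
                 dir = out_dir),
            class = "synthetic_plate")
}

write_well_tiffs <- function(fields, dir, plate_name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in fields) {
    for (channel in c("dna", "marker", "readout")) {
      img <- pmin(f[[channel]], 1)
      tiff::writeTIFF(img,
                      file.path(dir, sprintf("%s_%s_%d_%s.tif",
                                             plate_name, f$well, f$field,
                                             channel)),
                      bits.per.sample = 32L, compression = "none")
    }
  }
}

#' Generate and score a plate well by well
#'
#' Streaming variant for full plates: each well's fields are generated,
#' scored, and discarded before the next well, so memory stays at one well's
#' worth of images. The result is identical to [generate_plate()] followed
#' by [score_plate()] with the same seed.
#'
#' @inheritParams generate_plate
#' @param config An [hcs_config()].
#' @return As [score_plate()], plus the generator `truth`.
#' @export
simulate_and_score_plate <- function(spec, plate_map, curve, seed = 1L,
                                     config = hcs_config()) {
  stopifnot(inherits(spec, "plate_spec"), inherits(curve, "misloc_curve"))
  plate_map <- validate_plate_map(plate_map)
  active <- plate_map[plate_map$role != "blank", , drop = FALSE]
  cells <- list(); qc <- NULL
  cell_truth <- list()
  for (i in seq_len(nrow(active))) {
    w <- active$well[i]
    dose <- active$dose_molar[i]
    p <- if (active$role[i] == "vehicle") curve$p_min else misloc_probability(dose, curve)
    gen <- with_seed(well_seed(seed, match(w, plate_map$well)),
                     generate_well_fields(spec, w, p))
    sc <- score_fields(gen$fields, config)
    cells[[i]] <- sc$cells
    cell_truth[[i]] <- cbind(gen$truth, dose_molar = dose, p_mislocalized = p)
    qc <- if (is.null(qc)) sc$qc else qc + sc$qc
  }
  out <- finalize_plate_scores(do.call(rbind, cells), plate_map, config, qc)
  out$truth <- list(generator = "plate", seed = seed,
                    curve = unclass(curve), spec = unclass(spec),
                    cells = do.call(rbind, cell_truth))
  out
}

#' Generate a synthetic checkerboard combination grid
#'
#' Constructs observed inhibition on a dose checkerboard whose null follows
#' Bliss independence (multiplicative single-agent survival), with an
#' optional synergy bump added on the inhibition scale in a specified cell
#' region, plus Gaussian noise:
#' \deqn{inh(i,j) = 1 - S_a(i) S_b(j) + bump(i,j) + \epsilon.}
#' With no bump and no noise, [bliss_analysis()] scores are identically 0;
#' a bump of `+0.1` is recovered as a score of 0.1 at exactly the bumped
#' cells.
#'
#' @param pl4_a,pl4_b Single-agent survival curves, lists with `mid` and
#'   `slope` (survival runs from 1 at dose 0 towards 0; bottoms fixed at 0,
#'   tops at 1).
#' @param doses_a,doses_b Dose vectors (molar), first entry 0 (vehicle);
#'   defaults: 0 plus a 2-fold ladder to give 8 doses each.
#' @param bump List with `value` (inhibition added) and `rows`, `cols`
#'   (indices of bumped cells), or `NULL` for the Bliss null.
#' @param sigma Gaussian noise on the observed inhibition (default 0).
#' @param seed RNG seed.
#' @return List with `grid` (a [checkerboard_grid()]) and `truth`.
#' @export
generate_checkerboard <- function(pl4_a = list(mid = 1e-6, slope = 1),
                                  pl4_b = list(mid = 5e-7, slope = 1),
                                  doses_a = NULL, doses_b = NULL,
                                  bump = NULL, sigma = 0, seed = 1L) {
  doses_a <- doses_a %||% c(0, 1e-7 * 2^(0:6))
  doses_b <- doses_b %||% c(0, 5e-8 * 2^(0:6))
  if (doses_a[1] != 0 || doses_b[1] != 0) {
    stop("the first dose of each series must be the vehicle control (0)",
         call. = FALSE)
  }
  sa <- pl4(doses_a, 0, 1, pl4_a$mid, pl4_a$slope)
  sb <- pl4(doses_b, 0, 1, pl4_b$mid, pl4_b$slope)
  survival <- outer(sa, sb)
  inhibition <- 1 - survival
  bump_mat <- matrix(0, length(doses_a), length(doses_b))
  if (!is.null(bump)) {
    bump_mat[bump$rows, bump$cols] <- bump$value
    inhibition <- inhibition + bump_mat
    if (any(inhibition < 0) || any(inhibition > 1)) {
      stop("bump drives inhibition outside [0, 1]", call. = FALSE)
    }
  }
  if (sigma > 0) {
    inhibition <- inhibition +
      with_seed(seed, rnorm(length(inhibition), 0, sigma))
    inhibition <- matrix(pmin(pmax(inhibition, 0), 1),
                         length(doses_a), length(doses_b))
  }
  grid <- checkerboard_grid(doses_a, doses_b, inhibition)
  truth <- list(generator = "checkerboard", seed = seed,
                pl4_a = pl4_a, pl4_b = pl4_b, bump = bump_mat,
                sigma = sigma, null_inhibition = 1 - survival)
  list(grid = grid, truth = truth)
}

#' Generate a synthetic flow-cytometry event table
#'
#' DNA content is a mixture of Gaussians at 1 (diploid) and 2 (tetraploid)
#' diploid units; marker intensities are lognormal positive / negative
#' populations. Mitotic tumor cells have 4n DNA and a positive
#' phospho-histone H3 signal, and lose the activating phosphorylation with
#' probability `pt288_loss_prob`.
#'
#' @param n_events Number of events.
#' @param mitotic_fraction Fraction of tumor cells that are mitotic.
#' @param pt288_loss_prob Probability that a mitotic cell has lost the
#'   activating phosphorylation.
#' @param tumor_fraction Fraction of events carrying the tumor identity
#'   marker (default 0.95).
#' @param g2m_fraction Fraction of non-mitotic tumor cells with 4n DNA
#'   (default 0.15).
#' @param dna_cv Coefficient of variation of each DNA peak (default 0.04).
#' @param lnorm_sigma Lognormal sigma of marker intensities (default 0.25).
#' @param pos_median,neg_median Medians of the positive / negative marker
#'   populations (defaults 10 and 0.5; the default [gate_config()]
#'   thresholds of 3 separate them cleanly).
#' @param seed RNG seed.
#' @return List with `events` (data frame `dna`, `ph3`, `pt288`, `identity`)
#'   and `truth`.
#' @export
generate_flow <- function(n_events = 10000L, mitotic_fraction = 0.05,
                          pt288_loss_prob = 0, tumor_fraction = 0.95,
                          g2m_fraction = 0.15, dna_cv = 0.04,
                          lnorm_sigma = 0.25, pos_median = 10,
                          neg_median = 0.5, seed = 1L) {
  for (p in c(mitotic_fraction, pt288_loss_prob, tumor_fraction, g2m_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  events <- with_seed(seed, {
    identity <- runif(n_events) < tumor_fraction
    mitotic <- identity & runif(n_events) < mitotic_fraction
    tetra <- mitotic | (identity & runif(n_events) < g2m_fraction)
    dna_mean <- ifelse(tetra, 2, 1)
    dna <- rnorm(n_events, dna_mean, dna_cv * dna_mean)
    lost <- mitotic & runif(n_events) < pt288_loss_prob
    ph3 <- rlnorm(n_events, log(ifelse(mitotic, pos_median, neg_median)),
                  lnorm_sigma)
    pt288 <- rlnorm(n_events,
                    log(ifelse(mitotic & !lost, pos_median, neg_median)),
                    lnorm_sigma)
    data.frame(dna = pmax(dna, 0), ph3 = ph3, pt288 = pt288,
               identity = identity, true_mitotic = mitotic,
               true_lost = lost, stringsAsFactors = FALSE)
  })
  truth <- list(generator = "flow", seed = seed, n_events = n_events,
                mitotic_fraction = mitotic_fraction,
                pt288_loss_prob = pt288_loss_prob,
                tumor_fraction = tumor_fraction,
                g2m_fraction = g2m_fraction, dna_cv = dna_cv,
                lnorm_sigma = lnorm_sigma)
  list(events = events, truth = truth)
}
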