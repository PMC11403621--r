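# Plate maps, titration tables, and serialization helpers. All
# concentrations are serialized in molar; display units belong to the
# reporting layer.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' All well ids of a 96-well plate
#'
#' @return Character vector `"A1"` ... `"H12"`, row-major.
#' @export
all_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

is_valid_well <- function(x) {
  grepl("^[A-H](1[0-2]|[1-9])$", x)
}

is_edge_well <- function(x) {
  row <- substr(x, 1, 1)
  col <- as.integer(substring(x, 2))
  row %in% c("A", "H") | col %in% c(1, 12)
}

PLATE_MAP_ROLES <- c("treatment", "vehicle", "blank", "control")

validate_plate_map <- function(map) {
  req <- c("well", "compound", "dose_molar", "role")
  if (!is.data.frame(map)) stop("plate map must be a data frame", call. = FALSE)
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols)) {
    stop("plate map is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is_valid_well(map$well))
  if (length(bad)) {
    stop(sprintf("malformed well id '%s' in plate map row %d",
                 map$well[bad[1]], bad[1]), call. = FALSE)
  }
  dup <- which(duplicated(map$well))
  if (length(dup)) {
    stop(sprintf("duplicate well id '%s' in plate map row %d",
                 map$well[dup[1]], dup[1]), call. = FALSE)
  }
  badrole <- which(!map$role %in% PLATE_MAP_ROLES)
  if (length(badrole)) {
    stop(sprintf("unknown role '%s' in plate map row %d (allowed: %s)",
                 map$role[badrole[1]], badrole[1],
                 paste(PLATE_MAP_ROLES, collapse = ", ")), call. = FALSE)
  }
  map$dose_molar[map$role %in% c("vehicle", "blank")] <- 0
  map
}

#' Load and validate a plate map CSV
#'
#' Required columns: `well` (letter-number ids `A1`..`H12`), `compound`,
#' `dose_molar`, `role` (one of `treatment`, `vehicle`, `blank`, `control`).
#' Duplicate or malformed wells are rejected with the offending row named.
#'
#' @param path CSV path.
#' @return Validated plate map data frame.
#' @export
load_plate_map <- function(path) {
  if (!file.exists(path)) stop("plate map not found: ", path, call. = FALSE)
  validate_plate_map(read.csv(path, stringsAsFactors = FALSE))
}

#' Build a dose-titration plate map
#'
#' Lays out a titration in replicate on the inner wells of a 96-well plate
#' (rows B-G, columns 2-11), with vehicle replicates alongside and
#' media-only blanks on the outermost wells.
#'
#' @param doses Dose levels (molar), e.g. a 9-point 2-fold series.
#' @param replicates Replicate wells per dose (default 3).
#' @param compound Compound label.
#' @param vehicle_replicates Vehicle control wells (default 3).
#' @return A plate map data frame.
#' @export
make_plate_map <- function(doses, replicates = 3L, compound = "compound",
                           vehicle_replicates = 3L) {
  inner <- setdiff(all_wells(), all_wells()[is_edge_well(all_wells())])
  n_needed <- length(doses) * replicates + vehicle_replicates
  if (n_needed > length(inner)) {
    stop("titration does not fit on the inner wells", call. = FALSE)
  }
  wells <- inner[seq_len(n_needed)]
  treat <- data.frame(
    well = wells[seq_len(length(doses) * replicates)],
    compound = compound,
    dose_molar = rep(doses, each = replicates),
    role = "treatment", stringsAsFactors = FALSE)
  veh <- data.frame(
    well = wells[length(doses) * replicates + seq_len(vehicle_replicates)],
    compound = "vehicle", dose_molar = 0, role = "vehicle",
    stringsAsFactors = FALSE)
  edge <- all_wells()[is_edge_well(all_wells())]
  blank <- data.frame(well = edge, compound = "media", dose_molar = 0,
                      role = "blank", stringsAsFactors = FALSE)
  validate_plate_map(rbind(treat, veh, blank))
}

#' Build an all-vehicle (untreated) plate map
#'
#' Every well of the 96-well plate is an untreated vehicle control, as used
#' for threshold-rule calibration plates.
#'
#' @param wells Well ids (default all 96).
#' @return A plate map data frame.
#' @export
vehicle_plate_map <- function(wells = all_wells()) {
  validate_plate_map(data.frame(well = wells, compound = "vehicle",
                                dose_molar = 0, role = "vehicle",
                                stringsAsFactors = FALSE))
}

#' Read a titration table CSV
#'
#' Expected columns: `concentration_molar`, `anisotropy_mP`, and optionally
#' `well`, `species`, `total_fluorescence`, `replicate`.
#'
#' @param path CSV path.
#' @return Validated titration data frame.
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("titration table not found: ", path, call. = FALSE)
  validate_titration(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a fit report as JSON
#'
#' Serializes a `kd_estimate` or `dose_response_fit` (estimate, CI, flags,
#' residual summary) to a JSON file.
#'
#' @param fit The fit object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  report <- if (inherits(fit, "kd_estimate")) {
    list(estimate_molar = fit$estimate, ci_molar = fit$ci,
         residual_sd = fit$residual_sd, converged = fit$converged,
         flags = as.list(fit$flags))
  } else if (inherits(fit, "dose_response_fit")) {
    list(bottom = fit$bottom, top = fit$top, midpoint_molar = fit$ec50,
         slope = fit$slope, residual_norm = fit$residual_norm,
         converged = fit$converged, flags = as.list(fit$flags))
  } else {
    stop("unsupported fit object", call. = FALSE)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a checkerboard CSV into a grid
#'
#' Long format with columns `dose_A_molar`, `dose_B_molar`,
#' `fold_survival`; inhibition is computed as `1 - fold_survival`.
#'
#' @param path CSV path.
#' @return A [checkerboard_grid()].
#' @export
read_checkerboard_csv <- function(path) {
  if (!file.exists(path)) stop("checkerboard table not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("dose_A_molar", "dose_B_molar", "fold_survival")
  if (!all(req %in% names(d))) {
    stop("checkerboard CSV needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  da <- sort(unique(d$dose_A_molar)); db <- sort(unique(d$dose_B_molar))
  inh <- matrix(NA_real_, length(da), length(db))
  inh[cbind(match(d$dose_A_molar, da), match(d$dose_B_molar, db))] <-
    1 - d$fold_survival
  if (anyNA(inh)) stop("incomplete checkerboard grid", call. = FALSE)
  checkerboard_grid(da, db, inh)
}

#' Write a checkerboard grid (long CSV)
#'
#' @param grid A [checkerboard_grid()], analyzed or not.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checkerboard_csv <- function(grid, path) {
  idx <- expand.grid(i = seq_along(grid$dose_a), j = seq_along(grid$dose_b))
  d <- data.frame(dose_A_molar = grid$dose_a[idx$i],
                  dose_B_molar = grid$dose_b[idx$j],
                  fold_survival = 1 - grid$inhibition[cbind(idx$i, idx$j)])
  if (!is.null(grid$score)) {
    d$expected_inhibition <- grid$expected[cbind(idx$i, idx$j)]
    d$synergy_score <- grid$score[cbind(idx$i, idx$j)]
  }
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
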