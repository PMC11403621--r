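#' Normalize raw viability readings to fold-survival
#'
#' Blank-subtracted, vehicle-normalized fold-survival:
#' \deqn{fold = (raw - \bar{blank}) / (\bar{vehicle} - \bar{blank}).}
#' Cell-free blank wells set the assay zero; the vehicle-well mean has
#' fold-survival 1 by construction.
#'
#' @param raw Numeric vector of raw assay values for the wells of interest.
#' @param blank Raw values of cell-free blank wells (>= 1).
#' @param vehicle Raw values of vehicle (e.g. DMSO) control wells (>= 3).
#' @return Fold-survival values, same length as `raw`.
#' @examples
#' normalize_viability(600, blank = 100, vehicle = c(1050, 1100, 1150))
#' @export
normalize_viability <- function(raw, blank, vehicle) {
  if (length(blank) < 1) stop("need >= 1 blank well", call. = FALSE)
  if (length(vehicle) < 3) stop("need >= 3 vehicle wells", call. = FALSE)
  b <- mean(blank); v <- mean(vehicle)
  if (v <= b) stop("vehicle signal <= blank: assay failure", call. = FALSE)
  (raw - b) / (v - b)
}

# 4PL response at dose d (d = 0 handled as the slope-sign limit)
pl4 <- function(d, bottom, top, mid, slope) {
  out <- numeric(length(d))
  z <- d == 0
  out[z] <- if (slope > 0) top else bottom
  out[!z] <- bottom + (top - bottom) / (1 + (d[!z] / mid)^slope)
  out
}

new_dose_response_fit <- function(bottom, top, ec50, slope, residual_norm,
                                  converged, flags = character()) {
  structure(list(bottom = bottom, top = top, ec50 = ec50, slope = slope,
                 residual_norm = residual_norm, converged = converged,
                 flags = flags),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf(
      "4PL fit: bottom %.4g, top %.4g, midpoint %.4g M, slope %.3g\n",
      x$bottom, x$top, x$ec50, x$slope))
  } else {
    cat("4PL fit: not converged\n")
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{r(d) = bottom + \frac{top - bottom}{1 + (d / mid)^{slope}}}
#' with the midpoint searched on a log scale. Zero doses are admitted and
#' anchored at the slope-sign limit of the untransformed model (no
#' pseudo-dose offset enters the reported parameters). The fit is reported
#' in canonical orientation with `bottom <= top` (the `(bottom, top, slope)
#' -> (top, bottom, -slope)` reparametrization leaves the curve unchanged).
#' The midpoint is the EC50, or the GI50 when responses are fold-survival.
#'
#' Flat or non-sigmoidal data (fitted amplitude below three residual
#' standard deviations) are reported with `converged = FALSE`.
#'
#' @param dose Dose vector (molar); >= 5 distinct values required, 0 allowed.
#' @param response Response vector, same length.
#' @return A `dose_response_fit`.
#' @examples
#' d <- c(0, 1e-9 * 2^(0:8))
#' y <- pl4_response(d, bottom = 0, top = 1, mid = 1e-8, slope = 1)
#' fit_4pl(d, y)
#' @export
fit_4pl <- function(dose, response) {
  if (length(dose) != length(response)) stop("length mismatch", call. = FALSE)
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]; response <- response[keep]
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (length(unique(dose)) < 5) {
    stop("insufficient data: need >= 5 distinct doses", call. = FALSE)
  }

  pos <- dose[dose > 0]
  mid0 <- log10(geometric_mean(pos))
  rng <- range(response)
  if (diff(rng) < .Machine$double.eps * 1e3) {
    return(new_dose_response_fit(rng[1], rng[2], NA_real_, NA_real_,
                                 0, FALSE, flags = "flat_response"))
  }
  lb <- c(-Inf, -Inf, log10(min(pos)) - 3, -20)
  ub <- c(Inf, Inf, log10(max(pos)) + 3, 20)
  try_fit <- function(slope0) {
    start <- c(min(response), max(response), mid0, slope0)
    minpack.lm::nls.lm(
      par = start,
      fn = function(p) response - pl4(dose, p[1], p[2], 10^p[3], p[4]),
      lower = lb, upper = ub,
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  fits <- list(try_fit(1), try_fit(-1))
  dev <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  fit <- fits[[which.min(dev)]]

  p <- fit$par
  bottom <- p[1]; top <- p[2]; mid <- 10^p[3]; slope <- p[4]
  if (bottom > top) { # canonicalize
    tmp <- bottom; bottom <- top; top <- tmp; slope <- -slope
  }
  res <- fit$fvec
  amp <- top - bottom
  ok <- fit$info %in% 1:4 && amp > 3 * sd(res) && is.finite(mid)
  new_dose_response_fit(bottom, top, if (ok) mid else NA_real_,
                        if (ok) slope else NA_real_,
                        sqrt(sum(res^2)), ok,
                        flags = if (ok) character() else "non_sigmoidal")
}

#' Evaluate a four-parameter logistic curve
#'
#' @param dose Dose vector (molar, 0 allowed).
#' @param bottom,top Lower and upper plateaus (response units).
#' @param mid Midpoint (molar, > 0).
#' @param slope Hill slope; positive slopes descend from `top` at dose 0
#'   towards `bottom` at high dose.
#' @return Response vector.
#' @export
pl4_response <- function(dose, bottom, top, mid, slope) {
  stopifnot_scalar(mid, "mid", positive = TRUE)
  pl4(dose, bottom, top, mid, slope)
}

#' Bliss-independence analysis of a checkerboard combination grid
#'
#' Computes the expected additive surface and synergy scores of a dose
#' checkerboard under Bliss independence. The first dose of each series must
#' be 0 (vehicle): row and column 0 carry the single-agent inhibition values
#' \eqn{E_a(i)} and \eqn{E_b(j)}, the expected combination inhibition is
#' \deqn{E(i,j) = E_a(i) + E_b(j) - E_a(i) E_b(j),}
#' and the synergy score is observed minus expected, so positive values mark
#' synergy and negative values antagonism. Summaries are the mean score over
#' all combination cells and the maximum mean over any 2x2 window of
#' combination cells.
#'
#' @param grid A `checkerboard_grid` from [checkerboard_grid()], or a list
#'   with elements `dose_a`, `dose_b` (molar vectors, first entries 0) and
#'   `inhibition` (matrix, rows = doses of A, columns = doses of B, values
#'   in `[0, 1]`).
#' @param clamp_tolerance Inhibition values outside `[0, 1]` by at most this
#'   much are clamped (and flagged); larger excursions are an error.
#' @return The grid with `expected`, `score` matrices and `summary` list
#'   (`mean_score`, `max_window_mean`) attached.
#' @export
bliss_analysis <- function(grid, clamp_tolerance = 0.05) {
  grid <- as_checkerboard_grid(grid)
  obs <- grid$inhibition
  if (any(obs < -clamp_tolerance) || any(obs > 1 + clamp_tolerance)) {
    stop("inhibition values outside the clampable range", call. = FALSE)
  }
  flags <- character()
  if (any(obs < 0) || any(obs > 1)) {
    flags <- "inhibition_clamped"
    obs <- pmin(pmax(obs, 0), 1)
  }
  ea <- obs[, 1]  # single-agent A (dose_b = 0 column)
  eb <- obs[1, ]  # single-agent B (dose_a = 0 row)
  expected <- outer(ea, eb, function(a, b) a + b - a * b)
  score <- obs - expected

  comb <- score[-1, -1, drop = FALSE]
  max_window <- -Inf
  if (nrow(comb) >= 2 && ncol(comb) >= 2) {
    for (i in seq_len(nrow(comb) - 1)) {
      for (j in seq_len(ncol(comb) - 1)) {
        max_window <- max(max_window, mean(comb[i:(i + 1), j:(j + 1)]))
      }
    }
  }
  grid$inhibition <- obs
  grid$expected <- expected
  grid$score <- score
  grid$summary <- list(mean_score = mean(comb), max_window_mean = max_window)
  grid$flags <- flags
  grid
}

#' Construct a checkerboard combination grid
#'
#' @param dose_a,dose_b Dose vectors (molar); the first entry of each must
#'   be 0, the vehicle control, so single-agent responses sit in row/column
#'   one.
#' @param inhibition Matrix of observed inhibition fractions, rows indexed
#'   by `dose_a`, columns by `dose_b`.
#' @return A `checkerboard_grid`.
#' @export
checkerboard_grid <- function(dose_a, dose_b, inhibition) {
  inhibition <- as.matrix(inhibition)
  if (dose_a[1] != 0 || dose_b[1] != 0) {
    stop("first dose of each series must be the vehicle control (0)",
         call. = FALSE)
  }
  if (nrow(inhibition) != length(dose_a) || ncol(inhibition) != length(dose_b)) {
    stop("inhibition matrix does not match the dose vectors", call. = FALSE)
  }
  structure(list(dose_a = dose_a, dose_b = dose_b, inhibition = inhibition),
            class = "checkerboard_grid")
}

as_checkerboard_grid <- function(x) {
  if (inherits(x, "checkerboard_grid")) return(x)
  checkerboard_grid(x$dose_a, x$dose_b, x$inhibition)
}

#' @export
print.checkerboard_grid <- function(x, ...) {
  cat(sprintf("Checkerboard grid: %d x %d doses\n",
              length(x$dose_a), length(x$dose_b)))
  if (!is.null(x$summary)) {
    cat(sprintf("  mean synergy score %.4f, max 2x2 window mean %.4f\n",
                x$summary$mean_score, x$summary$max_window_mean))
  }
  invisible(x)
}

#' Ligand efficiency
#'
#' Binding free energy per non-hydrogen atom. The default convention is the
#' common approximation \eqn{LE = 1.4 \, pK_d / N_{heavy}} (kcal/mol per
#' heavy atom at ~300 K); the exact thermodynamic form
#' \eqn{-RT \ln K_d / N_{heavy}} at a configurable temperature is also
#' available.
#'
#' @param kd Dissociation constant (molar, > 0).
#' @param heavy_atoms Non-hydrogen atom count (>= 1).
#' @param convention `"1.4"` (default) or `"thermodynamic"`.
#' @param temperature Temperature in kelvin (thermodynamic convention only).
#' @return List with `value` (unrounded), `rounded` (2 decimals), and
#'   `flag` (`"nonpositive"` when `kd >= 1` M makes LE <= 0).
#' @examples
#' ligand_efficiency(19e-9, 33)$rounded # 0.33
#' @export
ligand_efficiency <- function(kd, heavy_atoms,
                              convention = c("1.4", "thermodynamic"),
                              temperature = 298.15) {
  stopifnot_scalar(kd, "kd", positive = TRUE)
  if (!is.numeric(heavy_atoms) || heavy_atoms < 1 ||
      heavy_atoms != round(heavy_atoms)) {
    stop("`heavy_atoms` must be an integer >= 1", call. = FALSE)
  }
  convention <- match.arg(convention)
  le <- if (convention == "1.4") {
    1.4 * (-log10(kd)) / heavy_atoms
  } else {
    R_KCAL <- 1.98720425864083e-3 # kcal / (mol K)
    -R_KCAL * temperature * log(kd) / heavy_atoms
  }
  list(value = le, rounded = round(le, 2),
       flag = if (le <= 0) "nonpositive" else NULL)
}

#' Fold selectivity between two targets
#'
#' Ratio of the off-target to on-target dissociation constants. When the
#' off-target affinity is only a lower bound (too weak to measure), the
#' result is flagged as a "greater than" bound.
#'
#' @param kd_target On-target dissociation constant (molar, > 0).
#' @param kd_off Off-target dissociation constant or lower bound (molar, > 0).
#' @param off_is_lower_bound Is `kd_off` only a lower bound?
#' @return List with `ratio`, `is_lower_bound`, and a display `label`
#'   (e.g. `">1052"` for a bound).
#' @export
selectivity_ratio <- function(kd_target, kd_off, off_is_lower_bound = FALSE) {
  stopifnot_scalar(kd_target, "kd_target", positive = TRUE)
  stopifnot_scalar(kd_off, "kd_off", positive = TRUE)
  ratio <- kd_off / kd_target
  label <- if (off_is_lower_bound) {
    sprintf(">%.0f", floor(ratio))
  } else {
    sprintf("%.3g", ratio)
  }
  list(ratio = ratio, is_lower_bound = off_is_lower_bound, label = label)
}

#' Tumor volume from three caliper diameters
#'
#' Sphere volume from the geometric mean diameter of three orthogonal
#' caliper measurements: `r = gmean(d1, d2, d3) / 2`, volume `4/3 pi r^3`.
#'
#' @param d1,d2,d3 Reference diameters (mm, > 0).
#' @return Volume (mm^3).
#' @examples
#' tumor_volume(2, 2, 2) # 4.18879
#' @export
tumor_volume <- function(d1, d2, d3) {
  d <- c(d1, d2, d3)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  r <- geometric_mean(d) / 2
  (4 / 3) * pi * r^3
}

#' Free drug concentration from total and unbound fraction
#'
#' @param total Total (e.g. plasma) concentration (molar, >= 0).
#' @param fu Unbound fraction, in `[0, 1]`.
#' @return Free concentration (molar).
#' @export
free_concentration <- function(total, fu) {
  if (any(total < 0)) stop("`total` must be >= 0", call. = FALSE)
  if (any(fu < 0) || any(fu > 1)) stop("`fu` must lie in [0, 1]", call. = FALSE)
  total * fu
}
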