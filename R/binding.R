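#' Describe a three-species competitive binding system
#'
#' Collects the total concentrations and dissociation constants of the
#' protein / labeled-ligand / competitor equilibrium used throughout the
#' fluorescence-polarization analysis:
#' \deqn{P + L \rightleftharpoons PL \quad (K_{dL}), \qquad
#'       P + B \rightleftharpoons PB \quad (K_{dB}).}
#'
#' The default composition matches a competition assay run with 30 nM kinase,
#' 10 nM labeled peptide probe, and a probe dissociation constant of 1.2 nM
#' as established by direct titration.
#'
#' @param P0 Total protein concentration (molar).
#' @param L0 Total labeled-ligand concentration (molar).
#' @param B0 Total competitor concentration (molar). Zero means no
#'   competition.
#' @param KdL Dissociation constant of the labeled ligand (molar).
#' @param KdB Dissociation constant of the competitor (molar). `Inf` is the
#'   "no competition" sentinel.
#' @return An object of class `binding_system`.
#' @examples
#' sys <- binding_system(B0 = 1e-6, KdB = 19e-9)
#' bound_competitive(sys)
#' @export
binding_system <- function(P0 = 30e-9, L0 = 10e-9, B0 = 0,
                           KdL = 1.2e-9, KdB = Inf) {
  stopifnot_scalar(P0, "P0", nonneg = TRUE)
  stopifnot_scalar(L0, "L0", nonneg = TRUE)
  stopifnot_scalar(B0, "B0", nonneg = TRUE)
  stopifnot_scalar(KdL, "KdL", positive = TRUE)
  if (!(is.numeric(KdB) && length(KdB) == 1L && !is.na(KdB) && KdB > 0)) {
    stop("`KdB` must be a single value > 0 (Inf = no competition)",
         call. = FALSE)
  }
  structure(list(P0 = P0, L0 = L0, B0 = B0, KdL = KdL, KdB = KdB),
            class = "binding_system")
}

#' @export
print.binding_system <- function(x, ...) {
  cat("Competitive binding system\n")
  cat(sprintf("  P0  = %.4g M   L0  = %.4g M   B0 = %.4g M\n",
              x$P0, x$L0, x$B0))
  cat(sprintf("  KdL = %.4g M   KdB = %.4g M\n", x$KdL, x$KdB))
  invisible(x)
}

#' Anisotropy calibration of a labeled ligand
#'
#' Free and fully bound anisotropies of the labeled probe, plus the
#' quantum-yield ratio of the bound over free fluorophore. With `q = 1`
#' the observed anisotropy is a linear interpolation between the two end
#' points; with `q != 1` the bound state is weighted by its relative
#' brightness. Defaults bracket a typical plate-reader target of 90 mP at
#' mid-saturation.
#'
#' @param r_free Anisotropy of the free labeled ligand (mP).
#' @param r_bound Anisotropy of the fully bound labeled ligand (mP).
#' @param q Quantum-yield ratio bound/free (dimensionless, > 0).
#' @return An object of class `anisotropy_calibration`.
#' @export
anisotropy_calibration <- function(r_free = 60, r_bound = 120, q = 1) {
  stopifnot_scalar(r_free, "r_free")
  stopifnot_scalar(r_bound, "r_bound")
  stopifnot_scalar(q, "q", positive = TRUE)
  if (!(r_bound > r_free)) stop("`r_bound` must exceed `r_free`", call. = FALSE)
  structure(list(r_free = r_free, r_bound = r_bound, q = q),
            class = "anisotropy_calibration")
}

#' Two-species equilibrium complex concentration
#'
#' Exact bound complex concentration for a single protein-ligand equilibrium
#' from the quadratic mass balance: `[PL]` is the physical root of
#' \deqn{[PL]^2 - (P_0 + L_0 + K_d)[PL] + P_0 L_0 = 0.}
#'
#' @param P0 Total protein concentration (molar), vectorized.
#' @param L0 Total ligand concentration (molar), vectorized.
#' @param Kd Dissociation constant (molar), vectorized.
#' @return Complex concentration `[PL]` (molar), in `[0, min(P0, L0)]`.
#' @examples
#' bound_direct(200e-9, 11e-9, 1.2e-9)
#' @export
bound_direct <- function(P0, L0, Kd) {
  if (!all(is.finite(P0), is.finite(L0), is.finite(Kd))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(P0 < 0) || any(L0 < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(Kd <= 0)) stop("`Kd` must be > 0", call. = FALSE)
  s <- P0 + L0 + Kd
  # numerically stable smaller quadratic root: 2*P0*L0 / (s + sqrt(disc))
  disc <- s^2 - 4 * P0 * L0
  disc[disc < 0] <- 0 # guard tiny negative from cancellation
  pl <- 2 * P0 * L0 / (s + sqrt(disc))
  pmin(pl, pmin(P0, L0))
}

# Free-protein mass balance for the three-species system:
# P_free * (1 + L0/(KdL+P) + B0/(KdB+P)) - P0 = 0
free_protein_balance <- function(P, P0, L0, B0, KdL, KdB) {
  bterm <- if (is.finite(KdB)) B0 / (KdB + P) else 0
  P * (1 + L0 / (KdL + P) + bterm) - P0
}

# Free-protein root to full relative precision by safeguarded Newton on the
# bracket [P0/m(0), P0], where m(P) = 1 + L0/(KdL+P) + B0/(KdB+P) is the
# (decreasing) binding multiplier, so P* = P0/m(P*) always lies inside.
# Bisection steps are taken in log space when Newton leaves the bracket,
# which keeps relative accuracy even when P* is many orders below P0.
# Vectorized over B0 (with scalar P0, L0, KdL, KdB) so titration curves are
# solved in one pass.
solve_free_protein <- function(P0, L0, B0, KdL, KdB, init = NA_real_) {
  if (P0 == 0) return(rep(0, length(B0)))
  n <- length(B0)
  bterm0 <- if (is.finite(KdB)) B0 / KdB else rep(0, n)
  lo <- P0 / (1 + L0 / KdL + bterm0)
  hi <- rep(P0, n)
  p <- ifelse(is.finite(init) & init > lo & init < hi, init, sqrt(lo * hi))
  active <- rep(TRUE, n)
  for (i in 1:200) {
    f <- free_protein_balance(p, P0, L0, B0, KdL, KdB)
    pos <- f > 0
    hi[active & pos] <- p[active & pos]
    lo[active & !pos] <- p[active & !pos]
    bderiv <- if (is.finite(KdB)) B0 * KdB / (KdB + p)^2 else 0
    df <- 1 + L0 * KdL / (KdL + p)^2 + bderiv
    p_new <- p - f / df
    bad <- !is.finite(p_new) | p_new <= lo | p_new >= hi
    p_new[bad] <- sqrt(lo[bad] * hi[bad]) # log-space bisection
    done <- abs(p_new - p) <= 4 * .Machine$double.eps * p_new
    p[active] <- p_new[active]
    active <- active & !done
    if (!any(active)) break
  }
  p
}

#' Labeled-complex concentration under competition (exact solution)
#'
#' Closed-form equilibrium solution for one protein and two competing
#' ligands. The free-protein concentration is the unique physical root of
#' the cubic
#' \deqn{[P]^3 + a[P]^2 + b[P] + c = 0}
#' with
#' \eqn{a = K_{dL} + K_{dB} + L_0 + B_0 - P_0},
#' \eqn{b = K_{dB}(L_0 - P_0) + K_{dL}(B_0 - P_0) + K_{dL} K_{dB}},
#' \eqn{c = -K_{dL} K_{dB} P_0}, evaluated with the trigonometric real-root
#' expression. The labeled complex is then
#' \eqn{[PL] = L_0 [P] / (K_{dL} + [P])}.
#'
#' When the trigonometric form is numerically pathological (the cosine
#' argument leaves `[-1, 1]` by more than 1e-9, or the discriminant
#' degenerates) the routine falls back to a bracketed root solve of the
#' free-protein mass balance on `[0, P0]`; arguments within 1e-9 of the
#' boundary are clamped. `B0 = 0` or `KdB = Inf` reduce exactly to
#' [bound_direct()].
#'
#' @param sys A [binding_system()].
#' @return Labeled-complex concentration `[PL]` (molar).
#' @examples
#' sys <- binding_system(P0 = 30e-9, L0 = 10e-9, KdL = 1.2e-9,
#'                       B0 = 1e-6, KdB = 19e-9)
#' bound_competitive(sys)
#' @export
bound_competitive <- function(sys) {
  stopifnot(inherits(sys, "binding_system"))
  P0 <- sys$P0; L0 <- sys$L0; B0 <- sys$B0; KdL <- sys$KdL; KdB <- sys$KdB
  if (!all(is.finite(c(P0, L0, B0, KdL))) || is.na(KdB)) {
    stop("non-finite binding parameters", call. = FALSE)
  }
  if (B0 == 0 || !is.finite(KdB)) {
    return(bound_direct(P0, L0, KdL))
  }
  if (P0 == 0 || L0 == 0) return(0)

  # The trig expression cancels catastrophically when the root lies many
  # orders below the coefficient scale; it serves as the initial guess for
  # a bracketed Newton refinement that restores full relative precision
  # (and is the standalone fallback when the cosine argument is
  # pathological).
  p_init <- trig_free_protein(P0, L0, B0, KdL, KdB)
  p_free <- solve_free_protein(P0, L0, B0, KdL, KdB, init = p_init)
  pl <- L0 * p_free / (KdL + p_free)
  min(pl, min(P0, L0))
}

#' Competitor-bound complex concentration
#'
#' Companion of [bound_competitive()]: the concentration of the
#' protein-competitor complex `[PB]` at the same equilibrium.
#'
#' @inheritParams bound_competitive
#' @return `[PB]` (molar).
#' @export
bound_competitor <- function(sys) {
  stopifnot(inherits(sys, "binding_system"))
  if (sys$B0 == 0 || !is.finite(sys$KdB)) return(0)
  if (sys$P0 == 0) return(0)
  pl <- bound_competitive(sys)
  # recover free protein from [PL], then [PB] from its own isotherm
  p_free <- if (pl >= sys$L0) {
    solve_free_protein(sys$P0, sys$L0, sys$B0, sys$KdL, sys$KdB)
  } else {
    sys$KdL * pl / (sys$L0 - pl)
  }
  sys$B0 * p_free / (sys$KdB + p_free)
}

#' Map a bound fraction to an observed anisotropy
#'
#' Observed anisotropy of a mixture of free and bound labeled ligand,
#' weighting the bound state by the quantum-yield ratio `q`:
#' \deqn{r = \frac{q f_b r_{bound} + (1 - f_b) r_{free}}
#'            {q f_b + (1 - f_b)}.}
#' With `q = 1` this is linear interpolation between the calibration end
#' points.
#'
#' @param fb Bound fraction of the labeled ligand, in `[0, 1]` (vectorized).
#' @param cal An [anisotropy_calibration()].
#' @return Observed anisotropy (mP).
#' @export
anisotropy_signal <- function(fb, cal) {
  stopifnot(inherits(cal, "anisotropy_calibration"))
  if (any(!is.finite(fb)) || any(fb < 0) || any(fb > 1)) {
    stop("`fb` must lie in [0, 1]", call. = FALSE)
  }
  (cal$q * fb * cal$r_bound + (1 - fb) * cal$r_free) /
    (cal$q * fb + (1 - fb))
}

# unvalidated signal equation used inside optimizers (parameters may pass
# through unphysical intermediate values during a least-squares search)
signal_mp <- function(fb, r_free, r_bound, q) {
  (q * fb * r_bound + (1 - fb) * r_free) / (q * fb + (1 - fb))
}

# model anisotropy for a direct titration at protein concentrations `p`
direct_model_mp <- function(p, L0, Kd, r_free, r_bound, q = 1) {
  fb <- bound_direct(p, L0, Kd) / L0
  signal_mp(pmin(pmax(fb, 0), 1), r_free, r_bound, q)
}

# trig real root of the free-protein cubic, vectorized over B0; NA where the
# expression is numerically pathological (callers refine / fall back)
trig_free_protein <- function(P0, L0, B0, KdL, KdB) {
  a <- KdL + KdB + L0 + B0 - P0
  b <- KdB * (L0 - P0) + KdL * (B0 - P0) + KdL * KdB
  c3 <- -KdL * KdB * P0
  q2 <- a^2 - 3 * b
  out <- rep(NA_real_, length(B0))
  ok <- q2 > 0
  arg <- rep(NA_real_, length(B0))
  arg[ok] <- (-2 * a[ok]^3 + 9 * a[ok] * b[ok] - 27 * c3) /
    (2 * sqrt(q2[ok]^3))
  ok <- ok & abs(arg) <= 1 + 1e-9
  arg <- pmin(1, pmax(-1, arg))
  out[ok] <- -a[ok] / 3 + (2 / 3) * sqrt(q2[ok]) * cos(acos(arg[ok]) / 3)
  out
}

# model anisotropy for a competition titration at competitor concentrations `b`
competition_model_mp <- function(b, P0, L0, KdL, KdB, r_free, r_bound, q = 1) {
  if (P0 == 0 || L0 == 0) {
    return(signal_mp(rep(0, length(b)), r_free, r_bound, q))
  }
  init <- if (is.finite(KdB)) trig_free_protein(P0, L0, b, KdL, KdB) else NA
  kdb_eff <- if (is.finite(KdB)) KdB else Inf
  p_free <- solve_free_protein(P0, L0, b, KdL, kdb_eff, init = init)
  fb <- (L0 * p_free / (KdL + p_free)) / L0
  signal_mp(pmin(pmax(fb, 0), 1), r_free, r_bound, q)
}

new_kd_estimate <- function(estimate, ci, residuals, converged,
                            flags = character(), fit = NULL) {
  structure(list(estimate = estimate, ci = ci,
                 residual_sd = if (length(residuals)) sd(residuals) else NA_real_,
                 residuals = residuals, converged = converged,
                 flags = flags, fit = fit),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  if (isTRUE(x$converged)) {
    cat(sprintf("Kd estimate: %.4g M", x$estimate))
    if (all(is.finite(x$ci))) {
      cat(sprintf("  [%.4g, %.4g] 95%% bootstrap CI", x$ci[1], x$ci[2]))
    }
    cat("\n")
  } else {
    cat("Kd estimate: not converged\n")
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

validate_titration <- function(series, conc_col = "concentration_molar") {
  req <- c(conc_col, "anisotropy_mP")
  if (!is.data.frame(series) || !all(req %in% names(series))) {
    stop(sprintf("titration series needs columns %s",
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  if (any(series[[conc_col]] < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (length(unique(series[[conc_col]])) < 2) {
    stop("concentrations must not all be equal", call. = FALSE)
  }
  if (anyNA(series$anisotropy_mP)) stop("missing anisotropy values", call. = FALSE)
  series
}

# Kd search bounds (molar, log10 scale) shared by both fitters.
KD_LOG10_RANGE <- c(-12, -1)

# bootstrap by resampling replicate groups within each concentration
resample_replicates <- function(series, conc_col) {
  idx <- unlist(lapply(split(seq_len(nrow(series)), series[[conc_col]]),
                       function(i) sample(i, length(i), replace = TRUE)),
                use.names = FALSE)
  series[idx, , drop = FALSE]
}

#' Fit a dissociation constant from a direct titration
#'
#' Least-squares estimate of the probe dissociation constant (and the free /
#' bound anisotropy end points) from a direct protein-into-probe titration,
#' under the exact two-species mass balance mapped to anisotropy. The
#' dissociation constant is searched on a log10 scale over 1e-12 to 1e-1 M,
#' initialized at the geometric mean of the tested (non-zero)
#' concentrations. Confidence intervals come from a percentile bootstrap
#' that resamples replicates within each concentration.
#'
#' A flat series (fitted amplitude below three residual standard deviations)
#' is reported as not converged.
#'
#' @param series Data frame with columns `concentration_molar` (varied
#'   protein concentration), `anisotropy_mP`, and optionally `replicate`.
#'   At least 5 distinct concentrations are required.
#' @param L0 Total labeled-ligand concentration (molar).
#' @param cal Starting [anisotropy_calibration()]; end points are refined
#'   during the fit, `q` is held fixed.
#' @param n_boot Bootstrap resamples for the CI (0 skips the bootstrap).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `kd_estimate` with the fitted calibration in `$fit`.
#' @export
fit_direct_kd <- function(series, L0, cal = anisotropy_calibration(),
                          n_boot = 1000L, boot_seed = 1L) {
  series <- validate_titration(series)
  stopifnot_scalar(L0, "L0", positive = TRUE)
  conc <- series$concentration_molar
  if (length(unique(conc)) < 5) {
    stop("need >= 5 distinct protein concentrations", call. = FALSE)
  }
  y <- series$anisotropy_mP
  q <- cal$q

  fit_once <- function(dat) {
    x <- dat$concentration_molar
    yy <- dat$anisotropy_mP
    start <- c(log10(geometric_mean(pmax(x[x > 0], 1e-12))),
               min(yy), max(yy))
    resid_fn <- function(par) {
      yy - direct_model_mp(x, L0, 10^par[1], par[2], par[3], q)
    }
    fit <- minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(KD_LOG10_RANGE[1], -Inf, -Inf),
      upper = c(KD_LOG10_RANGE[2], Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    fit
  }

  fit <- fit_once(series)
  res <- fit$fvec
  amp <- abs(fit$par[3] - fit$par[2])
  flat <- !(fit$info %in% 1:4) || amp < 3 * sd(res) || sd(y) < 1e-12
  if (flat) {
    return(new_kd_estimate(NA_real_, c(NA_real_, NA_real_), res, FALSE,
                           flags = "no_signal_change"))
  }
  kd_hat <- 10^fit$par[1]

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(i) {
        b <- resample_replicates(series, "concentration_molar")
        10^fit_once(b)$par[1]
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  new_kd_estimate(kd_hat, ci, res, TRUE,
                  fit = list(r_free = fit$par[2], r_bound = fit$par[3], q = q))
}

#' Fit a competitor dissociation constant from a displacement titration
#'
#' Least-squares estimate of the competitor dissociation constant from a
#' competition fluorescence-polarization series, under the exact
#' three-species equilibrium ([bound_competitive()]) mapped to anisotropy.
#' Assay composition (`P0`, `L0`, `KdL`) and the anisotropy calibration are
#' held fixed; only the competitor constant is fitted, on a log10 scale over
#' 1e-12 to 1e-1 M starting at the geometric mean of the tested non-zero
#' doses.
#'
#' If a `total_fluorescence` column is present, points whose total
#' fluorescence deviates from the series median by more than
#' `fluor_tolerance` (fractional) are flagged (never corrected or dropped):
#' the channel is monitored for compound interference artifacts.
#'
#' A series with no measurable displacement (fitted amplitude below three
#' residual standard deviations) is reported as a lower bound at the top of
#' the search range with flag `"too_weak_to_measure"`.
#'
#' @param series Data frame with columns `concentration_molar` (competitor),
#'   `anisotropy_mP`, optionally `replicate` and `total_fluorescence`.
#'   At least 6 distinct competitor concentrations are required.
#' @param sys A [binding_system()] giving `P0`, `L0`, `KdL` (its `B0`/`KdB`
#'   are ignored).
#' @param cal Fixed [anisotropy_calibration()].
#' @param n_boot,boot_seed Percentile-bootstrap settings as in
#'   [fit_direct_kd()].
#' @param fluor_tolerance Fractional deviation of total fluorescence that
#'   flags a point.
#' @return A `kd_estimate`.
#' @export
fit_competition_kd <- function(series, sys, cal = anisotropy_calibration(),
                               n_boot = 1000L, boot_seed = 1L,
                               fluor_tolerance = 0.2) {
  series <- validate_titration(series)
  stopifnot(inherits(sys, "binding_system"), inherits(cal, "anisotropy_calibration"))
  conc <- series$concentration_molar
  if (length(unique(conc)) < 6) {
    stop("need >= 6 distinct competitor concentrations", call. = FALSE)
  }

  flags <- character()
  if ("total_fluorescence" %in% names(series)) {
    tf <- series$total_fluorescence
    dev <- abs(tf / median(tf) - 1)
    if (any(dev > fluor_tolerance)) {
      flags <- c(flags, sprintf("total_fluorescence_artifact:%d_points",
                                sum(dev > fluor_tolerance)))
    }
  }

  fit_once <- function(dat) {
    x <- dat$concentration_molar
    yy <- dat$anisotropy_mP
    start <- log10(geometric_mean(pmax(x[x > 0], 1e-12)))
    resid_fn <- function(par) {
      yy - competition_model_mp(x, sys$P0, sys$L0, sys$KdL, 10^par,
                                cal$r_free, cal$r_bound, cal$q)
    }
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = KD_LOG10_RANGE[1], upper = KD_LOG10_RANGE[2],
                       control = minpack.lm::nls.lm.control(maxiter = 200))
  }

  fit <- fit_once(series)
  res <- fit$fvec
  kd_hat <- 10^fit$par[1]
  # displacement amplitude the fitted model spans over the tested doses
  pred <- competition_model_mp(range(conc), sys$P0, sys$L0, sys$KdL, kd_hat,
                               cal$r_free, cal$r_bound, cal$q)
  amp <- abs(diff(pred))
  sigma <- max(sd(res), .Machine$double.eps)
  if (amp < 3 * sigma || !(fit$info %in% 1:4)) {
    return(new_kd_estimate(10^KD_LOG10_RANGE[2], c(10^KD_LOG10_RANGE[2], Inf),
                           res, FALSE,
                           flags = c(flags, "too_weak_to_measure")))
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(i) {
        b <- resample_replicates(series, "concentration_molar")
        10^fit_once(b)$par[1]
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  new_kd_estimate(kd_hat, ci, res, TRUE, flags = flags)
}
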