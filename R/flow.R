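#' Gating configuration for flow-cytometry event tables
#'
#' @param dna_window 4n DNA gate in diploid units (diploid peak calibrated
#'   to 1, tetraploid to 2); default `c(1.8, 2.2)`.
#' @param ph3_threshold Phospho-histone H3 positivity threshold (a.u.).
#' @param pt288_threshold Activating-phosphorylation positivity threshold
#'   (a.u.).
#' @param min_events Minimum gated events below which downstream statistics
#'   are flagged undefined.
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(dna_window = c(1.8, 2.2), ph3_threshold = 3,
                        pt288_threshold = 3, min_events = 50) {
  if (!(length(dna_window) == 2 && dna_window[1] < dna_window[2])) {
    stop("`dna_window` must be (low, high) with low < high", call. = FALSE)
  }
  stopifnot_scalar(ph3_threshold, "ph3_threshold", positive = TRUE)
  stopifnot_scalar(pt288_threshold, "pt288_threshold", positive = TRUE)
  structure(list(dna_window = dna_window, ph3_threshold = ph3_threshold,
                 pt288_threshold = pt288_threshold, min_events = min_events),
            class = "gate_config")
}

validate_events <- function(events) {
  req <- c("dna", "ph3", "pt288", "identity")
  if (!is.data.frame(events) || !all(req %in% names(events))) {
    stop(sprintf("event table needs columns %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  if (!nrow(events)) stop("empty event table", call. = FALSE)
  events
}

#' Gate a flow-cytometry event table
#'
#' Nested conjunctive gates: tumor cells by identity marker; mitotic cells
#' as tumor cells with 4n DNA content and phospho-histone H3 positivity
#' (the marker is only detectable in mitotic cells, identifiable by their 4n
#' DNA); and among those, cells that have lost the activating
#' phosphorylation. Gating is deterministic and idempotent.
#'
#' @param events Data frame with columns `dna` (diploid units), `ph3`,
#'   `pt288` (a.u.), `identity` (logical tumor-cell flag).
#' @param config A [gate_config()].
#' @return List of logical row-masks `tumor`, `mitotic`, `ph3_pos` (alias of
#'   `mitotic`), `pt288_neg`, plus `flags` (contains
#'   `"empty_mitotic_subset"` when no events gate as mitotic).
#' @export
gate_events <- function(events, config = gate_config()) {
  events <- validate_events(events)
  tumor <- as.logical(events$identity)
  in_4n <- events$dna >= config$dna_window[1] & events$dna <= config$dna_window[2]
  mitotic <- tumor & in_4n & events$ph3 > config$ph3_threshold
  pt288_neg <- mitotic & events$pt288 < config$pt288_threshold
  flags <- if (!any(mitotic)) "empty_mitotic_subset" else character()
  list(tumor = tumor, mitotic = mitotic, ph3_pos = mitotic,
       pt288_neg = pt288_neg, flags = flags)
}

# percentile bootstrap of a binary-event fraction: resampling n events with
# replacement makes the resampled count Binomial(n, phat)
boot_fraction <- function(n, phat, n_boot) {
  rbinom(n_boot, n, phat) / n
}

#' Fold-change in mitotic (PH3-positive) cells versus vehicle
#'
#' Ratio of the mitotic fraction (PH3-positive cells among tumor-gated
#' events) in a treated sample to that in a vehicle sample — the
#' pharmacodynamic end point of a mitotic-delay phenotype. Confidence
#' interval by percentile bootstrap over events.
#'
#' @param treated,vehicle Event tables (see [gate_events()]).
#' @param config A [gate_config()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param boot_seed Seed for the bootstrap.
#' @return List with `fold`, `ci` (95% percentile interval),
#'   `treated_fraction`, `vehicle_fraction`, `flags`.
#' @export
ph3_fold_change <- function(treated, vehicle, config = gate_config(),
                            n_boot = 1000L, boot_seed = 1L) {
  gt <- gate_events(treated, config)
  gv <- gate_events(vehicle, config)
  nt <- sum(gt$tumor); nv <- sum(gv$tumor)
  if (nt < config$min_events || nv < config$min_events) {
    stop("too few tumor-gated events", call. = FALSE)
  }
  ft <- sum(gt$mitotic) / nt
  fv <- sum(gv$mitotic) / nv
  if (fv == 0) {
    return(list(fold = NA_real_, ci = c(NA_real_, NA_real_),
                treated_fraction = ft, vehicle_fraction = fv,
                flags = "vehicle_fraction_zero"))
  }
  ci <- with_seed(boot_seed, {
    bt <- boot_fraction(nt, ft, n_boot)
    bv <- boot_fraction(nv, fv, n_boot)
    ok <- bv > 0
    unname(quantile(bt[ok] / bv[ok], c(0.025, 0.975)))
  })
  list(fold = ft / fv, ci = ci, treated_fraction = ft, vehicle_fraction = fv,
       flags = character())
}

#' Fraction of mitotic cells losing the activating phosphorylation
#'
#' Among PH3-positive (mitotic) gated cells, the fraction whose
#' activating-phosphorylation signal falls below threshold, with a
#' percentile-bootstrap confidence interval.
#'
#' @param events Event table (see [gate_events()]).
#' @param config A [gate_config()].
#' @param n_boot,boot_seed Bootstrap settings.
#' @return List with `fraction`, `ci`, `n_mitotic`, `flags`.
#' @export
pthr288_loss <- function(events, config = gate_config(), n_boot = 1000L,
                         boot_seed = 1L) {
  g <- gate_events(events, config)
  n <- sum(g$mitotic)
  if (n == 0) {
    return(list(fraction = NA_real_, ci = c(NA_real_, NA_real_),
                n_mitotic = 0L, flags = "no_mitotic_events"))
  }
  if (n < config$min_events) {
    warning("fewer mitotic events than the configured minimum")
  }
  frac <- sum(g$pt288_neg) / n
  ci <- with_seed(boot_seed,
                  unname(quantile(boot_fraction(n, frac, n_boot),
                                  c(0.025, 0.975))))
  list(fraction = frac, ci = ci, n_mitotic = n, flags = character())
}
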