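# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the mass-balance oracle solves the free-protein
# equation by bracketed bisection on a log scale, and the fixed-point oracle
# iterates the two-species mass balance directly.

# free labeled-complex concentration by 1-D root solve on free protein,
# log10 scale (retains relative precision when the root is tiny)
oracle_bound_competitive <- function(P0, L0, B0, KdL, KdB) {
  if (P0 == 0 || L0 == 0) return(0)
  h <- function(u) {
    P <- 10^u
    P * (1 + L0 / (KdL + P) + B0 / (KdB + P)) - P0
  }
  m0 <- 1 + L0 / KdL + B0 / KdB
  u <- uniroot(h, c(log10(P0 / m0) - 1, log10(P0) + 1e-12),
               tol = 1e-13)$root
  pf <- 10^u
  L0 * pf / (KdL + pf)
}

# two-species complex by bracketed root solve of the mass-balance equation
# (P0 - PL)(L0 - PL) = Kd * PL on [0, min(P0, L0)] (independent of the
# quadratic formula)
oracle_bound_direct <- function(P0, L0, Kd) {
  if (P0 == 0 || L0 == 0) return(0)
  f <- function(pl) (P0 - pl) * (L0 - pl) - Kd * pl
  uniroot(f, c(0, min(P0, L0)), tol = 1e-25)$root
}

# reference 4PL used to construct synthetic response tables in tests
oracle_pl4 <- function(d, bottom, top, mid, slope) {
  ifelse(d == 0, if (slope > 0) top else bottom,
         bottom + (top - bottom) / (1 + (d / mid)^slope))
}
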