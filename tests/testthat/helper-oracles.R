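# Independent oracles, deliberately implemented differently from the package:
# numeric root-finding on the raw mass balances instead of closed forms.

# Bound fraction of probe Rt titrated by Lt: solve the mass balance for free
# titrant l (l + Rt*l/(KD+l) = Lt) by bisection, then f = l/(KD+l).
oracle_bound_fraction <- function(Rt, Lt, KD) {
  if (Lt == 0) return(0)
  h <- function(l) l + Rt * l / (KD + l) - Lt
  lo <- 0; hi <- Lt
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) hi <- mid else lo <- mid
  }
  l <- (lo + hi) / 2
  l / (KD + l)
}

# Competition speciation by dense bisection on free protein over [0, Pt].
oracle_speciation <- function(Pt, Lt, Ct, KDL, KDC) {
  if (Pt == 0) return(list(freeP = 0, freeL = Lt, freeC = Ct, PL = 0, PC = 0))
  g <- function(p) p * (1 + Lt / (KDL + p) + Ct / (KDC + p)) - Pt
  lo <- 0; hi <- Pt
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  p <- (lo + hi) / 2
  freeL <- Lt * KDL / (KDL + p)
  freeC <- Ct * KDC / (KDC + p)
  list(freeP = p, freeL = freeL, freeC = freeC,
       PL = p * freeL / KDL, PC = p * freeC / KDC)
}

# Sequential two-site speciation by brute-force grid search + bisection on
# free protein.
oracle_sequential <- function(Nt, KD1, KD2, ratio) {
  Pt <- ratio * Nt
  if (Pt == 0) return(c(1, 0, 0))
  tot <- function(p) {
    denom <- 1 + p / KD1 + p^2 / (KD1 * KD2)
    N <- Nt / denom
    p + N * p / KD1 + 2 * N * p^2 / (KD1 * KD2)
  }
  # coarse grid to bracket, then bisection
  grid <- c(0, 10^seq(-18, log10(Pt), length.out = 400), Pt)
  idx <- which(vapply(grid, tot, numeric(1)) >= Pt)[1]
  lo <- grid[max(idx - 1L, 1L)]; hi <- grid[idx]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (tot(mid) > Pt) hi <- mid else lo <- mid
  }
  p <- (lo + hi) / 2
  denom <- 1 + p / KD1 + p^2 / (KD1 * KD2)
  N <- Nt / denom
  c(N, N * p / KD1, N * p^2 / (KD1 * KD2)) / Nt
}

make_design <- function(...) simulation_design(...)

standard_truth <- function() {
  binding_parameters(A0 = 0.05, A1 = 0.15, KD1 = 2.1e-9, Rt = 2e-9)
}
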