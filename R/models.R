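#' Convert polarization to anisotropy
#'
#' Plate readers commonly report fluorescence polarization \eqn{P}; the binding
#' models in this package operate on anisotropy \eqn{r = 2P / (3 - P)}. Both
#' quantities are dimensionless.
#'
#' @param P numeric vector of polarization values, each in \eqn{(-1, 3)}.
#' @return Numeric vector of anisotropy values.
#' @examples
#' polarization_to_anisotropy(0.5) # 0.4
#' @seealso [anisotropy_to_polarization()]
#' @export
polarization_to_anisotropy <- function(P) {
  assert_numeric_vec(P, "P")
  if (any(P <= -1 | P >= 3))
    stop_equibind("polarization must lie in (-1, 3)", "equibind_domain_error")
  2 * P / (3 - P)
}

#' @rdname polarization_to_anisotropy
#' @param r numeric vector of anisotropy values, each in \eqn{(-2, 1)}.
#' @export
anisotropy_to_polarization <- function(r) {
  assert_numeric_vec(r, "r")
  if (any(r <= -2 | r >= 1))
    stop_equibind("anisotropy must lie in (-2, 1)", "equibind_domain_error")
  3 * r / (2 + r)
}

#' Binding parameters for the two-transition anisotropy model
#'
#' Container for the parameters of the depletion-corrected anisotropy curve:
#' lower baseline `A0`, upper baseline of the first (high-affinity) transition
#' `A1`, upper baseline of the second transition `A2`, the two dissociation
#' constants `KD1` and `KD2` (molar), and the total probe concentration `Rt`
#' (molar). Supplying `A2`/`KD2` as `NA` selects the one-transition variant,
#' in which the second binding term is omitted.
#'
#' @param A0,A1 anisotropy baselines (dimensionless, finite).
#' @param KD1 molar dissociation constant of the first transition (> 0).
#' @param Rt molar total probe concentration (>= 0).
#' @param A2 anisotropy baseline of the second transition, or `NA`.
#' @param KD2 molar dissociation constant of the second transition, or `NA`.
#' @return An object of class `binding_parameters`.
#' @examples
#' binding_parameters(A0 = 0.05, A1 = 0.15, KD1 = 2.1e-9, Rt = 2e-9)
#' @export
binding_parameters <- function(A0, A1, KD1, Rt, A2 = NA_real_, KD2 = NA_real_) {
  assert_scalar_number(A0, "A0")
  assert_scalar_number(A1, "A1")
  assert_scalar_number(KD1, "KD1", positive = TRUE)
  assert_scalar_number(Rt, "Rt", nonneg = TRUE)
  two <- !is.na(A2) || !is.na(KD2)
  if (two) {
    assert_scalar_number(A2, "A2")
    assert_scalar_number(KD2, "KD2", positive = TRUE)
  }
  structure(
    list(A0 = A0, A1 = A1, A2 = if (two) A2 else NA_real_,
         KD1 = KD1, KD2 = if (two) KD2 else NA_real_, Rt = Rt,
         two_transition = two),
    class = "binding_parameters"
  )
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat(sprintf("Binding parameters (%s-transition)\n",
              if (x$two_transition) "two" else "one"))
  cat(sprintf("  A0 = %.4g  A1 = %.4g", x$A0, x$A1))
  if (x$two_transition) cat(sprintf("  A2 = %.4g", x$A2))
  cat(sprintf("\n  KD1 = %.4g M", x$KD1))
  if (x$two_transition) cat(sprintf("  KD2 = %.4g M", x$KD2))
  cat(sprintf("\n  Rt  = %.4g M\n", x$Rt))
  invisible(x)
}

#' Fraction of probe bound under ligand depletion
#'
#' Exact single-site bound fraction from the mass-balance quadratic,
#' \deqn{f = \frac{(R_t + L_t + K_D) - \sqrt{(R_t + L_t + K_D)^2 - 4 R_t L_t}}
#' {2 R_t},}
#' valid when the probe concentration \eqn{R_t} is comparable to \eqn{K_D}
#' (ligand depletion). Evaluated in the conjugate form
#' \eqn{f = 2 L_t / (b + \sqrt{b^2 - 4 R_t L_t})} with
#' \eqn{b = R_t + L_t + K_D}, which avoids catastrophic cancellation at
#' \eqn{L_t \gg K_D}. Below `Rt = 1e-15` M the quadratic is numerically
#' degenerate and the Langmuir limit \eqn{L_t / (L_t + K_D)} is returned.
#'
#' @param Rt molar total probe concentration (>= 0).
#' @param Lt numeric vector of molar total titrant concentrations (>= 0).
#' @param KD1 molar dissociation constant (> 0).
#' @return Bound fraction(s) in \[0, 1\], non-decreasing in `Lt`.
#' @examples
#' bound_fraction_quadratic(Rt = 1e-8, Lt = 1e-8, KD1 = 1e-8) # (3 - sqrt(5))/2
#' @export
bound_fraction_quadratic <- function(Rt, Lt, KD1) {
  assert_scalar_number(Rt, "Rt", nonneg = TRUE)
  assert_numeric_vec(Lt, "Lt", nonneg = TRUE)
  assert_scalar_number(KD1, "KD1", positive = TRUE)
  if (Rt < 1e-15) return(Lt / (Lt + KD1))
  b <- Rt + Lt + KD1
  disc <- b * b - 4 * Rt * Lt
  2 * Lt / (b + sqrt(pmax(disc, 0)))
}

#' Two-transition anisotropy binding curve
#'
#' Evaluates the depletion-corrected anisotropy model
#' \deqn{A = A_0 + (A_1 - A_0) f_q(R_t, L_t, K_{D1}) +
#'       (A_2 - A_1) \frac{L_t}{L_t + K_{D2}},}
#' where \eqn{f_q} is [bound_fraction_quadratic()]. The second (hyperbolic,
#' no-depletion) term models the weak low-specificity transition seen at high
#' protein concentration; it is omitted for one-transition parameters.
#'
#' @param Lt numeric vector of molar total titrant (protein) concentrations.
#' @param params a [binding_parameters()] object.
#' @return Anisotropy values, `A0` at `Lt = 0`, approaching `A2` (or `A1` for
#'   the one-transition variant) at saturation.
#' @export
anisotropy_curve <- function(Lt, params) {
  if (!inherits(params, "binding_parameters"))
    stop_equibind("`params` must be a binding_parameters object",
                  "equibind_validation_error")
  assert_numeric_vec(Lt, "Lt", nonneg = TRUE)
  A <- params$A0 +
    (params$A1 - params$A0) * bound_fraction_quadratic(params$Rt, Lt, params$KD1)
  if (params$two_transition)
    A <- A + (params$A2 - params$A1) * Lt / (Lt + params$KD2)
  A
}

#' Competition system between a labeled ligand and an unlabeled competitor
#'
#' Describes one protein P binding mutually exclusively either a labeled
#' nucleic acid L (dissociation constant `KDL`) or an unlabeled competitor C
#' (`KDC`). All concentrations are totals in molar units.
#'
#' @param Pt,Lt,Ct molar totals of protein, labeled ligand, competitor (>= 0).
#' @param KDL,KDC molar dissociation constants (> 0).
#' @return An object of class `competition_system`.
#' @export
competition_system <- function(Pt, Lt, Ct, KDL, KDC) {
  assert_scalar_number(Pt, "Pt", nonneg = TRUE)
  assert_scalar_number(Lt, "Lt", nonneg = TRUE)
  assert_scalar_number(Ct, "Ct", nonneg = TRUE)
  assert_scalar_number(KDL, "KDL", positive = TRUE)
  assert_scalar_number(KDC, "KDC", positive = TRUE)
  structure(list(Pt = Pt, Lt = Lt, Ct = Ct, KDL = KDL, KDC = KDC),
            class = "competition_system")
}

#' Exact speciation of a two-ligand competition equilibrium
#'
#' Solves the coupled equilibria \eqn{PL = P \cdot L / K_{DL}} and
#' \eqn{PC = P \cdot C / K_{DC}} under the three mass balances by bracketed
#' root finding on free protein over \eqn{[0, P_t]} (the residual is strictly
#' monotone, so the root is unique), followed by Newton polishing to drive the
#' protein mass-balance residual below `1e-12` relative.
#'
#' @param sys a [competition_system()].
#' @param tol relative tolerance on the protein mass balance (default 1e-12).
#' @param max_iter iteration cap for the Newton polish.
#' @return A list of class `species_state` with molar concentrations
#'   `freeP`, `freeL`, `freeC`, `PL`, `PC`.
#' @export
solve_competition <- function(sys, tol = 1e-12, max_iter = 200L) {
  if (!inherits(sys, "competition_system"))
    stop_equibind("`sys` must be a competition_system", "equibind_validation_error")
  Pt <- sys$Pt; Lt <- sys$Lt; Ct <- sys$Ct; KDL <- sys$KDL; KDC <- sys$KDC
  if (Pt == 0) {
    out <- list(freeP = 0, freeL = Lt, freeC = Ct, PL = 0, PC = 0)
    return(structure(out, class = "species_state"))
  }
  g <- function(p) p * (1 + Lt / (KDL + p) + Ct / (KDC + p)) - Pt
  p <- stats::uniroot(g, c(0, Pt), tol = max(Pt * 1e-12, 1e-300))$root
  gp <- function(p) 1 + Lt * KDL / (KDL + p)^2 + Ct * KDC / (KDC + p)^2
  it <- 0L
  while (abs(g(p)) > tol * Pt && it < max_iter) {
    step <- g(p) / gp(p)
    pn <- p - step
    if (!is.finite(pn) || pn < 0) pn <- p / 2
    if (pn > Pt) pn <- (p + Pt) / 2
    p <- pn
    it <- it + 1L
  }
  if (abs(g(p)) > tol * Pt)
    stop_equibind(
      sprintf("speciation did not converge: residual %.3g after %d iterations",
              g(p) / Pt, it),
      "equibind_numerical_error")
  freeL <- Lt * KDL / (KDL + p)
  freeC <- Ct * KDC / (KDC + p)
  structure(
    list(freeP = p, freeL = freeL, freeC = freeC,
         PL = p * freeL / KDL, PC = p * freeC / KDC),
    class = "species_state"
  )
}

#' IC50 from the exact competition model
#'
#' Finds the total competitor concentration at which the labeled complex PL is
#' reduced to half its value without competitor, by monotone bracketed search
#' on the exact speciation of [solve_competition()].
#'
#' @param Pt,Lt molar totals of protein and labeled ligand (> 0).
#' @param KDL,KDC molar dissociation constants (> 0).
#' @param tol relative tolerance on the IC50 (default 1e-10).
#' @return Molar IC50 (total competitor concentration).
#' @export
ic50_from_exact_model <- function(Pt, Lt, KDL, KDC, tol = 1e-10) {
  assert_scalar_number(Pt, "Pt", positive = TRUE)
  assert_scalar_number(Lt, "Lt", positive = TRUE)
  assert_scalar_number(KDL, "KDL", positive = TRUE)
  assert_scalar_number(KDC, "KDC", positive = TRUE)
  PL0 <- solve_competition(competition_system(Pt, Lt, 0, KDL, KDC))$PL
  if (PL0 <= 0)
    stop_equibind("no labeled complex at Ct = 0; nothing to compete away",
                  "equibind_degenerate_error")
  target <- PL0 / 2
  h <- function(Ct) solve_competition(competition_system(Pt, Lt, Ct, KDL, KDC))$PL - target
  hi <- max(KDC, KDL, Pt, Lt)
  n_double <- 0L
  while (h(hi) > 0) {
    hi <- hi * 2
    n_double <- n_double + 1L
    if (n_double > 500L)
      stop_equibind("failed to bracket the IC50", "equibind_numerical_error")
  }
  stats::uniroot(h, c(0, hi), tol = hi * tol)$root
}

#' Inhibition constant from an IC50 (Nikolovska-Coleska equation)
#'
#' Converts a measured IC50 into the competitor's inhibition constant,
#' correcting for probe and protein depletion:
#' \deqn{K_I = \frac{[I]_{50}}{[L]_{50}/K_{DL} + [P]_0/K_{DL} + 1},}
#' where \eqn{[L]_{50}} is the free labeled ligand and \eqn{[I]_{50}} the free
#' competitor at 50% inhibition, and \eqn{[P]_0} the free protein at 0%
#' inhibition. The free concentrations are computed from the supplied totals
#' via the binary-binding quadratic: with \eqn{PL_0} the complex at zero
#' competitor, \eqn{PL_{50} = PL_0/2}, \eqn{[L]_{50} = L_t - PL_{50}},
#' \eqn{[P]_{50} = K_{DL} PL_{50}/[L]_{50}},
#' \eqn{[I]_{50} = IC_{50} - (P_t - PL_{50} - [P]_{50})} and
#' \eqn{[P]_0 = P_t - PL_0}. In the limit \eqn{P_t, L_t \to 0} the result
#' reduces to the IC50 itself (Cheng-Prusoff limit with a negligible ligand
#' term).
#'
#' @param IC50 molar half-inhibition total competitor concentration (> 0).
#' @param Lt molar total labeled ligand (> 0).
#' @param Pt molar total protein (> 0).
#' @param KDL molar dissociation constant of the labeled ligand (> 0).
#' @return Molar inhibition constant \eqn{K_I}.
#' @export
ki_from_ic50 <- function(IC50, Lt, Pt, KDL) {
  assert_scalar_number(IC50, "IC50", positive = TRUE)
  assert_scalar_number(Lt, "Lt", positive = TRUE)
  assert_scalar_number(Pt, "Pt", positive = TRUE)
  assert_scalar_number(KDL, "KDL", positive = TRUE)
  PL0 <- Lt * bound_fraction_quadratic(Rt = Lt, Lt = Pt, KD1 = KDL)
  PL50 <- PL0 / 2
  L50 <- Lt - PL50
  P50 <- KDL * PL50 / L50
  PI50 <- Pt - PL50 - P50
  I50 <- IC50 - PI50
  denom <- L50 / KDL + (Pt - PL0) / KDL + 1
  if (I50 <= 0 || denom <= 0)
    stop_equibind(
      "non-physical Nikolovska-Coleska terms: the stated IC50 is inconsistent with the given totals",
      "equibind_domain_error")
  I50 / denom
}
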