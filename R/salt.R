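#' A salt-dependence series of apparent affinities
#'
#' @param sample_id identifier.
#' @param M molar total monovalent cation concentrations (>= 3 distinct, > 0).
#' @param KD molar apparent dissociation constants, same length as `M`.
#' @param temperature kelvin (default 298.15).
#' @return A `salt_series` object.
#' @export
salt_series <- function(sample_id, M, KD, temperature = 298.15) {
  assert_numeric_vec(M, "M")
  assert_numeric_vec(KD, "KD")
  if (any(M <= 0) || any(KD <= 0))
    stop_equibind("salt and KD values must be > 0", "equibind_validation_error")
  if (length(M) != length(KD))
    stop_equibind("`M` and `KD` must have the same length",
                  "equibind_validation_error")
  if (length(unique(M)) < 3L)
    stop_equibind("need >= 3 distinct salt concentrations",
                  "equibind_validation_error")
  assert_scalar_number(temperature, "temperature", positive = TRUE)
  ord <- order(M)
  structure(list(sample_id = as.character(sample_id)[1],
                 M = M[ord], KD = KD[ord], temperature = temperature),
            class = "salt_series")
}

#' Log-linear salt dependence of the association constant
#'
#' Ordinary least squares of \eqn{\log_{10} K_A} (with \eqn{K_A = 1/K_D}) on
#' \eqn{\log_{10} [M^+]}. Binding that weakens with added salt gives a
#' negative slope under this convention; the intercept is
#' \eqn{\log_{10} K_A} extrapolated to 1 M monovalent cation.
#'
#' @param series a [salt_series()].
#' @return A list: `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `r_squared`, `n`.
#' @export
fit_log_linear <- function(series) {
  if (!inherits(series, "salt_series"))
    stop_equibind("`series` must be a salt_series", "equibind_validation_error")
  x <- log10(series$M)
  y <- log10(1 / series$KD)
  if (stats::var(x) == 0)
    stop_equibind("zero variance in salt concentration",
                  "equibind_validation_error")
  fit <- stats::lm(y ~ x)
  # noise-free series are a legitimate input; silence the perfect-fit notice
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = unname(sm$coefficients[2, 2]),
       intercept_se = unname(sm$coefficients[1, 2]),
       r_squared = sm$r.squared,
       n = length(x))
}

#' Counterions released on binding
#'
#' Polyelectrolyte-theory count of thermodynamically released cations,
#' \eqn{Z = |m| / \psi}, where `m` is the log-log salt-dependence slope and
#' \eqn{\psi} the degree of cation association per phosphate.
#'
#' @param m salt-dependence slope, d(log10 K_A)/d(log10 M).
#' @param psi cation association parameter per phosphate, in (0, 1\];
#'   default 0.695 (double-stranded nucleic-acid value consistent with this
#'   package's reference analyses; see the methods vignette).
#' @return Number of counterions released (dimensionless, >= 0).
#' @examples
#' counterions_released(-5.7) # ~8.2
#' @export
counterions_released <- function(m, psi = 0.695) {
  assert_scalar_number(m, "m")
  assert_scalar_number(psi, "psi")
  if (psi <= 0 || psi > 1)
    stop_equibind("`psi` must lie in (0, 1]", "equibind_validation_error")
  abs(m) / psi
}

# gas constant, kcal / (mol K)
R_KCAL <- 1.987204e-3

#' Decompose binding free energy into electrostatic and non-electrostatic parts
#'
#' From the log-linear salt dependence (slope `m`, intercept `b` =
#' log10 K_A at 1 M), the observed binding free energy at a reference salt
#' concentration splits as
#' \deqn{\Delta G_{nel} = -RT \ln(10)\, b, \qquad
#'       \Delta G_{el} = -RT \ln(10)\, m \log_{10} M_{ref},}
#' with \eqn{\Delta G_{obs} = \Delta G_{el} + \Delta G_{nel}} holding exactly
#' by construction. The non-electrostatic component is the 1 M monovalent-salt
#' extrapolation (where the electrostatic term vanishes by the choice of
#' standard state).
#'
#' @param m slope d(log10 K_A)/d(log10 M).
#' @param b intercept, log10 K_A at 1 M.
#' @param M_ref molar reference salt concentration (> 0).
#' @param temperature kelvin (default 298.15).
#' @return Named numeric vector `c(dG_obs, dG_el, dG_nel)` in kcal/mol.
#' @export
decompose_binding_energy <- function(m, b, M_ref, temperature = 298.15) {
  assert_scalar_number(m, "m")
  assert_scalar_number(b, "b")
  assert_scalar_number(M_ref, "M_ref", positive = TRUE)
  assert_scalar_number(temperature, "temperature", positive = TRUE)
  rtln10 <- R_KCAL * temperature * log(10)
  dG_nel <- -rtln10 * b
  dG_el <- -rtln10 * m * log10(M_ref)
  c(dG_obs = dG_el + dG_nel, dG_el = dG_el, dG_nel = dG_nel)
}

#' Full salt-dependence analysis of one series
#'
#' Runs [fit_log_linear()], [counterions_released()] and
#' [decompose_binding_energy()] on a series and collects the results.
#'
#' @param series a [salt_series()].
#' @param psi cation association parameter (default 0.695).
#' @param M_ref molar reference salt for the energy decomposition
#'   (default 0.15, the physiological low end of a typical series).
#' @return A `salt_fit` list: `sample_id`, `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `psi`, `Z`, `dG_obs`, `dG_el`, `dG_nel`, `M_ref`,
#'   `temperature`, `n`.
#' @export
analyze_salt_series <- function(series, psi = 0.695, M_ref = 0.15) {
  ll <- fit_log_linear(series)
  dg <- decompose_binding_energy(ll$slope, ll$intercept, M_ref,
                                 series$temperature)
  structure(
    c(list(sample_id = series$sample_id), ll,
      list(psi = psi, Z = counterions_released(ll$slope, psi),
           dG_obs = unname(dg["dG_obs"]), dG_el = unname(dg["dG_el"]),
           dG_nel = unname(dg["dG_nel"]),
           M_ref = M_ref, temperature = series$temperature)),
    class = "salt_fit"
  )
}

#' @export
print.salt_fit <- function(x, ...) {
  cat(sprintf("Salt dependence %s: slope = %.2f +/- %.2f (n = %d)\n",
              x$sample_id, x$slope, x$slope_se, x$n))
  cat(sprintf("  Z = %.2f counterions released (psi = %.3f)\n", x$Z, x$psi))
  cat(sprintf("  at %.2g M: dG_obs = %.2f, dG_el = %.2f, dG_nel = %.2f kcal/mol\n",
              x$M_ref, x$dG_obs, x$dG_el, x$dG_nel))
  invisible(x)
}
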