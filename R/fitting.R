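#' A single-replicate anisotropy titration curve
#'
#' @param sample_id,replicate_id identifiers (coerced to character).
#' @param Rt molar total probe concentration (single value per curve).
#' @param Lt molar total titrant concentrations (>= 6 points).
#' @param A anisotropy readings, same length as `Lt`.
#' @return A `titration_curve` object; points are sorted by `Lt`.
#' @export
titration_curve <- function(sample_id, replicate_id, Rt, Lt, A) {
  assert_scalar_number(Rt, "Rt", nonneg = TRUE)
  assert_numeric_vec(Lt, "Lt", nonneg = TRUE)
  assert_numeric_vec(A, "A")
  if (length(Lt) != length(A))
    stop_equibind("`Lt` and `A` must have the same length",
                  "equibind_validation_error")
  if (length(Lt) < 6L)
    stop_equibind("a titration curve needs at least 6 points",
                  "equibind_validation_error")
  ord <- order(Lt)
  structure(
    list(sample_id = as.character(sample_id)[1],
         replicate_id = as.character(replicate_id)[1],
         Rt = Rt, Lt = Lt[ord], A = A[ord]),
    class = "titration_curve"
  )
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve %s/%s: %d points, Rt = %.3g M, Lt %.3g-%.3g M\n",
              x$sample_id, x$replicate_id, length(x$Lt), x$Rt,
              min(x$Lt), max(x$Lt)))
  invisible(x)
}

titration_resid <- function(par, Lt, A, Rt, two) {
  p <- if (two)
    binding_parameters(A0 = par[1], A1 = par[2], A2 = par[3],
                       KD1 = 10^par[4], KD2 = 10^par[5], Rt = Rt)
  else
    binding_parameters(A0 = par[1], A1 = par[2], KD1 = 10^par[3], Rt = Rt)
  anisotropy_curve(Lt, p) - A
}

fit_one_start <- function(start, lower, upper, Lt, A, Rt, two) {
  tryCatch({
    m <- minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = titration_resid, Lt = Lt, A = A, Rt = Rt, two = two,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14))
    list(par = m$par, ssr = m$deviance, converged = m$info %in% 1:4,
         info = m$info, message = m$message)
  }, error = function(e) list(par = start, ssr = Inf, converged = FALSE,
                              info = NA_integer_, message = conditionMessage(e)))
}

#' Fit a titration curve to the depletion-corrected binding model
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of the one- or
#' two-transition anisotropy model against a [titration_curve()]. Dissociation
#' constants are optimized in log10 space with bounds `[1e-12, 1e-3]` M;
#' baselines are unbounded and initialized from the first and last points.
#' `KD1` starts are placed at every decade spanned by the titrant range
#' (multi-start); for the two-transition variant, `KD2` starts are every
#' decade above each `KD1` start. Standard errors come from the local
#' quadratic approximation at the optimum (Gauss-Newton covariance).
#'
#' @param curve a [titration_curve()].
#' @param variant `"one"`, `"two"`, or `"auto"` (delegates to [select_model()]).
#' @return A `binding_fit` list: `params` ([binding_parameters()]), `variant`,
#'   `se` (named standard errors on the molar/anisotropy scale), `ssr`,
#'   `converged`, `n`, `aicc`.
#' @export
fit_single_titration <- function(curve, variant = c("one", "two", "auto")) {
  if (!inherits(curve, "titration_curve"))
    stop_equibind("`curve` must be a titration_curve", "equibind_validation_error")
  variant <- match.arg(variant)
  if (variant == "auto") return(select_model(curve)$fit)
  two <- variant == "two"
  Lt <- curve$Lt; A <- curve$A; Rt <- curve$Rt
  n <- length(Lt)
  npar <- if (two) 5L else 3L
  if (n <= npar)
    stop_equibind(sprintf("%d points cannot constrain %d parameters", n, npar),
                  "equibind_validation_error")

  pos <- Lt[Lt > 0]
  lk_lo <- floor(log10(min(pos)))
  lk_hi <- ceiling(log10(max(pos)))
  lk_grid <- pmin(pmax(seq(lk_lo, lk_hi), -12), -3)
  lk_grid <- unique(lk_grid)
  A0_init <- mean(utils::head(A, 2))
  A1_init <- mean(utils::tail(A, 2))

  if (two) {
    starts <- list()
    for (lk1 in lk_grid) for (lk2 in lk_grid[lk_grid > lk1]) {
      starts[[length(starts) + 1L]] <-
        c(A0 = A0_init, A1 = (A0_init + A1_init) / 2, A2 = A1_init,
          lKD1 = lk1, lKD2 = lk2)
    }
    if (!length(starts))
      starts <- list(c(A0 = A0_init, A1 = (A0_init + A1_init) / 2,
                       A2 = A1_init, lKD1 = -9, lKD2 = -6))
    lower <- c(-Inf, -Inf, -Inf, -12, -12)
    upper <- c(Inf, Inf, Inf, -3, -3)
  } else {
    starts <- lapply(lk_grid, function(lk)
      c(A0 = A0_init, A1 = A1_init, lKD1 = lk))
    lower <- c(-Inf, -Inf, -12)
    upper <- c(Inf, Inf, -3)
  }

  fits <- lapply(starts, fit_one_start, lower = lower, upper = upper,
                 Lt = Lt, A = A, Rt = Rt, two = two)
  ok <- vapply(fits, function(f) f$converged && is.finite(f$ssr), logical(1))
  if (!any(ok)) {
    diag <- vapply(fits, function(f)
      sprintf("info=%s ssr=%.3g %s", f$info, f$ssr, f$message), character(1))
    stop_equibind(paste0("no start converged:\n", paste(diag, collapse = "\n")),
                  "equibind_fit_error")
  }
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "ssr"))]]

  par <- unname(best$par)
  se_par <- ls_standard_errors(titration_resid, par, Lt = Lt, A = A, Rt = Rt,
                               two = two, ssr = best$ssr)
  ln10 <- log(10)
  if (two) {
    params <- binding_parameters(A0 = par[1], A1 = par[2], A2 = par[3],
                                 KD1 = 10^par[4], KD2 = 10^par[5], Rt = Rt)
    se <- c(A0 = se_par[1], A1 = se_par[2], A2 = se_par[3],
            KD1 = params$KD1 * ln10 * se_par[4],
            KD2 = params$KD2 * ln10 * se_par[5])
  } else {
    params <- binding_parameters(A0 = par[1], A1 = par[2],
                                 KD1 = 10^par[3], Rt = Rt)
    se <- c(A0 = se_par[1], A1 = se_par[2],
            KD1 = params$KD1 * ln10 * se_par[3])
  }
  names(se) <- if (two) c("A0", "A1", "A2", "KD1", "KD2") else c("A0", "A1", "KD1")
  structure(
    list(sample_id = curve$sample_id, replicate_id = curve$replicate_id,
         params = params, variant = if (two) "two-transition" else "one-transition",
         se = se, ssr = best$ssr, converged = TRUE, n = n,
         aicc = aicc_ls(best$ssr, n, npar)),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit [%s] %s/%s\n", x$variant, x$sample_id, x$replicate_id))
  cat(sprintf("  KD1 = %.3g +/- %.2g M", x$params$KD1, x$se["KD1"]))
  if (x$params$two_transition)
    cat(sprintf("  KD2 = %.3g +/- %.2g M", x$params$KD2, x$se["KD2"]))
  cat(sprintf("\n  SSR = %.3g over %d points\n", x$ssr, x$n))
  invisible(x)
}

#' Choose between the one- and two-transition models
#'
#' Fits both variants and accepts the second transition only if all of the
#' following hold, mirroring how a weak second binding event is judged
#' "detected": corrected-AIC improvement of at least `delta_aicc` over the
#' one-transition fit; fitted `KD2 > KD1`; `KD2` no more than
#' `kd2_range_factor` times the maximum titrant concentration (a transition
#' entirely beyond the titration range is not evidence); and a second-transition
#' amplitude `|A2 - A1|` exceeding `amplitude_factor` times the residual noise
#' of the two-transition fit. Otherwise the one-transition model is kept.
#'
#' @param curve a [titration_curve()].
#' @param delta_aicc minimum AICc improvement (default 2).
#' @param kd2_range_factor maximum `KD2` as a multiple of `max(Lt)` (default 10).
#' @param amplitude_factor minimum amplitude in residual-sd units (default 3).
#' @return A list of class `model_selection`: `variant` (`"one-transition"` or
#'   `"two-transition"`), `fit` (the selected [fit_single_titration()] result),
#'   `fit_one`, `fit_two` (possibly `NULL`), and `criteria` (named logicals).
#' @export
select_model <- function(curve, delta_aicc = 2, kd2_range_factor = 10,
                         amplitude_factor = 3) {
  fit1 <- fit_single_titration(curve, "one")
  fit2 <- tryCatch(fit_single_titration(curve, "two"), error = function(e) NULL)
  criteria <- c(fit_converged = FALSE, aicc_improved = FALSE,
                kd_ordered = FALSE, kd2_in_range = FALSE,
                amplitude_detectable = FALSE)
  if (!is.null(fit2)) {
    noise <- sqrt(fit2$ssr / max(fit2$n - 5L, 1L))
    criteria <- c(
      fit_converged = fit2$converged,
      aicc_improved = (fit1$aicc - fit2$aicc) >= delta_aicc,
      kd_ordered = fit2$params$KD2 > fit2$params$KD1,
      kd2_in_range = fit2$params$KD2 <= kd2_range_factor * max(curve$Lt),
      amplitude_detectable =
        abs(fit2$params$A2 - fit2$params$A1) > amplitude_factor * noise
    )
  }
  two <- all(criteria)
  structure(
    list(variant = if (two) "two-transition" else "one-transition",
         fit = if (two) fit2 else fit1,
         fit_one = fit1, fit_two = fit2, criteria = criteria),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("Selected model: %s\n", x$variant))
  cat("  criteria:", paste(sprintf("%s=%s", names(x$criteria), x$criteria),
                           collapse = " "), "\n")
  invisible(x)
}

#' Summarize replicate fits of the same sample
#'
#' Arithmetic mean, standard deviation and standard error of the mean of the
#' per-replicate `KD1` estimates, the convention used when an affinity is
#' reported as "average and s.e.m. of n technical replicates".
#'
#' @param fits list of converged `binding_fit` objects (>= 1).
#' @return A `replicate_summary` list: `mean_KD`, `sd_KD`, `sem_KD` (molar),
#'   `n`, `KD_values`.
#' @export
aggregate_replicates <- function(fits) {
  if (!length(fits))
    stop_equibind("no fits supplied", "equibind_validation_error")
  if (inherits(fits, "binding_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) inherits(f, "binding_fit") && f$converged,
               logical(1))
  if (!all(ok))
    stop_equibind("all elements must be converged binding_fit objects",
                  "equibind_validation_error")
  kd <- vapply(fits, function(f) f$params$KD1, numeric(1))
  n <- length(kd)
  sd_kd <- if (n > 1) stats::sd(kd) else NA_real_
  structure(
    list(mean_KD = mean(kd), sd_KD = sd_kd,
         sem_KD = if (n > 1) sd_kd / sqrt(n) else NA_real_,
         n = n, KD_values = kd),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("KD,app = %.3g +/- %.2g M (s.e.m., n = %d)\n",
              x$mean_KD, x$sem_KD, x$n))
  invisible(x)
}

#' Normalize a titration curve to fraction bound
#'
#' Rescales anisotropy to fraction bound using the fitted first-transition
#' baselines: `(A - A0) / (A1 - A0)`. Values outside \[0, 1\] arising from
#' noise (or from the second transition) are retained, not clipped.
#'
#' @param curve a [titration_curve()].
#' @param fit a converged `binding_fit` for that curve.
#' @return A data.frame with columns `Lt` (molar) and `fraction_bound`.
#' @export
normalize_curve <- function(curve, fit) {
  if (!inherits(curve, "titration_curve") || !inherits(fit, "binding_fit"))
    stop_equibind("need a titration_curve and a binding_fit",
                  "equibind_validation_error")
  span <- fit$params$A1 - fit$params$A0
  if (abs(span) < .Machine$double.eps * 100)
    stop_equibind("degenerate fit: A1 equals A0, no amplitude to normalize by",
                  "equibind_degenerate_error")
  data.frame(Lt = curve$Lt,
             fraction_bound = (curve$A - fit$params$A0) / span)
}

competition_resid <- function(par, Ct, A) {
  top <- par[1]; bottom <- par[2]; ic50 <- 10^par[3]; h <- par[4]
  bottom + (top - bottom) / (1 + (Ct / ic50)^h) - A
}

#' Fit a competition curve and convert its IC50 to a K_I
#'
#' Fits a four-parameter logistic in log10 competitor concentration,
#' \eqn{A(C) = bottom + (top - bottom) / (1 + (C/IC_{50})^h)}, to anisotropy
#' measured at fixed protein, labeled-ligand and probe concentrations, then
#' converts the fitted IC50 to the inhibition constant via [ki_from_ic50()].
#' A flat curve (no competable complex, e.g. the no-protein control) is
#' detected by comparing against a constant model: if the logistic does not
#' improve AICc by at least 2, the result is flagged `flat` and carries no
#' IC50. If the data do not reach within 10% of both plateaus a
#' `plateau_warning` is set and the reported uncertainty widened is by the
#' extrapolation factor.
#'
#' @param Ct molar total competitor concentrations (>= 6, may include 0).
#' @param A anisotropy readings, same length as `Ct`.
#' @param Pt,Lt molar totals of protein and labeled ligand in the reactions.
#' @param KDL molar dissociation constant of the protein/labeled-ligand pair.
#' @return A `competition_fit` list: `IC50`, `KI`, `top`, `bottom`, `hill`,
#'   `se` (named: IC50, KI), `ssr`, `flat`, `plateau_warning`, `converged`.
#' @export
fit_competition_curve <- function(Ct, A, Pt, Lt, KDL) {
  assert_numeric_vec(Ct, "Ct", nonneg = TRUE)
  assert_numeric_vec(A, "A")
  if (length(Ct) != length(A) || length(Ct) < 6L)
    stop_equibind("need >= 6 matched (Ct, A) points", "equibind_validation_error")
  assert_scalar_number(Pt, "Pt", nonneg = TRUE)
  assert_scalar_number(Lt, "Lt", positive = TRUE)
  assert_scalar_number(KDL, "KDL", positive = TRUE)

  n <- length(Ct)
  ssr_const <- sum((A - mean(A))^2)
  aicc_const <- aicc_ls(ssr_const, n, 1L)

  pos <- Ct[Ct > 0]
  l_lo <- log10(min(pos)) - 2
  l_hi <- log10(max(pos)) + 2
  starts <- lapply(stats::quantile(log10(pos), c(0.25, 0.5, 0.75)), function(l)
    c(top = max(A), bottom = min(A), lIC50 = unname(l), h = 1))
  lower <- c(-Inf, -Inf, l_lo, 0.2)
  upper <- c(Inf, Inf, l_hi, 5)
  fits <- lapply(starts, function(s) tryCatch({
    m <- minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                            fn = competition_resid, Ct = Ct, A = A,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
    list(par = m$par, ssr = m$deviance, converged = m$info %in% 1:4)
  }, error = function(e) list(par = s, ssr = Inf, converged = FALSE)))
  ok <- vapply(fits, function(f) f$converged && is.finite(f$ssr), logical(1))

  flat <- FALSE
  if (!any(ok)) {
    flat <- TRUE
  } else {
    best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "ssr"))]]
    if (aicc_const - aicc_ls(best$ssr, n, 4L) < 2) flat <- TRUE
  }
  if (flat) {
    return(structure(
      list(IC50 = NA_real_, KI = NA_real_, top = mean(A), bottom = mean(A),
           hill = NA_real_, se = c(IC50 = NA_real_, KI = NA_real_),
           ssr = ssr_const, flat = TRUE, plateau_warning = FALSE,
           converged = FALSE),
      class = "competition_fit"))
  }

  par <- unname(best$par)
  ic50 <- 10^par[3]
  se_par <- ls_standard_errors(competition_resid, par, Ct = Ct, A = A,
                               ssr = best$ssr)
  se_ic50 <- ic50 * log(10) * se_par[3]

  # both plateaus should be approached within 10% of the fitted amplitude
  amp <- par[1] - par[2]
  plateau_warning <- abs(A[which.min(Ct)] - par[1]) > 0.1 * abs(amp) ||
    abs(A[which.max(Ct)] - par[2]) > 0.1 * abs(amp)
  if (plateau_warning) se_ic50 <- 2 * se_ic50

  ki <- tryCatch(ki_from_ic50(ic50, Lt = Lt, Pt = Pt, KDL = KDL),
                 error = function(e) NA_real_)
  se_ki <- if (is.na(ki)) NA_real_ else ki * se_ic50 / ic50
  structure(
    list(IC50 = ic50, KI = ki, top = par[1], bottom = par[2], hill = par[4],
         se = c(IC50 = unname(se_ic50), KI = unname(se_ki)),
         ssr = best$ssr, flat = FALSE, plateau_warning = plateau_warning,
         converged = TRUE),
    class = "competition_fit"
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  if (x$flat) {
    cat("Competition fit: flat curve (no competable complex detected)\n")
  } else {
    cat(sprintf("Competition fit: IC50 = %.3g M, K_I = %.3g +/- %.2g M%s\n",
                x$IC50, x$KI, x$se["KI"],
                if (x$plateau_warning) " [plateau warning]" else ""))
  }
  invisible(x)
}
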