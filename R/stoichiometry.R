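#' Species fractions from one gel lane
#'
#' Divides background-corrected integrated band intensities (free, first
#' bound species, second bound species) by the lane total. Scale-invariant:
#' only the intensity ratios matter.
#'
#' @param F,B1,B2 non-negative band intensities (arbitrary units); at least
#'   one must be positive. Vectorized over lanes.
#' @return A data.frame with columns `f_F`, `f_B1`, `f_B2` summing to 1.
#' @export
lane_fractions <- function(F, B1, B2) {
  assert_numeric_vec(F, "F", nonneg = TRUE)
  assert_numeric_vec(B1, "B1", nonneg = TRUE)
  assert_numeric_vec(B2, "B2", nonneg = TRUE)
  tot <- F + B1 + B2
  if (any(tot == 0))
    stop_equibind("a lane with all-zero intensities has no defined fractions",
                  "equibind_validation_error")
  data.frame(f_F = F / tot, f_B1 = B1 / tot, f_B2 = B2 / tot)
}

langmuir_resid <- function(par, P, f, fit_amplitude) {
  kd <- 10^par[1]
  amp <- if (fit_amplitude) par[2] else 1
  amp * P / (P + kd) - f
}

#' Fit a Langmuir binding isotherm to shift data
#'
#' Least-squares fit of \eqn{f = a \cdot P / (P + K_D)} to bound fractions
#' from gel quantification. The amplitude `a` is fixed at 1 by default; set
#' `fit_amplitude = TRUE` to let it absorb incomplete shifting.
#'
#' @param P molar protein concentrations (>= 4 points).
#' @param f bound fractions, same length.
#' @param fit_amplitude fit a free amplitude (default `FALSE`).
#' @return A list: `KD`, `KD_se`, `amplitude`, `ssr`, `converged`.
#' @export
fit_langmuir <- function(P, f, fit_amplitude = FALSE) {
  assert_numeric_vec(P, "P", nonneg = TRUE)
  assert_numeric_vec(f, "f")
  if (length(P) != length(f) || length(P) < 4L)
    stop_equibind("need >= 4 matched (P, f) points", "equibind_validation_error")
  pos <- P[P > 0]
  starts <- lapply(unique(round(seq(log10(min(pos)), log10(max(pos)),
                                    length.out = 4))), function(lk) {
    if (fit_amplitude) c(lKD = lk, amp = max(f)) else c(lKD = lk)
  })
  lower <- if (fit_amplitude) c(-15, 1e-3) else -15
  upper <- if (fit_amplitude) c(0, 2) else 0
  fits <- lapply(starts, function(s) tryCatch({
    m <- minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                            fn = langmuir_resid, P = P, f = f,
                            fit_amplitude = fit_amplitude,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    list(par = m$par, ssr = m$deviance, converged = m$info %in% 1:4)
  }, error = function(e) list(par = s, ssr = Inf, converged = FALSE)))
  ok <- vapply(fits, function(x) x$converged && is.finite(x$ssr), logical(1))
  if (!any(ok))
    stop_equibind("Langmuir fit failed to converge from any start",
                  "equibind_fit_error")
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, numeric(1), "ssr"))]]
  kd <- 10^best$par[1]
  se_par <- ls_standard_errors(langmuir_resid, best$par, P = P, f = f,
                               fit_amplitude = fit_amplitude, ssr = best$ssr)
  list(KD = unname(kd), KD_se = unname(kd * log(10) * se_par[1]),
       amplitude = if (fit_amplitude) unname(best$par[2]) else 1,
       ssr = best$ssr, converged = TRUE)
}

#' Simulate a stoichiometric titration with sequential two-site binding
#'
#' Solves the sequential, non-cooperative equilibria
#' \eqn{P + N \rightleftharpoons PN} (stepwise `KD1`) and
#' \eqn{P + PN \rightleftharpoons P_2N} (stepwise `KD2`) at total nucleic acid
#' `Nt` for each protein:ligand ratio, by bracketed monotone root finding on
#' free protein followed by Newton polishing (protein mass-balance residual
#' below 1e-10 relative). This is the model behind a stoichiometric EMSA in
#' which the free band F, the 1:1 band B1 and the 2:1 band B2 are resolved.
#'
#' @param Nt molar total nucleic acid (> 0).
#' @param KD1,KD2 molar stepwise dissociation constants (> 0).
#' @param ratios non-negative protein:ligand molar ratios.
#' @return A data.frame with columns `ratio`, `f_F`, `f_B1`, `f_B2`
#'   (nucleic-acid fractions, summing to 1).
#' @export
simulate_sequential_binding <- function(Nt, KD1, KD2, ratios) {
  assert_scalar_number(Nt, "Nt", positive = TRUE)
  assert_scalar_number(KD1, "KD1", positive = TRUE)
  assert_scalar_number(KD2, "KD2", positive = TRUE)
  assert_numeric_vec(ratios, "ratios", nonneg = TRUE)
  one <- function(r) {
    Pt <- r * Nt
    if (Pt == 0) return(c(1, 0, 0))
    species <- function(p) {
      p <- unname(p)
      denom <- 1 + p / KD1 + p * p / (KD1 * KD2)
      N <- Nt / denom
      PN <- N * p / KD1
      c(N, PN, PN * p / KD2)   # N, PN, P2N
    }
    g <- function(p) {
      s <- species(p)
      unname(p) + s[2] + 2 * s[3] - Pt
    }
    p <- stats::uniroot(g, c(0, Pt), tol = max(Pt * 1e-12, 1e-300))$root
    it <- 0L
    while (abs(g(p)) > 1e-11 * Pt && it < 200L) {
      eps <- max(abs(p), Pt * 1e-12) * 1e-7
      grad <- (g(p + eps) - g(p - eps)) / (2 * eps)
      pn <- p - g(p) / grad
      if (!is.finite(pn) || pn < 0) pn <- p / 2
      if (pn > Pt) pn <- (p + Pt) / 2
      p <- pn
      it <- it + 1L
    }
    if (abs(g(p)) > 1e-10 * Pt)
      stop_equibind(sprintf("sequential-binding solver stalled at ratio %g", r),
                    "equibind_numerical_error")
    s <- species(p)
    s / Nt
  }
  fr <- t(vapply(ratios, one, numeric(3)))
  data.frame(ratio = ratios, f_F = fr[, 1], f_B1 = fr[, 2], f_B2 = fr[, 3])
}

#' Cumulative protein occupancy per nucleic acid
#'
#' Protein equivalents bound per ligand, \eqn{f_{B1} + 2 f_{B2}}. In a
#' stoichiometric titration this rises with unit slope and saturates at the
#' final complex stoichiometry (2 for a 2:1 assembly), which is the series to
#' use when locating the assembly-completion breakpoint: the plain bound
#' fraction \eqn{f_{B1} + f_{B2}} saturates already at the 1:1 point.
#'
#' @param fractions a data.frame with columns `f_B1` and `f_B2`, as returned
#'   by [simulate_sequential_binding()] or [lane_fractions()].
#' @return Numeric vector of protein equivalents bound per nucleic acid.
#' @export
protein_occupancy <- function(fractions) {
  if (!all(c("f_B1", "f_B2") %in% names(fractions)))
    stop_equibind("`fractions` needs columns f_B1 and f_B2",
                  "equibind_validation_error")
  fractions$f_B1 + 2 * fractions$f_B2
}

piecewise_ssr <- function(knots, x, y) {
  if (any(diff(c(min(x), knots, max(x))) <= 1e-9)) return(Inf)
  X <- cbind(1, x)
  for (k in knots) X <- cbind(X, pmax(x - k, 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

piecewise_fit <- function(knots, x, y) {
  X <- cbind(1, x)
  for (k in knots) X <- cbind(X, pmax(x - k, 0))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  slopes <- cumsum(beta[-1])
  list(knots = knots, slopes = unname(slopes),
       ssr = sum(fit$residuals^2), coef = beta)
}

refine_knots <- function(knots, x, y) {
  if (length(knots) == 1L) {
    lo <- max(min(x), knots - diff(range(x)) / 4)
    hi <- min(max(x), knots + diff(range(x)) / 4)
    stats::optimize(function(k) piecewise_ssr(k, x, y), c(lo, hi),
                    tol = 1e-10)$minimum
  } else {
    stats::optim(knots, piecewise_ssr, x = x, y = y, method = "Nelder-Mead",
                 control = list(reltol = 1e-13, maxit = 2000))$par
  }
}

#' Detect the saturation breakpoint of a titration series
#'
#' Fits continuous piecewise-linear (broken-stick) models to a
#' (ratio, fraction) series by profiled least squares (knot positions by
#' numerical optimization, segment coefficients in closed form) and reports
#' the ratio at which the initial rising phase ends:
#'
#' * For a (near-)monotone series the classical two-segment broken stick is
#'   used and the breakpoint is the single knot.
#' * For a series that rises and then falls (e.g. the 1:1 band, which decays
#'   as the 2:1 complex forms) a two-segment line is structurally wrong -- its
#'   knot is pulled well below the apex even on ideal data -- so a two-knot
#'   (three-segment) model is fitted and the apex knot (end of the rising
#'   segment) is reported.
#'
#' A series is called rise-then-fall when its maximum is interior and the
#' terminal value has dropped by more than a quarter of the observed rise.
#' If a single straight line is not improved upon by at least 2 AICc units,
#' no breakpoint is reported.
#'
#' @param ratios non-negative, increasing x-values (>= 6 points spanning the
#'   pre- and post-saturation regions).
#' @param fractions the species fraction (or occupancy) series to analyze.
#' @return A `breakpoint_result` list: `breakpoint` (NA if none), `slopes`
#'   (fitted segment slopes), `knots`, `ssr`, `shape`
#'   (`"rise-plateau"`, `"rise-fall"`, or `"none"`).
#' @export
find_breakpoint <- function(ratios, fractions) {
  assert_numeric_vec(ratios, "ratios", nonneg = TRUE)
  assert_numeric_vec(fractions, "fractions")
  if (length(ratios) != length(fractions) || length(ratios) < 6L)
    stop_equibind("need >= 6 matched (ratio, fraction) points",
                  "equibind_validation_error")
  ord <- order(ratios)
  x <- ratios[ord]; y <- fractions[ord]
  n <- length(x)

  # a perfect straight line (zero residual) carries no breakpoint information
  line0 <- stats::lm.fit(cbind(1, x), y)
  tss <- sum((y - mean(y))^2)
  if (sum(line0$residuals^2) <= 1e-12 * max(tss, .Machine$double.xmin)) {
    return(structure(list(breakpoint = NA_real_, slopes = NA_real_,
                          knots = NA_real_, ssr = sum(line0$residuals^2),
                          shape = "none"),
                     class = "breakpoint_result"))
  }

  i_max <- which.max(y)
  rise <- y[i_max] - y[1]
  rise_fall <- i_max < n - 1L && rise > 0 &&
    (y[i_max] - y[n]) > 0.25 * rise

  interior <- x[2:(n - 1)]
  if (rise_fall) {
    grid <- expand.grid(k1 = interior, k2 = interior)
    grid <- grid[grid$k2 > grid$k1, , drop = FALSE]
    ss <- mapply(function(a, b) piecewise_ssr(c(a, b), x, y),
                 grid$k1, grid$k2)
    knots <- refine_knots(as.numeric(grid[which.min(ss), ]), x, y)
    knots <- sort(pmin(pmax(knots, min(x)), max(x)))
    fit <- piecewise_fit(knots, x, y)
    k_model <- 4L + length(knots)   # intercept + 3 slopes + knots
    bp <- knots[1]
    shape <- "rise-fall"
  } else {
    ss <- vapply(interior, function(k) piecewise_ssr(k, x, y), numeric(1))
    knots <- refine_knots(interior[which.min(ss)], x, y)
    fit <- piecewise_fit(knots, x, y)
    k_model <- 4L                   # intercept + 2 slopes + knot
    bp <- knots[1]
    shape <- "rise-plateau"
  }

  line <- stats::lm.fit(cbind(1, x), y)
  ssr_line <- sum(line$residuals^2)
  if (aicc_ls(ssr_line, n, 2L) - aicc_ls(fit$ssr, n, k_model) < 2) {
    return(structure(list(breakpoint = NA_real_, slopes = NA_real_,
                          knots = NA_real_, ssr = ssr_line, shape = "none"),
                     class = "breakpoint_result"))
  }
  structure(list(breakpoint = unname(bp), slopes = fit$slopes,
                 knots = unname(fit$knots), ssr = fit$ssr, shape = shape),
            class = "breakpoint_result")
}

#' @export
print.breakpoint_result <- function(x, ...) {
  if (x$shape == "none") {
    cat("No breakpoint detected (straight line not improved upon)\n")
  } else {
    cat(sprintf("Breakpoint at ratio %.3f (%s; segment slopes %s)\n",
                x$breakpoint, x$shape,
                paste(sprintf("%.3f", x$slopes), collapse = ", ")))
  }
  invisible(x)
}
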