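# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_equibind <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "equibind_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_equibind(sprintf("`%s` must be a single non-missing number", name),
                  "equibind_validation_error")
  if (finite && !is.finite(x))
    stop_equibind(sprintf("`%s` must be finite", name),
                  "equibind_validation_error")
  if (positive && x <= 0)
    stop_equibind(sprintf("`%s` must be > 0 (got %g)", name, x),
                  "equibind_validation_error")
  if (nonneg && x < 0)
    stop_equibind(sprintf("`%s` must be >= 0 (got %g)", name, x),
                  "equibind_validation_error")
  invisible(x)
}

assert_numeric_vec <- function(x, name, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stop_equibind(sprintf("`%s` must be a non-empty finite numeric vector", name),
                  "equibind_validation_error")
  if (nonneg && any(x < 0))
    stop_equibind(sprintf("`%s` must be non-negative", name),
                  "equibind_validation_error")
  invisible(x)
}

# Evaluate expr with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards. Generators must be pure functions of
# (parameters, seed); leaking into the global stream would break that.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# AICc from a least-squares fit: k counts mean-model parameters, +1 for sigma
aicc_ls <- function(ssr, n, k) {
  k <- k + 1
  aic <- n * log(max(ssr, .Machine$double.xmin) / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

# Central-difference Jacobian of a residual function at `par`
numeric_jacobian <- function(resid_fn, par, ..., rel_step = 1e-6) {
  r0 <- resid_fn(par, ...)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- rel_step * max(abs(par[j]), 1e-8)
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- par[j] - h
    J[, j] <- (resid_fn(up, ...) - resid_fn(dn, ...)) / (2 * h)
  }
  J
}

# Asymptotic standard errors of a least-squares optimum
ls_standard_errors <- function(resid_fn, par, ..., ssr = NULL) {
  J <- numeric_jacobian(resid_fn, par, ...)
  n <- nrow(J); p <- ncol(J)
  if (is.null(ssr)) ssr <- sum(resid_fn(par, ...)^2)
  sigma2 <- if (n > p) ssr / (n - p) else NA_real_
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * chol2inv(chol(JtJ)), error = function(e) {
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    sigma2 * (sv$v[, pos, drop = FALSE] %*%
                (t(sv$u[, pos, drop = FALSE]) / sv$d[pos]))
  })
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(par)
  se
}
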