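test_that("lane fractions are intensity ratios and scale-invariant", {
  expect_equal(unlist(lane_fractions(100, 0, 0)), c(f_F = 1, f_B1 = 0, f_B2 = 0))
  expect_equal(unlist(lane_fractions(50, 30, 20)),
               c(f_F = 0.5, f_B1 = 0.3, f_B2 = 0.2))
  set.seed(41)
  x <- runif(3, 1, 100)
  fr <- lane_fractions(x[1], x[2], x[3])
  expect_equal(unlist(fr), setNames(x / sum(x), c("f_F", "f_B1", "f_B2")))
  expect_equal(sum(unlist(fr)), 1)
  fr10 <- lane_fractions(10 * x[1], 10 * x[2], 10 * x[3])
  expect_equal(unlist(fr10), unlist(fr))
  expect_error(lane_fractions(0, 0, 0), class = "equibind_validation_error")
  expect_error(lane_fractions(-1, 2, 3), class = "equibind_validation_error")
})

test_that("Langmuir fitting recovers its generating constant", {
  KD <- 2e-8
  P <- 10^seq(-10, -6, length.out = 12)
  f <- P / (P + KD)
  fit <- fit_langmuir(P, f)
  expect_equal(fit$KD, KD, tolerance = 1e-6)
  # half-saturation identity of the model at P = KD
  expect_equal(fit$KD / (fit$KD + KD), 0.5, tolerance = 1e-6)
  set.seed(42)
  f_noisy <- f + rnorm(length(f), 0, 0.03)
  fit_n <- fit_langmuir(P, f_noisy)
  expect_equal(fit_n$KD, KD, tolerance = 0.15)
})

test_that("sequential-binding speciation is exact at its limits and vs grid search", {
  out0 <- simulate_sequential_binding(2e-6, 2e-9, 2e-8, 0)
  expect_equal(unlist(out0[c("f_F", "f_B1", "f_B2")]),
               c(f_F = 1, f_B1 = 0, f_B2 = 0))
  # huge excess of tight-binding protein saturates the 2:1 complex
  out10 <- simulate_sequential_binding(2e-6, 2e-10, 2e-10, 10)
  expect_gt(out10$f_B2, 0.99)
  # generic point against the brute-force oracle
  out1 <- simulate_sequential_binding(2e-6, 2e-9, 2e-8, 1)
  or <- oracle_sequential(2e-6, 2e-9, 2e-8, 1)
  expect_equal(unlist(out1[c("f_F", "f_B1", "f_B2")]),
               c(f_F = or[1], f_B1 = or[2], f_B2 = or[3]), tolerance = 1e-8)
})

test_that("simulated fractions are proper probabilities for arbitrary systems", {
  set.seed(43)
  for (i in 1:40) {
    Nt <- 10^runif(1, -7, -5)
    KD1 <- 10^runif(1, -10, -6)
    KD2 <- 10^runif(1, -10, -6)
    out <- simulate_sequential_binding(Nt, KD1, KD2, seq(0, 4, by = 0.5))
    fr <- as.matrix(out[c("f_F", "f_B1", "f_B2")])
    expect_true(all(fr >= -1e-12 & fr <= 1 + 1e-12))
    expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-9)
  }
})

test_that("breakpoint detection nails ideal piecewise data", {
  x <- seq(0, 3, by = 0.1)
  y <- pmin(x, 1)
  bp <- find_breakpoint(x, y)
  expect_equal(bp$breakpoint, 1, tolerance = 1e-6)
  expect_equal(bp$shape, "rise-plateau")
  # straight line: no breakpoint to report
  expect_equal(find_breakpoint(x, 0.3 * x)$shape, "none")
  # ideal sharp tent: apex knot, not the biased two-segment compromise
  tent <- ifelse(x <= 1, x, pmax(2 - x, 0))
  bp_t <- find_breakpoint(x, tent)
  expect_equal(bp_t$shape, "rise-fall")
  expect_equal(bp_t$breakpoint, 1, tolerance = 1e-6)
})

test_that("stoichiometric titration shows 1:1 saturation of B1 and 2:1 of the occupancy", {
  sim <- simulate_sequential_binding(2e-6, 2e-9, 2e-8, seq(0, 3, by = 0.1))
  bp1 <- find_breakpoint(sim$ratio, sim$f_B1)
  expect_true(bp1$breakpoint >= 0.95 && bp1$breakpoint <= 1.05)
  bp2 <- find_breakpoint(sim$ratio, protein_occupancy(sim))
  expect_true(bp2$breakpoint >= 1.9 && bp2$breakpoint <= 2.1)
})

test_that("breakpoints converge to exactly 1 and 2 in the stoichiometric limit", {
  # the sharp-corner limit needs BOTH steps stoichiometric and well separated:
  # KD2/KD1 controls the premature 2:1 rounding of the B1 apex, Nt/KD2 the
  # softness of the final saturation corner, so both ratios must diverge
  ratios <- seq(0, 3, by = 0.1)
  seps <- c(10, 100, 1000)
  b1 <- occ <- numeric(length(seps))
  for (i in seq_along(seps)) {
    Nt <- 2e-6
    KD1 <- Nt / (10 * seps[i]^2)
    sim <- simulate_sequential_binding(Nt, KD1, KD1 * seps[i], ratios)
    b1[i] <- find_breakpoint(sim$ratio, sim$f_B1)$breakpoint
    occ[i] <- find_breakpoint(sim$ratio, protein_occupancy(sim))$breakpoint
  }
  expect_true(all(diff(abs(b1 - 1)) < 0))     # monotone approach to 1
  expect_true(all(diff(abs(occ - 2)) < 0))    # monotone approach to 2
  expect_equal(b1[3], 1, tolerance = 0.01)
  expect_equal(occ[3], 2, tolerance = 0.01)
})

test_that("breakpoint detection needs enough points", {
  expect_error(find_breakpoint(1:4, c(1, 2, 3, 3)),
               class = "equibind_validation_error")
})
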