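test_that("noise-free one-transition data are recovered essentially exactly", {
  truth <- standard_truth()
  design <- make_design(noise_sd = 0)
  curve <- simulate_titration(design, truth, seed = 1)[[1]]
  fit <- fit_single_titration(curve, "one")
  expect_equal(fit$params$KD1, truth$KD1, tolerance = 1e-6)
  expect_equal(fit$params$A0, truth$A0, tolerance = 1e-6)
  expect_equal(fit$params$A1, truth$A1, tolerance = 1e-6)
  expect_lt(fit$ssr, 1e-16)
})

test_that("noise-free two-transition data are recovered essentially exactly", {
  truth <- binding_parameters(A0 = 0.05, A1 = 0.12, A2 = 0.16,
                              KD1 = 2e-9, KD2 = 2e-6, Rt = 2e-9)
  design <- make_design(start = 1e-5, n_points = 20L, noise_sd = 0)
  curve <- simulate_titration(design, truth, seed = 1)[[1]]
  fit <- fit_single_titration(curve, "two")
  expect_equal(fit$params$KD1, truth$KD1, tolerance = 1e-5)
  expect_equal(fit$params$KD2, truth$KD2, tolerance = 1e-5)
  expect_equal(fit$params$A2, truth$A2, tolerance = 1e-5)
})

test_that("a noisy titration at the standard design recovers KD1 within 10%", {
  curves <- simulate_titration(make_design(), standard_truth(), seed = 42)
  fits <- lapply(curves, fit_single_titration, variant = "one")
  summ <- aggregate_replicates(fits)
  expect_equal(summ$mean_KD, 2.1e-9, tolerance = 0.10)
})

test_that("depletion fit agrees with a Langmuir fit when probe is trace", {
  KD <- 5e-9
  design <- make_design(start = 1e-6, Rt = KD * 1e-6, noise_sd = 0)
  truth <- binding_parameters(A0 = 0.05, A1 = 0.15, KD1 = KD, Rt = KD * 1e-6)
  curve <- simulate_titration(design, truth, seed = 1)[[1]]
  fit_eq <- fit_single_titration(curve, "one")
  frac <- (curve$A - 0.05) / 0.1
  fit_lang <- fit_langmuir(curve$Lt, frac)
  expect_equal(fit_eq$params$KD1, fit_lang$KD, tolerance = 1e-3)
})

test_that("fits are invariant to the order of the points", {
  curves <- simulate_titration(make_design(), standard_truth(), seed = 5)
  cu <- curves[[1]]
  perm <- sample(seq_along(cu$Lt))
  cu2 <- titration_curve(cu$sample_id, cu$replicate_id, cu$Rt,
                         cu$Lt[perm], cu$A[perm])
  f1 <- fit_single_titration(cu, "one")
  f2 <- fit_single_titration(cu2, "one")
  expect_equal(f1$params$KD1, f2$params$KD1, tolerance = 1e-10)
  expect_equal(f1$ssr, f2$ssr, tolerance = 1e-10)
})

test_that("model selection detects a second transition only when warranted", {
  # no second transition simulated: A2 = A1
  tr1 <- standard_truth()
  curve1 <- simulate_titration(make_design(noise_sd = 0.001), tr1,
                               seed = 2)[[1]]
  expect_equal(select_model(curve1)$variant, "one-transition")
  # strong, in-range second transition
  tr2 <- binding_parameters(A0 = 0.05, A1 = 0.12, A2 = 0.16,
                            KD1 = 2e-9, KD2 = 2e-6, Rt = 2e-9)
  curve2 <- simulate_titration(make_design(start = 1e-5, n_points = 20L,
                                           noise_sd = 0.001), tr2,
                               seed = 2)[[1]]
  expect_equal(select_model(curve2)$variant, "two-transition")
  # second transition far beyond the titration range is rejected
  tr3 <- binding_parameters(A0 = 0.05, A1 = 0.12, A2 = 0.16,
                            KD1 = 2e-9, KD2 = 1e-3, Rt = 2e-9)
  curve3 <- simulate_titration(make_design(noise_sd = 0.001), tr3,
                               seed = 2)[[1]]
  expect_equal(select_model(curve3)$variant, "one-transition")
})

test_that("replicate aggregation is plain mean/sd/sem arithmetic", {
  mk <- function(kd) {
    structure(list(sample_id = "s", replicate_id = "r",
                   params = binding_parameters(0.05, 0.15, kd, 2e-9),
                   variant = "one-transition", se = c(KD1 = 0),
                   ssr = 0, converged = TRUE, n = 17),
              class = "binding_fit")
  }
  s3 <- aggregate_replicates(list(mk(1e-8), mk(1e-8), mk(1e-8)))
  expect_equal(s3$mean_KD, 1e-8)
  expect_equal(s3$sem_KD, 0)
  s <- aggregate_replicates(list(mk(1e-9), mk(2e-9), mk(3e-9)))
  expect_equal(s$mean_KD, 2e-9)
  expect_equal(s$sd_KD, 1e-9)
  expect_equal(s$sem_KD, 1e-9 / sqrt(3))
  # seeded noisy fits: the summary equals recomputation from the KD values
  fits <- lapply(simulate_titration(make_design(n_replicates = 4L),
                                    standard_truth(), seed = 9),
                 fit_single_titration, variant = "one")
  summ <- aggregate_replicates(fits)
  kd <- vapply(fits, function(f) f$params$KD1, numeric(1))
  expect_equal(summ$mean_KD, mean(kd))
  expect_equal(summ$sem_KD, sd(kd) / 2)
  expect_error(aggregate_replicates(list()), class = "equibind_validation_error")
})

test_that("normalization rescales by the fitted first-transition baselines", {
  curves <- simulate_titration(make_design(), standard_truth(), seed = 3)
  fit <- fit_single_titration(curves[[1]], "one")
  norm <- normalize_curve(curves[[1]], fit)
  expect_equal(norm$fraction_bound,
               (curves[[1]]$A - fit$params$A0) / (fit$params$A1 - fit$params$A0))
  # anchor points of the formula
  cu0 <- curves[[1]]
  cu0$A[1] <- fit$params$A0
  expect_equal(((cu0$A - fit$params$A0) / (fit$params$A1 - fit$params$A0))[1], 0)
  flat_fit <- fit
  flat_fit$params$A1 <- flat_fit$params$A0
  expect_error(normalize_curve(curves[[1]], flat_fit),
               class = "equibind_degenerate_error")
})

test_that("competition-curve fitting recovers the exact IC50 on clean data", {
  Pt <- 2e-8; Lt <- 3e-9; KDL <- 2e-8; KDC <- 1e-8
  Ct <- c(0, 10^seq(-10, -5.5, length.out = 18))
  cc <- simulate_competition(Pt, Lt, KDL, KDC, Ct, noise_sd = 0, seed = 1)
  fit <- fit_competition_curve(cc$Ct, cc$A, Pt = Pt, Lt = Lt, KDL = KDL)
  expect_false(fit$flat)
  expect_equal(fit$IC50, ic50_from_exact_model(Pt, Lt, KDL, KDC),
               tolerance = 0.02)
  # self-competition round trip recovers the probe affinity
  cc_self <- simulate_competition(Pt, Lt, KDL, KDL, Ct, noise_sd = 0, seed = 1)
  fit_self <- fit_competition_curve(cc_self$Ct, cc_self$A,
                                    Pt = Pt, Lt = Lt, KDL = KDL)
  expect_equal(fit_self$KI, KDL, tolerance = 0.15)
})

test_that("a no-protein control titration is flagged flat", {
  Ct <- c(0, 10^seq(-10, -6, length.out = 12))
  cc <- simulate_competition(Pt = 0, Lt = 3e-9, KDL = 2e-8, KDC = 1e-8,
                             Ct = Ct, noise_sd = 0.003, seed = 4)
  fit <- fit_competition_curve(cc$Ct, cc$A, Pt = 0, Lt = 3e-9, KDL = 2e-8)
  expect_true(fit$flat)
  expect_true(is.na(fit$IC50))
})
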