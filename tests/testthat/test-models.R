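test_that("polarization/anisotropy conversion matches direct arithmetic and inverts", {
  expect_equal(polarization_to_anisotropy(0), 0)
  expect_equal(polarization_to_anisotropy(0.5), 0.4)
  expect_equal(polarization_to_anisotropy(0.3), 2 * 0.3 / (3 - 0.3))
  p <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(anisotropy_to_polarization(polarization_to_anisotropy(p)), p)
  expect_error(polarization_to_anisotropy(3), class = "equibind_domain_error")
  expect_error(polarization_to_anisotropy(-1), class = "equibind_domain_error")
})

test_that("bound fraction solves the depletion quadratic", {
  # no-depletion limit: half saturation at Lt = KD
  expect_equal(bound_fraction_quadratic(1e-15, 1e-8, 1e-8), 0.5, tolerance = 1e-6)
  expect_equal(bound_fraction_quadratic(2e-9, 0, 1e-8), 0)
  # exact closed-form value at Rt = Lt = KD
  expect_equal(bound_fraction_quadratic(1e-8, 1e-8, 1e-8), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  expect_error(bound_fraction_quadratic(1e-9, -1e-9, 1e-8),
               class = "equibind_validation_error")
  expect_error(bound_fraction_quadratic(1e-9, 1e-9, 0),
               class = "equibind_validation_error")
})

test_that("bound fraction stays in [0,1], increases with titrant, and matches the mass-balance root", {
  set.seed(101)
  for (i in 1:200) {
    Rt <- 10^runif(1, -12, -5)
    KD <- 10^runif(1, -11, -5)
    Lt <- sort(10^runif(8, -12, -4))
    fb <- bound_fraction_quadratic(Rt, Lt, KD)
    expect_true(all(fb >= 0 & fb <= 1))
    expect_true(all(diff(fb) >= -1e-12))
  }
  set.seed(102)
  for (i in 1:50) {
    Rt <- 10^runif(1, -11, -6)
    KD <- 10^runif(1, -10, -6)
    Lt <- 10^runif(1, -11, -5)
    expect_equal(bound_fraction_quadratic(Rt, Lt, KD),
                 oracle_bound_fraction(Rt, Lt, KD), tolerance = 1e-9)
  }
})

test_that("quadratic reduces to the Langmuir isotherm when probe is trace", {
  KD <- 3e-9
  Lt <- 10^seq(-11, -6, length.out = 40)
  expect_equal(bound_fraction_quadratic(KD * 1e-6, Lt, KD), Lt / (Lt + KD),
               tolerance = 1e-6)
})

test_that("anisotropy curve hits its baselines and matches the numeric-root oracle", {
  p2 <- binding_parameters(A0 = 0.05, A1 = 0.12, A2 = 0.16,
                           KD1 = 2e-9, KD2 = 2e-6, Rt = 2e-9)
  expect_equal(anisotropy_curve(0, p2), 0.05)
  sat <- anisotropy_curve(1e3 * max(p2$KD1, p2$KD2, p2$Rt), p2)
  expect_equal(sat, p2$A2, tolerance = 2e-3)
  # mid-curve point against an evaluation using the bisection bound fraction
  Lt <- 5e-9
  expected <- p2$A0 +
    (p2$A1 - p2$A0) * oracle_bound_fraction(p2$Rt, Lt, p2$KD1) +
    (p2$A2 - p2$A1) * Lt / (Lt + p2$KD2)
  expect_equal(anisotropy_curve(Lt, p2), expected, tolerance = 1e-9)
  # one-transition variant saturates at A1
  p1 <- binding_parameters(A0 = 0.05, A1 = 0.15, KD1 = 2e-9, Rt = 2e-9)
  expect_equal(anisotropy_curve(1e3 * max(p1$KD1, p1$Rt), p1), p1$A1,
               tolerance = 2e-3)
})

test_that("competition speciation reduces to binary binding without competitor", {
  sys <- competition_system(Pt = 1e-8, Lt = 3e-9, Ct = 0,
                            KDL = 2e-9, KDC = 5e-9)
  st <- solve_competition(sys)
  expect_equal(st$PC, 0)
  expect_equal(st$PL, 3e-9 * bound_fraction_quadratic(3e-9, 1e-8, 2e-9),
               tolerance = 1e-9)
})

test_that("competition speciation is symmetric for identical ligands", {
  st <- solve_competition(competition_system(2e-8, 5e-9, 5e-9, 3e-9, 3e-9))
  expect_equal(st$PL, st$PC, tolerance = 1e-12)
})

test_that("speciation matches dense bisection and satisfies mass balances across 12 decades", {
  set.seed(7)
  for (i in 1:50) {
    Pt <- 10^runif(1, -12, -5); Lt <- 10^runif(1, -12, -5)
    Ct <- 10^runif(1, -12, -5)
    KDL <- 10^runif(1, -11, -5); KDC <- 10^runif(1, -11, -5)
    st <- solve_competition(competition_system(Pt, Lt, Ct, KDL, KDC))
    or <- oracle_speciation(Pt, Lt, Ct, KDL, KDC)
    expect_equal(st$PL, or$PL, tolerance = 1e-8)
    expect_equal(st$PC, or$PC, tolerance = 1e-8)
  }
  set.seed(8)
  for (i in 1:1000) {
    Pt <- 10^runif(1, -15, -3); Lt <- 10^runif(1, -15, -3)
    Ct <- 10^runif(1, -15, -3)
    KDL <- 10^runif(1, -12, -4); KDC <- 10^runif(1, -12, -4)
    st <- solve_competition(competition_system(Pt, Lt, Ct, KDL, KDC))
    expect_true(all(c(st$freeP, st$freeL, st$freeC, st$PL, st$PC) >= 0))
    expect_lt(abs(st$freeP + st$PL + st$PC - Pt), 1e-10 * Pt)
    expect_lt(abs(st$freeL + st$PL - Lt), 1e-10 * Lt)
    expect_lt(abs(st$freeC + st$PC - Ct), 1e-10 * Ct)
  }
})

test_that("IC50 from the exact model behaves like Cheng-Prusoff in the trace limit", {
  KDL <- 1e-8; KDC <- 4e-9
  ic <- ic50_from_exact_model(Pt = KDL / 1000, Lt = KDL / 1000,
                              KDL = KDL, KDC = KDC)
  expect_equal(ic, KDC, tolerance = 0.01)
})

test_that("IC50 matches a dense-bisection sweep and is monotone in KDC and Pt", {
  Pt <- 2e-8; Lt <- 3e-9; KDL <- 2e-8; KDC <- 1e-8
  ic <- ic50_from_exact_model(Pt, Lt, KDL, KDC)
  # oracle: bisection on Ct where the bisection speciation halves PL
  PL0 <- oracle_speciation(Pt, Lt, 0, KDL, KDC)$PL
  h <- function(Ct) oracle_speciation(Pt, Lt, Ct, KDL, KDC)$PL - PL0 / 2
  lo <- 0; hi <- 1e-5
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(ic, (lo + hi) / 2, tolerance = 1e-6)
  expect_gt(ic50_from_exact_model(Pt, Lt, KDL, 2 * KDC), ic)
  expect_gt(ic50_from_exact_model(2 * Pt, Lt, KDL, KDC), ic)
  expect_error(ic50_from_exact_model(1e-8, 1e-9, 1e-8, 1e-9, tol = 1e-10),
               NA) # sanity: valid call does not error
})

test_that("K_I conversion reduces to the IC50 without depletion", {
  KDL <- 1e-8
  ic50 <- 3e-9
  ki <- ki_from_ic50(ic50, Lt = KDL * 1e-6, Pt = KDL * 1e-6, KDL = KDL)
  expect_equal(ki, ic50, tolerance = 1e-3)
})

test_that("K_I round-trips against the exact speciation model", {
  # conditions of an RNA-probe competition: 3 nM probe, 20 nM protein
  Pt <- 2e-8; Lt <- 3e-9; KDL <- 2e-8
  for (KDC in c(1e-9, 5e-9, 2e-8, 1e-7)) {
    ic <- ic50_from_exact_model(Pt, Lt, KDL, KDC)
    expect_equal(ki_from_ic50(ic, Lt, Pt, KDL), KDC, tolerance = 0.15)
  }
  # self-competition control: unlabeled ligand identical to the probe
  ic_self <- ic50_from_exact_model(Pt, Lt, KDL, KDL)
  expect_equal(ki_from_ic50(ic_self, Lt, Pt, KDL), KDL, tolerance = 0.15)
})

test_that("K_I conversion stays within 15% across the documented validity regime", {
  set.seed(11)
  for (i in 1:100) {
    KDL <- 10^runif(1, -9, -7)
    Pt <- runif(1, 0.1, 5) * KDL
    Lt <- runif(1, 0.1, 1) * Pt
    KDC <- 10^runif(1, log10(KDL) - 1, log10(KDL) + 1)
    ic <- ic50_from_exact_model(Pt, Lt, KDL, KDC)
    expect_equal(ki_from_ic50(ic, Lt, Pt, KDL), KDC, tolerance = 0.15)
  }
})

test_that("K_I conversion rejects non-physical inputs", {
  # an IC50 smaller than the protein bound as competitor complex is impossible
  expect_error(ki_from_ic50(1e-12, Lt = 1e-8, Pt = 1e-6, KDL = 1e-9),
               class = "equibind_domain_error")
})
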