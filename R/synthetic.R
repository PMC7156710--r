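# Seeded generators for every input class the analysis consumes. All are pure
# functions of (parameters, seed); the caller's RNG stream is left untouched.

#' Design of a simulated anisotropy titration
#'
#' Defaults reproduce a typical plate-based design: 16 two-fold dilutions from
#' 1 uM titrant, 2 nM probe, triplicate curves each read three times, Gaussian
#' anisotropy noise with sd 0.003 per read.
#'
#' @param start molar top titrant concentration (default 1e-6).
#' @param dilution_factor serial dilution factor (> 1, default 2).
#' @param n_points number of titrant concentrations (>= 6, default 16).
#' @param Rt molar probe concentration (default 2e-9).
#' @param n_replicates technical replicates (default 3).
#' @param n_reads instrument reads per point, averaged (default 3).
#' @param noise_sd Gaussian anisotropy noise per read (default 0.003).
#' @param include_zero prepend a titrant-free point (default TRUE).
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(start = 1e-6, dilution_factor = 2, n_points = 16L,
                              Rt = 2e-9, n_replicates = 3L, n_reads = 3L,
                              noise_sd = 0.003, include_zero = TRUE) {
  assert_scalar_number(start, "start", positive = TRUE)
  assert_scalar_number(dilution_factor, "dilution_factor", positive = TRUE)
  if (dilution_factor <= 1)
    stop_equibind("`dilution_factor` must be > 1", "equibind_validation_error")
  if (n_points < 6L)
    stop_equibind("`n_points` must be >= 6", "equibind_validation_error")
  assert_scalar_number(Rt, "Rt", nonneg = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  Lt <- start / dilution_factor^(seq_len(n_points) - 1)
  if (include_zero) Lt <- c(Lt, 0)
  structure(list(Lt = sort(Lt), Rt = Rt,
                 n_replicates = as.integer(n_replicates),
                 n_reads = as.integer(n_reads), noise_sd = noise_sd),
            class = "simulation_design")
}

#' Simulate replicate anisotropy titrations
#'
#' Evaluates [anisotropy_curve()] on the design grid, adds independent
#' Gaussian read noise, and averages the reads per point, emulating a
#' plate-reader titration performed in replicate with repeated reads.
#' Deterministic for a fixed seed.
#'
#' @param design a [simulation_design()].
#' @param truth a [binding_parameters()] object (its `Rt` should match the
#'   design; the design's `Rt` is used).
#' @param sample_id identifier stamped on the curves.
#' @param seed integer seed (default 0).
#' @return A list of [titration_curve()] objects, one per replicate, with the
#'   generating truth attached as attribute `truth`.
#' @export
simulate_titration <- function(design, truth, sample_id = "sim", seed = 0L) {
  if (!inherits(design, "simulation_design"))
    stop_equibind("`design` must be a simulation_design",
                  "equibind_validation_error")
  if (!inherits(truth, "binding_parameters"))
    stop_equibind("`truth` must be binding_parameters",
                  "equibind_validation_error")
  p <- truth
  if (p$Rt != design$Rt)
    p <- binding_parameters(A0 = p$A0, A1 = p$A1, KD1 = p$KD1, Rt = design$Rt,
                            A2 = p$A2, KD2 = p$KD2)
  clean <- anisotropy_curve(design$Lt, p)
  curves <- with_seed(seed, {
    lapply(seq_len(design$n_replicates), function(r) {
      reads <- matrix(stats::rnorm(length(clean) * design$n_reads,
                                   mean = clean, sd = design$noise_sd),
                      nrow = length(clean))
      titration_curve(sample_id, sprintf("rep%d", r), design$Rt,
                      design$Lt, rowMeans(reads))
    })
  })
  attr(curves, "truth") <- p
  attr(curves, "seed") <- seed
  curves
}

#' Simulate a competition curve
#'
#' Computes the labeled-complex concentration PL over a competitor grid with
#' [solve_competition()], maps it linearly onto anisotropy between the
#' free-probe and fully-bound endpoints, and adds Gaussian noise.
#'
#' @param Pt,Lt molar totals of protein and labeled ligand.
#' @param KDL,KDC molar dissociation constants of probe and competitor.
#' @param Ct molar total competitor grid.
#' @param A_free,A_bound anisotropy of free and fully bound probe
#'   (defaults 0.05, 0.15).
#' @param noise_sd Gaussian anisotropy noise (default 0.003).
#' @param seed integer seed (default 0).
#' @return A data.frame with columns `Ct` and `A`, with attribute `truth`
#'   (list of the generating values).
#' @export
simulate_competition <- function(Pt, Lt, KDL, KDC, Ct,
                                 A_free = 0.05, A_bound = 0.15,
                                 noise_sd = 0.003, seed = 0L) {
  assert_numeric_vec(Ct, "Ct", nonneg = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  PL <- vapply(Ct, function(ct)
    solve_competition(competition_system(Pt, Lt, ct, KDL, KDC))$PL, numeric(1))
  A <- A_free + (A_bound - A_free) * PL / Lt
  A <- with_seed(seed, A + stats::rnorm(length(A), 0, noise_sd))
  out <- data.frame(Ct = Ct, A = A)
  attr(out, "truth") <- list(Pt = Pt, Lt = Lt, KDL = KDL, KDC = KDC,
                             A_free = A_free, A_bound = A_bound,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a salt-dependence series
#'
#' Generates apparent dissociation constants following
#' \eqn{\log_{10} K_A = -Z \psi \log_{10} M + \log_{10} K_A(1 M)} with
#' multiplicative lognormal noise on KD.
#'
#' @param Z counterions released.
#' @param psi cation association parameter (default 0.695).
#' @param KA_1M association constant extrapolated to 1 M salt (1/M).
#' @param M molar salt grid (default eight points over 0.15-0.27 M).
#' @param sdlog lognormal sd of the KD noise (default 0; 0.1 is ~10% scatter).
#' @param sample_id identifier.
#' @param seed integer seed (default 0).
#' @return A [salt_series()] with attribute `truth`.
#' @export
simulate_salt_series <- function(Z, psi = 0.695, KA_1M,
                                 M = seq(0.15, 0.27, length.out = 8),
                                 sdlog = 0, sample_id = "sim_salt", seed = 0L) {
  assert_scalar_number(Z, "Z", nonneg = TRUE)
  assert_scalar_number(KA_1M, "KA_1M", positive = TRUE)
  assert_numeric_vec(M, "M")
  assert_scalar_number(sdlog, "sdlog", nonneg = TRUE)
  log10KA <- -Z * psi * log10(M) + log10(KA_1M)
  KD <- 10^(-log10KA)
  KD <- with_seed(seed, KD * exp(stats::rnorm(length(KD), 0, sdlog)))
  out <- salt_series(sample_id, M, KD)
  attr(out, "truth") <- list(Z = Z, psi = psi, KA_1M = KA_1M,
                             slope = -Z * psi, sdlog = sdlog, seed = seed)
  out
}

#' Simulate a stoichiometric EMSA titration
#'
#' Converts [simulate_sequential_binding()] fractions into pseudo band
#' intensities with multiplicative lane-loading variation and additive
#' fraction noise (truncated at zero), mimicking densitometry of a
#' stoichiometric gel titration.
#'
#' @param Nt molar total nucleic acid (default 2e-6).
#' @param KD1,KD2 molar stepwise dissociation constants.
#' @param ratios protein:ligand ratios (default 0-3 in steps of 0.1).
#' @param fraction_sd additive noise on each fraction (default 0).
#' @param loading_sdlog lognormal sd of per-lane loading (default 0).
#' @param total_intensity mean lane intensity in arbitrary units (default 1e4).
#' @param seed integer seed (default 0).
#' @return A data.frame with columns `ratio`, `F`, `B1`, `B2` (intensities),
#'   with attribute `truth`.
#' @export
simulate_emsa <- function(Nt = 2e-6, KD1, KD2, ratios = seq(0, 3, by = 0.1),
                          fraction_sd = 0, loading_sdlog = 0,
                          total_intensity = 1e4, seed = 0L) {
  assert_scalar_number(fraction_sd, "fraction_sd", nonneg = TRUE)
  assert_scalar_number(loading_sdlog, "loading_sdlog", nonneg = TRUE)
  fr <- simulate_sequential_binding(Nt, KD1, KD2, ratios)
  out <- with_seed(seed, {
    n <- nrow(fr)
    load <- total_intensity * exp(stats::rnorm(n, 0, loading_sdlog))
    noisy <- as.matrix(fr[, c("f_F", "f_B1", "f_B2")]) +
      matrix(stats::rnorm(3 * n, 0, fraction_sd), ncol = 3)
    noisy[noisy < 0] <- 0
    data.frame(ratio = fr$ratio,
               F = load * noisy[, 1], B1 = load * noisy[, 2],
               B2 = load * noisy[, 3])
  })
  attr(out, "truth") <- list(Nt = Nt, KD1 = KD1, KD2 = KD2,
                             fraction_sd = fraction_sd,
                             loading_sdlog = loading_sdlog, seed = seed)
  out
}

#' Default alanine-panel design
#'
#' A fixed 48-mutant design emulating a comprehensive alanine scan of a
#' nucleic-acid-binding domain: 22 basic (R/K) and 26 other residues, with
#' true relative affinities spanning ~0.3- to ~280-fold so that replicate
#' apparent KDs at a ~2-3 nM wild-type affinity cover roughly 0.7-590 nM.
#' By construction 17 basic residues are affected at the 2.5-fold threshold
#' for either substrate and 11 of those have the greater RNA impact; these
#' truth labels are what panel-classification recovery is judged against.
#'
#' @return A data.frame with columns `mutant_id`, `residue_class`
#'   (`"basic"`/`"other"`), `krel_dna`, `krel_rna`.
#' @export
default_panel_design <- function() {
  basic_ids <- sprintf("%s%dA", rep(c("K", "R"), length.out = 22), 61:82)
  other_ids <- sprintf("%s%dA", rep(c("N", "S", "W", "M", "F", "Y"),
                                    length.out = 26), 83:108)
  # 11 basic, RNA impact dominant (affected for RNA, variably for DNA)
  rna_dom_dna <- c(1.2, 3.0, 1.5, 6.0, 2.0, 4.0, 1.0, 8.0, 1.4, 5.0, 2.2)
  rna_dom_rna <- c(12, 30, 9, 60, 15, 40, 7, 180, 10, 75, 20)
  # 6 basic, affected with DNA impact >= RNA impact
  dna_ge_dna <- c(25, 8, 60, 15, 280, 40)
  dna_ge_rna <- c(10, 4, 25, 7, 110, 18)
  # 5 basic residues essentially unaffected
  basic_null_dna <- c(1.1, 0.8, 1.3, 1.0, 0.9)
  basic_null_rna <- c(0.9, 1.2, 1.0, 1.4, 1.1)
  # 26 others: 8 affected (mixed preference), 18 near-neutral
  other_aff_dna <- c(30, 5, 1.2, 90, 12, 2.0, 45, 7)
  other_aff_rna <- c(12, 11, 8.0, 35, 30, 9.0, 18, 16)
  other_null_dna <- rep(c(1.0, 1.2, 0.8, 1.5, 0.9, 0.35), length.out = 18)
  other_null_rna <- rep(c(1.1, 0.9, 1.3, 0.7, 1.2, 0.45), length.out = 18)
  data.frame(
    mutant_id = c(basic_ids, other_ids),
    residue_class = rep(c("basic", "other"), c(22, 26)),
    krel_dna = c(rna_dom_dna, dna_ge_dna, basic_null_dna,
                 other_aff_dna, other_null_dna),
    krel_rna = c(rna_dom_rna, dna_ge_rna, basic_null_rna,
                 other_aff_rna, other_null_rna),
    stringsAsFactors = FALSE
  )
}

#' Simulate an alanine-scan mutant panel
#'
#' Draws replicate apparent dissociation constants for every mutant and both
#' substrates: `KD = wt_KD * krel_true * lognormal(cv)` per replicate, plus
#' wild-type rows. Truth (the design) is attached for recovery tests.
#'
#' @param design a design data.frame as from [default_panel_design()].
#' @param wt_kd named molar wild-type affinities, `c(DNA = ..., RNA = ...)`.
#' @param n_replicates replicates per mutant and substrate (default 3).
#' @param cv lognormal replicate scatter, sdlog units (default 0.1).
#' @param seed integer seed (default 0).
#' @return A long-format data.frame (`mutant_id`, `substrate`, `replicate`,
#'   `KD_M`, `residue_class`) including `"WT"` rows, with attribute `truth`.
#' @export
simulate_mutant_panel <- function(design = default_panel_design(),
                                  wt_kd = c(DNA = 2.1e-9, RNA = 2.8e-9),
                                  n_replicates = 3L, cv = 0.1, seed = 0L) {
  needed <- c("mutant_id", "residue_class", "krel_dna", "krel_rna")
  if (!all(needed %in% names(design)))
    stop_equibind("panel design needs columns mutant_id, residue_class, krel_dna, krel_rna",
                  "equibind_validation_error")
  if (!all(c("DNA", "RNA") %in% names(wt_kd)))
    stop_equibind("`wt_kd` must be named with DNA and RNA",
                  "equibind_validation_error")
  assert_scalar_number(cv, "cv", nonneg = TRUE)
  full <- rbind(
    data.frame(mutant_id = "WT", residue_class = "wildtype",
               krel_dna = 1, krel_rna = 1, stringsAsFactors = FALSE),
    design[needed]
  )
  out <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(full)), function(i) {
      do.call(rbind, lapply(c("DNA", "RNA"), function(sub) {
        krel <- if (sub == "DNA") full$krel_dna[i] else full$krel_rna[i]
        kd <- wt_kd[[sub]] * krel * exp(stats::rnorm(n_replicates, 0, cv))
        data.frame(mutant_id = full$mutant_id[i], substrate = sub,
                   replicate = seq_len(n_replicates), KD_M = kd,
                   residue_class = full$residue_class[i],
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "truth") <- list(design = design, wt_kd = wt_kd, cv = cv,
                             seed = seed)
  out
}
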