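#' Relative affinity of a mutant with propagated uncertainty
#'
#' \eqn{K_{rel} = \bar{K}_{D,app}(mutant) / \bar{K}_{D,app}(wild type)} from
#' replicate apparent dissociation constants measured on the same substrate.
#' The standard deviation is propagated to first order (relative errors in
#' quadrature): \eqn{sd(K_{rel}) = K_{rel} \sqrt{(sd_m/\bar{K}_m)^2 +
#' (sd_w/\bar{K}_w)^2}}.
#'
#' @param kd_mutant,kd_wildtype molar replicate KD vectors (> 0).
#' @param substrate_mutant,substrate_wildtype substrate labels; must match.
#' @return A list: `krel`, `sd`, `n_mutant`, `n_wildtype`, `substrate`.
#' @export
compute_krel <- function(kd_mutant, kd_wildtype,
                         substrate_mutant = "DNA",
                         substrate_wildtype = substrate_mutant) {
  assert_numeric_vec(kd_mutant, "kd_mutant")
  assert_numeric_vec(kd_wildtype, "kd_wildtype")
  if (any(kd_mutant <= 0) || any(kd_wildtype <= 0))
    stop_equibind("all KD values must be > 0", "equibind_validation_error")
  if (!identical(substrate_mutant, substrate_wildtype))
    stop_equibind(
      sprintf("substrate mismatch: mutant measured on %s, wild type on %s",
              substrate_mutant, substrate_wildtype),
      "equibind_validation_error")
  m_mut <- mean(kd_mutant); m_wt <- mean(kd_wildtype)
  rel_m <- if (length(kd_mutant) > 1) stats::sd(kd_mutant) / m_mut else 0
  rel_w <- if (length(kd_wildtype) > 1) stats::sd(kd_wildtype) / m_wt else 0
  krel <- m_mut / m_wt
  list(krel = krel, sd = krel * sqrt(rel_m^2 + rel_w^2),
       n_mutant = length(kd_mutant), n_wildtype = length(kd_wildtype),
       substrate = substrate_mutant)
}

#' Test whether a mutation affects DNA and RNA binding differently
#'
#' Two-sided test of the DNA-substrate against the RNA-substrate replicate
#' affinities on the log10 scale (affinities are ratio-scale quantities;
#' their logs are the conventional approximately normal variable). The
#' default is Welch's unequal-variance t-test; `method = "wilcoxon"` gives a
#' rank-sum alternative. Degenerate zero-variance inputs, which `t.test()`
#' refuses, are resolved exactly: equal constant samples give p = 1,
#' separated constant samples give p = 0.
#'
#' @param kd_dna,kd_rna replicate values for the two substrates (>= 3 each;
#'   raw KDs or relative affinities, either works since only the within-group
#'   spread and the group difference matter on the log scale).
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return Two-sided p-value in \[0, 1\].
#' @export
compare_substrates <- function(kd_dna, kd_rna, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  assert_numeric_vec(kd_dna, "kd_dna")
  assert_numeric_vec(kd_rna, "kd_rna")
  if (length(kd_dna) < 3L || length(kd_rna) < 3L)
    stop_equibind("need >= 3 replicates per substrate",
                  "equibind_validation_error")
  if (any(kd_dna <= 0) || any(kd_rna <= 0))
    stop_equibind("all values must be > 0 for the log-scale test",
                  "equibind_validation_error")
  x <- log10(kd_dna); y <- log10(kd_rna)
  if (method == "wilcoxon")
    return(suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value))
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Classify an alanine-scan panel by substrate impact
#'
#' Counts mutants whose relative affinity meets the fold threshold for either
#' substrate (binding weakened at least `fold_threshold`-fold), how many of
#' those are hit harder on RNA than on DNA, and the same two counts restricted
#' to basic residues. Residue class (`"basic"` vs anything else) is a required
#' annotation column, not inferred from the mutant name.
#'
#' @param panel a data.frame with columns `mutant_id`, `Krel_DNA`, `Krel_RNA`,
#'   `residue_class`.
#' @param fold_threshold minimum fold-weakening to call a mutant affected
#'   (default 2.5).
#' @return A list of counts: `n_mutants`, `affected_either`, `rna_greater`,
#'   `basic_affected`, `basic_rna_greater`, plus the annotated `panel`
#'   (logical columns `affected` and `rna_greater` added).
#' @export
classify_panel <- function(panel, fold_threshold = 2.5) {
  needed <- c("mutant_id", "Krel_DNA", "Krel_RNA", "residue_class")
  if (!is.data.frame(panel) || !all(needed %in% names(panel)))
    stop_equibind("`panel` needs columns mutant_id, Krel_DNA, Krel_RNA, residue_class",
                  "equibind_validation_error")
  if (!nrow(panel))
    stop_equibind("empty panel", "equibind_validation_error")
  if (anyNA(panel$residue_class))
    stop_equibind("missing residue_class annotation", "equibind_validation_error")
  assert_scalar_number(fold_threshold, "fold_threshold", positive = TRUE)
  affected <- panel$Krel_DNA >= fold_threshold | panel$Krel_RNA >= fold_threshold
  rna_greater <- affected & panel$Krel_RNA > panel$Krel_DNA
  basic <- panel$residue_class == "basic"
  panel$affected <- affected
  panel$rna_greater <- rna_greater
  list(n_mutants = nrow(panel),
       affected_either = sum(affected),
       rna_greater = sum(rna_greater),
       basic_affected = sum(affected & basic),
       basic_rna_greater = sum(rna_greater & basic),
       panel = panel)
}

#' Full mutant-panel comparison from replicate measurements
#'
#' Takes a long-format panel table (as produced by [simulate_mutant_panel()]
#' or [read_mutant_table()]), computes per-mutant relative affinities for each
#' substrate against the wild-type rows, the DNA-vs-RNA p-value from the
#' replicate relative affinities, and the panel classification.
#'
#' @param panel_table data.frame with columns `mutant_id`, `substrate`
#'   (`"DNA"`/`"RNA"`), `replicate`, `KD_M`, `residue_class`; must contain
#'   `mutant_id == wildtype_id` rows for both substrates.
#' @param wildtype_id identifier of the wild-type rows (default `"WT"`).
#' @param fold_threshold passed to [classify_panel()] (default 2.5).
#' @param method passed to [compare_substrates()].
#' @return A list: `comparison` (one row per mutant: `mutant_id`,
#'   `Krel_DNA`, `sd_DNA`, `Krel_RNA`, `sd_RNA`, `p_value`, `residue_class`)
#'   and `classification` (the [classify_panel()] counts).
#' @export
analyze_mutant_panel <- function(panel_table, wildtype_id = "WT",
                                 fold_threshold = 2.5,
                                 method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  needed <- c("mutant_id", "substrate", "replicate", "KD_M", "residue_class")
  if (!is.data.frame(panel_table) || !all(needed %in% names(panel_table)))
    stop_equibind("panel table needs columns mutant_id, substrate, replicate, KD_M, residue_class",
                  "equibind_validation_error")
  wt <- panel_table[panel_table$mutant_id == wildtype_id, ]
  if (!all(c("DNA", "RNA") %in% wt$substrate))
    stop_equibind(sprintf("wild-type rows '%s' must cover both substrates",
                          wildtype_id),
                  "equibind_validation_error")
  wt_kd <- split(wt$KD_M, wt$substrate)
  muts <- setdiff(unique(panel_table$mutant_id), wildtype_id)
  rows <- lapply(muts, function(id) {
    sub <- panel_table[panel_table$mutant_id == id, ]
    kd <- split(sub$KD_M, sub$substrate)
    if (!all(c("DNA", "RNA") %in% names(kd)))
      stop_equibind(sprintf("mutant %s lacks one substrate", id),
                    "equibind_validation_error")
    kr_d <- compute_krel(kd$DNA, wt_kd$DNA, "DNA")
    kr_r <- compute_krel(kd$RNA, wt_kd$RNA, "RNA")
    # relative affinities per replicate share the wild-type mean, which
    # cancels in the two-substrate comparison
    p <- compare_substrates(kd$DNA / mean(wt_kd$DNA),
                            kd$RNA / mean(wt_kd$RNA), method = method)
    data.frame(mutant_id = id,
               Krel_DNA = kr_d$krel, sd_DNA = kr_d$sd,
               Krel_RNA = kr_r$krel, sd_RNA = kr_r$sd,
               p_value = p,
               residue_class = sub$residue_class[1],
               stringsAsFactors = FALSE)
  })
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  list(comparison = comparison,
       classification = classify_panel(comparison, fold_threshold))
}
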