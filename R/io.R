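# Delimited-table readers/writers. Concentration columns are molar and carry
# an explicit _M suffix; comma and tab dialects are auto-detected; empty cells
# are treated as missing and dropped with a reported count; non-numeric cells
# are an error naming the offending lines.

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path))
    stop_equibind(sprintf("file not found: %s", path), "equibind_io_error")
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = NULL,
                          quote = "\"", comment.char = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_equibind(sprintf("%s: missing column(s): %s", path,
                          paste(missing_cols, collapse = ", ")),
                  "equibind_parse_error")
  # empty cells are missing values; drop those rows with a reported count
  blank <- rep(FALSE, nrow(df))
  for (cc in required) blank <- blank | !nzchar(trimws(df[[cc]]))
  if (any(blank))
    message(sprintf("%s: dropped %d row(s) with missing values", path,
                    sum(blank)))
  df <- df[!blank, , drop = FALSE]
  lines <- which(!blank) + 1L   # +1 for the header line
  for (cc in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- is.na(vals)
    if (any(bad))
      stop_equibind(
        sprintf("%s: non-numeric value(s) in column '%s' at line(s) %s", path,
                cc, paste(lines[bad], collapse = ", ")),
        "equibind_parse_error")
    df[[cc]] <- vals
  }
  df
}

#' Read a titration table into curves
#'
#' Expects a delimited text file (comma or tab, auto-detected) with header
#' columns `sample_id`, `replicate`, `titrant_conc_M`, `anisotropy` (or
#' `polarization` together with `polarization = TRUE`), `probe_conc_M`.
#' Each (sample, replicate) pair becomes one [titration_curve()]; the probe
#' concentration must be constant within a replicate.
#'
#' @param path file path.
#' @param polarization read a `polarization` column and convert it with
#'   [polarization_to_anisotropy()] (default `FALSE`).
#' @return A list of [titration_curve()] objects.
#' @export
read_titration_table <- function(path, polarization = FALSE) {
  signal_col <- if (polarization) "polarization" else "anisotropy"
  req <- c("sample_id", "replicate", "titrant_conc_M", signal_col,
           "probe_conc_M")
  df <- read_delim_checked(path, req, c("titrant_conc_M", signal_col,
                                        "probe_conc_M"))
  if (polarization)
    df$anisotropy <- polarization_to_anisotropy(df$polarization)
  key <- interaction(df$sample_id, df$replicate, drop = TRUE)
  lapply(split(df, key), function(g) {
    rt <- unique(g$probe_conc_M)
    if (length(rt) != 1L)
      stop_equibind(
        sprintf("inconsistent probe_conc_M within %s/%s: %s",
                g$sample_id[1], g$replicate[1],
                paste(signif(rt, 6), collapse = ", ")),
        "equibind_parse_error")
    titration_curve(g$sample_id[1], g$replicate[1], rt,
                    g$titrant_conc_M, g$anisotropy)
  })
}

#' Write titration curves to a delimited table
#'
#' @param curves list of [titration_curve()] objects.
#' @param path output file path (.csv or .tsv decides the delimiter).
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(curves, path) {
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cu)
    data.frame(sample_id = cu$sample_id, replicate = cu$replicate_id,
               titrant_conc_M = cu$Lt, anisotropy = cu$A,
               probe_conc_M = cu$Rt, stringsAsFactors = FALSE)))
  write_table(rows, path)
}

#' Read a competition-curve table
#'
#' Columns: `sample_id`, `competitor_conc_M`, `anisotropy`.
#'
#' @param path file path.
#' @return A list of data.frames (one per sample) with columns `Ct`, `A`.
#' @export
read_competition_table <- function(path) {
  df <- read_delim_checked(path, c("sample_id", "competitor_conc_M",
                                   "anisotropy"),
                           c("competitor_conc_M", "anisotropy"))
  lapply(split(df, df$sample_id), function(g)
    data.frame(Ct = g$competitor_conc_M, A = g$anisotropy))
}

#' Read a salt-dependence table
#'
#' Columns: `sample_id`, `salt_M`, `KD_M`.
#'
#' @param path file path.
#' @param temperature kelvin, stamped on each series (default 298.15).
#' @return A list of [salt_series()] objects.
#' @export
read_salt_table <- function(path, temperature = 298.15) {
  df <- read_delim_checked(path, c("sample_id", "salt_M", "KD_M"),
                           c("salt_M", "KD_M"))
  lapply(split(df, df$sample_id), function(g)
    salt_series(g$sample_id[1], g$salt_M, g$KD_M, temperature))
}

#' Read an EMSA lane table
#'
#' Columns: `sample_id`, `ratio`, `F`, `B1`, `B2` (background-corrected
#' integrated intensities).
#'
#' @param path file path.
#' @return A list of data.frames (one per sample) with the lane columns.
#' @export
read_lane_table <- function(path) {
  df <- read_delim_checked(path, c("sample_id", "ratio", "F", "B1", "B2"),
                           c("ratio", "F", "B1", "B2"))
  lapply(split(df, df$sample_id), function(g) {
    g <- g[order(g$ratio), ]
    data.frame(ratio = g$ratio, F = g$F, B1 = g$B1, B2 = g$B2)
  })
}

#' Read a mutant-panel table
#'
#' Columns: `mutant_id`, `substrate` (`DNA`/`RNA`), `replicate`, `KD_M`,
#' `residue_class`.
#'
#' @param path file path.
#' @return A data.frame in the long format [analyze_mutant_panel()] consumes.
#' @export
read_mutant_table <- function(path) {
  df <- read_delim_checked(path, c("mutant_id", "substrate", "replicate",
                                   "KD_M", "residue_class"), "KD_M")
  bad <- !df$substrate %in% c("DNA", "RNA")
  if (any(bad))
    stop_equibind(sprintf("%s: substrate must be DNA or RNA (line(s) %s)",
                          path, paste(which(bad) + 1L, collapse = ", ")),
                  "equibind_parse_error")
  df[c("mutant_id", "substrate", "replicate", "KD_M", "residue_class")]
}

#' Write a data.frame as delimited text
#'
#' Delimiter follows the file extension: tab for `.tsv`, comma otherwise.
#' Fixed column order (as supplied), header row, no quoting of numerics.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Fit report for a set of titration curves
#'
#' Runs [select_model()] on each curve and assembles the standard one-row-per
#' curve report.
#'
#' @param curves list of [titration_curve()] objects.
#' @return A data.frame: `sample_id`, `replicate`, `variant`, `KD1_M`,
#'   `KD1_se_M`, `KD2_M`, `A0`, `A1`, `A2`, `SSR`, `converged`.
#' @export
fit_report <- function(curves) {
  if (inherits(curves, "titration_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cu) {
    sel <- select_model(cu)
    f <- sel$fit
    data.frame(sample_id = f$sample_id, replicate = f$replicate_id,
               variant = f$variant,
               KD1_M = f$params$KD1, KD1_se_M = unname(f$se["KD1"]),
               KD2_M = f$params$KD2,
               A0 = f$params$A0, A1 = f$params$A1, A2 = f$params$A2,
               SSR = f$ssr, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
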