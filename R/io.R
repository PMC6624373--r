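#' Read a cross-link spectrum-match table (TSV)
#'
#' Xi-search-style tab-separated table with one row per cross-link spectrum
#' match. Mandatory columns: `spectrum_id`, `pep_seq_a`, `pep_seq_b`,
#' `pep_start_a`, `pep_start_b`, `link_pos_a`, `link_pos_b`, `match_score`,
#' `charge`, `experiment`, `labelling_complete`. Rows whose link positions
#' fall outside their peptide are skipped with a warning; a `crosslink`
#' identifier is derived from the peptide spans and link positions when not
#' already present.
#'
#' @param path File path.
#' @return Tibble of validated matches; `attr(, "n_skipped")` counts
#'   malformed rows.
#' @export
read_crosslink_table <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  need <- c("spectrum_id", "pep_seq_a", "pep_seq_b", "pep_start_a",
            "pep_start_b", "link_pos_a", "link_pos_b", "match_score",
            "charge", "experiment", "labelling_complete")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste("cross-link table is missing mandatory column(s):",
                paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warn("cross-link table contains a header but no rows")
    attr(df, "n_skipped") <- 0L
    return(df)
  }
  ok <- df$link_pos_a >= 1 & df$link_pos_a <= nchar(df$pep_seq_a) &
    df$link_pos_b >= 1 & df$link_pos_b <= nchar(df$pep_seq_b) &
    df$charge >= 1
  if (any(!ok)) {
    warn(sprintf("skipping %d malformed row(s) (link position outside peptide or bad charge)",
                 sum(!ok)))
  }
  df <- df[ok, , drop = FALSE]
  if (!"crosslink" %in% names(df)) {
    pos_a <- df$pep_start_a + df$link_pos_a - 1L
    pos_b <- df$pep_start_b + df$link_pos_b - 1L
    aa_a <- substr(df$pep_seq_a, df$link_pos_a, df$link_pos_a)
    aa_b <- substr(df$pep_seq_b, df$link_pos_b, df$link_pos_b)
    df <- dplyr::bind_cols(df, canonical_crosslinks(
      tibble(pos_a = pos_a, aa_a = aa_a, pos_b = pos_b, aa_b = aa_b)
    )["crosslink"])
  }
  attr(df, "n_skipped") <- sum(!ok)
  df
}

#' Read a precursor cluster-intensity table (CSV)
#'
#' Accepts either the wide form (`spectrum_id`, `area_LL`, `area_HL`,
#' `area_LH`, `area_HH`) or the long per-isotope-peak form (`spectrum_id`,
#' `combo`, `isotope_peak`, `area`), which is collapsed with
#' [sum_isotope_peaks()].
#'
#' @param path File path.
#' @param mode Isotope-peak aggregation for long input (`"sum"` or
#'   `"mean"`).
#' @return Wide tibble of per-spectrum cluster areas.
#' @export
read_intensity_table <- function(path, mode = "sum") {
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  wide <- c("area_LL", "area_HL", "area_LH", "area_HH")
  if (all(wide %in% names(df))) return(df)
  if (all(c("combo", "area") %in% names(df))) {
    return(sum_isotope_peaks(df, mode = mode))
  }
  abort("intensity table needs either area_LL/area_HL/area_LH/area_HH columns or long-form combo/area columns")
}

#' Read rod-length measurements (CSV)
#'
#' @param path CSV with columns `condition` and `length_nm`.
#' @return Tibble.
#' @export
read_rod_lengths <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("condition", "length_nm"), names(df))
  if (length(miss)) {
    abort(paste("rod-length table is missing column(s):",
                paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(df$length_nm) | df$length_nm <= 0)) {
    abort("rod lengths must be positive and finite")
  }
  df
}

#' Read a protein sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return A single character string (uppercase, gaps removed).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  fa <- bio3d::read.fasta(path)
  toupper(paste(fa$ali[1, fa$ali[1, ] != "-"], collapse = ""))
}

#' Write / read coordinate models as PDB
#'
#' Thin adapters between the package's atom tibbles and PDB ATOM records.
#'
#' @param model A [coord_model()].
#' @param path File path.
#' @return `write_model_pdb()` returns `path` invisibly; `read_model_pdb()`
#'   returns a [coord_model()] tibble with any `REMARK I_SC` score attached
#'   as the `i_sc` attribute.
#' @export
write_model_pdb <- function(model, path) {
  model <- coord_model(model)
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$resno, chain = model$chain,
                   resid = unname(AA_1TO3[model$aa]),
                   elety = model$elety,
                   eleno = seq_len(nrow(model)))
  i_sc <- attr(model, "i_sc")
  if (!is.null(i_sc)) {
    lines <- readLines(path)
    writeLines(c(sprintf("REMARK I_SC %.3f", i_sc), lines), path)
  }
  invisible(path)
}

#' @rdname write_model_pdb
#' @export
read_model_pdb <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  model <- coord_model(tibble(
    chain = at$chain, resno = at$resno,
    aa = unname(AA_3TO1[at$resid]),
    elety = at$elety, x = at$x, y = at$y, z = at$z
  ))
  header <- grep("^REMARK I_SC", readLines(path), value = TRUE)
  if (length(header)) {
    attr(model, "i_sc") <- as.numeric(sub("^REMARK I_SC\\s+", "", header[1]))
  }
  model
}

#' Read a sidecar interface-score table
#'
#' Docking interface scores (I_sc) are produced externally and imported as
#' model metadata; this reads the TSV sidecar (`model`, `i_sc`).
#'
#' @param path TSV file path.
#' @return Tibble with `model`, `i_sc`.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("model", "i_sc"), names(df))
  if (length(miss)) {
    abort(paste("score table is missing column(s):",
                paste(miss, collapse = ", ")))
  }
  df
}

#' Write a cross-link frequency / classification report (TSV)
#'
#' @param freqs Frequency or classification tibble.
#' @param path Output path.
#' @param comment Optional header lines written as `# `-prefixed comments
#'   (thresholds, seeds, versions).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freqs, path, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(as_tibble(freqs), path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(as_tibble(freqs), path)
  }
  invisible(path)
}
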