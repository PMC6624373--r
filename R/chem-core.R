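#' EDC cross-linking compatibility of a residue pair
#'
#' EDC is a zero-length cross-linker: it condenses a side-chain carboxyl
#' group (Asp/Glu) with a primary amine (Lys, or the protein N-terminal
#' methionine amine) or a side-chain hydroxyl (Ser/Thr/Tyr). A residue pair
#' can therefore only cross-link if exactly one partner carries the carboxyl
#' and the other the amine/hydroxyl.
#'
#' @param aa_a,aa_b One-letter amino-acid codes (vectorized).
#' @param pos_a,pos_b 1-based residue positions on the mature protein
#'   sequence. Only used to recognise the N-terminal methionine (position 1),
#'   whose alpha-amine is cross-linkable.
#' @return Logical vector, `TRUE` where the pair is EDC-compatible.
#'   Symmetric in its arguments.
#' @examples
#' edc_compatible("E", "K")               # TRUE
#' edc_compatible("K", "K")               # FALSE
#' edc_compatible("M", "E", pos_a = 1)    # TRUE: N-terminal amine
#' edc_compatible("M", "E", pos_a = 5)    # FALSE
#' @export
edc_compatible <- function(aa_a, aa_b, pos_a = NA_integer_, pos_b = NA_integer_) {
  aa_a <- check_aa(aa_a, "aa_a")
  aa_b <- check_aa(aa_b, "aa_b")
  acid  <- c("D", "E")
  nucleo <- c("K", "S", "T", "Y")
  is_nuc_a <- aa_a %in% nucleo | (aa_a == "M" & !is.na(pos_a) & pos_a == 1L)
  is_nuc_b <- aa_b %in% nucleo | (aa_b == "M" & !is.na(pos_b) & pos_b == 1L)
  (aa_a %in% acid & is_nuc_b) | (aa_b %in% acid & is_nuc_a)
}

#' Canonical residue-pair identifiers for cross-links
#'
#' Orders each cross-linked residue pair so that the smaller position comes
#' first (ties broken by amino-acid code), making "unique cross-linked
#' residue pair" counts well defined, and builds the conventional
#' `"E65-K97"` style identifier.
#'
#' @param xl A data frame with columns `pos_a`, `aa_a`, `pos_b`, `aa_b`
#'   (and optionally `protein_a`, `protein_b`; any other columns pass
#'   through).
#' @return A tibble with the pair columns canonically ordered and a
#'   `crosslink` identifier column. Calling it twice is a no-op.
#' @examples
#' canonical_crosslinks(tibble::tibble(pos_a = 97, aa_a = "K",
#'                                     pos_b = 65, aa_b = "E"))
#' @export
canonical_crosslinks <- function(xl) {
  xl <- as_tibble(xl)
  stopifnot(all(c("pos_a", "aa_a", "pos_b", "aa_b") %in% names(xl)))
  swap <- xl$pos_b < xl$pos_a |
    (xl$pos_b == xl$pos_a & xl$aa_b < xl$aa_a)
  swap[is.na(swap)] <- FALSE
  swap_cols <- function(a, b) {
    tmp <- xl[[a]]
    xl[[a]][swap] <<- xl[[b]][swap]
    xl[[b]][swap] <<- tmp[swap]
  }
  swap_cols("pos_a", "pos_b")
  swap_cols("aa_a", "aa_b")
  if (all(c("protein_a", "protein_b") %in% names(xl))) {
    swap_cols("protein_a", "protein_b")
  }
  xl$crosslink <- crosslink_id(xl$pos_a, xl$aa_a, xl$pos_b, xl$aa_b)
  xl
}

#' @rdname canonical_crosslinks
#' @param pos_a,aa_a,pos_b,aa_b Pair fields (vectorized); assumed already in
#'   canonical order when called directly.
#' @export
crosslink_id <- function(pos_a, aa_a, pos_b, aa_b) {
  paste0(toupper(aa_a), pos_a, "-", toupper(aa_b), pos_b)
}

#' Count SILAC-labelled residues in a peptide
#'
#' Heavy SILAC labelling shifts every lysine and arginine in a peptide, so
#' the mass offset of a heavy peptide is `n_lys * K-shift + n_arg * R-shift`.
#'
#' @param sequence Character vector of peptide sequences.
#' @return A tibble with columns `sequence`, `n_lys`, `n_arg`.
#' @export
count_label_sites <- function(sequence) {
  tibble(
    sequence = sequence,
    n_lys = stringr::str_count(toupper(sequence), "K"),
    n_arg = stringr::str_count(toupper(sequence), "R")
  )
}

#' Monoisotopic peptide mass
#'
#' @param sequence Character vector of peptide sequences.
#' @return Numeric vector of neutral monoisotopic masses in Da (residue
#'   masses plus one water).
#' @export
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- check_aa(strsplit(toupper(s), "")[[1]], "sequence")
    sum(AA_MONO[aa]) + MASS_H2O
  }, numeric(1), USE.NAMES = FALSE)
}

#' SILAC label scheme
#'
#' Mass shifts of the heavy amino acids. Defaults are the standard
#' 13C6 15N2-lysine (K8) and 13C6 15N4-arginine (R10) shifts.
#'
#' @param heavy_lys,heavy_arg Heavy-label mass shifts in Da (> 0).
#' @return A list of class `label_scheme`.
#' @export
label_scheme <- function(heavy_lys = 8.014199, heavy_arg = 10.008269) {
  stopifnot(heavy_lys > 0, heavy_arg > 0)
  structure(list(heavy_lys = heavy_lys, heavy_arg = heavy_arg),
            class = "label_scheme")
}

#' Precursor m/z of a cross-linked peptide pair cluster
#'
#' Computes the m/z of one of the four SILAC label-combination precursor
#' clusters (LL, HL, LH, HH) of an EDC cross-linked peptide pair. The EDC
#' condensation forms an amide/ester bond with loss of one water, so the
#' cross-linked mass is `mass(pep_a) + mass(pep_b) - H2O`. Heavy shifts are
#' applied per K/R count of each heavy peptide ("H" in first position means
#' peptide a is heavy).
#'
#' @param seq_a,seq_b Peptide sequences.
#' @param charge Precursor charge (>= 1).
#' @param combo One of `"LL"`, `"HL"`, `"LH"`, `"HH"`.
#' @param scheme A [label_scheme()].
#' @return Precursor m/z in Th.
#' @examples
#' cluster_mz("EK", "EK", charge = 1, combo = "LL")
#' @export
cluster_mz <- function(seq_a, seq_b, charge, combo = c("LL", "HL", "LH", "HH"),
                       scheme = label_scheme()) {
  combo <- match.arg(combo)
  if (!is.numeric(charge) || charge < 1) {
    abort("`charge` must be a positive integer (precursors are observed at z >= 1)")
  }
  shift_of <- function(seq) {
    ls <- count_label_sites(seq)
    ls$n_lys * scheme$heavy_lys + ls$n_arg * scheme$heavy_arg
  }
  shift <- switch(combo,
    LL = 0,
    HL = shift_of(seq_a),
    LH = shift_of(seq_b),
    HH = shift_of(seq_a) + shift_of(seq_b)
  )
  m <- peptide_mass(seq_a) + peptide_mass(seq_b) - MASS_H2O + shift
  (m + charge * MASS_PROTON) / charge
}
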