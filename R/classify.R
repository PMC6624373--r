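#' Classify cross-links from their frequency triples
#'
#' Applies the threshold rules used to interpret the frequency triples:
#' a cross-link with `f_interdimeric >= 0.8` is mostly inter-dimeric; among
#' the rest, the within-dimer ratio
#' `R = f_interchain / (f_intrachain + f_interchain)` assigns `intra_chain`
#' (`R < 0.2`), `inter_chain` (`R >= 0.8`) or `both_ways` (in between).
#' A degenerate `R` (zero denominator) is treated as intra-chain with
#' `R = 0`.
#'
#' @param freqs Data frame with columns `f_interdimeric`, `f_interchain`,
#'   `f_intrachain` (e.g. a [quantify_crosslinks()] result).
#' @param f_interdimeric_min,r_low,r_high Classification thresholds
#'   (defaults 0.8, 0.2, 0.8).
#' @return The input tibble with `r_value` and `category` columns
#'   (`category` is a factor with levels `inter_dimeric`, `intra_chain`,
#'   `inter_chain`, `both_ways`).
#' @export
classify_crosslinks <- function(freqs, f_interdimeric_min = 0.8,
                                r_low = 0.2, r_high = 0.8) {
  freqs <- as_tibble(freqs)
  stopifnot(all(c("f_interdimeric", "f_interchain", "f_intrachain") %in%
                  names(freqs)))
  denom <- freqs$f_interchain + freqs$f_intrachain
  r <- ifelse(denom > 0, freqs$f_interchain / denom, 0)
  category <- dplyr::case_when(
    is.na(freqs$f_interdimeric) ~ NA_character_,
    freqs$f_interdimeric >= f_interdimeric_min ~ "inter_dimeric",
    is.na(r) ~ NA_character_,
    r < r_low ~ "intra_chain",
    r >= r_high ~ "inter_chain",
    TRUE ~ "both_ways"
  )
  freqs$r_value <- ifelse(category %in% "inter_dimeric", NA_real_, r)
  freqs$category <- factor(category, levels = c("inter_dimeric", "intra_chain",
                                                "inter_chain", "both_ways"))
  freqs
}

#' Ternary (triangle-plot) coordinates of frequency triples
#'
#' Barycentric mapping of the `(inter-dimeric, inter-chain, intra-chain)`
#' simplex onto an equilateral triangle with unit sides: the inter-dimeric
#' vertex at the top `(0.5, sqrt(3)/2)`, intra-chain at the bottom-left
#' `(0, 0)` and inter-chain at the bottom-right `(1, 0)`.
#'
#' @param freqs Data frame with the three frequency columns; each row must
#'   sum to 1 (within `tol`).
#' @param tol Normalisation tolerance (default `1e-6`).
#' @return The input tibble with `tern_x` and `tern_y` columns.
#' @export
ternary_coordinates <- function(freqs, tol = 1e-6) {
  freqs <- as_tibble(freqs)
  cols <- c("f_interdimeric", "f_interchain", "f_intrachain")
  stopifnot(all(cols %in% names(freqs)))
  s <- freqs$f_interdimeric + freqs$f_interchain + freqs$f_intrachain
  if (any(abs(s - 1) > tol, na.rm = TRUE)) {
    abort("frequency triples must sum to 1 for ternary coordinates")
  }
  freqs$tern_x <- freqs$f_interchain * 1 + freqs$f_interdimeric * 0.5
  freqs$tern_y <- freqs$f_interdimeric * sqrt(3) / 2
  freqs
}

#' Triangle plot of classified cross-links
#'
#' @param object A classified frequency table (output of
#'   [classify_crosslinks()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ternary <- function(object, ...) {
  df <- ternary_coordinates(object)
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tern_x, y = .data$tern_y)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if ("category" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$category),
                                 alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::annotate("text", x = 0.5, y = sqrt(3) / 2 + 0.05,
                      label = "inter-dimeric") +
    ggplot2::annotate("text", x = -0.02, y = -0.05, label = "intra-chain",
                      hjust = 0) +
    ggplot2::annotate("text", x = 1.02, y = -0.05, label = "inter-chain",
                      hjust = 1)
}

#' @export
autoplot.xl_quant <- function(object, ...) {
  plot_ternary(classify_crosslinks(tidy(object)), ...)
}

#' Inter-molecularity forced by overlapping peptides
#'
#' A cross-link between two peptides whose sequence spans overlap on the
#' same protein cannot come from a single chain — one chain cannot supply
#' two copies of the same residue stretch — so it is unambiguously
#' inter-molecular.
#'
#' @param start_a,end_a,start_b,end_b 1-based inclusive peptide span bounds
#'   (vectorized).
#' @param protein_a,protein_b Optional protein identifiers; pairs on
#'   different proteins return `NA` (the rule does not apply).
#' @return Logical vector: `TRUE` where inter-molecularity is forced.
#' @export
overlap_implies_intermolecular <- function(start_a, end_a, start_b, end_b,
                                           protein_a = NULL, protein_b = NULL) {
  overlap <- start_a <= end_b & start_b <= end_a
  if (!is.null(protein_a) && !is.null(protein_b)) {
    overlap[protein_a != protein_b] <- NA
  }
  overlap
}

#' Count inter-dimeric cross-links in a single-experiment table
#'
#' For material analysed only in the homo-iso-dimer mix (the tetramer band),
#' only `f_interdimeric` is measurable. Two counting conventions are
#' provided: cross-links at or above the inter-dimeric threshold
#' (`"threshold"`), or any with non-zero inter-dimeric frequency
#' (`"nonzero"`).
#'
#' @param freqs Data frame with an `f_interdimeric` column.
#' @param mode `"threshold"` (default) or `"nonzero"`.
#' @param f_interdimeric_min Threshold used in `"threshold"` mode.
#' @return Integer count.
#' @export
count_interdimeric <- function(freqs, mode = c("threshold", "nonzero"),
                               f_interdimeric_min = 0.8) {
  mode <- match.arg(mode)
  f <- freqs$f_interdimeric
  f <- f[!is.na(f)]
  if (mode == "threshold") sum(f >= f_interdimeric_min) else sum(f > 0)
}
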