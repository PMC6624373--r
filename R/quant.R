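#' Filter cross-link spectrum matches
#'
#' Discards spectra of peptide pairs with incomplete SILAC labelling and
#' spectra with match score below the threshold (score equal to the
#' threshold is kept). A rejection log is attached as the `"rejections"`
#' attribute.
#'
#' @param matches Data frame of spectrum matches with at least
#'   `spectrum_id`, `match_score` and `labelling_complete` columns.
#' @param score_min Minimum match score kept (default 8).
#' @return Tibble of kept matches; `attr(, "rejections")` is a tibble of
#'   `spectrum_id`, `reason`.
#' @export
filter_matches <- function(matches, score_min = 8) {
  matches <- as_tibble(matches)
  stopifnot(all(c("spectrum_id", "match_score", "labelling_complete") %in%
                  names(matches)))
  reason <- dplyr::case_when(
    !matches$labelling_complete ~ "incomplete_silac_labelling",
    matches$match_score < score_min ~ "match_score_below_threshold",
    TRUE ~ NA_character_
  )
  kept <- matches[is.na(reason), , drop = FALSE]
  attr(kept, "rejections") <- tibble(
    spectrum_id = matches$spectrum_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept
}

#' Per-spectrum mixed-label ratio
#'
#' The 4-ion comparative ratio (HL + LH) / (LL + HL + LH + HH) of the four
#' precursor isotope-cluster areas of one spectrum.
#'
#' @param intensities Data frame with columns `area_LL`, `area_HL`,
#'   `area_LH`, `area_HH` (already summed over mono/+1/+2 isotope peaks;
#'   see [sum_isotope_peaks()] for long-format input).
#' @return The input tibble with a `ratio` column in `[0, 1]`.
#' @export
spectrum_mixed_ratio <- function(intensities) {
  intensities <- as_tibble(intensities)
  cols <- c("area_LL", "area_HL", "area_LH", "area_HH")
  stopifnot(all(cols %in% names(intensities)))
  a <- as.matrix(intensities[cols])
  if (any(a < 0, na.rm = TRUE)) abort("cluster areas must be non-negative")
  total <- rowSums(a)
  if (any(total <= 0)) {
    bad <- intensities$spectrum_id[total <= 0] %||% which(total <= 0)
    abort(paste0("unquantifiable spectra (all four cluster areas zero): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  intensities$ratio <- (a[, "area_HL"] + a[, "area_LH"]) / total
  intensities
}

#' Collapse per-isotope-peak rows into per-cluster areas
#'
#' Long-format intensity tables carry one row per isotope peak (mono, +1,
#' +2) per label combination; the quantification uses their sum per cluster
#' (mean-intensity mode is available for data quantified as average peak
#' intensities rather than XiC areas).
#'
#' @param long Data frame with columns `spectrum_id`, `combo` (LL/HL/LH/HH),
#'   `area` and optionally `isotope_peak`.
#' @param mode `"sum"` (default) or `"mean"` across isotope peaks.
#' @return Wide tibble with one row per spectrum and `area_LL` ... columns.
#' @export
sum_isotope_peaks <- function(long, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  long <- as_tibble(long)
  stopifnot(all(c("spectrum_id", "combo", "area") %in% names(long)))
  agg <- if (mode == "sum") sum else mean
  long |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      setdiff(names(long), c("area", "isotope_peak", "combo")))), .data$combo) |>
    dplyr::summarise(area = agg(.data$area), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "combo", values_from = "area",
                       names_prefix = "area_", values_fill = 0)
}

#' Median mixed-label ratio of the spectra supporting one cross-link
#'
#' @param ratios Numeric vector of per-spectrum ratios (at least one).
#' @return The median (for an even count, the mean of the central pair).
#' @export
aggregate_median_ratio <- function(ratios) {
  if (length(ratios) == 0) abort("no supporting spectra: cannot aggregate")
  stats::median(ratios)
}

#' Convert a median mixed ratio into an occurrence frequency
#'
#' A cross-link occurring purely in its mixed-capable context does not show
#' a mixed ratio of 1: in a 1:1 light/heavy mix half of the random pairings
#' are same-label. The observed median ratio is therefore divided by the
#' design's expected mixed fraction for a fully inter-molecular (or fully
#' inter-dimeric) link, and clamped to `[0, 1]`. For both 1:1 designs used
#' here that expected fraction is 0.5, so `F = min(2 * ratio, 1)`.
#'
#' @param median_ratio Median (HL+LH)/(all) ratio in `[0, 1]` (vectorized).
#' @param design A [mixture_design()].
#' @param link_type Context whose expected mixed fraction scales the ratio:
#'   `"inter_dimeric"` (homo-iso-dimer mix experiment) or `"inter_chain"`
#'   (refolded mix experiment, where the frequency read out is
#'   inter-molecular).
#' @return Frequency in `[0, 1]`.
#' @export
ratio_to_frequency <- function(median_ratio, design,
                               link_type = c("inter_dimeric", "inter_chain")) {
  link_type <- match.arg(link_type)
  if (any(median_ratio < 0 | median_ratio > 1, na.rm = TRUE)) {
    abort("`median_ratio` must lie in [0, 1]")
  }
  ef <- expected_mixed_fraction(design, link_type)
  if (ef <= 0) {
    abort("design has zero expected mixed fraction for this link type; frequency undefined")
  }
  pmin(median_ratio / ef, 1)
}

#' Derive the frequency triple from the two measured frequencies
#'
#' Applies the identities `F_interchain = F_intermolecular - F_interdimeric`
#' and `F_intrachain = 1 - F_intermolecular`. Sampling noise can push the
#' subtraction below zero; the inter-chain component is then clamped to 0
#' and the inter-dimeric component reduced to `F_intermolecular` so the
#' triple still sums to 1.
#'
#' @param f_interdimeric,f_intermolecular Frequencies in `[0, 1]`
#'   (vectorized).
#' @return Tibble with columns `f_interdimeric`, `f_interchain`,
#'   `f_intrachain` (rows sum to 1).
#' @export
derive_frequencies <- function(f_interdimeric, f_intermolecular) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(f_interdimeric) || !ok(f_intermolecular)) {
    abort("frequencies must lie in [0, 1]")
  }
  f_id <- pmin(f_interdimeric, f_intermolecular)
  tibble(
    f_interdimeric = f_id,
    f_interchain = pmax(f_intermolecular - f_interdimeric, 0),
    f_intrachain = 1 - f_intermolecular
  )
}

#' Quantify cross-link occurrence frequencies from two SILAC experiments
#'
#' End-to-end 4-ion comparative quantification: filters spectrum matches,
#' computes per-spectrum mixed ratios from cluster intensities, aggregates
#' medians per cross-link and experiment, converts medians into frequencies
#' (inter-dimeric from the homo-iso-dimer mix, inter-molecular from the
#' refolded homo-/hetero-iso-dimer mix), and derives the
#' inter-dimeric/inter-chain/intra-chain triple for cross-links seen in both
#' experiments. Cross-links supported by only one experiment keep `NA` in
#' the underivable components.
#'
#' @param matches Spectrum-match table: `spectrum_id`, `crosslink`,
#'   `experiment` (`"HIDm"`/`"HhIDm"`), `match_score`, `labelling_complete`.
#' @param intensities Cluster-intensity table: `spectrum_id`, `area_LL`,
#'   `area_HL`, `area_LH`, `area_HH`.
#' @param design_hidm,design_hhidm Mixture designs of the two experiments.
#' @param score_min Match-score threshold (default 8).
#' @return An object of class `xl_quant`: a tibble with one row per
#'   cross-link (`crosslink`, `f_interdimeric`, `f_interchain`,
#'   `f_intrachain`, `f_intermolecular`, `n_spectra_hidm`,
#'   `n_spectra_hhidm`), with the filter log and designs in attributes.
#' @export
quantify_crosslinks <- function(matches, intensities,
                                design_hidm = hidm_design(),
                                design_hhidm = hhidm_design(),
                                score_min = 8) {
  matches <- as_tibble(matches)
  stopifnot(all(c("spectrum_id", "crosslink", "experiment") %in% names(matches)))
  kept <- filter_matches(matches, score_min = score_min)
  ratios <- spectrum_mixed_ratio(intensities)[c("spectrum_id", "ratio")]
  quant <- dplyr::inner_join(kept, ratios, by = "spectrum_id")

  med <- quant |>
    dplyr::group_by(.data$crosslink, .data$experiment) |>
    dplyr::summarise(median_ratio = aggregate_median_ratio(.data$ratio),
                     n_spectra = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "experiment",
                       values_from = c("median_ratio", "n_spectra"))
  for (col in c("median_ratio_HIDm", "median_ratio_HhIDm",
                "n_spectra_HIDm", "n_spectra_HhIDm")) {
    if (!col %in% names(med)) med[[col]] <- NA_real_
  }

  f_id <- ratio_to_frequency(dplyr::coalesce(med$median_ratio_HIDm, NA_real_),
                             design_hidm, "inter_dimeric")
  f_im <- ratio_to_frequency(dplyr::coalesce(med$median_ratio_HhIDm, NA_real_),
                             design_hhidm, "inter_chain")
  both <- !is.na(f_id) & !is.na(f_im)
  trip <- tibble(f_interdimeric = f_id, f_interchain = NA_real_,
                 f_intrachain = NA_real_)
  trip[both, ] <- derive_frequencies(f_id[both], f_im[both])

  out <- tibble(
    crosslink = med$crosslink,
    f_interdimeric = trip$f_interdimeric,
    f_interchain = trip$f_interchain,
    f_intrachain = trip$f_intrachain,
    f_intermolecular = f_im,
    n_spectra_hidm = as.integer(dplyr::coalesce(med$n_spectra_HIDm, 0)),
    n_spectra_hhidm = as.integer(dplyr::coalesce(med$n_spectra_HhIDm, 0))
  )
  structure(out,
            class = c("xl_quant", class(out)),
            rejections = attr(kept, "rejections"),
            score_min = score_min,
            designs = list(HIDm = design_hidm, HhIDm = design_hhidm))
}

#' @export
tidy.xl_quant <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "xl_quant")
  attr(out, "rejections") <- NULL
  attr(out, "score_min") <- NULL
  attr(out, "designs") <- NULL
  out
}

#' @export
glance.xl_quant <- function(x, ...) {
  tibble(
    n_crosslinks = nrow(x),
    n_both_experiments = sum(x$n_spectra_hidm > 0 & x$n_spectra_hhidm > 0),
    n_spectra = sum(x$n_spectra_hidm) + sum(x$n_spectra_hhidm),
    n_rejected_spectra = nrow(attr(x, "rejections")),
    score_min = attr(x, "score_min")
  )
}

#' Spectrum support shared between experiments
#'
#' Summarises how many filtered spectra support cross-links identified in
#' both experiments, versus the filtered total — the reproducibility measure
#' for abundant cross-links.
#'
#' @param matches Filtered spectrum-match table (`crosslink`, `experiment`).
#' @return A one-row tibble: `n_shared_crosslinks`, `n_spectra_shared`,
#'   `n_spectra_total`, `pct_shared`.
#' @export
crosslink_overlap_summary <- function(matches) {
  matches <- as_tibble(matches)
  sets <- split(matches$crosslink, matches$experiment)
  shared <- Reduce(intersect, sets)
  tibble(
    n_shared_crosslinks = length(shared),
    n_spectra_shared = sum(matches$crosslink %in% shared),
    n_spectra_total = nrow(matches),
    pct_shared = 100 * sum(matches$crosslink %in% shared) / nrow(matches)
  )
}
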