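#' Dimer mixture designs
#'
#' Describes the composition of an isotope-mixing experiment: the proportions
#' of light homo-dimers, heavy homo-dimers and light/heavy hetero-dimers in
#' solution, plus the overall light-chain fraction used for random
#' inter-dimer pairing.
#'
#' Two designs cover the study conditions:
#' * `hidm_design()` — homo-iso-dimer mix: light and heavy homodimers mixed
#'   1:1. Dimers do not exchange chains, so there are no hetero-dimers.
#' * `hhidm_design()` — homo-/hetero-iso-dimer mix: a 1:1 monomer mix
#'   refolded into dimers, giving 25% light-light, 25% heavy-heavy and 50%
#'   light-heavy dimers.
#'
#' @param p_light_homo,p_heavy_homo,p_hetero Dimer-class proportions
#'   (non-negative, summing to 1).
#' @param chain_light_fraction Fraction of light chains in the whole
#'   population (used for random inter-dimer pairing).
#' @return A list of class `mixture_design`.
#' @export
mixture_design <- function(p_light_homo, p_heavy_homo, p_hetero,
                           chain_light_fraction = p_light_homo + p_hetero / 2) {
  p <- c(p_light_homo, p_heavy_homo, p_hetero)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("dimer-class proportions must be non-negative and sum to 1")
  }
  stopifnot(chain_light_fraction >= 0, chain_light_fraction <= 1)
  structure(
    list(p_light_homo = p_light_homo, p_heavy_homo = p_heavy_homo,
         p_hetero = p_hetero, chain_light_fraction = chain_light_fraction),
    class = "mixture_design"
  )
}

#' @rdname mixture_design
#' @export
hidm_design <- function() mixture_design(0.5, 0.5, 0)

#' @rdname mixture_design
#' @export
hhidm_design <- function() mixture_design(0.25, 0.25, 0.5)

#' Expected mixed-label fraction of a cross-link under a mixture design
#'
#' The expected (HL+LH)/(LL+HL+LH+HH) intensity fraction for a cross-link
#' that occurs purely in one structural context, assuming random assembly:
#' * `intra_chain`: both peptides come from one chain, never mixed — 0.
#' * `inter_chain`: mixed exactly when the dimer is a hetero-dimer —
#'   `p_hetero`.
#' * `inter_dimeric`: the two chains come from two random dimers — with
#'   light-chain fraction `q` the mixed probability is `2 q (1 - q)`.
#'
#' @param design A [mixture_design()].
#' @param link_type `"intra_chain"`, `"inter_chain"` or `"inter_dimeric"`.
#' @return Expected mixed fraction in `[0, 1]`.
#' @examples
#' expected_mixed_fraction(hhidm_design(), "inter_chain")  # 0.5
#' expected_mixed_fraction(hidm_design(), "inter_dimeric") # 0.5
#' @export
expected_mixed_fraction <- function(design,
                                    link_type = c("intra_chain", "inter_chain",
                                                  "inter_dimeric")) {
  stopifnot(inherits(design, "mixture_design"))
  link_type <- match.arg(link_type)
  q <- design$chain_light_fraction
  switch(link_type,
    intra_chain   = 0,
    inter_chain   = design$p_hetero,
    inter_dimeric = 2 * q * (1 - q)
  )
}
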