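---
title: "Quantitative SILAC cross-linking of homo-oligomers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SILAC cross-linking of homo-oligomers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminxl)
library(dplyr)
```

## The disambiguation problem

Cross-linking mass spectrometry of a homo-oligomer is ambiguous by
construction: when both linked peptides come from copies of the *same*
protein, a cross-link between residues X and Y may have formed within one
chain, between the two chains of one dimer, or between two different
dimers. For lamin A — a coiled-coil protein that dimerises and then
assembles head-to-tail and laterally — distinguishing these three origins
is the whole game: intra-chain and inter-chain contacts report on the dimer
fold, inter-dimeric contacts on higher-order assembly.

The package implements the isotope-mixing solution. Lamin is expressed in
light and heavy (13C/15N Lys+Arg, "K8/R10") SILAC forms and combined in two
ways:

* **HIDm** (homo-iso-dimer mix): light and heavy *dimers* are mixed 1:1.
  Dimers do not exchange chains in solution, so any cross-link bridging a
  light and a heavy peptide must connect two different dimers.
* **H/hIDm** (homo-/hetero-iso-dimer mix): the 1:1 mix is monomerised and
  refolded, randomising chain pairing into 25% light-light, 25%
  heavy-heavy and 50% light-heavy dimers. A mixed-label cross-link now
  reports any *inter-molecular* contact (inter-chain or inter-dimeric).

## The 4-ion comparative quantification

Each cross-linked peptide pair appears in MS1 as up to four precursor
clusters — LL, HL, LH, HH — separated by the SILAC mass shifts of the
peptides' K/R content. For every spectrum the mono/+1/+2 isotope-peak XiC
areas of each cluster are summed (a mean-intensity mode is available for
data quantified as average peak heights) and reduced to

$$r = \frac{HL + LH}{LL + HL + LH + HH}.$$

Spectra with incomplete SILAC labelling or a match score below 8.0 are
discarded; a score of exactly 8.0 is kept ("below 8.0" is the discard
rule). Per cross-link and experiment the supporting spectra are aggregated
by the **median** of $r$, which is robust to the occasional mis-assigned
cluster.

A fully mixed-capable cross-link does not reach $r = 1$: in a 1:1 mix, a
random pairing is same-label half the time. The median ratio is therefore
divided by the design's expected mixed fraction for a fully
inter-molecular (or inter-dimeric) link and clamped to $[0,1]$. For both
1:1 designs that expected fraction is 0.5, so $F = \min(2\,r_{med},\,1)$ —
this conversion is the package's explicit design choice; the underlying
combinatorics are exposed in `expected_mixed_fraction()` and verified
against exact enumeration and a Monte-Carlo assembly simulator. From the
two experiments,

$$F^{\mathrm{inter\text{-}chain}} = F^{\mathrm{inter\text{-}molecular}} -
F^{\mathrm{inter\text{-}dimeric}}, \qquad
F^{\mathrm{intra\text{-}chain}} = 1 - F^{\mathrm{inter\text{-}molecular}}.$$

Sampling noise can push the subtraction below zero; the inter-chain
component is clamped at 0 and the inter-dimeric component reduced so the
triple still sums to 1. Cross-links supported in only one experiment keep
`NA` in the underivable components rather than a guessed value.

```{r quant-example}
truth <- crosslink_truth(n_crosslinks = 20, seed = 1)
sim <- simulate_silac_study(truth, n_spectra = 20, noise_cv = 0.06, seed = 2)
q <- quantify_crosslinks(sim$matches, sim$intensities)
glance(q)
classify_crosslinks(tidy(q)) |> count(category)
```

## Classification and the ternary view

With the triple in hand, each cross-link is categorised with the study's
thresholds: `f_interdimeric >= 0.8` is *inter-dimeric*; otherwise the
within-dimer ratio $R = F^{ic}/(F^{ic}+F^{intra})$ assigns *intra-chain*
($R < 0.2$), *inter-chain* ($R \ge 0.8$) or *both ways*. Where the figure
caption and the methods text disagree on boundary inclusion
(≤ vs <), the methods wording wins; all thresholds are arguments.
`ternary_coordinates()` places each triple in an equilateral triangle
(inter-dimeric apex up, intra-chain bottom-left, inter-chain bottom-right
— the orientation is a documented convention, emitted as plain
coordinates so any plotter can reproduce the figure), and
`autoplot()` draws it.

Two special rules: a cross-link between *overlapping* peptide spans is
unconditionally inter-molecular (one chain cannot supply two copies of a
residue stretch); and material analysed in only the HIDm experiment (the
tetramer band) supports only `f_interdimeric`, for which both a
threshold-count and a nonzero-count convention are provided
(`count_interdimeric()`), since the study's operational choice is not
stated.

## Zero-length chemistry

EDC condenses a side-chain carboxyl (D/E) with a primary amine (K, or the
protein N-terminal methionine's alpha-amine) or a hydroxyl (S/T/Y), with
loss of one water. `edc_compatible()` encodes the pairing rule (the
N-terminal amine only at position 1); `cluster_mz()` computes the four
cluster m/z values using the standard monoisotopic residue masses, the
amide-condensation water loss, and the default K8/R10 shifts
(8.014199/10.008269 Da — standard values, configurable via
`label_scheme()`).

## Coordinate-model validation

Cross-links constrain structure only if the model could plausibly have
formed them. Three geometric criteria are implemented:

* **Cβ–Cβ solvent-accessible-surface (SAS) distance ≤ 13 Å** — the rough
  EDC feasibility test. `sas_distance()` computes the shortest path
  between two atoms over a 3-D grid (default 1 Å spacing) that avoids the
  protein volume (van-der-Waals radii by element plus a 1.4 Å probe
  margin), using Dijkstra over first- plus coprime second-shell lattice
  moves; the second shell keeps the lattice metric within ~2% of the true
  geodesic. The obstacle volume is the backbone+Cβ representation; the
  side chains of the two linked residues are never obstacles (they are
  what reaches across), and a small bubble at each endpoint keeps a
  residue from being sealed in by its sequence neighbours. Results are
  clamped from below by the Euclidean distance, are reported as `Inf`
  beyond the 60 Å search horizon (no-path is a value, not an error), and
  are deterministic — no seed enters the computation.
* **Contact distance ≤ 4 Å** — the stringent criterion for residues
  already in electrostatic or hydrogen-bond contact:
  minimum straight-line distance over carboxyl oxygens versus amine
  nitrogen / hydroxyl oxygen (one 4 Å cap for both the O–N and O–O cases,
  as no separate numbers are given).
* **Linker extension caps** — a stagger is only feasible if the linker can
  still bridge its flanking coil ends: SAS distance between backbone
  anchors (e.g. O of residue 66 to N of residue 78 across L1) at most
  46 Å for L1/L2/L3; L12 is long enough for any overlap and is uncapped.

`build_coiled_coil()` supplies the idealized null model: a parallel
two-chain coiled coil from a standard superhelical parameterization
(superhelix radius 4.9 Å, minor radius 2.26 Å, rise 1.485 Å/residue —
exact by construction; heptads at 4π/7 minor phase per residue on a
left-handed 140 Å-pitch supercoil, hendecads at 6π/11 on a straight
bundle). Atoms are N/CA/C/O/CB plus single side-chain tip atoms for
D/E/K/S/T/Y at extended reach — enough for every distance criterion, not a
physical side-chain model. The exact Crick parameters of the study's
models are not published; these defaults are configurable arguments.

## Rod length and tandem-stagger compression

The rod segment map (head, coil 1A, L1, coil 1B, L12, the parallel
hendecad PH, coil 2, tail) is reconstructed from the docking fragment
ranges and the rod schematic; boundaries are arguments because no table of
them is published. At 1.485 Å/residue the coils contribute ≈ 48.3 nm and
the 3.4 nm linker allowance brings the rod to ≈ 51.7 nm, matching the
~48/~51 nm predictions.

A tandem stagger at a linker slides the ends of the two flanking coils
over one another, shortening the rod by the axial overlap. Plain
subtraction of the maximal per-linker shortenings (5 nm at L1, 4 nm at
L12, 5 nm at L3) would predict 50.9 − 14 = 36.9 nm, which contradicts the
reported compressed length of 40–41 nm and the "up to ~10 nm" total. The
package resolves this geometrically: a stagger cannot fold away more of a
coil segment than exists, and adjacent staggers share their common
segment's capacity. L12 and L3 both draw on the ~5.5 nm parallel-hendecad
region, capping their combined shortening; with the default map the three
maximal staggers compress 50.9 nm to ≈ 40.4 nm. Staggers are applied in
N→C rod order; the order only matters when requests exceed a shared
capacity, in which case earlier (more N-terminal) staggers win — a
documented tie-break.

`screen_stagger_decoys()` reproduces the decoy triage: imported docking
interface score ≤ −5.0 (the score is Rosetta metadata read from a sidecar
table or PDB remark, never computed here), at least one cross-link
satisfied, linker cap respected, and fragments parallel or close to
parallel. The parallelism threshold is unstated in the source material;
the default is 45°, configurable. Fragment axes are least-squares first
principal components of the CA trace, oriented N→C; the reported
shortening is the measured axial overlap of the two fragments.

## Rod-length statistics

`length_histogram()` bins measurements in half-open 2 nm bins anchored at
40 nm (the visual binning of the EM histograms); `median_and_range()`
reports the median and the central 90% interval using linear-interpolation
quantiles (the interpolation rule is a documented choice — the source does
not state one). `rod_kruskal()` wraps the tie-corrected Kruskal-Wallis
test; `dunn_holm()` implements Dunn's tie-corrected post-hoc z tests
against a reference condition with Holm step-down adjustment (no installed
package provides Dunn's test, so it is implemented directly and verified
against hand-stepped and permutation oracles). Two-sided p-values are
assumed; the source does not say.

## What the simulators emulate — and what they do not

`simulate_experiment()` generates the generative process the
quantification presumes: each cross-link has a ground-truth occurrence
triple; each spectrum's four cluster areas are the population-expected
label fractions under the mixture design times a log-normal total
intensity, with independent multiplicative log-normal noise per cluster
(default CV 6%, the scale of the disagreement between the two
quantification softwares used in practice; the recovery studies use a
deliberately harsher 20%). A key modelling decision: cluster areas are
*ensemble* quantities (a XiC integrates many molecules co-eluting), so
per-spectrum ratios estimate the population mixed fraction rather than
being single-molecule 0/1 draws — this is exactly the assumption under
which a median of per-spectrum ratios is meaningful. Isotope peaks are
split 0.5/0.35/0.15 (inert by default, since quantification sums them).

The simulators do **not** emulate chromatographic peak shapes,
co-elution interference, missed monoisotopic assignment, charge-state
splitting, or FDR behaviour of the search engine. Passing recovery tests
therefore show the *analysis* is correct and well-calibrated under its own
assumptions, not that the upstream spectral processing of real data is.

The bundled protein sequence is a **synthetic** 646-residue lamin-A-like
stand-in (`synthetic_lamin_sequence()`): a repeating coiled-coil-like
12-mer with tryptic K/R spacing, with every residue position named in the
analysis pinned to its published identity (M1, E31/K32, E55, E65, S66,
E67/E68, K78, K97, S143/E145, D192, S239, D254, Y267, Q276, H289, …). The
real mature sequence is deliberately not embedded; all structural tests
depend only on the pinned positions and the idealized geometry.

## Numerical choices and degenerate inputs

* Score boundary: keep `match_score == 8.0` exactly.
* All-zero intensity spectra are an error (unquantifiable), not a silent 0.
* An empty supporting-spectra set is an error; a single ratio is its own
  median.
* Degenerate within-dimer ratio (both components 0) classifies as
  intra-chain with $R = 0$.
* SAS grids are deterministic; distances are exact for unobstructed pairs
  up to grid resolution, and validated against an independent 0.25 Å-grid
  Dijkstra oracle on random obstacle fields.
* Problem sizes in the test-suite: 233 simulated cross-links at 50
  spectra/experiment for recovery (the study's dimer-band scale), 20
  obstacle fields for the geometry oracle, $10^5$ draws for assembly
  convergence — sizes chosen so the full suite completes in well under a
  minute while keeping Monte-Carlo error far below the assertion margins.

## Known limitations

* The ratio→frequency conversion assumes the mixing design is exactly 1:1
  and assembly is label-blind; systematic deviations in mixing ratio bias
  frequencies multiplicatively.
* The idealized coiled-coil builder is a Cβ-level geometric model; it
  supports distance/angle reasoning, not energetics or packing.
* Rod compression treats staggers as independent axial overlaps with
  capacity sharing; it does not model bending energetics at the stagger
  point beyond the fragment-angle filter.
* Docking scores are imported metadata; no attempt is made to rescore
  models.
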