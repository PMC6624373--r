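find_atoms <- function(model, resno, elety, chain = NULL) {
  sel <- model$resno == resno & model$elety %in% elety
  if (!is.null(chain)) sel <- sel & model$chain %in% chain
  model[sel, , drop = FALSE]
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Solvent-accessible-surface distance between two atoms
#'
#' Shortest path between two atoms over a 3-D grid that avoids the protein
#' volume: grid cells inside any obstructing atom's van-der-Waals sphere
#' plus a solvent-probe margin are blocked, and the path runs over
#' 26-connected moves with Euclidean edge weights (Dijkstra). Side-chain
#' atoms of the two linked residues themselves are not obstacles (the
#' cross-linked side chains are what reaches across). The result is always
#' at least the straight-line distance; `Inf` means no accessible path
#' within `max_dist`.
#'
#' @param model A [coord_model()].
#' @param resno_a,resno_b Residue numbers of the two atoms.
#' @param chain_a,chain_b Chain identifiers (default `"A"`).
#' @param atom_a,atom_b Atom names (default `"CB"`).
#' @param spacing Grid spacing in Angstrom (default 1).
#' @param probe Solvent probe margin added to van-der-Waals radii
#'   (default 1.4 A).
#' @param max_dist Search horizon in Angstrom (default 60, beyond which
#'   `Inf` is returned).
#' @param pad Margin (A) added around the two endpoints' bounding box to
#'   form the search region; `NULL` (default) chooses it from the
#'   straight-line distance.
#' @return Distance in Angstrom, or `Inf` when no path exists.
#' @export
sas_distance <- function(model, resno_a, resno_b, chain_a = "A", chain_b = "A",
                         atom_a = "CB", atom_b = "CB", spacing = 1,
                         probe = 1.4, max_dist = 60, pad = NULL) {
  model <- coord_model(model)
  at_a <- find_atoms(model, resno_a, atom_a, chain_a)
  at_b <- find_atoms(model, resno_b, atom_b, chain_b)
  if (nrow(at_a) == 0 || nrow(at_b) == 0) {
    abort(sprintf("atom %s of residue %s (or %s of %s) absent from model",
                  atom_a, resno_a, atom_b, resno_b))
  }
  p_a <- as.numeric(at_a[1, c("x", "y", "z")])
  p_b <- as.numeric(at_b[1, c("x", "y", "z")])
  d_euc <- euclid(p_a, p_b)
  if (d_euc > max_dist) return(Inf)

  # obstacle volume: the backbone + CB representation of the protein
  # (side-chain tip atoms are reach heuristics for the contact mode, not
  # volume), minus the side chains of the two linked residues themselves
  backbone <- c("N", "CA", "C", "O")
  chain_match <- function(chain) {
    if (is.null(chain)) rep(TRUE, nrow(model)) else model$chain %in% chain
  }
  linked <- (model$resno == resno_a & chain_match(chain_a)) |
    (model$resno == resno_b & chain_match(chain_b))
  is_tip <- model$elety %in% unname(TIP_ATOMS)
  obst <- model[!is_tip & !(linked & !model$elety %in% backbone), ,
                drop = FALSE]

  if (is.null(pad)) pad <- min(max(0.75 * d_euc, 10), 30)
  lo <- pmin(p_a, p_b) - pad
  hi <- pmax(p_a, p_b) + pad
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  radii <- vdw_radius(obst$element) + probe
  keep <- obst$x > lo[1] - radii & obst$x < hi[1] + radii &
    obst$y > lo[2] - radii & obst$y < hi[2] + radii &
    obst$z > lo[3] - radii & obst$z < hi[3] + radii
  obst <- obst[keep, , drop = FALSE]
  radii <- radii[keep]
  blocked <- .grid_block_spheres(dims, lo, spacing, obst$x, obst$y, obst$z,
                                 radii)
  # the reactive groups displace solvent at their own positions: keep a
  # small accessible bubble around each endpoint so it is not sealed in by
  # its sequence neighbours
  bubble <- .grid_block_spheres(dims, lo, spacing,
                                c(p_a[1], p_b[1]), c(p_a[2], p_b[2]),
                                c(p_a[3], p_b[3]),
                                rep(max(2, 1.5 * spacing), 2))
  blocked <- blocked & !bubble

  idx_of <- function(p) {
    ijk <- pmin(pmax(round((p - lo) / spacing), 0), dims - 1L)
    free <- nearest_free(blocked, dims, as.integer(ijk))
    free
  }
  start <- idx_of(p_a)
  goal <- idx_of(p_b)
  if (is.na(start) || is.na(goal)) return(Inf)
  d <- .grid_dijkstra(blocked, dims, start, goal, spacing,
                      max_dist + 4 * spacing)
  if (d < 0) return(Inf)
  d <- max(d, d_euc)  # grid snapping can never beat the straight line
  if (d > max_dist) Inf else d
}

# nearest unblocked grid node to an integer grid position (searches shells
# of increasing radius up to 3 cells); NA if everything nearby is blocked
nearest_free <- function(blocked, dims, ijk) {
  lin <- function(v) v[3] * dims[1] * dims[2] + v[2] * dims[1] + v[1] + 1L
  if (!blocked[lin(ijk)]) return(lin(ijk) - 1L)
  for (r in 1:3) {
    offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
    offs <- offs[order(rowSums(offs^2)), , drop = FALSE]
    for (i in seq_len(nrow(offs))) {
      v <- ijk + offs[i, ]
      if (any(v < 0) || any(v > dims - 1L)) next
      if (!blocked[lin(v)]) return(lin(v) - 1L)
    }
  }
  NA_integer_
}

#' Side-chain contact distance of an EDC cross-linked residue pair
#'
#' Straight-line distance between the reactive atoms of the pair: the
#' carboxyl oxygens (OE1/OE2 for Glu, OD1/OD2 for Asp) versus the amine
#' nitrogen (NZ for Lys) or hydroxyl oxygen (OG/OG1/OH for Ser/Thr/Tyr);
#' the N-terminal methionine contributes its backbone N. The minimum over
#' all available relevant atom pairs is returned. A contact supports
#' zero-length cross-linking when it does not exceed 4 Angstrom.
#'
#' @inheritParams sas_distance
#' @param chain_a,chain_b Chains searched for each residue (default: all
#'   chains in the model; the minimum over chain combinations is taken).
#' @return Minimum contact distance in Angstrom.
#' @export
sidechain_contact_distance <- function(model, resno_a, resno_b,
                                       chain_a = NULL, chain_b = NULL) {
  model <- coord_model(model)
  reactive_atoms <- function(resno, chain) {
    rows <- model[model$resno == resno, , drop = FALSE]
    if (!is.null(chain)) rows <- rows[rows$chain %in% chain, , drop = FALSE]
    if (nrow(rows) == 0) abort(sprintf("residue %s absent from model", resno))
    aa <- rows$aa[1]
    names <- switch(aa,
      E = c("OE1", "OE2"), D = c("OD1", "OD2"), K = "NZ",
      S = "OG", T = "OG1", Y = "OH",
      M = if (resno == 1) "N" else
        abort("methionine amine is only cross-linkable at the N-terminus"),
      abort(sprintf("residue %s%s has no EDC-reactive side chain", aa, resno))
    )
    out <- rows[rows$elety %in% names, , drop = FALSE]
    if (nrow(out) == 0) {
      abort(sprintf("model is missing the reactive atom(s) %s of residue %s%s",
                    paste(names, collapse = "/"), aa, resno))
    }
    out
  }
  a <- reactive_atoms(resno_a, chain_a)
  b <- reactive_atoms(resno_b, chain_b)
  d2 <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    (a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2
  })
  sqrt(min(d2))
}

#' Is a cross-link satisfied by a coordinate model?
#'
#' Two validation modes: `"sas13"` — the CB-CB solvent-accessible-surface
#' distance does not exceed `sas_cap` (13 A, the rough EDC feasibility
#' criterion); `"contact4"` — the reactive side-chain atoms are within
#' `contact_cap` (4 A, the close-range electrostatic/hydrogen-bond
#' criterion).
#'
#' @inheritParams sas_distance
#' @param mode `"sas13"` or `"contact4"`.
#' @param sas_cap,contact_cap Caps in Angstrom (defaults 13 and 4).
#' @param ... Passed to [sas_distance()].
#' @return Logical.
#' @export
crosslink_satisfied <- function(model, resno_a, resno_b,
                                mode = c("sas13", "contact4"),
                                chain_a = "A", chain_b = "A",
                                sas_cap = 13, contact_cap = 4, ...) {
  mode <- match.arg(mode)
  if (mode == "sas13") {
    d <- sas_distance(model, resno_a, resno_b, chain_a, chain_b, ...)
    is.finite(d) && d <= sas_cap
  } else {
    d <- sidechain_contact_distance(model, resno_a, resno_b, chain_a, chain_b)
    d <= contact_cap
  }
}

#' Check a linker's maximal-extension constraint
#'
#' A tandem stagger is only feasible if the linker can still bridge its
#' flanking coil ends: the solvent-accessible-surface distance between the
#' linker's anchor atoms (e.g. the backbone O preceding and backbone N
#' following linker L1) must not exceed the linker's cap (46 A for
#' L1/L2/L3; L12 is uncapped).
#'
#' @param model A [coord_model()].
#' @param linker Linker name (must exist in the map's caps).
#' @param map Segment map carrying `linker_caps` and `linker_anchors`
#'   attributes (default [lamin_segment_map()]).
#' @param chain Chain on which anchors are looked up (default `NULL`: any
#'   chain — stagger fixtures place the two anchors on different chains).
#' @param ... Passed to [sas_distance()].
#' @return Logical.
#' @export
linker_extension_ok <- function(model, linker, map = lamin_segment_map(),
                                chain = NULL, ...) {
  caps <- attr(map, "linker_caps")
  anchors <- attr(map, "linker_anchors")
  if (!linker %in% names(caps)) {
    abort(sprintf("unknown linker '%s' (known: %s)", linker,
                  paste(names(caps), collapse = ", ")))
  }
  cap <- caps[[linker]]
  if (!is.finite(cap)) return(TRUE)
  an <- anchors[[linker]]
  d <- sas_distance(model, an$a$resno, an$b$resno, chain, chain,
                    atom_a = an$a$elety, atom_b = an$b$elety,
                    max_dist = cap + 20, ...)
  is.finite(d) && d <= cap
}

#' Angle between the helical axes of two fragments
#'
#' Fits each fragment's axis as the first principal component of its CA
#' coordinates (oriented from the fragment's first to last residue) and
#' returns the angle between the two axes.
#'
#' @param model A [coord_model()].
#' @param range_a,range_b Residue-number ranges (integer vectors; their
#'   range is used) of the two fragments; each needs >= 7 residues.
#' @param chain Optional chain filter for the axis fit (default `NULL`:
#'   all chains; both chains of a parallel dimer share the fragment axis).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
helix_pair_angle <- function(model, range_a, range_b, chain = NULL) {
  model <- coord_model(model)
  axis_of <- function(rng) {
    ca <- model[model$elety == "CA" &
                  (if (is.null(chain)) TRUE else model$chain == chain) &
                  model$resno >= min(rng) & model$resno <= max(rng), ,
                drop = FALSE]
    ca <- ca[order(ca$resno), , drop = FALSE]
    if (length(unique(ca$resno)) < 7) {
      abort("fragment too short for a stable axis fit (need >= 7 residues)")
    }
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    ax <- prcomp(xyz, center = TRUE)$rotation[, 1]
    if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax
    ax
  }
  a <- axis_of(range_a)
  b <- axis_of(range_b)
  acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
}
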