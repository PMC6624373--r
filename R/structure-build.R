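# Minimal side-chain tip atoms used for contact-distance checks, with
# approximate extended CA-to-tip lengths (A).
TIP_ATOMS <- c(E = "OE1", D = "OD1", K = "NZ", S = "OG", T = "OG1", Y = "OH")
TIP_LENGTHS <- c(E = 5.0, D = 3.7, K = 6.4, S = 2.4, T = 2.4, Y = 6.5)

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_1TO3 <- setNames(names(AA_3TO1), AA_3TO1)

element_of <- function(elety) substr(gsub("^[0-9]", "", elety), 1, 1)

#' Validate / coerce an atomic coordinate model
#'
#' Coordinate models are plain tibbles with one row per atom: `chain`,
#' `resno` (1-based residue number), `aa` (one-letter code), `elety` (PDB
#' atom name, e.g. `CA`, `CB`, `NZ`), `element`, `x`, `y`, `z` in Angstrom.
#'
#' @param atoms Data frame with the columns above (`element` is derived
#'   from `elety` if absent).
#' @return A validated tibble.
#' @export
coord_model <- function(atoms) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "aa", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste("coordinate model lacks columns:",
                                paste(miss, collapse = ", ")))
  if (!"element" %in% names(atoms)) atoms$element <- element_of(atoms$elety)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("coordinate model contains non-finite coordinates")
  }
  atoms
}

#' Default rod segment map of mature lamin A
#'
#' Heptad/hendecad/linker annotation of the lamin A rod on mature-protein
#' numbering: head, coil 1A, linker L1 (alpha-helical), coil 1B, unstructured
#' linker L12, the parallel-hendecad (PH) region opening coil 2, the rest of
#' coil 2, and the tail. Boundaries are configurable — they are a modelling
#' choice, not a measured quantity.
#'
#' Attributes carry the linker machinery: `linker_caps` (maximal
#' solvent-accessible-surface extension per linker, Angstrom; `L12` is
#' uncapped because it can accommodate any overlap and exceeds the 60 A
#' SAS-computation horizon), `linker_anchors` (backbone anchor atoms of each
#' cap) and `stagger_flanks` (which coil segments a tandem stagger at each
#' linker slides over, used to bound rod compression).
#'
#' @return A tibble with columns `name`, `start`, `end`, `kind`.
#' @export
lamin_segment_map <- function() {
  map <- tibble(
    name  = c("head", "coil1A", "L1", "coil1B", "L12", "PH", "coil2", "tail"),
    start = c(1L, 30L, 67L, 78L, 219L, 240L, 277L, 387L),
    end   = c(29L, 66L, 77L, 218L, 239L, 276L, 386L, 646L),
    kind  = c("unstructured", "heptad_coil", "linker", "heptad_coil",
              "linker", "hendecad_coil", "heptad_coil", "unstructured")
  )
  attr(map, "linker_caps") <- c(L1 = 46, L12 = Inf, L2 = 46, L3 = 46)
  attr(map, "linker_anchors") <- list(
    L1  = list(a = list(resno = 66L, elety = "O"), b = list(resno = 78L, elety = "N")),
    L12 = list(a = list(resno = 218L, elety = "O"), b = list(resno = 240L, elety = "N")),
    L2  = list(a = list(resno = 254L, elety = "O"), b = list(resno = 267L, elety = "N")),
    L3  = list(a = list(resno = 276L, elety = "O"), b = list(resno = 289L, elety = "N"))
  )
  attr(map, "stagger_flanks") <- list(
    L1  = c("coil1A", "coil1B"),
    L12 = c("coil1B", "PH"),
    L2  = c("PH", "PH"),
    L3  = c("PH", "coil2")
  )
  map
}

#' Predicted rod length from a segment map
#'
#' Sums the axial extent of the coiled-coil segments (residue count times
#' rise per residue) and adds a fixed total linker contribution. For the
#' default lamin A map this gives a coil-only contribution of about 48 nm
#' and a total of about 51 nm.
#'
#' @param map Segment map tibble (see [lamin_segment_map()]).
#' @param rise_per_res Axial rise per residue in Angstrom (default 1.485).
#' @param linker_total_nm Total linker contribution in nm (default 3.4).
#' @return One-row tibble: `coil_nm`, `linker_nm`, `total_nm`.
#' @export
predicted_rod_length <- function(map, rise_per_res = 1.485,
                                 linker_total_nm = 3.4) {
  coil <- map[map$kind %in% c("heptad_coil", "hendecad_coil"), , drop = FALSE]
  nres <- sum(coil$end - coil$start + 1L)
  coil_nm <- nres * rise_per_res / 10
  tibble(coil_nm = coil_nm, linker_nm = linker_total_nm,
         total_nm = coil_nm + linker_total_nm)
}

#' Build an idealized parallel coiled-coil dimer
#'
#' Generates a two-chain parallel coiled coil from a standard superhelical
#' parameterization: the minor (alpha) helix of each chain winds around a
#' superhelical path of radius `radius0`, with exact axial rise
#' `rise_per_res` per residue along the z axis. Heptads use a minor-helix
#' phase of 4*pi/7 per residue (two turns per 7 residues) on a left-handed
#' supercoil; hendecads use 6*pi/11 (three turns per 11 residues) on a
#' straight (near-parallel bundle) path. Atoms built per residue: N, CA, C,
#' O, CB, plus the side-chain tip atom for D/E/K/S/T/Y (see
#' [sidechain_contact_distance()]). Chain B is chain A rotated 180 degrees
#' about the superhelix axis.
#'
#' @param sequence Amino-acid sequence of the window (length >= 7).
#' @param start_resno Residue number of the first residue (1-based).
#' @param register `"heptad"` or `"hendecad"`.
#' @param rise_per_res Axial rise per residue (A); axial length is exactly
#'   `(n - 1) * rise_per_res`.
#' @param radius0 Superhelix radius (A, default 4.9).
#' @param radius1 Minor helix radius (A, default 2.26).
#' @param pitch Superhelix pitch (A, default 140; ignored for hendecads).
#' @param chains Chain identifiers (default A and B).
#' @return A [coord_model()] tibble.
#' @export
build_coiled_coil <- function(sequence, start_resno = 1L,
                              register = c("heptad", "hendecad"),
                              rise_per_res = 1.485, radius0 = 4.9,
                              radius1 = 2.26, pitch = 140,
                              chains = c("A", "B")) {
  register <- match.arg(register)
  aa <- check_aa(strsplit(toupper(sequence), "")[[1]], "sequence")
  n <- length(aa)
  if (n < 7) abort("coiled-coil window must span at least one repeat (7 residues)")
  omega1 <- if (register == "heptad") 4 * pi / 7 else 6 * pi / 11
  omega0 <- if (register == "heptad") -2 * pi * rise_per_res / pitch else 0

  build_chain <- function(phase0, chain_id) {
    t <- seq_len(n) - 1
    phi0 <- phase0 + omega0 * t
    cx <- radius0 * cos(phi0)
    cy <- radius0 * sin(phi0)
    cz <- rise_per_res * t
    psi <- omega1 * t
    # local frame: u radial, v tangential (horizontal), axis along z
    ux <- cos(phi0); uy <- sin(phi0)
    vx <- -sin(phi0); vy <- cos(phi0)
    ca_x <- cx + radius1 * (cos(psi) * ux + sin(psi) * vx)
    ca_y <- cy + radius1 * (cos(psi) * uy + sin(psi) * vy)
    ca_z <- cz
    # outward direction from the minor-helix axis (horizontal)
    dx <- ca_x - cx; dy <- ca_y - cy
    dn <- sqrt(dx^2 + dy^2)
    dx <- dx / dn; dy <- dy / dn
    per_res <- function(elety, off_out, off_z) {
      tibble(chain = chain_id, resno = start_resno + as.integer(t), aa = aa,
             elety = elety,
             x = ca_x + off_out * dx, y = ca_y + off_out * dy,
             z = ca_z + off_z)
    }
    atoms <- dplyr::bind_rows(
      per_res("N", -0.45, -0.70),
      per_res("CA", 0, 0),
      per_res("C", -0.30, 1.10),
      per_res("O", 0.60, 1.35),
      per_res("CB", 1.53, 0)
    )
    has_tip <- aa %in% names(TIP_ATOMS)
    if (any(has_tip)) {
      tip_aa <- aa[has_tip]
      len <- unname(TIP_LENGTHS[tip_aa])
      tips <- tibble(
        chain = chain_id, resno = start_resno + as.integer(t[has_tip]),
        aa = tip_aa, elety = unname(TIP_ATOMS[tip_aa]),
        x = ca_x[has_tip] + len * dx[has_tip],
        y = ca_y[has_tip] + len * dy[has_tip],
        z = ca_z[has_tip]
      )
      atoms <- dplyr::bind_rows(atoms, tips)
    }
    atoms
  }
  model <- dplyr::bind_rows(build_chain(0, chains[1]),
                            build_chain(pi, chains[2]))
  model <- model[order(model$chain, model$resno), , drop = FALSE]
  coord_model(model)
}

#' Rigid-body transform of a coordinate model
#'
#' @param model A [coord_model()].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Length-3 translation vector (A).
#' @return Transformed model.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  model <- coord_model(model)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rotation)
  model$x <- xyz[, 1] + translation[1]
  model$y <- xyz[, 2] + translation[2]
  model$z <- xyz[, 3] + translation[3]
  model
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg Angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c2, -s2, 0, s2, c2), 3, byrow = TRUE),
    y = matrix(c(c2, 0, s2, 0, 1, 0, -s2, 0, c2), 3, byrow = TRUE),
    z = matrix(c(c2, -s2, 0, s2, c2, 0, 0, 0, 1), 3, byrow = TRUE)
  )
}
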