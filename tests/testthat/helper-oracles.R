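# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths.

# Monoisotopic masses summed from published residue masses (independent
# table entry-by-entry, not the package's constant vector).
oracle_peptide_pair_mz <- function(seq_a, seq_b, charge, heavy_a = 0,
                                   heavy_b = 0) {
  masses <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  water <- 18.0105646
  proton <- 1.00727646
  m <- function(s) sum(masses[strsplit(s, "")[[1]]]) + water
  # condensation of the two peptides loses one water
  (m(seq_a) + m(seq_b) - water + heavy_a + heavy_b + charge * proton) / charge
}

# Fine-grid Dijkstra shortest path around spheres, via igraph. Grid covers
# [box_lo, box_hi] at spacing h with 26-connectivity.
oracle_sas_distance <- function(centers, radii, start, goal,
                                box_lo, box_hi, h = 0.25) {
  gx <- seq(box_lo[1], box_hi[1], by = h)
  gy <- seq(box_lo[2], box_hi[2], by = h)
  gz <- seq(box_lo[3], box_hi[3], by = h)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  coords <- cbind(rep(gx, times = ny * nz),
                  rep(rep(gy, each = nx), times = nz),
                  rep(gz, each = nx * ny))
  blocked <- rep(FALSE, nrow(coords))
  for (s in seq_len(nrow(centers))) {
    d2 <- (coords[, 1] - centers[s, 1])^2 + (coords[, 2] - centers[s, 2])^2 +
      (coords[, 3] - centers[s, 3])^2
    blocked <- blocked | d2 <= radii[s]^2
  }
  idx <- function(p) {
    i <- round((p - box_lo) / h)
    as.integer(i[3] * nx * ny + i[2] * nx + i[1] + 1)
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ]
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  id <- seq_len(nx * ny * nz)
  froms <- vector("list", nrow(offs)); tos <- froms; ws <- froms
  for (k in seq_len(nrow(offs))) {
    jx <- ix + offs[k, 1]; jy <- iy + offs[k, 2]; jz <- iz + offs[k, 3]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny & jz >= 1 & jz <= nz
    j <- (jz - 1) * nx * ny + (jy - 1) * nx + jx
    ok[ok] <- !blocked[id[ok]] & !blocked[j[ok]]
    froms[[k]] <- id[ok]; tos[[k]] <- j[ok]
    ws[[k]] <- rep(h * sqrt(sum(offs[k, ]^2)), sum(ok))
  }
  g <- igraph::make_graph(rbind(unlist(froms), unlist(tos)),
                          n = nx * ny * nz, directed = FALSE)
  as.numeric(igraph::distances(g, v = idx(start), to = idx(goal),
                               weights = unlist(ws)))
}

# Tie-corrected Kruskal-Wallis H from the textbook rank formula.
oracle_kruskal_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation distribution of H for two groups (small n).
oracle_kruskal_perm_p <- function(a, b) {
  x <- c(a, b)
  obs <- oracle_kruskal_H(list(a, b))
  combs <- utils::combn(length(x), length(a))
  hs <- apply(combs, 2, function(i) oracle_kruskal_H(list(x[i], x[-i])))
  mean(hs >= obs - 1e-12)
}

# Holm step-down adjustment done by hand.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact enumeration of the mixed-label fraction under a dimer-class
# composition: enumerate dimer classes (and, for inter-dimer links, the
# chain drawn from each of two independent dimers).
oracle_mixed_fraction <- function(p_light_homo, p_heavy_homo, p_hetero,
                                  link_type) {
  classes <- c(light = p_light_homo, heavy = p_heavy_homo, hetero = p_hetero)
  if (link_type == "intra_chain") return(0)
  if (link_type == "inter_chain") {
    # mixed iff the dimer holding both chains is a hetero-dimer
    return(unname(classes["hetero"]))
  }
  # inter-dimeric: draw one chain from each of two independent dimers
  chain_light_prob <- function(class) {
    switch(class, light = 1, heavy = 0, hetero = 0.5)
  }
  p_mixed <- 0
  for (c1 in names(classes)) for (c2 in names(classes)) {
    q1 <- chain_light_prob(c1); q2 <- chain_light_prob(c2)
    p_pair_mixed <- q1 * (1 - q2) + (1 - q1) * q2
    p_mixed <- p_mixed + classes[[c1]] * classes[[c2]] * p_pair_mixed
  }
  p_mixed
}

# Single-pass brute-force re-quantification from raw areas (no package
# aggregation helpers): per-spectrum ratio, per-link median, frequency
# conversion and triple derivation written out longhand.
oracle_quantify <- function(matches, intensities, score_min = 8) {
  keep <- matches$labelling_complete & matches$match_score >= score_min
  m <- matches[keep, c("spectrum_id", "crosslink", "experiment")]
  i <- intensities[match(m$spectrum_id, intensities$spectrum_id), ]
  ratio <- (i$area_HL + i$area_LH) /
    (i$area_LL + i$area_HL + i$area_LH + i$area_HH)
  links <- unique(m$crosslink)
  out <- lapply(links, function(cl) {
    r_hidm <- ratio[m$crosslink == cl & m$experiment == "HIDm"]
    r_hh <- ratio[m$crosslink == cl & m$experiment == "HhIDm"]
    f_id <- if (length(r_hidm)) min(stats::median(r_hidm) / 0.5, 1) else NA
    f_im <- if (length(r_hh)) min(stats::median(r_hh) / 0.5, 1) else NA
    f_id2 <- min(f_id, f_im)
    data.frame(crosslink = cl, f_interdimeric = f_id2,
               f_interchain = max(f_im - f_id, 0), f_intrachain = 1 - f_im)
  })
  do.call(rbind, out)
}
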