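# Residues of mature lamin A that the cross-linking study names explicitly,
# pinned into the synthetic stand-in sequence at their published positions.
LAMIN_PINNED <- c(
  `1` = "M", `12` = "S", `31` = "E", `32` = "K", `33` = "E", `55` = "E",
  `65` = "E", `66` = "S", `67` = "E", `68` = "E", `78` = "K", `94` = "S",
  `97` = "K", `143` = "S", `145` = "E", `192` = "D", `239` = "S",
  `247` = "E", `254` = "D", `267` = "Y", `270` = "K", `276` = "Q",
  `289` = "H", `361` = "E", `378` = "K", `385` = "E", `407` = "S"
)

#' Synthetic lamin-A-like sequence
#'
#' A 646-residue stand-in for mature lamin A: a repeating coiled-coil-like
#' pattern with tryptic K/R spacing, with every residue named in the
#' cross-linking analysis pinned at its published mature-protein position
#' (M1, E31, K32, E55, E65, S66, E67/68, K78, K97, S143, E145, D192, S239,
#' D254, Y267, Q276, H289, ...). This is a synthetic sequence, not the real
#' lamin A sequence; it exists so that every pipeline stage is exercisable
#' with correct residue identities at the positions that matter.
#'
#' @param length Total length (default 646, the mature lamin A length).
#' @return A single character string.
#' @export
synthetic_lamin_sequence <- function(length = 646L) {
  unit <- "ELADSLQATGLK"  # 12-mer: acidic + hydroxyl sites, tryptic K
  seq <- strsplit(strrep(unit, ceiling(length / nchar(unit))), "")[[1]][1:length]
  pins <- LAMIN_PINNED[as.integer(names(LAMIN_PINNED)) <= length]
  seq[as.integer(names(pins))] <- unname(pins)
  paste(seq, collapse = "")
}

# tryptic span (start, end) containing position `pos` (span bookkeeping
# only: cut after every K/R)
tryptic_span <- function(sequence, pos) {
  aa <- strsplit(sequence, "")[[1]]
  cuts <- which(aa %in% c("K", "R"))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(aa))
  i <- findInterval(pos, starts)
  c(start = starts[i], end = ends[i])
}

#' Simulate dimer assembly of a light/heavy monomer population
#'
#' Refolded populations pair chains at random (hetero-dimer fraction
#' converging to `2 q (1 - q)`); un-refolded populations keep their
#' homodimers — dimers do not exchange chains.
#'
#' @param q_light Light-chain fraction in `[0, 1]`.
#' @param refolded Logical: was the population refolded from mixed
#'   monomers?
#' @param n Number of dimers to draw.
#' @param seed Random seed.
#' @return Tibble with `class` (`light_homo`/`heavy_homo`/`hetero`),
#'   `count`, `fraction`.
#' @export
simulate_dimer_mixture <- function(q_light, refolded, n, seed = 1L) {
  stopifnot(q_light >= 0, q_light <= 1, n >= 1)
  set.seed(seed)
  if (refolded) {
    c1 <- runif(n) < q_light
    c2 <- runif(n) < q_light
    class <- ifelse(c1 & c2, "light_homo",
                    ifelse(!c1 & !c2, "heavy_homo", "hetero"))
  } else {
    class <- ifelse(runif(n) < q_light, "light_homo", "heavy_homo")
  }
  counts <- table(factor(class, levels = c("light_homo", "heavy_homo", "hetero")))
  tibble(class = names(counts), count = as.integer(counts),
         fraction = as.integer(counts) / n)
}

#' Ground-truth table of simulated cross-links
#'
#' Draws EDC-compatible residue pairs from a protein sequence and assigns
#' each a ground-truth occurrence-probability triple (intra-chain,
#' inter-chain, inter-dimeric) consistent with a target category, placed
#' away from the classification boundaries.
#'
#' @param n_crosslinks Number of unique cross-links (default 233, the
#'   dimer-band count of the study).
#' @param sequence Protein sequence (default [synthetic_lamin_sequence()]).
#' @param category_probs Sampling proportions of the four true categories.
#' @param seed Random seed.
#' @return Tibble with pair columns, `crosslink`, the probability triple
#'   and `category_true`; the sequence is attached as the `"sequence"`
#'   attribute.
#' @export
crosslink_truth <- function(n_crosslinks = 233L,
                            sequence = synthetic_lamin_sequence(),
                            category_probs = c(intra_chain = 0.45,
                                               inter_chain = 0.2,
                                               both_ways = 0.15,
                                               inter_dimeric = 0.2),
                            seed = 1L) {
  set.seed(seed)
  aa <- strsplit(sequence, "")[[1]]
  acid <- which(aa %in% c("D", "E"))
  nuc <- which(aa %in% c("K", "S", "T", "Y"))
  pairs <- NULL
  while (is.null(pairs) || nrow(pairs) < n_crosslinks) {
    m <- 2L * n_crosslinks
    cand <- tibble(pos_a = sample(acid, m, replace = TRUE),
                   pos_b = sample(nuc, m, replace = TRUE))
    cand$aa_a <- aa[cand$pos_a]
    cand$aa_b <- aa[cand$pos_b]
    cand <- canonical_crosslinks(cand)
    pairs <- dplyr::distinct(dplyr::bind_rows(pairs, cand), .data$crosslink,
                             .keep_all = TRUE)
  }
  pairs <- pairs[seq_len(n_crosslinks), ]

  cat_true <- sample(names(category_probs), n_crosslinks, replace = TRUE,
                     prob = category_probs)
  draw_triple <- function(cat) {
    switch(cat,
      intra_chain = {
        p_id <- runif(1, 0, 0.1)
        r <- runif(1, 0, 0.1)
        c((1 - p_id) * (1 - r), (1 - p_id) * r, p_id)
      },
      inter_chain = {
        p_id <- runif(1, 0, 0.1)
        r <- runif(1, 0.9, 1)
        c((1 - p_id) * (1 - r), (1 - p_id) * r, p_id)
      },
      both_ways = {
        p_id <- runif(1, 0, 0.3)
        r <- runif(1, 0.35, 0.65)
        c((1 - p_id) * (1 - r), (1 - p_id) * r, p_id)
      },
      inter_dimeric = {
        p_id <- runif(1, 0.9, 1)
        rest <- 1 - p_id
        r <- runif(1)
        c(rest * (1 - r), rest * r, p_id)
      }
    )
  }
  trip <- t(vapply(cat_true, draw_triple, numeric(3), USE.NAMES = FALSE))
  pairs$p_intrachain <- unname(trip[, 1])
  pairs$p_interchain <- unname(trip[, 2])
  pairs$p_interdimeric <- unname(trip[, 3])
  pairs$category_true <- factor(cat_true, levels = c("inter_dimeric",
                                                     "intra_chain",
                                                     "inter_chain",
                                                     "both_ways"))
  attr(pairs, "sequence") <- sequence
  attr(pairs, "seed") <- seed
  pairs
}

#' Simulate one SILAC cross-linking experiment
#'
#' Generates spectrum matches and precursor-cluster intensities for every
#' cross-link of a truth table under one mixture design. Each spectrum's
#' four cluster areas reflect the population composition: a precursor
#' cluster integrates many molecules of the peptide pair, so the expected
#' mixed fraction per spectrum is the truth-weighted mixed probability
#' under the design; cluster areas get independent multiplicative
#' log-normal noise of the stated CV. A configurable fraction of spectra is
#' flagged labelling-incomplete or given a sub-threshold match score (these
#' should be removed by [filter_matches()]).
#'
#' @param truth A [crosslink_truth()] table.
#' @param design A [mixture_design()].
#' @param experiment Experiment label (`"HIDm"` or `"HhIDm"`).
#' @param n_spectra Spectra per cross-link (default 50).
#' @param noise_cv Multiplicative noise CV on cluster areas (default 0.06,
#'   matching the scatter between the two quantification softwares used in
#'   practice).
#' @param mean_intensity Mean total precursor intensity (arbitrary units).
#' @param frac_incomplete,frac_lowscore Fractions of spectra flagged
#'   labelling-incomplete / scored below 8.
#' @param isotope_split Mono/+1/+2 isotope-peak split of each cluster
#'   (summed back by default quantification, so inert unless long-format
#'   output is requested).
#' @param seed Random seed.
#' @return List with `matches` and `intensities` tibbles.
#' @export
simulate_experiment <- function(truth, design,
                                experiment = c("HIDm", "HhIDm"),
                                n_spectra = 50L, noise_cv = 0.06,
                                mean_intensity = 1e6,
                                frac_incomplete = 0, frac_lowscore = 0,
                                isotope_split = c(0.5, 0.35, 0.15),
                                seed = 1L) {
  experiment <- match.arg(experiment)
  p <- truth$p_intrachain + truth$p_interchain + truth$p_interdimeric
  if (any(abs(p - 1) > 1e-8)) abort("truth probability triples must sum to 1")
  set.seed(seed)
  sequence <- attr(truth, "sequence") %||% synthetic_lamin_sequence()
  q <- design$chain_light_fraction
  sdlog <- sqrt(log(1 + noise_cv^2))

  rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    p_mixed <- truth$p_interchain[i] * expected_mixed_fraction(design, "inter_chain") +
      truth$p_interdimeric[i] * expected_mixed_fraction(design, "inter_dimeric")
    frac <- c(LL = (1 - p_mixed) * q, HL = p_mixed / 2,
              LH = p_mixed / 2, HH = (1 - p_mixed) * (1 - q))
    total <- if (noise_cv > 0) {
      rlnorm(n_spectra, log(mean_intensity), sdlog)
    } else rep(mean_intensity, n_spectra)
    noise <- function() if (noise_cv > 0) {
      exp(rnorm(n_spectra, -sdlog^2 / 2, sdlog))
    } else rep(1, n_spectra)
    span_a <- tryptic_span(sequence, truth$pos_a[i])
    span_b <- tryptic_span(sequence, truth$pos_b[i])
    tibble(
      spectrum_id = sprintf("%s_%s_s%03d", experiment, truth$crosslink[i],
                            seq_len(n_spectra)),
      crosslink = truth$crosslink[i],
      experiment = experiment,
      pep_seq_a = substr(sequence, span_a["start"], span_a["end"]),
      pep_seq_b = substr(sequence, span_b["start"], span_b["end"]),
      pep_start_a = unname(span_a["start"]), pep_end_a = unname(span_a["end"]),
      pep_start_b = unname(span_b["start"]), pep_end_b = unname(span_b["end"]),
      link_pos_a = unname(truth$pos_a[i] - span_a["start"] + 1L),
      link_pos_b = unname(truth$pos_b[i] - span_b["start"] + 1L),
      charge = sample(3:5, n_spectra, replace = TRUE),
      band = "band1_3",
      area_LL = total * frac["LL"] * noise(),
      area_HL = total * frac["HL"] * noise(),
      area_LH = total * frac["LH"] * noise(),
      area_HH = total * frac["HH"] * noise()
    )
  })
  out <- dplyr::bind_rows(rows)
  n <- nrow(out)
  out$match_score <- runif(n, 8, 20)
  low <- runif(n) < frac_lowscore
  out$match_score[low] <- runif(sum(low), 2, 7.99)
  out$labelling_complete <- runif(n) >= frac_incomplete

  match_cols <- c("spectrum_id", "crosslink", "experiment", "pep_seq_a",
                  "pep_seq_b", "pep_start_a", "pep_end_a", "pep_start_b",
                  "pep_end_b", "link_pos_a", "link_pos_b", "charge", "band",
                  "match_score", "labelling_complete")
  list(
    matches = out[match_cols],
    intensities = out[c("spectrum_id", "crosslink", "experiment",
                        "area_LL", "area_HL", "area_LH", "area_HH")]
  )
}

#' Simulate the paired two-experiment SILAC study
#'
#' Runs [simulate_experiment()] for the homo-iso-dimer mix and the
#' refolded homo-/hetero-iso-dimer mix and concatenates the outputs.
#'
#' @inheritParams simulate_experiment
#' @param design_hidm,design_hhidm Designs of the two experiments.
#' @return List with `matches` and `intensities` tibbles covering both
#'   experiments.
#' @export
simulate_silac_study <- function(truth, n_spectra = 50L, noise_cv = 0.06,
                                 design_hidm = hidm_design(),
                                 design_hhidm = hhidm_design(),
                                 seed = 1L, ...) {
  a <- simulate_experiment(truth, design_hidm, "HIDm", n_spectra = n_spectra,
                           noise_cv = noise_cv, seed = seed, ...)
  b <- simulate_experiment(truth, design_hhidm, "HhIDm", n_spectra = n_spectra,
                           noise_cv = noise_cv, seed = seed + 1L, ...)
  list(matches = dplyr::bind_rows(a$matches, b$matches),
       intensities = dplyr::bind_rows(a$intensities, b$intensities))
}

#' Simulate rod-length measurements from a Gaussian mixture
#'
#' Draws rod lengths from a mixture of compressed/extended states,
#' truncated at positive lengths.
#'
#' @param means,sds,weights Component means (nm), standard deviations and
#'   weights (weights sum to 1).
#' @param n Number of measurements (default 300 per condition, as in the
#'   EM study design).
#' @param condition Condition label attached to the sample.
#' @param seed Random seed.
#' @return Tibble with `condition`, `length_nm`.
#' @export
simulate_rod_lengths <- function(means, sds, weights = rep(1 / length(means),
                                                           length(means)),
                                 n = 300L, condition = "sim", seed = 1L) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            abs(sum(weights) - 1) < 1e-8)
  set.seed(seed)
  comp <- sample(seq_along(means), n, replace = TRUE, prob = weights)
  x <- rnorm(n, means[comp], sds[comp])
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- rnorm(sum(bad), means[comp[bad]], sds[comp[bad]])
  }
  tibble(condition = condition, length_nm = x)
}

#' Deterministic coordinate fixtures for structural validation
#'
#' Builds small coordinate models with known geometry:
#' * `"straight_rod"` — idealized straight coiled-coil dimer over the rod
#'   region of the segment map (linkers built helically, the "straight
#'   linker" null model).
#' * `"single_stagger"` — two coiled-coil fragments with a configured
#'   axial overlap, inter-fragment angle and lateral offset; carries
#'   `frag_a`/`frag_b`/`linker`/`i_sc` attributes for
#'   [screen_stagger_decoys()].
#' * `"contact_pair"` — two residues whose reactive side-chain atoms sit
#'   at an exact requested distance.
#' * `"obstacle_field"` — a random field of carbon-sphere obstacles in a
#'   box plus two free probe atoms, for shortest-path checks.
#'
#' @param kind Fixture kind.
#' @param ... Kind-specific parameters, see Details in each branch of the
#'   source; common ones: `sequence`, `map`, `overlap_nm`, `angle_deg`,
#'   `distance`, `n_spheres`, `seed`.
#' @return A [coord_model()] tibble (with fixture attributes).
#' @export
make_fixture_model <- function(kind = c("straight_rod", "single_stagger",
                                        "contact_pair", "obstacle_field"),
                               ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    straight_rod = {
      sequence <- args$sequence %||% synthetic_lamin_sequence()
      map <- args$map %||% lamin_segment_map()
      rod <- map[!map$kind %in% "unstructured", ]
      from <- min(rod$start); to <- max(rod$end)
      model <- build_coiled_coil(substr(sequence, from, to),
                                 start_resno = from, register = "heptad",
                                 rise_per_res = args$rise_per_res %||% 1.485)
      attr(model, "map") <- map
      model
    },
    single_stagger = {
      sequence <- args$sequence %||% synthetic_lamin_sequence()
      frag_a <- args$frag_a %||% 30:66
      frag_b <- args$frag_b %||% 78:120
      overlap_nm <- args$overlap_nm %||% 3
      angle_deg <- args$angle_deg %||% 0
      lateral <- args$lateral_offset %||% 12
      rise <- args$rise_per_res %||% 1.485
      a <- build_coiled_coil(substr(sequence, min(frag_a), max(frag_a)),
                             start_resno = min(frag_a), rise_per_res = rise)
      b <- build_coiled_coil(substr(sequence, min(frag_b), max(frag_b)),
                             start_resno = min(frag_b), rise_per_res = rise)
      end_a_z <- (length(frag_a) - 1) * rise
      b <- transform_model(b, rotation_matrix("x", angle_deg),
                           c(0, lateral, end_a_z - overlap_nm * 10))
      b$chain <- chartr("AB", "CD", b$chain)
      model <- coord_model(dplyr::bind_rows(a, b))
      attr(model, "frag_a") <- frag_a
      attr(model, "frag_b") <- frag_b
      attr(model, "linker") <- args$linker
      attr(model, "i_sc") <- args$i_sc
      model
    },
    contact_pair = {
      aa_a <- args$aa_a %||% "E"
      aa_b <- args$aa_b %||% "K"
      d <- args$distance %||% 3.5
      tip_a <- TIP_ATOMS[[aa_a]]
      tip_b <- TIP_ATOMS[[aa_b]]
      coord_model(tibble(
        chain = c("A", "A", "A", "B", "B", "B"),
        resno = c(args$resno_a %||% 1L, args$resno_a %||% 1L,
                  args$resno_a %||% 1L, args$resno_b %||% 2L,
                  args$resno_b %||% 2L, args$resno_b %||% 2L),
        aa = c(aa_a, aa_a, aa_a, aa_b, aa_b, aa_b),
        elety = c("CA", "CB", tip_a, tip_b, "CB", "CA"),
        x = c(-4, -2.5, 0, d, d + 2.5, d + 4),
        y = 0, z = 0
      ))
    },
    obstacle_field = {
      seed <- args$seed %||% 1L
      set.seed(seed)
      n_spheres <- args$n_spheres %||% 8L
      box <- args$box %||% c(16, 16, 16)
      start <- args$start %||% c(1, box[2] / 2, box[3] / 2)
      goal <- args$goal %||% c(box[1] - 1, box[2] / 2, box[3] / 2)
      margin <- args$clearance %||% 3.4
      centers <- matrix(NA_real_, n_spheres, 3)
      k <- 0
      while (k < n_spheres) {
        p <- runif(3) * box
        if (euclid(p, start) > margin && euclid(p, goal) > margin) {
          k <- k + 1
          centers[k, ] <- p
        }
      }
      obst <- tibble(chain = "O", resno = 100L + seq_len(n_spheres),
                     aa = "G", elety = "C",
                     x = centers[, 1], y = centers[, 2], z = centers[, 3])
      probes <- tibble(chain = c("A", "B"), resno = c(1L, 2L), aa = "G",
                       elety = "CB",
                       x = c(start[1], goal[1]), y = c(start[2], goal[2]),
                       z = c(start[3], goal[3]))
      model <- coord_model(dplyr::bind_rows(probes, obst))
      attr(model, "spheres") <- obst
      model
    }
  )
}
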