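test_that("synthetic sequence pins the published residues", {
  s <- synthetic_lamin_sequence()
  expect_equal(nchar(s), 646)
  aa <- strsplit(s, "")[[1]]
  expect_equal(aa[1], "M")
  expect_equal(aa[c(31, 32, 33)], c("E", "K", "E"))
  expect_equal(aa[c(55, 65, 66, 67, 68)], c("E", "E", "S", "E", "E"))
  expect_equal(aa[c(78, 97)], c("K", "K"))
  expect_equal(aa[c(254, 267, 276, 289)], c("D", "Y", "Q", "H"))
  # EDC-relevant residue classes are abundant enough to draw cross-links
  expect_gt(sum(aa %in% c("D", "E")), 50)
  expect_gt(sum(aa %in% c("K", "S", "T", "Y")), 50)
})

test_that("truth tables are valid and reproducible", {
  t1 <- crosslink_truth(n_crosslinks = 50, seed = 3)
  t2 <- crosslink_truth(n_crosslinks = 50, seed = 3)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 50)
  expect_false(any(duplicated(t1$crosslink)))
  expect_equal(t1$p_intrachain + t1$p_interchain + t1$p_interdimeric,
               rep(1, 50), tolerance = 1e-12)
  # every drawn pair respects the zero-length chemistry
  expect_true(all(edc_compatible(t1$aa_a, t1$aa_b, t1$pos_a, t1$pos_b)))
})

test_that("simulated spectra honour their generative ratios", {
  # pure intra-chain: no mixed signal at all
  t_intra <- crosslink_truth(5, seed = 1,
                             category_probs = c(intra_chain = 1,
                                                inter_chain = 0, both_ways = 0,
                                                inter_dimeric = 0))
  t_intra$p_intrachain <- 1
  t_intra$p_interchain <- 0
  t_intra$p_interdimeric <- 0
  sim <- simulate_experiment(t_intra, hhidm_design(), "HhIDm",
                             n_spectra = 10, noise_cv = 0, seed = 2)
  r <- spectrum_mixed_ratio(sim$intensities)$ratio
  expect_true(all(r == 0))
  # pure inter-chain in the refolded mix: mean ratio 0.5 within 3 SE
  t_ic <- t_intra
  t_ic$p_intrachain <- 0; t_ic$p_interchain <- 1
  sim2 <- simulate_experiment(t_ic[1, ], hhidm_design(), "HhIDm",
                              n_spectra = 2000, noise_cv = 0.2, seed = 3)
  r2 <- spectrum_mixed_ratio(sim2$intensities)$ratio
  expect_lt(abs(mean(r2) - 0.5), 3 * sd(r2) / sqrt(length(r2)) + 0.01)
  # determinism contract
  a <- simulate_experiment(t_intra, hidm_design(), "HIDm", n_spectra = 5,
                           seed = 9)
  b <- simulate_experiment(t_intra, hidm_design(), "HIDm", n_spectra = 5,
                           seed = 9)
  expect_identical(a, b)
})

test_that("simulated matches carry consistent peptide spans", {
  truth <- crosslink_truth(10, seed = 6)
  sim <- simulate_experiment(truth, hidm_design(), "HIDm", n_spectra = 2,
                             seed = 6)
  m <- sim$matches
  expect_true(all(nchar(m$pep_seq_a) == m$pep_end_a - m$pep_start_a + 1))
  expect_true(all(m$link_pos_a >= 1 & m$link_pos_a <= nchar(m$pep_seq_a)))
  expect_true(all(m$charge >= 3))
  # linked residue letter inside the peptide matches the cross-link id
  aa_at_link <- substr(m$pep_seq_a, m$link_pos_a, m$link_pos_a)
  expect_true(all(aa_at_link == sub("^([A-Z])\\d+-.*$", "\\1", m$crosslink) |
                    aa_at_link == sub("^.*-([A-Z])\\d+$", "\\1", m$crosslink)))
})

test_that("flagged spectra fractions are controllable", {
  truth <- crosslink_truth(20, seed = 8)
  sim <- simulate_experiment(truth, hidm_design(), "HIDm", n_spectra = 50,
                             frac_incomplete = 0.3, frac_lowscore = 0.2,
                             seed = 8)
  expect_equal(mean(!sim$matches$labelling_complete), 0.3, tolerance = 0.1)
  expect_equal(mean(sim$matches$match_score < 8), 0.2, tolerance = 0.1)
  kept <- filter_matches(sim$matches)
  expect_true(all(kept$match_score >= 8 & kept$labelling_complete))
})

test_that("full loop recovers generating categories at scale", {
  truth <- crosslink_truth(n_crosslinks = 120, seed = 13)
  sim <- simulate_silac_study(truth, n_spectra = 50, noise_cv = 0.2,
                              seed = 14)
  q <- tidy(quantify_crosslinks(sim$matches, sim$intensities))
  res <- dplyr::inner_join(q, truth, by = "crosslink")
  err <- pmax(abs(res$f_interdimeric - res$p_interdimeric),
              abs(res$f_interchain - res$p_interchain),
              abs(res$f_intrachain - res$p_intrachain))
  expect_gte(mean(err <= 0.05), 0.95)
  cl <- classify_crosslinks(res)
  expect_gte(mean(cl$category == cl$category_true), 0.95)
  # noise-free recovery is exact
  sim0 <- simulate_silac_study(truth[1:40, ], n_spectra = 20, noise_cv = 0,
                               seed = 15)
  q0 <- tidy(quantify_crosslinks(sim0$matches, sim0$intensities))
  res0 <- dplyr::inner_join(q0, truth[1:40, ], by = "crosslink")
  cl0 <- classify_crosslinks(res0)
  expect_equal(mean(cl0$category == cl0$category_true), 1)
})

test_that("fixture models honour their requested geometry", {
  cp <- make_fixture_model("contact_pair", distance = 2.8)
  expect_equal(sidechain_contact_distance(cp, 1, 2), 2.8, tolerance = 1e-6)
  stag <- make_fixture_model("single_stagger", overlap_nm = 3)
  expect_equal(laminxl:::fragment_axial_overlap(stag, attr(stag, "frag_a"),
                                                attr(stag, "frag_b")),
               3, tolerance = 0.25)
  rod <- make_fixture_model("straight_rod")
  ca <- rod[rod$elety == "CA" & rod$chain == "A", ]
  # rod region 30..386 as a continuous helix: length matches the rise
  expect_equal((max(ca$z) - min(ca$z)) / 10, (386 - 30) * 1.485 / 10,
               tolerance = 1e-6)
  # deterministic obstacle fields
  o1 <- make_fixture_model("obstacle_field", seed = 4)
  o2 <- make_fixture_model("obstacle_field", seed = 4)
  expect_identical(o1, o2)
})
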