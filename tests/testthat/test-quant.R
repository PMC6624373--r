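make_matches <- function(score, complete) {
  tibble::tibble(
    spectrum_id = sprintf("s%02d", seq_along(score)),
    crosslink = "E65-K97", experiment = "HIDm",
    match_score = score, labelling_complete = complete
  )
}

test_that("spectrum filter drops incomplete labelling and sub-threshold scores", {
  m <- make_matches(c(7.9, 8.0, 12, 15), c(TRUE, TRUE, FALSE, TRUE))
  kept <- filter_matches(m)
  expect_equal(kept$spectrum_id, c("s02", "s04"))  # 8.0 exactly is kept
  rej <- attr(kept, "rejections")
  expect_equal(rej$reason[rej$spectrum_id == "s01"],
               "match_score_below_threshold")
  expect_equal(rej$reason[rej$spectrum_id == "s03"],
               "incomplete_silac_labelling")
  # empty output allowed
  expect_equal(nrow(filter_matches(make_matches(5, TRUE))), 0)
})

test_that("mixed-label ratio follows (HL+LH)/(LL+HL+LH+HH)", {
  ci <- tibble::tibble(
    spectrum_id = c("a", "b", "c"),
    area_LL = c(8, 0, 1), area_HL = c(0, 3, 1),
    area_LH = c(0, 5, 1), area_HH = c(8, 0, 1)
  )
  expect_equal(spectrum_mixed_ratio(ci)$ratio, c(0, 1, 0.5))
  # invariant under uniform intensity scaling
  scaled <- ci
  scaled[, -1] <- scaled[, -1] * 1234.5
  expect_equal(spectrum_mixed_ratio(scaled)$ratio, spectrum_mixed_ratio(ci)$ratio)
  # all-zero spectra are unquantifiable
  bad <- tibble::tibble(spectrum_id = "z", area_LL = 0, area_HL = 0,
                        area_LH = 0, area_HH = 0)
  expect_error(spectrum_mixed_ratio(bad), "unquantifiable")
})

test_that("median aggregation matches a sort-and-index oracle", {
  expect_equal(aggregate_median_ratio(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(aggregate_median_ratio(c(0.1, 0.3)), 0.2)  # even: central mean
  set.seed(42)
  r <- runif(101)
  s <- sort(r)
  expect_equal(aggregate_median_ratio(r), s[51])
  expect_error(aggregate_median_ratio(numeric(0)), "no supporting spectra")
})

test_that("ratio-to-frequency conversion uses the design's expected mixed fraction", {
  expect_equal(ratio_to_frequency(0, hidm_design()), 0)
  # fully inter-dimeric link in a 1:1 mix shows mixed pairs half the time
  expect_equal(ratio_to_frequency(0.5, hidm_design(), "inter_dimeric"), 1)
  expect_equal(ratio_to_frequency(0.25, hhidm_design(), "inter_chain"), 0.5)
  expect_equal(ratio_to_frequency(0.6, hidm_design()), 1)  # clamped
  expect_error(ratio_to_frequency(1.2, hidm_design()), "\\[0, 1\\]")
  # a design with no mixed-capable assembly has no defined conversion
  expect_error(ratio_to_frequency(0.1, mixture_design(1, 0, 0), "inter_chain"),
               "zero expected mixed fraction")
})

test_that("frequency triple derivation reproduces the defining identities", {
  d <- derive_frequencies(0.4, 0.9)
  expect_equal(d$f_interchain, 0.5)
  expect_equal(d$f_intrachain, 0.1)
  d0 <- derive_frequencies(0, 0)
  expect_equal(d0$f_intrachain, 1)
  expect_equal(d0$f_interchain, 0)
  # noise-induced negative inter-chain is clamped and renormalized
  dc <- derive_frequencies(0.6, 0.5)
  expect_equal(dc$f_interchain, 0)
  expect_equal(dc$f_interdimeric, 0.5)
  expect_equal(dc$f_intrachain, 0.5)
  expect_error(derive_frequencies(-0.1, 0.5), "\\[0, 1\\]")
  # triples always sum to 1 on a random grid
  set.seed(7)
  f1 <- runif(200); f2 <- runif(200)
  dd <- derive_frequencies(f1, f2)
  expect_equal(dd$f_interdimeric + dd$f_interchain + dd$f_intrachain,
               rep(1, 200))
  expect_true(all(as.matrix(dd) >= 0 & as.matrix(dd) <= 1))
})

test_that("pipeline equals a single-pass brute-force re-quantification", {
  truth <- crosslink_truth(n_crosslinks = 25, seed = 3)
  sim <- simulate_silac_study(truth, n_spectra = 11, noise_cv = 0.15,
                              seed = 5, frac_lowscore = 0.1,
                              frac_incomplete = 0.05)
  q <- tidy(quantify_crosslinks(sim$matches, sim$intensities))
  o <- oracle_quantify(sim$matches, sim$intensities)
  o <- o[match(q$crosslink, o$crosslink), ]
  expect_equal(q$f_interdimeric, o$f_interdimeric, tolerance = 1e-12)
  expect_equal(q$f_interchain, o$f_interchain, tolerance = 1e-12)
  expect_equal(q$f_intrachain, o$f_intrachain, tolerance = 1e-12)
})

test_that("cross-links seen in one experiment keep undefined components", {
  truth <- crosslink_truth(n_crosslinks = 4, seed = 2)
  sim_h <- simulate_experiment(truth[1:3, ], hidm_design(), "HIDm",
                               n_spectra = 5, seed = 1)
  sim_hh <- simulate_experiment(truth[2:4, ], hhidm_design(), "HhIDm",
                                n_spectra = 5, seed = 2)
  q <- quantify_crosslinks(rbind(sim_h$matches, sim_hh$matches),
                           rbind(sim_h$intensities, sim_hh$intensities))
  only_hidm <- q[q$n_spectra_hhidm == 0, ]
  expect_true(all(is.na(only_hidm$f_interchain)))
  expect_true(all(!is.na(only_hidm$f_interdimeric)))
  only_hh <- q[q$n_spectra_hidm == 0, ]
  expect_true(all(is.na(only_hh$f_interdimeric)))
  expect_true(all(!is.na(only_hh$f_intermolecular)))
  g <- glance(q)
  expect_equal(g$n_crosslinks, 4L)
  expect_equal(g$n_both_experiments, 2L)
})

test_that("isotope-peak collapse supports sum and mean modes", {
  long <- tibble::tibble(
    spectrum_id = rep("s1", 12),
    combo = rep(c("LL", "HL", "LH", "HH"), each = 3),
    isotope_peak = rep(0:2, 4),
    area = c(5, 3, 2, 1, 1, 1, 2, 1, 0, 4, 3, 3)
  )
  wide_sum <- sum_isotope_peaks(long)
  expect_equal(wide_sum$area_LL, 10)
  expect_equal(wide_sum$area_HH, 10)
  wide_mean <- sum_isotope_peaks(long, mode = "mean")
  expect_equal(wide_mean$area_HL, 1)
  # the ratio is the same either way for a proportional split
  expect_equal(spectrum_mixed_ratio(wide_sum)$ratio,
               spectrum_mixed_ratio(wide_mean)$ratio, tolerance = 1e-12)
})
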