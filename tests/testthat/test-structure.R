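seq646 <- synthetic_lamin_sequence()

test_that("ideal coiled-coil dimer has exact rise and 2-fold symmetry", {
  win <- substr(seq646, 30, 129)  # 100 residues
  m <- build_coiled_coil(win, start_resno = 30)
  ca_a <- m[m$elety == "CA" & m$chain == "A", ]
  # axial extent of 100 residues at 1.485 A rise
  expect_equal(max(ca_a$z) - min(ca_a$z), 99 * 1.485, tolerance = 1e-9)
  # chain B is chain A rotated 180 degrees about the superhelix axis
  ca_b <- m[m$elety == "CA" & m$chain == "B", ]
  expect_equal(ca_b$x, -ca_a$x, tolerance = 1e-9)
  expect_equal(ca_b$y, -ca_a$y, tolerance = 1e-9)
  expect_equal(ca_b$z, ca_a$z, tolerance = 1e-9)
  # rise configurable and linear in residue count
  m2 <- build_coiled_coil(win, rise_per_res = 1.5)
  ca2 <- m2[m2$elety == "CA" & m2$chain == "A", ]
  expect_equal(max(ca2$z) - min(ca2$z), 99 * 1.5, tolerance = 1e-9)
  expect_error(build_coiled_coil("EKL"), "at least one repeat")
  expect_error(build_coiled_coil(substr(seq646, 1, 20), register = "helix"))
})

test_that("predicted rod length matches the segment-map arithmetic", {
  len <- predicted_rod_length(lamin_segment_map())
  expect_gte(len$coil_nm, 47); expect_lte(len$coil_nm, 49)
  expect_gte(len$total_nm, 50); expect_lte(len$total_nm, 52)
  # single 322-residue heptad block
  single <- tibble::tibble(name = "c", start = 1L, end = 322L,
                           kind = "heptad_coil")
  expect_equal(predicted_rod_length(single, linker_total_nm = 0)$total_nm,
               322 * 1.485 / 10, tolerance = 1e-9)
  empty <- tibble::tibble(name = character(0), start = integer(0),
                          end = integer(0), kind = character(0))
  expect_equal(predicted_rod_length(empty)$total_nm, 3.4)
})

test_that("side-chain contact distances take the minimum over reactive atoms", {
  cp <- make_fixture_model("contact_pair", distance = 3.5)
  expect_equal(sidechain_contact_distance(cp, 1, 2), 3.5, tolerance = 1e-6)
  expect_true(crosslink_satisfied(cp, 1, 2, mode = "contact4",
                                  chain_a = NULL, chain_b = NULL))
  cp2 <- make_fixture_model("contact_pair", distance = 4.1)
  expect_equal(sidechain_contact_distance(cp2, 1, 2), 4.1, tolerance = 1e-6)
  expect_false(crosslink_satisfied(cp2, 1, 2, mode = "contact4",
                                   chain_a = NULL, chain_b = NULL))
  # with OE1 and OE2 both present the minimum is used
  both <- coord_model(tibble::tibble(
    chain = c("A", "A", "B"), resno = c(1, 1, 2), aa = c("E", "E", "K"),
    elety = c("OE1", "OE2", "NZ"),
    x = c(0, 2, 5), y = 0, z = 0
  ))
  expect_equal(sidechain_contact_distance(both, 1, 2), 3)
  # missing reactive atoms are reported by residue
  incomplete <- coord_model(tibble::tibble(
    chain = "A", resno = 1:2, aa = c("E", "K"), elety = c("OE1", "CB"),
    x = c(0, 3), y = 0, z = 0
  ))
  expect_error(sidechain_contact_distance(incomplete, 1, 2), "NZ")
})

test_that("SAS distance is straight-line in empty space and detours around obstacles", {
  free <- make_fixture_model("obstacle_field", n_spheres = 1, box = c(14, 14, 14),
                             seed = 3)
  d <- sas_distance(free, 1, 2, chain_a = "A", chain_b = "B")
  expect_gte(d, 12)           # never below the Euclidean distance
  expect_lte(d, 13)           # within grid resolution of 12 A
  # a blocking sphere forces a strictly longer path
  wall <- coord_model(tibble::tibble(
    chain = c("A", "B", "O"), resno = c(1, 2, 3), aa = "G",
    elety = c("CB", "CB", "C"),
    x = c(0, 12, 6), y = 5, z = 5
  ))
  d_block <- sas_distance(wall, 1, 2, chain_a = "A", chain_b = "B")
  expect_gt(d_block, 12)
  expect_true(is.finite(d_block))
  # fully enclosed target reports no path, not an error
  shell <- expand.grid(x = c(4, 8), y = c(3, 7), z = c(3, 7))
  boxed <- coord_model(tibble::tibble(
    chain = c("A", "B", rep("O", 8)), resno = c(1, 2, 10 + 1:8), aa = "G",
    elety = c("CB", "CB", rep("C", 8)),
    x = c(0, 6, shell$x), y = c(5, 5, shell$y), z = c(5, 5, shell$z)
  ))
  expect_true(is.infinite(sas_distance(boxed, 1, 2, chain_a = "A",
                                       chain_b = "B", probe = 2.5)))
})

test_that("SAS distance matches a fine-grid Dijkstra oracle on random obstacle fields", {
  # 20 random sphere fields; implementation at 1 A grid, oracle at 0.25 A
  probe <- 0.8
  r_sphere <- 1.7 + probe
  box <- c(10, 10, 10)
  for (seed in 1:20) {
    fix <- make_fixture_model("obstacle_field", n_spheres = 4, box = box,
                              seed = seed, clearance = r_sphere + 1.2)
    d_impl <- sas_distance(fix, 1, 2, chain_a = "A", chain_b = "B",
                           probe = probe, pad = 4)
    sph <- attr(fix, "spheres")
    start <- c(1, box[2] / 2, box[3] / 2)
    goal <- c(box[1] - 1, box[2] / 2, box[3] / 2)
    d_orc <- oracle_sas_distance(
      as.matrix(sph[, c("x", "y", "z")]), rep(r_sphere, nrow(sph)),
      start, goal, box_lo = pmin(start, goal) - 4,
      box_hi = pmax(start, goal) + 4, h = 0.25
    )
    if (is.finite(d_orc)) {
      expect_lt(abs(d_impl - d_orc), 2, label = sprintf("seed %d", seed))
    } else {
      expect_true(is.infinite(d_impl), label = sprintf("seed %d", seed))
    }
  }
})

test_that("helix pair angles recover constructed rotations within 2 degrees", {
  win <- substr(seq646, 240, 276)
  # hendecad register builds a straight near-parallel bundle: exact axis
  m <- build_coiled_coil(win, start_resno = 240, register = "hendecad")
  shift <- function(mm, rot, tr) {
    out <- transform_model(mm, rot, tr)
    out$resno <- out$resno + 200L
    coord_model(dplyr::bind_rows(mm, out))
  }
  expect_equal(helix_pair_angle(shift(m, diag(3), c(0, 0, 70)),
                                240:276, 440:476), 0, tolerance = 2)
  expect_equal(helix_pair_angle(shift(m, rotation_matrix("y", 90), c(40, 0, 0)),
                                240:276, 440:476), 90, tolerance = 2)
  expect_equal(helix_pair_angle(shift(m, rotation_matrix("x", 180), c(0, 0, 120)),
                                240:276, 440:476), 180, tolerance = 2)
  expect_equal(helix_pair_angle(shift(m, rotation_matrix("y", 45), c(40, 0, 0)),
                                240:276, 440:476), 45, tolerance = 2)
  expect_error(helix_pair_angle(m, 240:243, 250:276), "too short")
})

test_that("linker extension caps accept short anchors and reject overstretch", {
  ok_fix <- make_fixture_model("single_stagger", overlap_nm = 3, i_sc = -7,
                               linker = "L1")
  expect_true(linker_extension_ok(ok_fix, "L1"))
  far_fix <- make_fixture_model("single_stagger", overlap_nm = 5, i_sc = -7,
                                linker = "L1")
  expect_false(linker_extension_ok(far_fix, "L1"))
  # L12 is uncapped: always feasible
  expect_true(linker_extension_ok(far_fix, "L12"))
  expect_error(linker_extension_ok(ok_fix, "L9"), "unknown linker")
})

test_that("rod shortening subtracts stagger overlaps with segment capacity limits", {
  none <- rod_shortening(50.9, tibble::tibble(linker = character(0),
                                              shortening_nm = numeric(0)))
  expect_equal(none$length_nm, 50.9)
  expect_equal(rod_shortening(20, 5)$length_nm, 15)  # plain subtraction
  # the L12+L3 pair shares the short parallel-hendecad segment
  three <- rod_shortening(50.9, tibble::tibble(
    linker = c("L1", "L12", "L3"), shortening_nm = c(5, 4, 5)
  ))
  expect_gte(three$length_nm, 40)
  expect_lte(three$length_nm, 41.9)
  expect_error(rod_shortening(10, 15), "exceeds")
  expect_error(rod_shortening(50, tibble::tibble(linker = "LX",
                                                 shortening_nm = 1)),
               "unknown stagger linker")
})

test_that("stagger decoy screening applies the ordered filter pipeline", {
  xls <- tibble::tibble(pos_a = c(49, 52, 40), pos_b = c(84, 84, 110))
  good <- make_fixture_model("single_stagger", i_sc = -7, linker = "L1")
  anti <- make_fixture_model("single_stagger", angle_deg = 170, i_sc = -7,
                             linker = "L1")
  weak <- make_fixture_model("single_stagger", i_sc = -3, linker = "L1")
  xls_anti <- tibble::tibble(pos_a = 34, pos_b = 86)  # satisfiable on `anti`
  scr <- screen_stagger_decoys(list(good = good, anti = anti, weak = weak),
                               xls)
  expect_equal(scr$accepted, c(TRUE, FALSE, FALSE))
  expect_equal(scr$n_satisfied[1], 2)
  expect_equal(sort(scr$satisfied[[1]]), c(1L, 2L))
  expect_equal(scr$shortening_nm[1], 3, tolerance = 0.25)
  expect_false(scr$pass_score[3])
  # anti-parallel fold that does satisfy a cross-link is still rejected
  scr_anti <- screen_stagger_decoys(list(anti = anti), xls_anti)
  expect_equal(scr_anti$n_satisfied, 1)
  expect_gt(scr_anti$angle_deg, 45)
  expect_false(scr_anti$accepted)
  # accepted set is invariant to input ordering
  scr_rev <- screen_stagger_decoys(list(weak = weak, anti = anti,
                                        good = good), xls)
  expect_equal(sort(scr_rev$model[scr_rev$accepted]),
               sort(scr$model[scr$accepted]))
})

test_that("PDB round trip preserves coordinates and imported scores", {
  fix <- make_fixture_model("single_stagger", i_sc = -6.25, linker = "L1")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(fix, path)
  back <- read_model_pdb(path)
  expect_equal(attr(back, "i_sc"), -6.25)
  expect_equal(nrow(back), nrow(fix))
  ref <- fix[order(fix$chain, fix$resno, fix$elety), ]
  got <- back[order(back$chain, back$resno, back$elety), ]
  expect_equal(got$x, ref$x, tolerance = 1e-3)
  expect_equal(got$aa, ref$aa)
})
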