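test_that("water dimers produce exactly one bond inside the cutoff", {
  hb <- hydrogen_bonds(water_dimer(2.8))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)
  expect_equal(nrow(hydrogen_bonds(water_dimer(5.0))), 0L)
})

test_that("ion pairs require opposite signs within the cutoff", {
  ip <- ion_pairs(lys_asp_pair(3.0))
  expect_equal(nrow(ip), 1L)
  expect_equal(ip$atom_i, "A:1:NZ")   # cation listed first
  expect_equal(ip$atom_j, "A:2:OD1")
  expect_equal(nrow(ion_pairs(lys_asp_pair(4.5))), 0L)
  # same sign: two lysines
  expect_equal(nrow(ion_pairs(lys_asp_pair(3.0, resname_b = "LYS",
                                           name_b = "NZ"))), 0L)
})

test_that("histidine charge is off by default and opt-in by residue", {
  his <- lys_asp_pair(3.0, resname_b = "HIS", name_b = "ND1")
  his$atoms$resname[1L] <- "ASP"
  his$atoms$name[1L] <- "OD1"
  expect_equal(nrow(ion_pairs(his)), 0L)
  tab <- default_contact_tables(protonated_his = "A:2")
  expect_equal(nrow(ion_pairs(his, tables = tab)), 1L)
})

test_that("detected contacts equal a brute-force per-pair scan on random frames", {
  p <- toy_tec_params(seed = 13, helix_length = 12L, hinge_position = 6L,
                      duplex_length = 4L, n_transient_waters = 15L,
                      contact_swap = list(residue = 3L, partner_a = 7L,
                                          partner_b = 10L, swap_frame = Inf),
                      n_waters = list(list(center = "M:1:MG", distance = 2,
                                           count = 2L, resident = TRUE)),
                      noise_sigma = 0.5, n_frames = 100L)
  s <- build_toy_tec(p)
  tr <- simulate_trajectory(s, p)
  crit <- contact_criteria()
  tab <- default_contact_tables()
  for (k in seq_len(n_frames(tr))) {
    xyz <- tr$frames[[k]]
    hb <- hydrogen_bonds(s, crit, tab, xyz = xyz)
    expect_identical(hbond_pair_set(hb),
                     brute_force_hbonds(s, crit, tab, xyz = xyz))
    ip <- ion_pairs(s, crit, tab, xyz = xyz)
    expect_identical(ionpair_residue_set(ip),
                     brute_force_ionpairs(s, crit, tab, xyz = xyz))
  }
})

test_that("occupancy counts frames with the contact present", {
  fx <- small_toy(1)
  st <- static_traj(fx$structure, 8L)
  expect_equal(contact_occupancy(st, "A:10", "A:14"), 1.0)
  expect_equal(contact_occupancy(st, "A:10", "A:30"), 0.0)
  expect_error(contact_occupancy(st, "A:10", "Q:99"), "Q:99")

  # planted square wave: swap at midpoint -> one-half occupancy each
  p <- small_toy_params(seed = 14, n_frames = 40, noise_sigma = 0,
                        contact_swap = list(residue = 10L, partner_a = 14L,
                                            partner_b = 6L,
                                            swap_frame = 21L))
  s <- build_toy_tec(p)
  tr <- simulate_trajectory(s, p)
  # the planted square wave lives in the side-chain ion pair; the helical
  # backbone i,i+4 hydrogen bond keeps "any"-kind occupancy at 1
  expect_equal(contact_occupancy(tr, "A:10", "A:14", kind = "ionpair"),
               0.5, tolerance = 1 / 40)
  expect_equal(contact_occupancy(tr, "A:10", "A:6", kind = "ionpair"),
               0.5, tolerance = 1 / 40)
  expect_equal(contact_occupancy(tr, "A:10", "A:14"), 1.0)

  # occupancy is monotone non-increasing as the cutoff tightens
  occs <- vapply(c(4.5, 4.0, 3.5, 3.0, 2.5), function(cut)
    contact_occupancy(tr, "A:10", "A:14", kind = "ionpair",
                      criteria = contact_criteria(ionpair_cutoff = cut)),
    numeric(1L))
  expect_true(all(diff(occs) <= 1e-12))
})

test_that("planted contact swaps are flagged as switch residues", {
  pa <- small_toy_params(seed = 15, n_frames = 40)
  pb <- small_toy_params(seed = 16, n_frames = 40,
                         contact_swap = list(residue = 10L, partner_a = 14L,
                                             partner_b = 6L,
                                             swap_frame = 1L))
  sa <- build_toy_tec(pa); ta <- simulate_trajectory(sa, pa)
  sb <- build_toy_tec(pb); tb <- simulate_trajectory(sb, pb)
  sw <- switch_residues(ta, tb, c("A:10", "A:25"))
  expect_equal(sw$residue[1L], "A:10")
  expect_gte(sw$switch_score[1L], 0.85)
  expect_true(sw$is_switch[1L])
  expect_equal(sw$top_partner[1L], "A:14")
  expect_false(sw$is_switch[sw$residue == "A:25"])

  # identical ensembles show no switches
  sw0 <- switch_residues(ta, ta, c("A:10", "A:25"))
  expect_true(all(sw0$switch_score == 0))

  # symmetric in the ensemble order
  sw_rev <- switch_residues(tb, ta, c("A:10"))
  expect_equal(sw_rev$switch_score[1L], sw$switch_score[1L])

  # shuffling frames leaves occupancies unchanged
  perm <- sample(seq_len(n_frames(ta)))
  ta_shuf <- tec_trajectory(sa, ta$frames[perm],
                            frame_interval = ta$frame_interval)
  sw_shuf <- switch_residues(ta_shuf, tb, c("A:10"))
  expect_equal(sw_shuf$switch_score[1L], sw$switch_score[1L])

  expect_error(switch_residues(ta, tb, "Z:1"), "absent")
})

test_that("adding contact-holding frames never lowers occupancy", {
  fx <- small_toy(1)
  s <- fx$structure
  xyz <- coords(s)
  # break the planted pair in half the frames by pulling NZ away
  nz <- atom_index(s, "A:10:NZ")
  far <- xyz; far[nz, ] <- far[nz, ] + c(15, 0, 0)
  tr1 <- tec_trajectory(s, list(far, xyz, far, xyz))
  tr2 <- tec_trajectory(s, c(tr1$frames, list(xyz, xyz)))
  o1 <- contact_occupancy(tr1, "A:10", "A:14")
  o2 <- contact_occupancy(tr2, "A:10", "A:14")
  expect_gte(o2, o1)
  expect_true(o1 >= 0 && o2 <= 1)
})
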