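ideal_frame <- function(d_acc = 2.9, h_offset = c(1.0, 0, 0)) {
  atoms <- rbind(
    data.frame(chain = "A", res_seq = 1, res_name = "SER",
               atom_name = c("OG", "HG"), element = c("O", "H"),
               x = c(0, h_offset[1]), y = c(0, h_offset[2]),
               z = c(0, h_offset[3])),
    data.frame(chain = "A", res_seq = 2, res_name = "GLU", atom_name = "OE2",
               element = "O", x = d_acc, y = 0, z = 0))
  structure_model(atoms)
}

test_that("geometric criteria accept ideal bonds and reject bad distance/angle", {
  hb <- detect_hbonds(ideal_frame(2.9))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, "S_1@OG")
  expect_equal(hb$acceptor, "E_2@OE2")
  expect_equal(hb$dha_angle, 180)

  expect_equal(nrow(detect_hbonds(ideal_frame(4.0))), 0)      # distance fail
  # hydrogen perpendicular to the D-A axis: angle 90 < 120
  expect_equal(nrow(detect_hbonds(ideal_frame(2.9, c(0, 1.0, 0)))), 0)
  # loosened angle criterion admits it again
  expect_equal(nrow(detect_hbonds(ideal_frame(2.9, c(0, 1.0, 0)),
                                  hbond_criteria(min_dha_angle = 45))), 1)
})

test_that("planted bonds among decoys are recovered exactly, matching brute force", {
  sched <- list(P1 = 1:2, P2 = 1:2, P3 = 1:2, P4 = 1:2, P5 = 1:2)
  tr <- make_trajectory(11, n_frames = 2, n_pairs = 5, bond_schedule = sched,
                        n_decoys = 50)
  frame <- tr$frames[[1]]
  hb <- detect_hbonds(frame)
  expect_equal(nrow(hb), 5)
  expect_setequal(paste(hb$donor, hb$acceptor), paste(tr$pairs$donor, tr$pairs$acceptor))

  donors <- data.frame(chain = "A", res_seq = c(1, 3, 5, 7, 9),
                       atom_name = "OG", h_name = "HG")
  acc_res <- frame$atoms[frame$atoms$atom_name %in% c("OE2", "O"), ]
  acceptors <- data.frame(chain = acc_res$chain, res_seq = acc_res$res_seq,
                          atom_name = acc_res$atom_name)
  expect_length(oracle_hbonds(frame, donors, acceptors), 5)
})

test_that("occupancy equals the planted frame fractions", {
  tr <- make_trajectory(5, n_frames = 20, n_pairs = 2,
                        bond_schedule = list(P1 = 1:20, P2 = 1:13))
  occ <- occupancy(tr$frames, pairs = tr$pairs)
  expect_equal(occ$occupancy_pct[occ$donor == tr$pairs$donor[1]], 100)
  expect_equal(occ$occupancy_pct[occ$donor == tr$pairs$donor[2]], 65)
  expect_true(all(diff(occ$occupancy_pct) <= 0))   # sorted descending

  # unscheduled pair reported at 0% only when explicitly requested
  tr0 <- make_trajectory(6, n_frames = 10, n_pairs = 1,
                         bond_schedule = list(P1 = integer(0)))
  expect_equal(nrow(occupancy(tr0$frames)), 0)
  expect_equal(occupancy(tr0$frames, pairs = tr0$pairs)$occupancy_pct, 0)
})

test_that("occupancy over a union window is the frame-weighted mean of windows", {
  tr <- make_trajectory(8, n_frames = 20, n_pairs = 1,
                        bond_schedule = list(P1 = c(1:4, 11:19)))
  o1 <- occupancy(tr$frames, pairs = tr$pairs, window = 1:8)$occupancy_pct
  o2 <- occupancy(tr$frames, pairs = tr$pairs, window = 9:20)$occupancy_pct
  o <- occupancy(tr$frames, pairs = tr$pairs, window = 1:20)$occupancy_pct
  expect_equal(o, (8 * o1 + 12 * o2) / 20)
})

test_that("window strings select trailing/leading frame ranges", {
  expect_equal(parse_window("last:25%", 20), 16:20)
  expect_equal(parse_window("first:10%", 20), 1:2)
  expect_equal(parse_window("all", 4), 1:4)
  expect_error(parse_window("middle:10%", 20), "bad window")
  tr <- make_trajectory(9, n_frames = 20, n_pairs = 1,
                        bond_schedule = list(P1 = 16:20))
  expect_equal(occupancy(tr$frames, pairs = tr$pairs,
                         window = "last:25%")$occupancy_pct, 100)
})

test_that("loosened criteria saturate every catalogued cross-residue pair", {
  tr <- make_trajectory(10, n_frames = 3, n_pairs = 2,
                        bond_schedule = list(P1 = 1:3), n_decoys = 4)
  crit <- hbond_criteria(max_da_dist = 1e6, min_dha_angle = 0)
  occ <- occupancy(tr$frames, criteria = crit)
  expect_true(all(occ$occupancy_pct == 100))
  # donors: 2 OG; acceptors: 2 OE2 + 2 OG + 4 decoy O, minus same-residue OG
  expect_equal(nrow(occ), 2 * 7)
})

test_that("hydrogen-bond detection is rigid-motion invariant", {
  fr <- ideal_frame(3.2)
  base <- detect_hbonds(fr)
  moved <- transform_model(fr, angles = c(12, 144, -61), shift = c(9, -4, 2))
  hb <- detect_hbonds(moved)
  expect_equal(hb$donor, base$donor)
  expect_equal(hb$da_dist, base$da_dist, tolerance = 1e-9)
  expect_equal(hb$dha_angle, base$dha_angle, tolerance = 1e-6)
})

test_that("hydrogen-free frames fall back to distance-only mode", {
  fr <- ideal_frame(2.9)
  fr$atoms <- fr$atoms[fr$atoms$element != "H", ]
  hb <- detect_hbonds(fr)
  expect_true(attr(hb, "distance_only"))
  expect_equal(nrow(hb), 1)
  expect_true(is.na(hb$dha_angle))
})

test_that("mismatched rosters across frames raise a consistency error", {
  tr <- make_trajectory(3, n_frames = 2, n_pairs = 1,
                        bond_schedule = list(P1 = 1:2))
  broken <- tr$frames
  broken[[2]]$atoms <- broken[[2]]$atoms[-1, ]
  expect_error(occupancy(broken, pairs = tr$pairs), "rosters differ")
  expect_error(detect_hbonds(structure_model(
    data.frame(chain = character(0), res_seq = integer(0),
               res_name = character(0), atom_name = character(0),
               element = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0)))), "empty frame")
})
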