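# inter-chain anchor distances, separation classification, disulfide distance

two_chain_traj <- function(co1, co2, n_res = nrow(co1)) {
  atoms <- rbind(ca_line_atoms(n_res, chain = "A"),
                 ca_line_atoms(n_res, chain = "B"))
  trajectory(atoms, matrix(c(xyz_row(co1), xyz_row(co2)), nrow = 1))
}

test_that("anchor distance is plain euclidean CA-CA geometry", {
  co1 <- noncollinear_ca(4)
  co1[2, ] <- c(0, 0, 0)
  co2 <- co1
  co2[2, ] <- c(3, 4, 0)      # 3-4-5 triangle at anchor residue 2
  traj <- two_chain_traj(co1, co2)
  ad <- anchor_distances(traj, "A", "B", anchors = 2)
  expect_equal(ad$d_2, 5.0)

  same <- two_chain_traj(co1, co1)
  ad0 <- anchor_distances(same, "A", "B", anchors = c(1, 2, 4))
  expect_equal(unlist(ad0[, -1]), c(0, 0, 0), ignore_attr = TRUE)

  expect_error(anchor_distances(traj, "A", "B", anchors = 99),
               "anchor residue 99")
})

test_that("a scripted separating dimer follows distance(t) = d0 + rate * t", {
  h <- static_backbone_traj(n_res = 8, n_frames = 50)
  dim_traj <- make_dimer(h, "separating", rate = 1, start_frame = 1,
                         initial_offset = 10, jitter_sd = 0, seed = 1)
  ad <- anchor_distances(dim_traj, "A", "B", anchors = c(353, 356))
  expected <- 10 + pmax(0, seq_len(50) - 1)
  expect_equal(ad$d_353, expected, tolerance = 1e-9)
  expect_equal(ad$d_356, expected, tolerance = 1e-9)
})

test_that("separation classification: growth separates, oscillation stays stable", {
  t_ps <- 100 * (0:99)
  grow <- data.frame(time_ps = t_ps, d_360 = seq(5, 250, length.out = 100))
  class(grow) <- c("anchor_distances", "data.frame")
  v <- classify_separation(grow, threshold_A = 50, persistence_fraction = 0.2)
  expect_equal(v$label, "separated")
  expect_equal(v$max_distance_A, 250)
  # onset = first frame of the terminal excursion above the threshold
  first_above <- max(which(grow$d_360 <= 50)) + 1
  expect_equal(v$onset_time_ps, t_ps[first_above])

  osc <- data.frame(time_ps = t_ps, d_360 = 5 + 3 * abs(sin(1:100)))
  class(osc) <- c("anchor_distances", "data.frame")
  expect_equal(classify_separation(osc, 50, 0.2)$label, "stable")

  # single-frame spike then return: persistence rule keeps it stable
  spike <- osc
  spike$d_360[50] <- 120
  expect_equal(classify_separation(spike, 50, 0.2)$label, "stable")
})

test_that("verdicts match the generator's scripted scenarios", {
  h <- static_backbone_traj(n_res = 8, n_frames = 40)
  sep <- make_dimer(h, "separating", rate = 2, start_frame = 5,
                    initial_offset = 10, jitter_sd = 0, seed = 2)
  ad <- anchor_distances(sep, "A", "B", anchors = c(352, 355, 359))
  expect_equal(classify_separation(ad)$label, "separated")

  stab <- make_dimer(h, "stable", initial_offset = 10, jitter_sd = 0.1,
                     seed = 3)
  ads <- anchor_distances(stab, "A", "B", anchors = c(352, 355, 359))
  expect_equal(classify_separation(ads)$label, "stable")

  # rate 0 separating mode degenerates to stable
  r0 <- make_dimer(h, "separating", rate = 0, initial_offset = 10,
                   jitter_sd = 0, seed = 4)
  adr <- anchor_distances(r0, "A", "B", anchors = c(352, 355, 359))
  expect_equal(classify_separation(adr)$label, "stable")
})

test_that("anchor distances are invariant under a global rigid transform", {
  h <- static_backbone_traj(n_res = 6, n_frames = 5)
  dim_traj <- make_dimer(h, "separating", rate = 3, initial_offset = 12,
                         jitter_sd = 0, seed = 5)
  ad <- anchor_distances(dim_traj, "A", "B", anchors = 354)
  set.seed(8)
  moved <- transform_traj(dim_traj, random_rotation(), c(7, -1, 4))
  ad2 <- anchor_distances(moved, "A", "B", anchors = 354)
  expect_equal(ad2$d_354, ad$d_354, tolerance = 1e-8)
})

test_that("disulfide distance uses SG atoms and falls back to CA with a flag", {
  n_res <- 3
  mk_chain <- function(chain, sg_z) {
    atoms <- data.frame(
      chain = chain, resno = rep(418:420, each = 2), resname = "CYS",
      atom = rep(c("CA", "SG"), 3), element = rep(c("C", "S"), 3),
      polymer = TRUE, stringsAsFactors = FALSE)
    co <- matrix(0, 6, 3)
    co[, 1] <- rep(3 * (1:3), each = 2)
    co[seq(2, 6, 2), 3] <- sg_z
    list(atoms = atoms, co = co)
  }
  c1 <- mk_chain("A", 0); c2 <- mk_chain("B", 2.05)
  traj <- trajectory(rbind(c1$atoms, c2$atoms),
                     matrix(c(xyz_row(c1$co), xyz_row(c2$co)), nrow = 1))
  d <- disulfide_distance(traj, "A", "B", 419, 419)
  expect_equal(d$distance_A, 2.05)
  expect_equal(d$atom, "SG")

  c2b <- mk_chain("B", 7.0)
  traj7 <- trajectory(rbind(c1$atoms, c2b$atoms),
                      matrix(c(xyz_row(c1$co), xyz_row(c2b$co)), nrow = 1))
  expect_equal(disulfide_distance(traj7, "A", "B", 419, 419)$distance_A, 7.0)

  # no SG anywhere: CA fallback, flagged
  ca_only <- two_chain_traj(noncollinear_ca(4),
                            sweep(noncollinear_ca(4), 2, c(5, 0, 0), "+"))
  expect_warning(dca <- disulfide_distance(ca_only, "A", "B", 2, 2),
                 "falling back")
  expect_equal(dca$atom, "CA")
  expect_equal(dca$distance_A, 5.0)
})
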