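# ion occupancy, binding onset, bound-count series

# manual system: n_res CA-only residues plus one ion whose per-frame
# distance to residue `target` is scripted
scripted_ion_traj <- function(dists, target = 3, n_res = 5) {
  atoms <- rbind(ca_line_atoms(n_res), ion_atoms(1, "Ca"))
  co <- noncollinear_ca(n_res)
  xyz <- t(vapply(dists, function(d) {
    ion <- co[target, ] + c(0, 0, d)
    c(xyz_row(co), ion)
  }, numeric(3 * n_res + 3)))
  trajectory(atoms, xyz)
}

test_that("occupancy is 1 within the cutoff and 0 beyond it", {
  traj <- scripted_ion_traj(rep(2.0, 4))
  occ <- ion_occupancy(traj, "Ca", 3.0)
  expect_equal(occ$occupancy[occ$resno == 3], 1.0)

  traj5 <- scripted_ion_traj(rep(5.0, 4))
  occ5 <- ion_occupancy(traj5, "Ca", 3.0)
  expect_equal(occ5$occupancy, rep(0, 5))
})

test_that("scripted fractional occupancy is recovered exactly", {
  h <- static_backbone_traj(n_res = 6, n_frames = 10)
  sched <- data.frame(target_resno = 354, bind_frame = 1, unbind_frame = 7)
  traj <- add_ions(h, sched, element = "Ca", seed = 3)
  occ <- ion_occupancy(traj, "Ca", 3.0)
  expect_equal(occ$occupancy[occ$resno == 354], 0.7)
})

test_that("binding onset follows the schedule and the persistence rule", {
  h <- static_backbone_traj(n_res = 6, n_frames = 60)
  sched <- data.frame(target_resno = c(353, 355, 356),
                      bind_frame = c(40, NA, 20),
                      unbind_frame = c(NA, NA, 20))  # 3rd: 1-frame contact
  traj <- add_ions(h, sched, element = "Ca", seed = 4)

  ons <- binding_onset(traj, "Ca", 3.0, persistence_frames = 10)
  expect_equal(ons$status, c("bound", "never", "never"))
  expect_equal(ons$onset_time_ps[1], traj$time_ps[40])

  # persistence 1 accepts the single-frame grazing contact
  ons1 <- binding_onset(traj, "Ca", 3.0, persistence_frames = 1)
  expect_equal(ons1$status[3], "bound")
  expect_equal(ons1$onset_time_ps[3], traj$time_ps[20])
})

test_that("bound-count series reflects the number of scripted bound ions", {
  h <- static_backbone_traj(n_res = 8, n_frames = 12)
  sched <- data.frame(target_resno = rep(352:357, length.out = 13),
                      bind_frame = 5, unbind_frame = NA)
  traj <- add_ions(h, sched, element = "Ca", seed = 5)
  cnt <- bound_count_series(traj, "Ca", 3.0)
  expect_equal(cnt$n_bound[1:4], rep(0, 4))
  expect_equal(cnt$n_bound[5:12], rep(13, 8))

  # half the ions bound
  sched2 <- data.frame(target_resno = rep(352:355, 3),
                       bind_frame = rep(c(1, NA), each = 6),
                       unbind_frame = NA)
  traj2 <- add_ions(h, sched2, element = "Ca", seed = 6)
  expect_equal(bound_count_series(traj2, "Ca", 3.0)$n_bound,
               rep(6, 12))
})

test_that("a missing ion element is an error naming the element", {
  h <- static_backbone_traj(n_res = 5, n_frames = 2)
  expect_error(ion_occupancy(h, "Ca"), "'Ca'")
  expect_error(bound_count_series(h, "Na"), "'Na'")
})

test_that("occupancy is monotone non-decreasing in the cutoff", {
  h <- static_backbone_traj(n_res = 6, n_frames = 8)
  sched <- data.frame(target_resno = c(353, 356), bind_frame = c(1, 4),
                      unbind_frame = c(6, NA))
  traj <- add_ions(h, sched, element = "Ca", seed = 7)
  cuts <- c(1, 2, 2.5, 3, 5, 10, 30)
  occs <- sapply(cuts, function(ct) ion_occupancy(traj, "Ca", ct)$occupancy)
  expect_true(all(diff(t(occs)) >= -1e-12))
})

test_that("vectorized occupancy equals the brute-force triple loop exactly", {
  g <- make_helix_with_tails(n_res = 7, core_range = c(3, 5),
                             n_frames = 6, seed = 9)
  sched <- data.frame(target_resno = c(353, 355), bind_frame = c(1, 3),
                      unbind_frame = c(4, NA))
  traj <- add_ions(g$trajectory, sched, element = "Ca", seed = 10)
  occ <- ion_occupancy(traj, "Ca", 3.0)

  a <- traj$atoms
  ions <- which(!a$polymer & a$element == "Ca")
  res <- polymer_residues(traj)
  brute <- numeric(nrow(res))
  for (r in seq_len(nrow(res))) {
    heavy <- which(a$polymer & a$chain == res$chain[r] &
                     a$resno == res$resno[r] & a$element != "H")
    hit <- 0L
    for (f in seq_len(n_frames(traj))) {
      co <- frame_coords(traj, f)
      found <- FALSE
      for (i in ions) for (hh in heavy) {
        if (sqrt(sum((co[i, ] - co[hh, ])^2)) <= 3.0) found <- TRUE
      }
      hit <- hit + found
    }
    brute[r] <- hit / n_frames(traj)
  }
  expect_identical(occ$occupancy, brute)
})
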