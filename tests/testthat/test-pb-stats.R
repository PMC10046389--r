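# PB profiles, Neq, Delta-Neq, Delta-PB

mk_pbs <- function(mat) {
  # character matrix (frames x positions) with resno column names
  colnames(mat) <- seq_len(ncol(mat)) + 351L
  mat
}

test_that("profile frequencies follow the observed counts", {
  pbs <- mk_pbs(matrix(c(rep("m", 10)), ncol = 1))
  prof <- pb_profile(pbs)
  expect_equal(unname(prof$freq["m", 1]), 1)
  expect_equal(sum(prof$freq[, 1]), 1)

  pbs2 <- mk_pbs(matrix(c("m", "m", "d", "d"), ncol = 1))
  prof2 <- pb_profile(pbs2)
  expect_equal(unname(prof2$freq["m", 1]), 0.5)
  expect_equal(unname(prof2$freq["d", 1]), 0.5)
})

test_that("Z observations are excluded, never counted as a 17th state", {
  pbs <- mk_pbs(matrix(c("m", "d", "Z", "Z", "d", "Z"), ncol = 2))
  prof <- pb_profile(pbs)
  expect_equal(unname(prof$n_assignable), c(2L, 1L))
  expect_equal(unname(prof$freq["m", 1]), 0.5)
  expect_equal(sum(prof$freq[, 1]), 1)
  # a never-assignable position is flagged and Neq is NA there
  pbs2 <- mk_pbs(matrix(c("m", "m", "Z", "Z"), ncol = 2))
  prof2 <- pb_profile(pbs2)
  expect_false(prof2$assignable[2])
  expect_true(is.na(neq(prof2)[2]))
})

test_that("Neq closed forms: single block 1, uniform 16, entropy inverse", {
  single <- pb_profile_from_freq(c(1, rep(0, 15)))
  expect_equal(unname(unclass(neq(single))), 1)

  uniform <- pb_profile_from_freq(rep(1 / 16, 16))
  expect_equal(unname(unclass(neq(uniform))), 16)

  f <- c(0.5, 0.25, 0.25, rep(0, 13))
  expect_equal(unname(unclass(neq(pb_profile_from_freq(f)))),
               exp(1.5 * log(2)), tolerance = 1e-12)
})

test_that("Neq equals exp(Shannon entropy) from an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (i in 1:20) {
    f <- random_freq()
    ours <- unclass(neq(pb_profile_from_freq(f)))
    oracle <- exp(vegan::diversity(f, index = "shannon"))
    expect_equal(unname(ours), unname(oracle), tolerance = 1e-10)
  }
})

test_that("delta_neq is the absolute difference at aligned positions", {
  n1 <- structure(c(`352` = 1, `353` = 2), class = "neq_profile")
  n2 <- structure(c(`352` = 16, `353` = 7), class = "neq_profile")
  d <- delta_neq(n1, n2)
  expect_equal(d$delta_neq, c(15, 5))
  expect_equal(delta_neq(n1, n1)$delta_neq, c(0, 0))
})

test_that("delta_pb spans 0 (identity) to 2 (disjoint support)", {
  pm <- pb_profile_from_freq(c(rep(0, 12), 1, rep(0, 3)), resno = 352)  # all m
  pd <- pb_profile_from_freq(c(0, 0, 0, 1, rep(0, 12)), resno = 352)    # all d
  expect_equal(delta_pb(pm, pm)$delta_pb, 0)
  expect_equal(delta_pb(pm, pd)$delta_pb, 2)

  p1 <- pb_profile_from_freq(c(1, rep(0, 15)), resno = 352)
  p2 <- pb_profile_from_freq(c(0.5, 0.5, rep(0, 14)), resno = 352)
  expect_equal(delta_pb(p1, p2)$delta_pb, 1)
})

test_that("divergences are symmetric and respect their bounds on random profiles", {
  set.seed(77)
  for (i in 1:50) {
    f1 <- random_freq(); f2 <- random_freq()
    p1 <- pb_profile_from_freq(f1, 400); p2 <- pb_profile_from_freq(f2, 400)
    d12 <- delta_pb(p1, p2)$delta_pb
    d21 <- delta_pb(p2, p1)$delta_pb
    expect_equal(d12, d21)
    expect_gte(d12, 0); expect_lte(d12, 2)
    nn1 <- neq(p1); nn2 <- neq(p2)
    dn <- delta_neq(nn1, nn2)$delta_neq
    expect_equal(dn, delta_neq(nn2, nn1)$delta_neq)
    expect_gte(dn, 0); expect_lte(dn, 15)
    expect_gte(min(unclass(nn1), unclass(nn2)), 1)
    expect_lte(max(unclass(nn1), unclass(nn2)), 16)
  }
})

test_that("systems of unequal length align by author number or pairing map", {
  p1 <- pb_profile(mk_pbs(matrix("m", 4, 4)))           # 352..355
  pbs2 <- matrix("d", 4, 6); colnames(pbs2) <- 354:359  # offset, longer
  p2 <- pb_profile(pbs2)
  expect_warning(d <- delta_pb(p1, p2), "unaligned")
  expect_equal(d$pos1, c(354, 355))
  # explicit pairing map overrides identity alignment
  pair <- data.frame(pos1 = c(352, 353), pos2 = c(358, 359))
  d2 <- delta_pb(p1, p2, pairing = pair)
  expect_equal(d2$delta_pb, c(2, 2))
  # disjoint numbering without a map is an error
  pbs3 <- matrix("m", 2, 2); colnames(pbs3) <- 900:901
  expect_error(suppressWarnings(delta_pb(p1, pb_profile(pbs3))),
               "no aligned positions")
})

test_that("the exported PB map mirrors the profile exactly", {
  g <- sample_system(9, rep(1 / 16, 16), jitter_deg = 0, n_frames = 20,
                     seed = 12)
  prof <- pb_profile(assign_pbs(compute_phi_psi(g$trajectory, "A")))
  map <- export_pb_map(prof)
  expect_equal(map$pb, letters[1:16])
  sums <- colSums(as.matrix(map[, -1]))
  expect_equal(unname(sums[prof$assignable]),
               rep(1, sum(prof$assignable)))
  expect_equal(as.matrix(map[, -1]), prof$freq, ignore_attr = TRUE)

  path <- withr::local_tempfile(fileext = ".tsv")
  export_pb_map(prof, path, params = list(seed = 12))
  back <- read_tsv_provenance(path)
  expect_equal(ncol(back), 1L + length(prof$resno))
  expect_match(attr(back, "provenance")[1], "pbtraj")
})

test_that("profiles sampled from a known mixture converge to it", {
  mix <- rep(0, 16); mix[13] <- 0.7; mix[4] <- 0.3
  g <- sample_system(9, mix, jitter_deg = 5, n_frames = 600, seed = 9,
                     frame_coherent = TRUE)
  prof <- pb_profile(assign_pbs(compute_phi_psi(g$trajectory, "A")))
  center <- 5
  tv <- 0.5 * sum(abs(prof$freq[, center] - mix))
  # 3 sigma of the binomial sampling noise at n = 600
  expect_lt(tv, 3 * sqrt(0.7 * 0.3 / 600))
  expect_equal(unname(unclass(neq(prof))[center]),
               exp(-(0.7 * log(0.7) + 0.3 * log(0.3))),
               tolerance = 0.1)
})
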