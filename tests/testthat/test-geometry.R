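torsion1 <- function(q) phycofret:::torsion_deg(q[1, , drop = FALSE],
                                                q[2, , drop = FALSE],
                                                q[3, , drop = FALSE],
                                                q[4, , drop = FALSE])

test_that("signed torsions match the standard convention and bio3d", {
  expect_equal(torsion1(quartet_with_torsion(0)), 0, tolerance = 1e-10)
  expect_equal(abs(torsion1(quartet_with_torsion(180))), 180, tolerance = 1e-8)
  expect_equal(torsion1(quartet_with_torsion(75)), 75, tolerance = 1e-8)
  expect_equal(torsion1(quartet_with_torsion(-100)), -100, tolerance = 1e-8)

  set.seed(8)
  for (i in 1:25) {
    q <- matrix(rnorm(12, sd = 2), 4, 3)
    mine <- torsion1(q)
    oracle <- bio3d::torsion.xyz(as.vector(t(q)), atm.inc = 4)
    expect_equal(mine, oracle, tolerance = 1e-6)
    # reversal invariance and reflection antisymmetry
    expect_equal(torsion1(q[4:1, ]), mine, tolerance = 1e-8)
    qm <- q; qm[, 3] <- -qm[, 3]
    expect_equal(torsion1(qm), -mine, tolerance = 1e-8)
  }
})

test_that("chi angles land in the standard rotamer bins", {
  expect_equal(phycofret:::chi_state(c(75, 1, 120)), c("g+", "g+", "g+"))
  expect_equal(phycofret:::chi_state(c(121, 180, -150, -121)), rep("t", 4))
  # the g- bin is the half-open interval (-120, 0]: -120 itself is trans
  expect_equal(phycofret:::chi_state(c(-1, -75, -119.9, 0)), rep("g-", 4))
  expect_equal(phycofret:::chi_state(-120), "t")
})

test_that("lysine chi series reports occupancies that sum to one", {
  tr <- simulate_trajectory(trajectory_spec(n_frames = 20, seed = 4))
  rot <- chi_dihedrals(tr, "A", 6)
  expect_equal(dim(rot$chi), c(20, 4))
  expect_true(all(rot$chi > -180 & rot$chi <= 180))
  expect_equal(sum(rot$occupancy), 1, tolerance = 1e-9)
  # the planar all-anti toy side chain is the t|t|t|t rotamer
  expect_equal(names(rot$occupancy), "t|t|t|t")
  expect_error(chi_dihedrals(tr, "A", 50), "missing side-chain atom")
  expect_error(chi_dihedrals(tr, "Z", 6), "not found")
})

test_that("contact frequencies are exact for constructed occupancy", {
  spec <- trajectory_spec(n_frames = 10, fluctuation_sigma = 0, seed = 1)
  tr <- simulate_trajectory(spec)
  sites <- classify_pockets(tr$topology)
  mono <- which(sites$pocket == "monomer" & sites$chain == "B")
  # displace the monomer bilin far away in frames 4..10 (in contact 30%)
  idx <- attr(sites, "atom_idx")[[mono]]
  for (f in 4:10) tr$xyz[f, 3 * idx] <- tr$xyz[f, 3 * idx] + 100
  cm <- contact_frequency(tr, sites[mono, ], window = c(1, 10), cutoff = 4.0)
  a50 <- cm$frequency[cm$chain == "A" & cm$resno == 50]
  b50 <- cm$frequency[cm$chain == "B" & cm$resno == 50]
  expect_equal(a50, 0.3)
  expect_equal(b50, 0.3)
  # residues of remote chains never touch this chromophore
  expect_true(all(cm$frequency[cm$chain %in% c("C", "D", "E", "F")] == 0))
  expect_true(all(cm$frequency >= 0 & cm$frequency <= 1))
  # monotone non-decreasing in the cutoff
  cm2 <- contact_frequency(tr, sites[mono, ], window = c(1, 10), cutoff = 6.0)
  expect_true(all(cm2$frequency >= cm$frequency))
  expect_error(contact_frequency(tr, sites[mono, ], window = integer(0)),
               "empty")
})

test_that("salt-bridge series flags formed, broken, and two-state bridges", {
  apo <- simulate_trajectory(trajectory_spec("apo", n_frames = 10,
                                             fluctuation_sigma = 0, seed = 1))
  sb <- salt_bridge_series(apo, c("A", 6), c("A", 100))
  expect_equal(sb$bound_fraction, 1.0)
  expect_equal(unique(round(sb$min_NO_distance, 6)), 2.8)

  co2 <- simulate_trajectory(trajectory_spec("co2", n_frames = 10,
                                             fluctuation_sigma = 0, seed = 1))
  sb2 <- salt_bridge_series(co2, c("A", 6), c("A", 100))
  expect_equal(sb2$bound_fraction, 0.0)
  expect_equal(unique(round(sb2$min_NO_distance, 6)), 8.0)

  # first half formed, second half broken -> 0.5 by construction
  half <- apo
  half$xyz <- rbind(apo$xyz[1:5, ], co2$xyz[1:5, ])
  sbh <- salt_bridge_series(half, c("A", 6), c("A", 100))
  expect_equal(sbh$bound_fraction, 0.5)

  expect_error(salt_bridge_series(apo, c("A", 50), c("A", 100)), "NZ")
  expect_error(salt_bridge_series(apo, c("A", 6), c("A", 50)), "carboxylate")
})

test_that("pair distances recover the configured state geometry", {
  # zero fluctuation: exactly the configured means
  tr0 <- simulate_trajectory(trajectory_spec(n_frames = 3,
                                             fluctuation_sigma = 0, seed = 1))
  s0 <- classify_pockets(tr0$topology)
  d0 <- pair_distances(tr0, s0)
  expect_equal(length(d0), 3)
  for (d in d0) expect_equal(as.numeric(d), rep(24.5, 3), tolerance = 1e-6)

  # apo: all three medians in 24-25 A within 3 SE of the mean setting
  apo <- simulate_trajectory(trajectory_spec("apo", n_frames = 2000, seed = 21))
  da <- pair_distances(apo, classify_pockets(apo$topology))
  for (d in da) {
    se <- 1.2533 * stats::sd(d) / sqrt(length(d))
    expect_lt(abs(stats::median(d) - 24.5), 3 * se + 0.02)
    expect_true(stats::median(d) > 24 && stats::median(d) < 25)
  }

  # co2: the designated pair contracts to ~22 A, the others stay put
  co2 <- simulate_trajectory(trajectory_spec("co2", n_frames = 2000, seed = 22))
  dc <- pair_distances(co2, classify_pockets(co2$topology))
  med <- sort(vapply(dc, stats::median, numeric(1)))
  expect_lt(abs(med[1] - 22.0), 0.1)
  expect_true(all(med[2:3] > 24 & med[2:3] < 25))

  # configured 2.5 A shift recovered within 3 SE
  shift <- stats::median(da[[1]]) - med[1]
  se_sh <- 1.2533 * sqrt(stats::var(da[[1]]) / length(da[[1]]) +
                           stats::var(dc[[1]]) / length(dc[[1]]))
  expect_lt(abs(shift - 2.5), 3 * se_sh + 0.03)

  # unclassified sites are rejected
  s_un <- chromophore_sites(tr0$topology)
  expect_error(pair_distances(tr0, s_un), "unclassified")
})

test_that("geometric observables are invariant under a global rigid transform", {
  spec <- trajectory_spec("co2", n_frames = 50, seed = 9)
  tr <- simulate_trajectory(spec)
  sites <- classify_pockets(tr$topology)
  d_ref <- pair_distances(tr, sites)
  sb_ref <- salt_bridge_series(tr, c("A", 6), c("A", 100))
  rot_ref <- chi_dihedrals(tr, "A", 6)

  set.seed(77)
  R <- random_rotation(); tvec <- c(30, -12, 7)
  tr2 <- tr
  for (f in seq_len(nrow(tr$xyz))) {
    m <- phycofret:::frame_coords(tr, f) %*% t(R)
    tr2$xyz[f, ] <- as.vector(t(sweep(m, 2, tvec, "+")))
  }
  tr2$topology <- transform_structure(tr$topology, R, tvec)
  sites2 <- classify_pockets(tr2$topology)
  d_rot <- pair_distances(tr2, sites2)
  for (nm in names(d_ref))
    expect_equal(as.numeric(d_rot[[nm]]), as.numeric(d_ref[[nm]]),
                 tolerance = 1e-9)
  expect_equal(salt_bridge_series(tr2, c("A", 6), c("A", 100))$min_NO_distance,
               sb_ref$min_NO_distance, tolerance = 1e-9)
  # compare as angles: +/-180 are the same torsion
  dang <- ((chi_dihedrals(tr2, "A", 6)$chi - rot_ref$chi + 180) %% 360) - 180
  expect_lt(max(abs(dang)), 1e-6)
})

test_that("distance histograms preserve mass, mean and mode", {
  const <- rep(24.5, 100)
  h <- distance_histogram(const, bin_width = 0.25)
  expect_equal(sum(h$frequencies), 1, tolerance = 1e-9)
  expect_equal(sum(h$frequencies > 0), 1)
  expect_equal(max(h$frequencies), 1.0)

  set.seed(123)
  x <- rnorm(30000, mean = 22, sd = 0.4)
  hg <- distance_histogram(x, bin_width = 0.25)
  mode_bin <- which.max(hg$frequencies)
  expect_true(hg$bin_edges[mode_bin] <= 22.0 &&
                hg$bin_edges[mode_bin + 1] >= 22.0)
  # histogram mean consistent with the series mean within half a bin width
  bw <- 0.25
  ctr <- hg$bin_edges[-length(hg$bin_edges)] + bw / 2
  expect_lt(abs(sum(ctr * hg$frequencies) - mean(x)), bw / 2)
  expect_equal(hg$summary$median, stats::median(x))

  counts <- distance_histogram(x, bin_width = 0.25, normalised = FALSE)
  expect_equal(sum(counts$frequencies), 30000)
  expect_error(distance_histogram(x, bin_width = 0), "bin_width")
  expect_error(distance_histogram(numeric(0)), "empty")
})
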