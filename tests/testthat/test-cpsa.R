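# CPSA descriptors: hand-computed examples, brute-force loop oracles,
# the PPSA1 + PNSA1 = TMSA identity and rigid-motion invariance.

hand_profile <- function(charges, areas) {
  n <- length(charges)
  mol <- molecule(
    data.frame(element = rep("C", n), x = seq_len(n) * 4, y = 0, z = 0,
               formal_charge = 0L),
    data.frame(i = integer(), j = integer(), order = integer()), id = "hand")
  surface_charge_profile(mol, charge = charges, area = areas,
                         scheme = "test", probe = 1.4, radii_set = "bondi",
                         n_points = 960L)
}

test_that("CPSA descriptors reproduce hand-computed values", {
  p <- hand_profile(c(0.2, -0.1, 0.05), c(10, 20, 5))
  expect_equal(ppsa1(p), 15)
  expect_equal(pnsa1(p), 20)
  expect_equal(fpsa3(p), (0.2 * 10 + 0.05 * 5) / 35)
  expect_equal(wnsa1(hand_profile(c(-1, 1), c(20, 15))), 20 * 35 / 1000)
  expect_equal(rncg(hand_profile(c(-0.5, -0.25, 0.75), c(1, 1, 1))),
               0.5 / 0.75)
  expect_equal(rncg(hand_profile(c(-0.3, 0.3), c(1, 1))), 1.0)
})

test_that("degenerate partitions behave as defined", {
  all_neg <- hand_profile(c(-0.1, -0.2), c(10, 20))
  expect_equal(ppsa1(all_neg), 0)
  expect_equal(ppsa3(all_neg), 0)
  expect_equal(fpsa3(all_neg), 0)
  all_pos <- hand_profile(c(0.1, 0.2), c(10, 20))
  expect_equal(wnsa1(all_pos), 0)
  expect_error(rncg(all_pos), "undefined")
})

test_that("descriptors equal brute-force loop oracles on random profiles", {
  for (seed in 1:5) {
    p <- random_profile(n = 50, seed = seed)
    pp1 <- pn1 <- pp3 <- 0
    neg_sum <- 0; neg_max <- 0
    for (i in seq_along(p$charge)) {
      if (p$charge[i] > 0) {
        pp1 <- pp1 + p$area[i]
        pp3 <- pp3 + p$charge[i] * p$area[i]
      } else {
        pn1 <- pn1 + p$area[i]
      }
      if (p$charge[i] < 0) {
        neg_sum <- neg_sum + abs(p$charge[i])
        neg_max <- max(neg_max, abs(p$charge[i]))
      }
    }
    expect_equal(ppsa1(p), pp1, tolerance = 1e-12)
    expect_equal(pnsa1(p), pn1, tolerance = 1e-12)
    expect_equal(ppsa3(p), pp3, tolerance = 1e-12)
    expect_equal(wnsa1(p), pn1 * sum(p$area) / 1000, tolerance = 1e-12)
    expect_equal(rncg(p), neg_max / neg_sum, tolerance = 1e-12)
    expect_equal(fpsa3(p), pp3 / sum(p$area), tolerance = 1e-12)
    expect_true(rncg(p) > 0 && rncg(p) <= 1)
  }
})

test_that("PPSA1 + PNSA1 equals TMSA exactly on real molecules", {
  for (id in c("1", "3", "5a")) {
    m <- embedded_cached(id)
    prof <- merge_profiles(assign_partial_charges(m),
                           atomic_sasa(m, n_points = 500L))
    expect_equal(ppsa1(prof) + pnsa1(prof), tmsa(prof), tolerance = 1e-12)
  }
})

test_that("hydrogen-donor surface area sums donor hydrogens only", {
  w <- make_water()
  prof <- merge_profiles(assign_partial_charges(w), atomic_sasa(w))
  h_area <- sum(prof$area[w$atoms$element == "H"])
  expect_equal(hdonors_psa(prof, w), h_area)

  # ester 3 has no N-H/O-H: donor area 0
  m3 <- embedded_cached("3")
  prof3 <- merge_profiles(assign_partial_charges(m3),
                          atomic_sasa(m3, n_points = 500L))
  expect_equal(hdonors_psa(prof3, m3), 0)

  # brute-force oracle on ibuprofen (one O-H)
  m1 <- embedded_cached("1")
  prof1 <- merge_profiles(assign_partial_charges(m1),
                          atomic_sasa(m1, n_points = 500L))
  donors <- 0
  for (i in seq_len(n_atoms(m1))) {
    if (m1$atoms$element[i] == "H" &&
        any(m1$atoms$element[bonded_atoms(m1, i)] %in% c("N", "O"))) {
      donors <- donors + prof1$area[i]
    }
  }
  expect_equal(hdonors_psa(prof1, m1), donors, tolerance = 1e-12)
  expect_gt(donors, 0)
})

test_that("CPSA values are invariant under rigid motion", {
  m <- embedded_cached("3")
  base <- cpsa_descriptors(m, n_points = 500L)
  # translation leaves every occlusion decision unchanged: exact invariance
  m_tr <- set_coordinates(m, sweep(coordinates(m), 2, c(5, -3, 2), "+"))
  expect_equal(unclass(cpsa_descriptors(m_tr, n_points = 500L)),
               unclass(base), tolerance = 1e-9)
  # rotation re-samples the fixed quadrature grid, so invariance holds to
  # quadrature accuracy
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  m_rot <- set_coordinates(m, coordinates(m) %*% t(R))
  expect_equal(unclass(cpsa_descriptors(m_rot, n_points = 500L)),
               unclass(base), tolerance = 5e-3)
})

test_that("unknown descriptor names are rejected", {
  m <- embedded_cached("3")
  expect_error(cpsa_descriptors(m, descriptors = c("ppsa1", "nope")),
               "unknown CPSA descriptor")
})
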