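# Extended Hueckel engine and the frontier-orbital / energy descriptors:
# closed-form overlap checks, symmetry patterns and brute-force oracles.

test_that("STO overlap matches closed forms and a quadrature oracle", {
  # 1s-1s with equal exponents: S = exp(-rho)(1 + rho + rho^2/3)
  for (rho in c(0.8, 1.4, 2.5)) {
    expect_equal(sto_overlap(1, 0, 1, 0, 1, 1, rho),
                 exp(-rho) * (1 + rho + rho^2 / 3), tolerance = 1e-10)
  }
  # frozen values from independent 2D quadrature of the raw integrand
  expect_equal(sto_overlap(2, 1, 2, 1, 1.625, 1.625, 2.5, m = 0),
               -0.322352, tolerance = 1e-4)
  expect_equal(sto_overlap(2, 1, 2, 1, 1.625, 1.625, 2.5, m = 1),
               0.277602, tolerance = 1e-4)
  expect_equal(sto_overlap(1, 0, 2, 1, 1.3, 1.625, 2.0, m = 0),
               -0.502014, tolerance = 1e-4)
  expect_equal(sto_overlap(2, 0, 3, 1, 1.625, 1.733, 3.0, m = 0),
               -0.462505, tolerance = 1e-4)
  expect_equal(sto_overlap(3, 1, 3, 1, 1.733, 1.733, 4.0, m = 1),
               0.142136, tolerance = 1e-4)
  # s|p sigma overlap is antisymmetric under centre exchange
  expect_equal(sto_overlap(2, 1, 1, 0, 1.625, 1.3, 2.0),
               -sto_overlap(1, 0, 2, 1, 1.3, 1.625, 2.0), tolerance = 1e-12)
})

test_that("H2 gives a symmetric bonding HOMO and correct bookkeeping", {
  es <- build_electronic_structure(make_h2())
  expect_equal(nrow(es$basis), 2)
  expect_equal(es$n_electrons, 2)
  expect_equal(abs(es$C[1, es$homo]), abs(es$C[2, es$homo]),
               tolerance = 1e-10)
  expect_lt(es$energies[es$homo], es$energies[es$lumo])
  # coefficients normalised under the overlap metric
  expect_equal(diag(t(es$C) %*% es$S %*% es$C), rep(1, 2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("benzene reproduces the simple-Hueckel pi-block pattern", {
  es <- build_electronic_structure(make_benzene())
  expect_equal(sum(es$occ), 30)  # valence electron count
  # pi MOs carry only pz character (ring in the xy plane)
  pz <- which(es$basis$type == "pz")
  pi_weight <- colSums(es$C[pz, , drop = FALSE]^2) /
    colSums(es$C^2)
  pi_mos <- which(pi_weight > 0.99)
  expect_length(pi_mos, 6)
  e_pi <- sort(es$energies[pi_mos])
  # pattern 1 - 2 - 2 - 1: two degenerate pairs within 1e-6 eV
  expect_lt(e_pi[3] - e_pi[2], 1e-6)
  expect_lt(e_pi[5] - e_pi[4], 1e-6)
  expect_gt(e_pi[2] - e_pi[1], 0.1)
  expect_gt(e_pi[4] - e_pi[3], 0.1)
  # the degenerate pi pair is the HOMO
  expect_equal(sort(pi_mos)[2:3], c(es$homo - 1L, es$homo))
})

test_that("density matrix satisfies trace and idempotency conditions", {
  for (id in c("benzene", "water")) {
    mol <- if (id == "benzene") make_benzene() else make_water()
    es <- build_electronic_structure(mol)
    expect_equal(sum(diag(es$P_orth)), es$n_electrons, tolerance = 1e-6)
    expect_lt(max(abs(es$P_orth %*% es$P_orth - 2 * es$P_orth)), 1e-6)
    expect_true(all(diff(es$energies) >= -1e-10))
  }
})

test_that("orbital energies are invariant under rigid rotation", {
  m <- make_water()
  e1 <- build_electronic_structure(m)$energies
  th <- 1.1; ax <- c(2, -1, 1) / sqrt(6)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  m2 <- set_coordinates(m, sweep(coordinates(m) %*% t(R), 2, c(1, 2, 3), "+"))
  e2 <- build_electronic_structure(m2)$energies
  expect_equal(e2, e1, tolerance = 1e-6)
})

test_that("open-shell systems are rejected", {
  cation <- molecule(
    data.frame(element = c("C", "H", "H", "H"), x = c(0, 1, -0.5, -0.5),
               y = c(0, 0, 0.87, -0.87), z = 0,
               formal_charge = c(0L, 0L, 0L, 0L)),
    data.frame(i = 1L, j = 2:4, order = 1L), id = "methyl")
  expect_error(build_electronic_structure(cation), "odd electron")
})

test_that("reactivity indices reproduce hand arithmetic on a toy structure", {
  es <- build_electronic_structure(make_h2())
  ch <- es$C[1, es$homo]; cl <- es$C[1, es$lumo]
  eh <- es$energies[es$homo]; el <- es$energies[es$lumo]
  expect_equal(nucleophilic_index(es, 1), ch^2 / (1 - eh), tolerance = 1e-12)
  expect_equal(electrophilic_index(es, 1), cl^2 / (el + 10),
               tolerance = 1e-12)
  expect_equal(one_electron_index(es, 1), ch * cl / (el - eh),
               tolerance = 1e-12)
  # symmetric atoms carry identical indices
  expect_equal(nucleophilic_index(es, 1), nucleophilic_index(es, 2),
               tolerance = 1e-10)
  expect_equal(one_electron_index(es, 1)^2, one_electron_index(es, 2)^2,
               tolerance = 1e-10)
})

test_that("indices and energies match brute-force loop oracles", {
  for (seed in 1:4) {
    mol <- random_chain_molecule(n_heavy = 3, seed = seed)
    es <- build_electronic_structure(mol)
    n_at <- n_atoms(mol)
    for (a in seq_len(min(n_at, 3))) {
      idx <- which(es$basis$atom == a)
      # nucleophilic: explicit loop over basis functions
      acc <- 0
      for (mu in idx) acc <- acc + es$C[mu, es$homo]^2
      expect_equal(nucleophilic_index(es, a),
                   acc / (1 - es$energies[es$homo]), tolerance = 1e-12)
      # one-electron: double loop
      acc2 <- 0
      for (mu in idx) for (nu in idx) {
        acc2 <- acc2 + es$C[mu, es$homo] * es$C[nu, es$lumo]
      }
      expect_equal(one_electron_index(es, a),
                   acc2 / (es$energies[es$lumo] - es$energies[es$homo]),
                   tolerance = 1e-12)
    }
    # resonance energy: double loop over the first bond
    b <- mol$bonds[1, ]
    ia <- which(es$basis$atom == b$i); ib <- which(es$basis$atom == b$j)
    acc3 <- 0
    for (mu in ia) for (nu in ib) acc3 <- acc3 + es$P[mu, nu] * es$beta[mu, nu]
    expect_equal(resonance_energy(es, b$i, b$j), acc3, tolerance = 1e-12)
    # state energy: explicit sum over atom pairs
    pops <- vapply(seq_len(n_at), function(a) {
      sum(diag(es$P)[es$basis$atom == a])
    }, numeric(1))
    a <- 1
    acc4 <- 0
    for (bb in seq_len(n_at)) {
      if (bb == a) next
      acc4 <- acc4 + pops[a] * pops[bb] * es$gamma[a, bb] -
        pops[a] * es$core_charge[bb] * es$gamma[a, bb]
    }
    expect_equal(atomic_state_energy(es, a), acc4, tolerance = 1e-10)
  }
})

test_that("zero frontier amplitude on an atom gives zero indices", {
  # methane: the HOMO is triply degenerate but every index is finite;
  # fabricate the zero-amplitude case directly instead
  es <- build_electronic_structure(make_h2())
  es$C[2, es$lumo] <- 0
  es$C[2, es$homo] <- 0
  expect_equal(nucleophilic_index(es, 2), 0)
  expect_equal(electrophilic_index(es, 2), 0)
  expect_equal(one_electron_index(es, 2), 0)
})

test_that("resonance energy toy cases follow the definition", {
  es <- build_electronic_structure(make_h2())
  # beta = 0 forces zero resonance energy
  es0 <- es; es0$beta[] <- 0
  expect_equal(resonance_energy(es0, 1, 2), 0)
  # 1x1 toy: P = 1.2, beta = -2.0 -> -2.4
  es1 <- es
  es1$P[1, 2] <- 1.2; es1$beta[1, 2] <- -2.0
  expect_equal(resonance_energy(es1, 1, 2), -2.4)
  expect_error(resonance_energy(es, 1, 1), "distinct")
})

test_that("element aggregation follows max/min/avg with neutral fallback", {
  m <- embedded_cached("5a")
  es <- build_electronic_structure(m)
  n_atoms_idx <- which(m$atoms$element == "N")
  vals <- vapply(n_atoms_idx, function(a) nucleophilic_index(es, a),
                 numeric(1))
  expect_equal(aggregate_index(es, "nucleophilic", "N", "max"), max(vals))
  expect_equal(aggregate_index(es, "nucleophilic", "N", "min"), min(vals))
  expect_equal(aggregate_index(es, "nucleophilic", "N", "avg"),
               sum(vals) / length(vals))
  expect_error(aggregate_index(es, "nucleophilic", "Qq", "max"),
               "unknown element")
  # no matching atom: neutral 0 with a warning
  expect_warning(out <- aggregate_index(es, "state_energy", "S", "max"),
                 "no S atom")
  expect_equal(out, 0)
  # H-C resonance aggregation needs the bond list
  r <- aggregate_index(es, "resonance", "H-C", "max", mol = m)
  hb <- m$bonds[(m$atoms$element[m$bonds$i] == "H" &
                   m$atoms$element[m$bonds$j] == "C") |
                  (m$atoms$element[m$bonds$i] == "C" &
                     m$atoms$element[m$bonds$j] == "H"), ]
  vals <- mapply(function(i, j) resonance_energy(es, i, j), hb$i, hb$j)
  expect_equal(r, max(vals))
})
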