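# Shared fixtures built in code: small molecules with hand-set geometry and
# random surface-charge profiles / electronic systems for oracle tests.

# tetrahedral methane, C-H 1.09 A
make_methane <- function() {
  s <- 1.09 / sqrt(3)
  molecule(
    data.frame(element = c("C", "H", "H", "H", "H"),
               x = c(0, s, s, -s, -s), y = c(0, s, -s, s, -s),
               z = c(0, s, -s, -s, s), formal_charge = 0L),
    data.frame(i = 1L, j = 2:5, order = 1L), id = "methane")
}

make_water <- function() {
  # O-H 0.96 A, H-O-H 104.5 deg
  a <- 104.5 * pi / 180
  molecule(
    data.frame(element = c("O", "H", "H"),
               x = c(0, 0.96, 0.96 * cos(a)),
               y = c(0, 0, 0.96 * sin(a)), z = 0, formal_charge = 0L),
    data.frame(i = 1L, j = 2:3, order = 1L), id = "water")
}

# idealised D6h benzene (C-C 1.39, C-H 1.08, planar)
make_benzene <- function() {
  ang <- (0:5) * pi / 3
  rc <- 1.39; rh <- rc + 1.08
  molecule(
    data.frame(element = rep(c("C", "H"), each = 6),
               x = c(rc * cos(ang), rh * cos(ang)),
               y = c(rc * sin(ang), rh * sin(ang)),
               z = 0, formal_charge = 0L),
    data.frame(i = c(1:6, 1:6), j = c(2:6, 1L, 7:12),
               order = c(2L, 1L, 2L, 1L, 2L, 1L, rep(1L, 6))),
    id = "benzene")
}

# H2 at the experimental bond length
make_h2 <- function(d = 0.74) {
  molecule(data.frame(element = c("H", "H"), x = c(0, d), y = 0, z = 0,
                      formal_charge = 0L),
           data.frame(i = 1L, j = 2L, order = 1L), id = "H2")
}

# random surface-charge profile over a random rigid cluster
random_profile <- function(n = 50, seed = 1) {
  set.seed(seed)
  els <- sample(c("C", "H", "N", "O"), n, replace = TRUE)
  mol <- molecule(
    data.frame(element = els, x = stats::runif(n, 0, 15),
               y = stats::runif(n, 0, 15), z = stats::runif(n, 0, 15),
               formal_charge = 0L),
    data.frame(i = integer(), j = integer(), order = integer()),
    id = sprintf("random%d", seed))
  surface_charge_profile(
    mol, charge = stats::rnorm(n, sd = 0.2),
    area = stats::runif(n, 0, 30), scheme = "test", probe = 1.4,
    radii_set = "bondi", n_points = 960L)
}

# random small closed-shell hydrocarbon-like chain for electronic oracles
random_chain_molecule <- function(n_heavy = 3, seed = 1) {
  set.seed(seed)
  els <- sample(c("C", "N", "O"), n_heavy, replace = TRUE)
  # zig-zag chain, 1.5 A spacing, capped with enough H to stay closed-shell
  xs <- seq(0, by = 1.5, length.out = n_heavy)
  atoms <- data.frame(element = els, x = xs,
                      y = rep(c(0, 0.5), length.out = n_heavy),
                      z = 0, formal_charge = 0L)
  bonds <- if (n_heavy > 1) {
    data.frame(i = seq_len(n_heavy - 1), j = seq(2, n_heavy), order = 1L)
  } else {
    data.frame(i = integer(), j = integer(), order = integer())
  }
  # hydrogen caps to make every heavy atom tetravalent-ish and the electron
  # count even
  free_val <- c(C = 4L, N = 3L, O = 2L)[els]
  used <- integer(n_heavy)
  for (k in seq_len(nrow(bonds))) {
    used[bonds$i[k]] <- used[bonds$i[k]] + 1L
    used[bonds$j[k]] <- used[bonds$j[k]] + 1L
  }
  n_h_per <- pmax(free_val - used, 0L)
  # drop one hydrogen if needed to keep the valence electron count even
  if ((sum(c(C = 4L, N = 5L, O = 6L)[els]) + sum(n_h_per)) %% 2 == 1) {
    n_h_per[which.max(n_h_per)] <- n_h_per[which.max(n_h_per)] - 1L
  }
  h_count <- 0L
  for (a in seq_len(n_heavy)) {
    for (hh in seq_len(n_h_per[a])) {
      h_count <- h_count + 1L
      phi <- 2 * pi * hh / max(n_h_per[a], 1) + a
      atoms <- rbind(atoms, data.frame(
        element = "H", x = atoms$x[a] + 1.05 * cos(phi),
        y = atoms$y[a] + 1.05 * sin(phi),
        z = 0.5 + 0.3 * hh, formal_charge = 0L))
      bonds <- rbind(bonds, data.frame(i = a, j = n_heavy + h_count,
                                       order = 1L))
    }
  }
  molecule(atoms, bonds, id = sprintf("chain%d", seed))
}

# cached packaged compound set (parsing 18 SMILES once per test session)
fixture_set_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_fixture_set()
    cache
  }
})

# cached embedded molecules
embedded_cached <- local({
  cache <- list()
  function(id) {
    if (is.null(cache[[id]])) {
      cache[[id]] <<- embed_3d(fixture_set_cached()[[id]]$molecule)
    }
    cache[[id]]
  }
})
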