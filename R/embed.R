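# 3D embedding. Surface and orbital descriptors need one reasonable single
# conformer per molecule; conformational averaging is out of scope. The
# embedder is a seeded distance-geometry construction with force-field
# style refinement, so coordinates are a pure function of (structure, seed).

# single-bond covalent radii (Angstrom)
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                     P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
# bond-length contraction by bond order
.order_factor <- c(`1` = 1.00, `2` = 0.88, `3` = 0.79)

.ideal_bond_length <- function(el_i, el_j, order) {
  (.covalent_radii[el_i] + .covalent_radii[el_j]) *
    .order_factor[as.character(order)]
}

# ideal bond angle (radians) at a centre, from its hybridisation
.ideal_angle <- function(hyb) {
  switch(hyb, sp = pi, sp2 = 2 * pi / 3, sp3 = acos(-1 / 3))
}

# distance-restraint tables: bonds (exact), 1-3 pairs (exact, law of
# cosines), nonbonded lower bounds
.embed_restraints <- function(mol) {
  el <- mol$atoms$element
  b <- mol$bonds
  hyb <- .hybridisation(mol)
  r_bond <- .ideal_bond_length(el[b$i], el[b$j], b$order)
  nbrs <- lapply(seq_len(n_atoms(mol)), function(i) bonded_atoms(mol, i))
  ang_i <- integer(); ang_j <- integer(); ang_t <- numeric()
  for (c_idx in seq_len(n_atoms(mol))) {
    nb <- nbrs[[c_idx]]
    if (length(nb) < 2) next
    theta <- .ideal_angle(hyb[c_idx])
    # near-linear angles at 3+-coordinate centres are geometrically
    # impossible; fall back to trigonal
    if (length(nb) > 2 && theta > 2.9) theta <- 2 * pi / 3
    for (a in seq_len(length(nb) - 1)) for (bb in seq(a + 1, length(nb))) {
      i <- nb[a]; j <- nb[bb]
      ri <- .ideal_bond_length(el[c_idx], el[i],
                               b$order[(b$i == c_idx & b$j == i) |
                                         (b$j == c_idx & b$i == i)][1])
      rj <- .ideal_bond_length(el[c_idx], el[j],
                               b$order[(b$i == c_idx & b$j == j) |
                                         (b$j == c_idx & b$i == j)][1])
      ang_i <- c(ang_i, i); ang_j <- c(ang_j, j)
      ang_t <- c(ang_t, sqrt(ri^2 + rj^2 - 2 * ri * rj * cos(theta)))
    }
  }
  # topological distance 1 or 2 pairs are restrained above; everything else
  # gets a soft lower bound
  n <- n_atoms(mol)
  near <- matrix(FALSE, n, n)
  if (nrow(b)) { near[cbind(b$i, b$j)] <- TRUE; near <- near | t(near) }
  near13 <- near
  if (length(ang_i)) near13[cbind(ang_i, ang_j)] <- TRUE
  near13 <- near13 | t(near13)
  lb_i <- integer(); lb_j <- integer(); lb_t <- numeric()
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (!near13[i, j]) {
        lb_i <- c(lb_i, i); lb_j <- c(lb_j, j)
        lb_t <- c(lb_t, 0.72 * (.bondi_radii[el[i]] + .bondi_radii[el[j]]))
      }
    }
  }
  sp2_centres <- which(hyb == "sp2" &
                         vapply(nbrs, length, integer(1)) == 3)
  list(bond_i = b$i, bond_j = b$j, bond_t = r_bond,
       ang_i = ang_i, ang_j = ang_j, ang_t = ang_t,
       lb_i = lb_i, lb_j = lb_j, lb_t = lb_t,
       planar_centres = sp2_centres, nbrs = nbrs)
}

# initial coordinates: classical MDS on ideal-bond-length graph distances
.embed_init <- function(mol, restraints, seed) {
  n <- n_atoms(mol)
  g <- igraph::graph_from_data_frame(
    data.frame(from = restraints$bond_i, to = restraints$bond_j),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  D <- igraph::distances(g, weights = restraints$bond_t)
  D[!is.finite(D)] <- max(D[is.finite(D)]) + 3  # disconnected fragments
  X <- suppressWarnings(stats::cmdscale(D, k = 3))
  if (ncol(X) < 3) X <- cbind(X, matrix(0, n, 3 - ncol(X)))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  X + matrix(stats::rnorm(3 * n, sd = 0.25), n, 3)
}

# gradient of the squared out-of-plane volume at each trigonal sp2 centre
.planar_gradient <- function(X, centres, nbrs, weight) {
  G <- matrix(0, nrow(X), 3)
  pen <- 0
  for (c_idx in centres) {
    nb <- nbrs[[c_idx]]
    a <- X[nb[1], ] - X[c_idx, ]
    b <- X[nb[2], ] - X[c_idx, ]
    cc <- X[nb[3], ] - X[c_idx, ]
    cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                              u[3] * v[1] - u[1] * v[3],
                              u[1] * v[2] - u[2] * v[1])
    v <- sum(a * cross(b, cc))
    pen <- pen + weight * v^2
    dv_a <- cross(b, cc); dv_b <- cross(cc, a); dv_c <- cross(a, b)
    G[nb[1], ] <- G[nb[1], ] + 2 * weight * v * dv_a
    G[nb[2], ] <- G[nb[2], ] + 2 * weight * v * dv_b
    G[nb[3], ] <- G[nb[3], ] + 2 * weight * v * dv_c
    G[c_idx, ] <- G[c_idx, ] - 2 * weight * v * (dv_a + dv_b + dv_c)
  }
  list(G = G, penalty = pen)
}

.pair_gradient <- function(X, i, j, t, w, lower_only = FALSE) {
  G <- matrix(0, nrow(X), 3)
  if (!length(i)) return(list(G = G, penalty = 0))
  dvec <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  d <- pmax(sqrt(rowSums(dvec^2)), 1e-6)
  err <- d - t
  if (lower_only) err <- pmin(err, 0)
  Fv <- dvec * (2 * w * err / d)
  acc <- rowsum(rbind(Fv, -Fv), group = c(i, j))
  rows <- as.integer(rownames(acc))
  G[rows, ] <- acc
  list(G = G, penalty = sum(w * err^2))
}

.embed_refine <- function(X, restraints, n_iter = 500L, step0 = 0.03) {
  vel <- matrix(0, nrow(X), 3)
  for (it in seq_len(n_iter)) {
    step <- step0 * (1 - 0.95 * it / n_iter)  # annealed step size
    gb <- .pair_gradient(X, restraints$bond_i, restraints$bond_j,
                         restraints$bond_t, w = 10)
    ga <- .pair_gradient(X, restraints$ang_i, restraints$ang_j,
                         restraints$ang_t, w = 4)
    gl <- .pair_gradient(X, restraints$lb_i, restraints$lb_j,
                         restraints$lb_t, w = 6, lower_only = TRUE)
    gp <- .planar_gradient(X, restraints$planar_centres, restraints$nbrs,
                           weight = 8)
    G <- gb$G + ga$G + gl$G + gp$G
    vel <- 0.7 * vel - step * G
    # trust region: cap per-atom displacement to keep the descent stable
    vn <- sqrt(rowSums(vel^2))
    too_big <- vn > 0.25
    if (any(too_big)) vel[too_big, ] <- vel[too_big, ] * (0.25 / vn[too_big])
    X <- X + vel
  }
  X
}

.embed_quality <- function(X, restraints) {
  dvec <- X[restraints$bond_i, , drop = FALSE] -
    X[restraints$bond_j, , drop = FALSE]
  bond_err <- max(abs(sqrt(rowSums(dvec^2)) - restraints$bond_t))
  min_nb <- Inf
  if (length(restraints$lb_i)) {
    dnb <- X[restraints$lb_i, , drop = FALSE] -
      X[restraints$lb_j, , drop = FALSE]
    min_nb <- min(sqrt(rowSums(dnb^2)))
  }
  c(bond_err = bond_err, min_nonbonded = min_nb)
}

#' Assign 3D coordinates to a molecule
#'
#' Distance-geometry embedding: initial coordinates from classical
#' multidimensional scaling of ideal-bond-length graph distances with a
#' seeded perturbation, refined against bond-length, 1-3 angle-distance,
#' sp2-planarity and nonbonded lower-bound restraints by fixed-iteration
#' gradient descent. The result is bit-identical for identical
#' (structure, seed).
#'
#' @param mol a \code{molecule} with explicit hydrogens.
#' @param seed integer seed for the initial perturbation.
#' @param max_tries bounded retry count (each retry derives a new
#'   perturbation from the seed) before an explicit error.
#' @return the molecule with coordinates in Angstrom; the seed is recorded
#'   in the \code{"embed_seed"} attribute.
#' @export
embed_3d <- function(mol, seed = 1L, max_tries = 5L) {
  stopifnot(inherits(mol, "molecule"))
  restraints <- .embed_restraints(mol)
  for (attempt in seq_len(max_tries)) {
    X <- .embed_init(mol, restraints,
                     seed = as.integer(seed) + 7919L * (attempt - 1L))
    X <- .embed_refine(X, restraints)
    q <- .embed_quality(X, restraints)
    if (q["bond_err"] < 0.15 && q["min_nonbonded"] > 0.9) {
      out <- set_coordinates(mol, round(X, 6))
      attr(out, "embed_seed") <- as.integer(seed)
      return(out)
    }
  }
  stop("3D embedding failed for ", sQuote(mol$id), " after ", max_tries,
       " attempts (restraint violations persisted)")
}
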