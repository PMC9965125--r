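# Minimal extended Hueckel valence-orbital engine. It exists to provide a
# transparent, deterministic source for the frontier-orbital quantities the
# reactivity and energy descriptors consume: orbital energies and
# coefficients, the closed-shell density matrix and the resonance
# (off-diagonal Hamiltonian) integrals. Energies are in eV, Slater-type
# orbitals (STO) with standard single-zeta exponents.

.bohr_per_angstrom <- 1 / 0.52917721067
.ev_angstrom <- 14.397  # e^2/(4 pi eps0), eV * Angstrom

# valence shell parameters: principal quantum number, valence-state
# ionisation potentials (eV) and STO exponents (bohr^-1)
.eht_params <- list(
  H  = list(n = 1L, zeta_s = 1.300, zeta_p = NA,    h_s = -13.60, h_p = NA),
  C  = list(n = 2L, zeta_s = 1.625, zeta_p = 1.625, h_s = -21.40, h_p = -11.40),
  N  = list(n = 2L, zeta_s = 1.950, zeta_p = 1.950, h_s = -26.00, h_p = -13.40),
  O  = list(n = 2L, zeta_s = 2.275, zeta_p = 2.275, h_s = -32.30, h_p = -14.80),
  F  = list(n = 2L, zeta_s = 2.425, zeta_p = 2.425, h_s = -40.00, h_p = -18.10),
  S  = list(n = 3L, zeta_s = 1.817, zeta_p = 1.817, h_s = -20.00, h_p = -13.30),
  Cl = list(n = 3L, zeta_s = 2.183, zeta_p = 1.733, h_s = -30.00, h_p = -15.00)
)

# one-centre electron repulsion parameters (eV), Pariser-Parr style
.gamma_one_centre <- c(H = 12.85, C = 11.13, N = 12.34, O = 14.52,
                       F = 16.92, S = 10.09, Cl = 11.30)

# ---- STO overlap integrals -------------------------------------------------
# Overlap of two Slater orbitals on centres separated by R (bohr), both with
# the same |m| along the internuclear axis, evaluated in prolate spheroidal
# coordinates: the integrand reduces to a polynomial in (xi, eta) times
# exp(-alpha xi) exp(-beta eta), integrated term-by-term with the classical
# A_k / B_k auxiliary functions.

.aux_A <- function(kmax, p) {
  # A_k(p) = int_1^inf x^k exp(-p x) dx, k = 0..kmax
  out <- numeric(kmax + 1)
  e <- exp(-p)
  out[1] <- e / p
  if (kmax >= 1) for (k in 1:kmax) out[k + 1] <- (k * out[k] + e) / p
  out
}

.aux_B <- function(kmax, t) {
  # B_k(t) = int_-1^1 x^k exp(-t x) dx, k = 0..kmax
  out <- numeric(kmax + 1)
  if (abs(t) < 2) {
    for (k in 0:kmax) {
      acc <- 0
      term_pow <- 1  # (-t)^m / m!
      for (m in 0:40) {
        if ((k + m) %% 2 == 0) acc <- acc + term_pow * 2 / (k + m + 1)
        term_pow <- term_pow * (-t) / (m + 1)
        if (abs(term_pow) < 1e-18) break
      }
      out[k + 1] <- acc
    }
  } else {
    ep <- exp(t); em <- exp(-t)
    out[1] <- (ep - em) / t
    if (kmax >= 1) for (k in 1:kmax) {
      out[k + 1] <- (k * out[k] + (-1)^k * ep - em) / t
    }
  }
  out
}

# polynomial in (xi, eta) as coefficient matrix: coef[a+1, b+1] * xi^a eta^b
.poly_const <- function(c0) matrix(c0, 1, 1)

.poly_mult <- function(P, Q) {
  out <- matrix(0, nrow(P) + nrow(Q) - 1, ncol(P) + ncol(Q) - 1)
  for (a in seq_len(nrow(P))) for (b in seq_len(ncol(P))) {
    if (P[a, b] != 0) {
      out[a:(a + nrow(Q) - 1), b:(b + ncol(Q) - 1)] <-
        out[a:(a + nrow(Q) - 1), b:(b + ncol(Q) - 1)] + P[a, b] * Q
    }
  }
  out
}

.poly_pow <- function(P, k) {
  out <- .poly_const(1)
  for (i in seq_len(k)) out <- .poly_mult(out, P)
  out
}

# binomials used by the expansion
.P_XI_PLUS_ETA <- matrix(c(0, 1, 1, 0), 2, 2)   # xi + eta
.P_XI_MINUS_ETA <- matrix(c(0, 1, -1, 0), 2, 2) # xi - eta
.P_ONE_PLUS_XIETA <- matrix(c(1, 0, 0, 1), 2, 2)   # 1 + xi eta
.P_XIETA_MINUS_ONE <- matrix(c(-1, 0, 0, 1), 2, 2) # xi eta - 1
.P_XISQ_MINUS_ONE <- matrix(c(-1, 0, 1), 3, 1)     # xi^2 - 1
.P_ONE_MINUS_ETASQ <- matrix(c(1, 0, -1), 1, 3)    # 1 - eta^2

#' Overlap between two Slater-type orbitals along the internuclear axis
#'
#' @param n1,l1 principal and angular quantum numbers of the orbital on
#'   centre A (\code{l} 0 or 1).
#' @param n2,l2 quantum numbers of the orbital on centre B.
#' @param zeta1,zeta2 STO exponents (bohr^-1).
#' @param R internuclear distance (bohr).
#' @param m 0 for sigma alignment, 1 for pi (requires l1 = l2 = 1).
#' @return the overlap integral. The sigma convention takes both p lobes
#'   pointing along the A-to-B axis.
#' @export
sto_overlap <- function(n1, l1, n2, l2, zeta1, zeta2, R, m = 0) {
  stopifnot(l1 %in% 0:1, l2 %in% 0:1, n1 >= l1 + 1, n2 >= l2 + 1, R > 0)
  if (m == 1 && (l1 != 1 || l2 != 1)) return(0)
  half_R <- R / 2
  # radial normalisation (2 zeta)^(n + 1/2) / sqrt((2n)!)
  nrm <- function(n, z) (2 * z)^(n + 0.5) / sqrt(factorial(2 * n))
  angn <- function(l) if (l == 0) sqrt(1 / (4 * pi)) else sqrt(3 / (4 * pi))
  p_plus <- n1 - 1L   # power of (xi + eta) from r_A^(n1-1)
  p_minus <- n2 - 1L  # power of (xi - eta) from r_B^(n2-1)
  poly <- .poly_const(1)
  phi_fac <- 2 * pi
  if (m == 0) {
    if (l1 == 1) { poly <- .poly_mult(poly, .P_ONE_PLUS_XIETA); p_plus <- p_plus - 1L }
    if (l2 == 1) { poly <- .poly_mult(poly, .P_XIETA_MINUS_ONE); p_minus <- p_minus - 1L }
  } else {
    poly <- .poly_mult(poly, .poly_mult(.P_XISQ_MINUS_ONE, .P_ONE_MINUS_ETASQ))
    p_plus <- p_plus - 1L; p_minus <- p_minus - 1L
    phi_fac <- pi
  }
  # volume element contributes one extra power of each binomial
  poly <- .poly_mult(poly, .poly_pow(.P_XI_PLUS_ETA, p_plus + 1L))
  poly <- .poly_mult(poly, .poly_pow(.P_XI_MINUS_ETA, p_minus + 1L))
  alpha <- half_R * (zeta1 + zeta2)
  beta <- half_R * (zeta1 - zeta2)
  A <- .aux_A(nrow(poly) - 1, alpha)
  B <- .aux_B(ncol(poly) - 1, beta)
  val <- sum(poly * outer(A[seq_len(nrow(poly))], B[seq_len(ncol(poly))]))
  pref <- nrm(n1, zeta1) * nrm(n2, zeta2) * angn(l1) * angn(l2) * phi_fac *
    half_R^(3 + (n1 - 1) + (n2 - 1))
  pref * val
}

# ---- basis construction and matrices --------------------------------------

.build_basis <- function(mol) {
  rows <- list()
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[i]
    par <- .eht_params[[el]]
    if (is.null(par)) {
      stop("no extended Hueckel parameters for element ", sQuote(el))
    }
    rows[[length(rows) + 1]] <- data.frame(
      atom = i, element = el, type = "s", n = par$n,
      zeta = par$zeta_s, hii = par$h_s, lx = 0, ly = 0, lz = 0)
    if (!is.na(par$zeta_p)) {
      for (ax in c("x", "y", "z")) {
        rows[[length(rows) + 1]] <- data.frame(
          atom = i, element = el, type = paste0("p", ax), n = par$n,
          zeta = par$zeta_p, hii = par$h_p,
          lx = as.numeric(ax == "x"), ly = as.numeric(ax == "y"),
          lz = as.numeric(ax == "z"))
      }
    }
  }
  do.call(rbind, rows)
}

# overlap matrix over the valence basis; p blocks rotated through the
# sigma/pi decomposition along each pair axis
.overlap_matrix <- function(basis, xyz_bohr) {
  nb <- nrow(basis)
  S <- diag(1, nb)
  atoms <- unique(basis$atom)
  for (ai in atoms) for (aj in atoms) {
    if (aj <= ai) next
    rows_i <- which(basis$atom == ai)
    rows_j <- which(basis$atom == aj)
    rvec <- xyz_bohr[aj, ] - xyz_bohr[ai, ]
    R <- sqrt(sum(rvec^2))
    u <- rvec / R
    for (bi in rows_i) for (bj in rows_j) {
      li <- as.integer(basis$type[bi] != "s")
      lj <- as.integer(basis$type[bj] != "s")
      s_sigma <- sto_overlap(basis$n[bi], li, basis$n[bj], lj,
                             basis$zeta[bi], basis$zeta[bj], R, m = 0)
      if (li == 1 && lj == 1) {
        s_pi <- sto_overlap(basis$n[bi], 1, basis$n[bj], 1,
                            basis$zeta[bi], basis$zeta[bj], R, m = 1)
        di <- c(basis$lx[bi], basis$ly[bi], basis$lz[bi])
        dj <- c(basis$lx[bj], basis$ly[bj], basis$lz[bj])
        val <- (s_sigma - s_pi) * sum(di * u) * sum(dj * u) +
          s_pi * sum(di * dj)
      } else if (li == 0 && lj == 1) {
        dj <- c(basis$lx[bj], basis$ly[bj], basis$lz[bj])
        val <- s_sigma * sum(dj * u)
      } else if (li == 1 && lj == 0) {
        di <- c(basis$lx[bi], basis$ly[bi], basis$lz[bi])
        val <- s_sigma * sum(di * u)
      } else {
        val <- s_sigma
      }
      S[bi, bj] <- val
      S[bj, bi] <- val
    }
  }
  S
}

#' Build the electronic structure of a molecule
#'
#' Extended Hueckel calculation over the valence STO basis with
#' Wolfsberg-Helmholz off-diagonal elements
#' \code{H_ij = K S_ij (H_ii + H_jj) / 2}, \code{K = 1.75}, solved through
#' Loewdin symmetric orthogonalisation. Closed-shell occupation: two
#' electrons per lowest molecular orbital.
#'
#' @param mol a \code{molecule} with 3D coordinates and explicit hydrogens.
#' @param K Wolfsberg-Helmholz constant.
#' @return an object of class \code{"electronic_structure"} with basis
#'   labels, orbital energies (eV, ascending), coefficient matrix
#'   (basis x MO, normalised under the overlap metric), occupations, HOMO
#'   and LUMO indices, density matrix (atomic-orbital and orthogonalised
#'   bases), resonance integrals and the two-centre Coulomb kernel used by
#'   the atomic state energy.
#' @export
build_electronic_structure <- function(mol, K = 1.75) {
  stopifnot(inherits(mol, "molecule"))
  if (!has_coordinates(mol)) stop("electronic structure needs 3D coordinates")
  basis <- .build_basis(mol)
  xyz_bohr <- coordinates(mol) * .bohr_per_angstrom
  S <- .overlap_matrix(basis, xyz_bohr)
  hii <- basis$hii
  H <- K * S * outer(hii, hii, "+") / 2
  diag(H) <- hii
  es_S <- eigen(S, symmetric = TRUE)
  if (min(es_S$values) < 1e-8) {
    stop("overlap matrix is numerically singular (near-degenerate geometry)")
  }
  X <- es_S$vectors %*% diag(1 / sqrt(es_S$values)) %*% t(es_S$vectors)
  Ht <- X %*% H %*% X
  Ht <- (Ht + t(Ht)) / 2
  eg <- eigen(Ht, symmetric = TRUE)
  ord <- order(eg$values)
  energies <- eg$values[ord]
  C <- X %*% eg$vectors[, ord, drop = FALSE]
  n_elec <- sum(.valence_electrons[mol$atoms$element]) - mol$net_charge
  if (n_elec %% 2 != 0) {
    stop("odd electron count (", n_elec, "): open-shell systems unsupported")
  }
  n_occ <- n_elec / 2
  nb <- nrow(basis)
  if (n_occ > nb) stop("more electron pairs than basis functions")
  occ <- c(rep(2, n_occ), rep(0, nb - n_occ))
  C_occ <- C[, seq_len(n_occ), drop = FALSE]
  P <- 2 * C_occ %*% t(C_occ)
  V_occ <- eg$vectors[, ord, drop = FALSE][, seq_len(n_occ), drop = FALSE]
  P_orth <- 2 * V_occ %*% t(V_occ)
  beta <- H
  same_atom <- outer(basis$atom, basis$atom, "==")
  beta[same_atom] <- 0
  # two-centre Coulomb kernel (Mataga-Nishimoto), eV, for state energies
  els <- mol$atoms$element
  g_aa <- .gamma_one_centre[els]
  if (anyNA(g_aa)) {
    stop("no Coulomb parameters for element(s): ",
         paste(unique(els[is.na(g_aa)]), collapse = ", "))
  }
  Rmat <- as.matrix(stats::dist(coordinates(mol)))  # Angstrom
  a_ab <- 2 * .ev_angstrom / outer(g_aa, g_aa, "+")
  gamma <- .ev_angstrom / (Rmat + a_ab)
  structure(list(
    basis = basis, S = S, H = H, energies = energies, C = C, occ = occ,
    n_electrons = n_elec, homo = n_occ,
    lumo = if (n_occ < nb) n_occ + 1L else NA_integer_,
    P = P, P_orth = P_orth, beta = beta, gamma = gamma,
    core_charge = unname(.valence_electrons[els]),
    element = els, id = mol$id), class = "electronic_structure")
}

#' @export
print.electronic_structure <- function(x, ...) {
  cat(sprintf(
    "<electronic structure %s> %d basis fn, %d electrons, HOMO %.3f eV%s\n",
    x$id, nrow(x$basis), x$n_electrons, x$energies[x$homo],
    if (!is.na(x$lumo)) sprintf(", LUMO %.3f eV", x$energies[x$lumo]) else ""))
  invisible(x)
}
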