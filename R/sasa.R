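# Per-atom solvent-accessible surface area by sphere-point (Shrake-Rupley
# style) sampling. The point set is a deterministic golden-section spiral,
# so areas are a pure function of (coordinates, probe, n_points).

#' Deterministic unit-sphere point set (golden-section spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' Samples \code{n_points} on each atom's solvent-accessible sphere
#' (van der Waals radius + probe radius) and counts the points not buried
#' inside any neighbouring atom's accessible sphere. Bondi van der Waals
#' radii; water probe 1.4 Angstrom by default.
#'
#' @param mol a \code{molecule} with 3D coordinates.
#' @param probe probe radius in Angstrom (> 0).
#' @param n_points quadrature points per atom (>= 92).
#' @return a \code{surface_charge_profile} carrying per-atom areas
#'   (Angstrom^2); their sum is the total molecular surface area (TMSA).
#' @export
atomic_sasa <- function(mol, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(mol, "molecule"), probe > 0, n_points >= 92)
  if (!has_coordinates(mol)) {
    stop("atomic_sasa needs 3D coordinates; run embed_3d first")
  }
  xyz <- coordinates(mol)
  radii <- .bondi_radii[mol$atoms$element] + probe
  n <- n_atoms(mol)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    # neighbours whose accessible spheres can occlude atom i
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    surf <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        free <- free & (dj2 > radii[j]^2)
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * radii[i]^2 * frac
  }
  surface_charge_profile(mol, area = area, probe = probe,
                         radii_set = "bondi", n_points = as.integer(n_points))
}

#' Total molecular surface area
#'
#' @param profile a \code{surface_charge_profile} with areas.
#' @return TMSA in Angstrom^2 (sum of per-atom areas).
#' @export
tmsa <- function(profile) {
  if (is.null(profile$area)) stop("profile carries no areas")
  sum(profile$area)
}
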