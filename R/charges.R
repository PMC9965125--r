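# Empirical partial charges. The CPSA descriptor definitions are
# charge-scheme agnostic; the scheme used is recorded in every profile so
# descriptor values stay traceable.

# Gasteiger-Marsili orbital electronegativity parameters (a, b, c) by
# element and hybridisation; chi(q) = a + b q + c q^2 (eV).
.peoe_params <- list(
  "H"      = c(7.17,  6.24, -0.56),
  "C.sp3"  = c(7.98,  9.18,  1.88),
  "C.sp2"  = c(8.79,  9.32,  1.51),
  "C.sp"   = c(10.39, 9.45,  0.73),
  "N.sp3"  = c(11.54, 10.82, 1.36),
  "N.sp2"  = c(12.87, 11.15, 0.85),
  "N.sp"   = c(15.68, 11.70, -0.27),
  "O.sp3"  = c(14.18, 12.92, 1.39),
  "O.sp2"  = c(17.07, 13.79, 0.47),
  "F"      = c(14.66, 13.85, 2.31),
  "Cl"     = c(11.00, 9.69,  1.35),
  "Br"     = c(10.08, 8.47,  1.16),
  "I"      = c(9.90,  7.96,  0.96),
  "S.sp3"  = c(10.14, 9.13,  1.38),
  "S.sp2"  = c(10.14, 9.13,  1.38)
)

.peoe_key <- function(element, hyb) {
  key <- ifelse(element %in% c("H", "F", "Cl", "Br", "I"),
                element, paste(element, hyb, sep = "."))
  # sp-hybridised O/S etc. fall back to the sp2 row
  miss <- !(key %in% names(.peoe_params))
  key[miss] <- paste(element[miss], "sp2", sep = ".")
  if (any(!(key %in% names(.peoe_params)))) {
    bad <- unique(element[!(key %in% names(.peoe_params))])
    stop("no charge parameters for element(s): ", paste(bad, collapse = ", "))
  }
  key
}

# Partial equalisation of orbital electronegativity. Charge flows across
# each bond toward the more electronegative atom, damped by 0.5^iter;
# the transfer is normalised by the cation electronegativity (a + b + c)
# of the donor atom, with hydrogen's special value 20.02.
.peoe_iterate <- function(element, hyb, formal_charge, bonds,
                          n_iter = 8L, damping = 0.5) {
  key <- .peoe_key(element, hyb)
  par <- do.call(rbind, .peoe_params[key])
  q <- as.numeric(formal_charge)
  chi_plus <- par[, 1] + par[, 2] + par[, 3]
  chi_plus[element == "H"] <- 20.02
  for (it in seq_len(n_iter)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    damp <- damping^it
    dq <- numeric(length(q))
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j   # donor: less electronegative
      hi <- if (chi[i] < chi[j]) j else i
      tr <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
      dq[lo] <- dq[lo] + tr
      dq[hi] <- dq[hi] - tr
    }
    q <- q + dq
  }
  q
}

#' Assign empirical partial charges
#'
#' Default scheme is the Gasteiger-Marsili iterative partial equalisation of
#' orbital electronegativity (PEOE): fast, deterministic and parameter-light.
#' Charges sum to the molecular net charge by construction (each iteration
#' only transfers charge across bonds).
#'
#' @param mol a \code{molecule} with explicit hydrogens.
#' @param scheme charge scheme name; currently \code{"gasteiger"}.
#' @param n_iter number of damped equalisation iterations.
#' @return a \code{surface_charge_profile} carrying per-atom charges
#'   (elementary charge units); areas are absent until
#'   \code{\link{atomic_sasa}} is merged in.
#' @export
assign_partial_charges <- function(mol, scheme = "gasteiger", n_iter = 8L) {
  stopifnot(inherits(mol, "molecule"))
  supported <- "gasteiger"
  if (!scheme %in% supported) {
    stop("unknown charge scheme ", sQuote(scheme), "; supported: ",
         paste(supported, collapse = ", "))
  }
  hyb <- .hybridisation(mol)
  q <- .peoe_iterate(mol$atoms$element, hyb, mol$atoms$formal_charge,
                     mol$bonds, n_iter = n_iter)
  if (abs(sum(q) - mol$net_charge) > 1e-3) {
    stop("charge conservation violated (internal error)")
  }
  surface_charge_profile(mol, charge = q, scheme = scheme)
}

#' Surface charge profile container
#'
#' Holds per-atom partial charges and/or per-atom solvent-accessible
#' surface areas together with their provenance (scheme, probe radius,
#' radii set, quadrature size).
#'
#' @param mol the parent \code{molecule}.
#' @param charge per-atom partial charges, or \code{NULL}.
#' @param area per-atom solvent-accessible areas (Angstrom^2), or \code{NULL}.
#' @param scheme charge scheme name.
#' @param probe probe radius (Angstrom).
#' @param radii_set radii table name.
#' @param n_points quadrature points per sphere.
#' @return object of class \code{"surface_charge_profile"}.
#' @export
surface_charge_profile <- function(mol, charge = NULL, area = NULL,
                                   scheme = NA_character_, probe = NA_real_,
                                   radii_set = NA_character_,
                                   n_points = NA_integer_) {
  n <- n_atoms(mol)
  if (!is.null(charge)) stopifnot(length(charge) == n, all(is.finite(charge)))
  if (!is.null(area)) stopifnot(length(area) == n, all(area >= 0))
  structure(list(element = mol$atoms$element, charge = charge, area = area,
                 net_charge = mol$net_charge, scheme = scheme, probe = probe,
                 radii_set = radii_set, n_points = n_points, id = mol$id),
            class = "surface_charge_profile")
}

#' Merge charge-only and area-only profiles
#'
#' @param charge_profile profile carrying charges.
#' @param area_profile profile carrying areas (same molecule).
#' @return a complete \code{surface_charge_profile}.
#' @export
merge_profiles <- function(charge_profile, area_profile) {
  stopifnot(identical(charge_profile$element, area_profile$element))
  out <- charge_profile
  out$area <- area_profile$area
  out$probe <- area_profile$probe
  out$radii_set <- area_profile$radii_set
  out$n_points <- area_profile$n_points
  out
}

#' @export
print.surface_charge_profile <- function(x, ...) {
  cat(sprintf("<surface charge profile %s> %d atoms; charges: %s; areas: %s\n",
              x$id, length(x$element),
              if (is.null(x$charge)) "absent" else x$scheme,
              if (is.null(x$area)) "absent"
              else sprintf("%s radii, probe %.2f A, %d pts", x$radii_set,
                           x$probe, x$n_points)))
  invisible(x)
}
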