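# Charged partial surface area (CPSA) descriptors. Atoms with strictly
# positive partial charge form the "positive" partition; zero-charge atoms
# are counted with the negative partition so that PPSA1 + PNSA1 = TMSA
# holds exactly.

.check_full_profile <- function(profile) {
  if (is.null(profile$charge) || is.null(profile$area)) {
    stop("profile must carry both charges and areas")
  }
}

#' Partial positively charged surface area (PPSA1)
#'
#' Sum of solvent-accessible areas over atoms with positive partial charge.
#'
#' @param profile a complete \code{surface_charge_profile}.
#' @return area in Angstrom^2.
#' @export
ppsa1 <- function(profile) {
  .check_full_profile(profile)
  sum(profile$area[profile$charge > 0])
}

#' Partial negatively charged surface area (PNSA1)
#'
#' Sum of solvent-accessible areas over atoms with non-positive partial
#' charge (complement of the PPSA1 set).
#'
#' @param profile a complete \code{surface_charge_profile}.
#' @return area in Angstrom^2.
#' @export
pnsa1 <- function(profile) {
  .check_full_profile(profile)
  sum(profile$area[profile$charge <= 0])
}

#' Charge-weighted positive surface area (PPSA3)
#'
#' Sum of (charge x area) over positively charged atoms.
#'
#' @param profile a complete \code{surface_charge_profile}.
#' @return charge-weighted area (e Angstrom^2).
#' @export
ppsa3 <- function(profile) {
  .check_full_profile(profile)
  pos <- profile$charge > 0
  sum(profile$charge[pos] * profile$area[pos])
}

#' Surface-weighted negative surface area (WNSA-1)
#'
#' PNSA1 x TMSA / 1000.
#'
#' @param profile a complete \code{surface_charge_profile}.
#' @return value in Angstrom^4 / 1000.
#' @export
wnsa1 <- function(profile) {
  pnsa1(profile) * tmsa(profile) / 1000
}

#' Relative negative charge (RNCG)
#'
#' Magnitude of the most negative atomic charge divided by the total
#' negative charge; lies in (0, 1] whenever at least one atom carries
#' negative charge.
#'
#' @param profile a \code{surface_charge_profile} with charges.
#' @return dimensionless value in (0, 1].
#' @export
rncg <- function(profile) {
  if (is.null(profile$charge)) stop("profile carries no charges")
  neg <- profile$charge[profile$charge < 0]
  if (!length(neg)) {
    stop("RNCG undefined: no atom carries negative charge")
  }
  max(abs(neg)) / sum(abs(neg))
}

#' Fractional charge-weighted positive surface area (FPSA3)
#'
#' PPSA3 / TMSA.
#'
#' @param profile a complete \code{surface_charge_profile}.
#' @return dimensionless value.
#' @export
fpsa3 <- function(profile) {
  total <- tmsa(profile)
  if (total <= 0) stop("FPSA3 undefined: TMSA is zero")
  ppsa3(profile) / total
}

#' Hydrogen-bond donor surface area (H-donors PSA)
#'
#' Sum of solvent-accessible areas over hydrogen atoms bonded to nitrogen
#' or oxygen. Molecules without N-H or O-H groups score 0.
#'
#' @param profile a \code{surface_charge_profile} with areas.
#' @param mol the parent \code{molecule} (for connectivity).
#' @return area in Angstrom^2.
#' @export
hdonors_psa <- function(profile, mol) {
  if (is.null(profile$area)) stop("profile carries no areas")
  stopifnot(identical(profile$element, mol$atoms$element))
  donors <- vapply(seq_len(n_atoms(mol)), function(i) {
    mol$atoms$element[i] == "H" &&
      any(mol$atoms$element[bonded_atoms(mol, i)] %in% c("N", "O"))
  }, logical(1))
  sum(profile$area[donors])
}

# registered CPSA descriptor catalogue: name -> function(profile, mol)
.cpsa_catalogue <- function() {
  list(
    ppsa1 = function(p, m) ppsa1(p),
    pnsa1 = function(p, m) pnsa1(p),
    ppsa3 = function(p, m) ppsa3(p),
    tmsa = function(p, m) tmsa(p),
    wnsa1 = function(p, m) wnsa1(p),
    rncg = function(p, m) rncg(p),
    fpsa3 = function(p, m) fpsa3(p),
    hdonors_psa = function(p, m) hdonors_psa(p, m)
  )
}

#' Compute the CPSA descriptor block for one molecule
#'
#' @param mol a \code{molecule} with 3D coordinates.
#' @param profile optional pre-computed complete profile; computed from
#'   \code{mol} when missing.
#' @param descriptors names from the registered CPSA catalogue.
#' @param probe,n_points surface parameters passed to
#'   \code{\link{atomic_sasa}}.
#' @param scheme charge scheme passed to
#'   \code{\link{assign_partial_charges}}.
#' @return named numeric vector of descriptor values with a provenance
#'   attribute.
#' @export
cpsa_descriptors <- function(mol, profile = NULL,
                             descriptors = names(.cpsa_catalogue()),
                             probe = 1.4, n_points = 960L,
                             scheme = "gasteiger") {
  cat_ <- .cpsa_catalogue()
  unknown <- setdiff(descriptors, names(cat_))
  if (length(unknown)) {
    stop("unknown CPSA descriptor(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(profile)) {
    profile <- merge_profiles(
      assign_partial_charges(mol, scheme = scheme),
      atomic_sasa(mol, probe = probe, n_points = n_points))
  }
  vals <- vapply(descriptors, function(d) cat_[[d]](profile, mol), numeric(1))
  if (any(!is.finite(vals))) stop("non-finite descriptor value computed")
  attr(vals, "provenance") <- list(
    charge_scheme = profile$scheme, probe = profile$probe,
    radii_set = profile$radii_set, n_points = profile$n_points)
  vals
}
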