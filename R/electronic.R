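# Frontier-orbital reactivity indices and semi-empirical energy
# descriptors, all read off one electronic_structure object.

.basis_on_atom <- function(es, atom) which(es$basis$atom == atom)

.check_atom <- function(es, atom) {
  if (!(atom %in% es$basis$atom)) stop("atom index ", atom, " out of range")
}

#' Nucleophilic (HOMO) reactivity index of an atom
#'
#' Sum of squared HOMO coefficients on the atom divided by
#' \code{(1 - e_HOMO)}, orbital energy in eV.
#'
#' @param es an \code{electronic_structure}.
#' @param atom atom index.
#' @return dimensionless index.
#' @export
nucleophilic_index <- function(es, atom) {
  .check_atom(es, atom)
  idx <- .basis_on_atom(es, atom)
  sum(es$C[idx, es$homo]^2) / (1 - es$energies[es$homo])
}

#' Electrophilic (LUMO) reactivity index of an atom
#'
#' Sum of squared LUMO coefficients on the atom divided by
#' \code{(e_LUMO + 10)}, orbital energy in eV.
#'
#' @param es an \code{electronic_structure}.
#' @param atom atom index.
#' @return dimensionless index.
#' @export
electrophilic_index <- function(es, atom) {
  .check_atom(es, atom)
  if (is.na(es$lumo)) stop("no virtual orbital available for LUMO index")
  denom <- es$energies[es$lumo] + 10
  if (abs(denom) < 1e-12) stop("singular denominator: e_LUMO = -10 eV")
  idx <- .basis_on_atom(es, atom)
  sum(es$C[idx, es$lumo]^2) / denom
}

#' One-electron (HOMO-LUMO) reactivity index of an atom
#'
#' Double sum of HOMO x LUMO coefficient products on the atom divided by
#' the frontier gap \code{(e_LUMO - e_HOMO)}.
#'
#' @param es an \code{electronic_structure}.
#' @param atom atom index.
#' @return dimensionless index.
#' @export
one_electron_index <- function(es, atom) {
  .check_atom(es, atom)
  if (is.na(es$lumo)) stop("no virtual orbital available for one-electron index")
  gap <- es$energies[es$lumo] - es$energies[es$homo]
  if (abs(gap) < 1e-9) stop("degenerate frontier gap: index undefined")
  idx <- .basis_on_atom(es, atom)
  ch <- es$C[idx, es$homo]
  cl <- es$C[idx, es$lumo]
  sum(outer(ch, cl)) / gap
}

#' Resonance energy of a bonded atom pair
#'
#' Sum over basis functions of density-matrix elements times resonance
#' integrals between the two atoms, in eV.
#'
#' @param es an \code{electronic_structure}.
#' @param atom_a,atom_b distinct atom indices.
#' @return energy in eV.
#' @export
resonance_energy <- function(es, atom_a, atom_b) {
  .check_atom(es, atom_a); .check_atom(es, atom_b)
  if (atom_a == atom_b) stop("resonance energy needs two distinct atoms")
  ia <- .basis_on_atom(es, atom_a)
  ib <- .basis_on_atom(es, atom_b)
  sum(es$P[ia, ib, drop = FALSE] * es$beta[ia, ib, drop = FALSE])
}

#' Atomic state energy (two-centre electron repulsion plus nuclear attraction)
#'
#' Zero-differential-overlap form: the atom's electron population repels
#' the populations of all other atoms through the two-centre Coulomb kernel
#' and is attracted by their core charges through the same kernel:
#' \code{E(A) = Q_A * sum_B (Q_B - Z_B) * gamma_AB}, eV.
#'
#' @param es an \code{electronic_structure}.
#' @param atom atom index.
#' @return energy in eV.
#' @export
atomic_state_energy <- function(es, atom) {
  .check_atom(es, atom)
  n_at <- length(es$element)
  pops <- vapply(seq_len(n_at), function(a) {
    idx <- .basis_on_atom(es, a)
    sum(diag(es$P)[idx])
  }, numeric(1))
  others <- setdiff(seq_len(n_at), atom)
  if (!length(others)) return(0)
  q_a <- pops[atom]
  sum(q_a * (pops[others] - es$core_charge[others]) *
        es$gamma[atom, others])
}

#' Aggregate a per-atom (or per-bond) electronic descriptor over an element
#'
#' Evaluates the given index for every atom of the named element and takes
#' the max, min or mean. For \code{resonance_energy} the aggregation runs
#' over bonded pairs whose element pair matches \code{element} (e.g.
#' \code{"H-C"}). Molecules with no matching atom or bond score the neutral
#' value 0, with a warning.
#'
#' @param es an \code{electronic_structure}.
#' @param index one of \code{"nucleophilic"}, \code{"electrophilic"},
#'   \code{"one_electron"}, \code{"state_energy"}, \code{"resonance"}.
#' @param element element symbol, or \code{"X-Y"} bond spec for resonance.
#' @param mode \code{"max"}, \code{"min"} or \code{"avg"}.
#' @param mol parent \code{molecule}; required for resonance (bond list).
#' @return aggregated value.
#' @export
aggregate_index <- function(es, index = c("nucleophilic", "electrophilic",
                                          "one_electron", "state_energy",
                                          "resonance"),
                            element, mode = c("max", "min", "avg"),
                            mol = NULL) {
  index <- match.arg(index)
  mode <- match.arg(mode)
  agg <- switch(mode, max = max, min = min, avg = mean)
  if (index == "resonance") {
    if (is.null(mol)) stop("resonance aggregation needs the molecule's bonds")
    pair <- strsplit(element, "-", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% names(.atomic_number))) {
      stop("unknown bond specification ", sQuote(element))
    }
    b <- mol$bonds
    match_pair <- (mol$atoms$element[b$i] == pair[1] &
                     mol$atoms$element[b$j] == pair[2]) |
      (mol$atoms$element[b$i] == pair[2] & mol$atoms$element[b$j] == pair[1])
    if (!any(match_pair)) {
      warning("no ", element, " bond present; descriptor set to 0")
      return(0)
    }
    vals <- mapply(function(i, j) resonance_energy(es, i, j),
                   b$i[match_pair], b$j[match_pair])
    return(agg(vals))
  }
  if (!element %in% names(.atomic_number)) {
    stop("unknown element symbol ", sQuote(element))
  }
  atoms <- which(es$element == element)
  if (!length(atoms)) {
    warning("no ", element, " atom present; descriptor set to 0")
    return(0)
  }
  fn <- switch(index,
               nucleophilic = nucleophilic_index,
               electrophilic = electrophilic_index,
               one_electron = one_electron_index,
               state_energy = atomic_state_energy)
  agg(vapply(atoms, function(a) fn(es, a), numeric(1)))
}

# registered electronic descriptor catalogue used by the pipeline; the
# entries mirror the model descriptors of the analgesic QSAR equations
.electronic_catalogue <- function() {
  list(
    nucleophilic_avg_N = function(es, mol)
      aggregate_index(es, "nucleophilic", "N", "avg"),
    electrophilic_max_C = function(es, mol)
      aggregate_index(es, "electrophilic", "C", "max"),
    one_electron_max_N = function(es, mol)
      aggregate_index(es, "one_electron", "N", "max"),
    state_energy_max_H = function(es, mol)
      aggregate_index(es, "state_energy", "H", "max"),
    resonance_max_HC = function(es, mol)
      aggregate_index(es, "resonance", "H-C", "max", mol = mol),
    homo_energy = function(es, mol) es$energies[es$homo],
    lumo_energy = function(es, mol) es$energies[es$lumo]
  )
}

#' Compute the electronic descriptor block for one molecule
#'
#' @param mol a \code{molecule} with 3D coordinates.
#' @param es optional pre-built \code{electronic_structure}.
#' @param descriptors names from the registered electronic catalogue.
#' @return named numeric vector with a provenance attribute.
#' @export
electronic_descriptors <- function(mol, es = NULL,
                                   descriptors = names(.electronic_catalogue())) {
  cat_ <- .electronic_catalogue()
  unknown <- setdiff(descriptors, names(cat_))
  if (length(unknown)) {
    stop("unknown electronic descriptor(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(es)) es <- build_electronic_structure(mol)
  vals <- vapply(descriptors, function(d) {
    withCallingHandlers(cat_[[d]](es, mol),
                        warning = function(w) invokeRestart("muffleWarning"))
  }, numeric(1))
  if (any(!is.finite(vals))) stop("non-finite electronic descriptor value")
  attr(vals, "provenance") <- list(method = "extended_hueckel", K = 1.75,
                                   energy_unit = "eV")
  vals
}
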