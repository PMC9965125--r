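# Molecule: the shared substrate for every descriptor. A light S3 container
# over an atom table and a bond table, with explicit hydrogens throughout.

#' Construct a Molecule
#'
#' @param atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (Angstrom; may be \code{NA} before 3D embedding) and
#'   \code{formal_charge}.
#' @param bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (1, 2 or 3).
#' @param id text label.
#' @return object of class \code{"molecule"}.
#' @export
molecule <- function(atoms, bonds, id = "") {
  atoms$element <- as.character(atoms$element)
  unknown <- setdiff(unique(atoms$element), names(.atomic_number))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  atoms$Z <- .atomic_number[atoms$element]
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$x)) atoms$x <- NA_real_
  if (is.null(atoms$y)) atoms$y <- NA_real_
  if (is.null(atoms$z)) atoms$z <- NA_real_
  n <- nrow(atoms)
  if (nrow(bonds)) {
    stopifnot(all(bonds$i >= 1), all(bonds$i <= n),
              all(bonds$j >= 1), all(bonds$j <= n))
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
  }
  mol <- structure(
    list(atoms = atoms[, c("element", "Z", "x", "y", "z", "formal_charge")],
         bonds = as.data.frame(bonds)[, c("i", "j", "order"), drop = FALSE],
         net_charge = sum(atoms$formal_charge),
         id = id),
    class = "molecule")
  coords <- coordinates(mol)
  if (anyNA(coords)) {
    if (!all(is.na(coords))) stop("coordinates must be all present or all absent")
  } else if (any(!is.finite(coords))) {
    stop("non-finite coordinates")
  }
  mol
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s> %s: %d atoms, %d bonds, net charge %+d, %s\n",
              x$id, molecular_formula(x), nrow(x$atoms), nrow(x$bonds),
              x$net_charge,
              if (has_coordinates(x)) "3D" else "no coordinates"))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a \code{molecule}.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Atom coordinate matrix
#' @param mol a \code{molecule}.
#' @return numeric n x 3 matrix (Angstrom), possibly \code{NA}.
#' @export
coordinates <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Does the molecule carry 3D coordinates?
#' @param mol a \code{molecule}.
#' @return logical.
#' @export
has_coordinates <- function(mol) !anyNA(coordinates(mol))

#' Replace the coordinates of a molecule
#' @param mol a \code{molecule}.
#' @param xyz numeric n x 3 matrix (Angstrom).
#' @return the updated \code{molecule}.
#' @export
set_coordinates <- function(mol, xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == n_atoms(mol), ncol(xyz) == 3)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Elemental formula of a molecule
#' @param mol a \code{molecule}.
#' @return Hill-notation formula string.
#' @export
molecular_formula <- function(mol) {
  format_formula(table(mol$atoms$element))
}

#' Parse a structure from SMILES or an SDF block
#'
#' Hydrogens are made explicit on parsing; every downstream descriptor
#' assumes them. Parsing is delegated to OpenBabel (via ChemmineOB) for
#' SMILES and to ChemmineR for SDF blocks.
#'
#' @param text a SMILES string or a complete SDF (MOL) V2000 block.
#' @param format \code{"smiles"} or \code{"sdf"}.
#' @param id label for the returned molecule.
#' @return a \code{molecule} with explicit hydrogens. SMILES input yields a
#'   molecule without coordinates (see \code{\link{embed_3d}}); SDF input
#'   keeps the coordinates in the block.
#' @export
parse_structure <- function(text, format = c("smiles", "sdf"), id = "") {
  format <- match.arg(format)
  if (format == "smiles") {
    if (!is.character(text) || length(text) != 1L || !nzchar(text) ||
        grepl("[[:space:]]", text)) {
      stop("malformed SMILES input: ", deparse(text))
    }
    sdf_txt <- tryCatch(
      ChemmineOB::convertFormat(
        "SMI", "SDF", paste0(text, " ", if (nzchar(id)) id else "mol"),
        options = data.frame(names = "h", args = "")),
      error = function(e) stop("SMILES parse error in ", sQuote(text), ": ",
                               conditionMessage(e)))
    if (!nzchar(sdf_txt) || !grepl("V2000", sdf_txt)) {
      stop("SMILES parse error: OpenBabel rejected ", sQuote(text))
    }
    mol <- sdf_block_to_molecule(sdf_txt, id = id)
    # 2D/0D placeholder coordinates from the converter are not geometry
    mol$atoms$x <- NA_real_; mol$atoms$y <- NA_real_; mol$atoms$z <- NA_real_
    mol
  } else {
    sdf_block_to_molecule(text, id = id)
  }
}

# MDL old-style charge codes used in the atom block
.mdl_charge_codes <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)

sdf_block_to_molecule <- function(text, id = "") {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  if (!any(grepl("V2000", lines))) stop("SDF parse error: no V2000 counts line")
  if (!any(grepl("^M  END", lines))) lines <- c(lines, "M  END")
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  sdfset <- ChemmineR::read.SDFset(tmp)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  codes <- as.integer(ab[, 5])
  codes[is.na(codes) | codes < 0 | codes > 7] <- 0L
  atoms <- data.frame(
    element = element,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    formal_charge = .mdl_charge_codes[codes + 1L])
  if (all(atoms$x == 0 & atoms$y == 0 & atoms$z == 0) && nrow(atoms) > 1) {
    atoms$x <- NA_real_; atoms$y <- NA_real_; atoms$z <- NA_real_
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  if (!nzchar(id)) id <- ChemmineR::sdfid(sdf)
  molecule(atoms, bonds, id = id)
}

#' Write a molecule as an SDF V2000 block
#'
#' @param mol a \code{molecule}.
#' @param file optional path; when missing the block is returned as a string.
#' @return the SDF block, invisibly when written to a file.
#' @export
write_sdf <- function(mol, file = NULL) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  xyz <- coordinates(mol)
  if (anyNA(xyz)) xyz[] <- 0
  header <- c(mol$id, "  clickqsar", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  # old-style atom-block charge codes (read back by most V2000 parsers),
  # duplicated in M CHG lines below
  code_of <- function(q) match(q, c(0L, 3L, 2L, 1L, NA, -1L, -2L, -3L)) - 1L
  codes <- code_of(mol$atoms$formal_charge)
  codes[is.na(codes)] <- 0L
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                        xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element,
                        codes)
  bond_lines <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                                mol$bonds$i, mol$bonds$j, mol$bonds$order)
  chg <- which(mol$atoms$formal_charge != 0)
  chg_lines <- if (length(chg)) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(idx) {
      paste0(sprintf("M  CHG%3d", length(idx)),
             paste0(sprintf("%4d%4d", idx, mol$atoms$formal_charge[idx]),
                    collapse = ""))
    }, character(1))
  }
  block <- paste(c(header, atom_lines, bond_lines, chg_lines,
                   "M  END", "$$$$"), collapse = "\n")
  if (is.null(file)) return(block)
  writeLines(block, file)
  invisible(block)
}

#' Canonical SMILES of a molecule
#'
#' Round-trips through OpenBabel's canonical writer; used for structure
#' de-duplication in library enumeration.
#'
#' @param mol a \code{molecule}.
#' @return canonical SMILES string (no explicit hydrogens).
#' @export
to_canonical_smiles <- function(mol) {
  out <- ChemmineOB::convertFormat("SDF", "CAN", write_sdf(mol))
  strsplit(trimws(out), "[[:space:]]+")[[1]][1]
}

#' Element-wise adjacency helpers
#'
#' @param mol a \code{molecule}.
#' @param i atom index.
#' @return integer vector of atoms bonded to \code{i}.
#' @export
bonded_atoms <- function(mol, i) {
  b <- mol$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}

# highest bond order incident to each atom; 0 for isolated atoms
.max_bond_order <- function(mol) {
  n <- n_atoms(mol)
  out <- numeric(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    out[b$i[k]] <- max(out[b$i[k]], b$order[k])
    out[b$j[k]] <- max(out[b$j[k]], b$order[k])
  }
  out
}

# count of double bonds incident to each atom (to spot cumulated sp carbons)
.n_double_bonds <- function(mol) {
  n <- n_atoms(mol)
  out <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2) {
      out[b$i[k]] <- out[b$i[k]] + 1L
      out[b$j[k]] <- out[b$j[k]] + 1L
    }
  }
  out
}

# simple hybridisation tags ("sp3", "sp2", "sp") from incident bond orders
.hybridisation <- function(mol) {
  mx <- .max_bond_order(mol)
  nd <- .n_double_bonds(mol)
  ifelse(mx >= 3 | nd >= 2, "sp", ifelse(mx == 2, "sp2", "sp3"))
}
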