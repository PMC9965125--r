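# In-silico conjugate construction: propargyl esterification of an NSAID
# carboxylic acid and copper-catalysed azide-alkyne cycloaddition to the
# 1,4-disubstituted 1,2,3-triazole. Both templates are pure graph edits
# that conserve every reactant atom (esterification releases HBr from the
# propargyl bromide side, accounted at the formula level).

# carboxylic acid: C(=O)-O-H; returns data.frame(carbon, o_double, o_single, h)
.find_carboxylic_acids <- function(mol) {
  el <- mol$atoms$element
  b <- mol$bonds
  hits <- list()
  for (c_idx in which(el == "C")) {
    o2 <- o1 <- h <- NA_integer_
    for (k in which((b$i == c_idx & el[b$j] == "O") |
                    (b$j == c_idx & el[b$i] == "O"))) {
      o <- if (b$i[k] == c_idx) b$j[k] else b$i[k]
      if (b$order[k] == 2) o2 <- o
      if (b$order[k] == 1) {
        nb <- bonded_atoms(mol, o)
        h_nb <- nb[el[nb] == "H"]
        if (length(h_nb) == 1) { o1 <- o; h <- h_nb }
      }
    }
    if (!is.na(o2) && !is.na(o1)) {
      hits[[length(hits) + 1]] <- data.frame(carbon = c_idx, o_double = o2,
                                             o_single = o1, h = h)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(carbon = integer(), o_double = integer(),
                  o_single = integer(), h = integer())
}

# terminal alkyne: C#C-H; returns data.frame(c_internal, c_terminal, h)
.find_terminal_alkynes <- function(mol) {
  el <- mol$atoms$element
  b <- mol$bonds
  hits <- list()
  for (k in which(b$order == 3)) {
    ci <- b$i[k]; cj <- b$j[k]
    if (el[ci] != "C" || el[cj] != "C") next
    for (pair in list(c(ci, cj), c(cj, ci))) {
      nb <- bonded_atoms(mol, pair[2])
      h_nb <- nb[el[nb] == "H"]
      if (length(h_nb) == 1 && length(nb) == 2) {
        hits[[length(hits) + 1]] <- data.frame(
          c_internal = pair[1], c_terminal = pair[2], h = h_nb)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(c_internal = integer(), c_terminal = integer(),
                  h = integer())
}

# organic azide: R-N=N+=N-; returns data.frame(n_attached, n_mid, n_term)
.find_azides <- function(mol) {
  el <- mol$atoms$element
  b <- mol$bonds
  order_of <- function(i, j) {
    k <- which((b$i == i & b$j == j) | (b$i == j & b$j == i))
    if (length(k)) b$order[k[1]] else 0L
  }
  hits <- list()
  for (n_mid in which(el == "N" & mol$atoms$formal_charge == 1L)) {
    nb <- bonded_atoms(mol, n_mid)
    nb_n <- nb[el[nb] == "N"]
    if (length(nb_n) != 2) next
    for (perm in list(nb_n, rev(nb_n))) {
      n_term <- perm[1]; n_att <- perm[2]
      if (mol$atoms$formal_charge[n_term] != -1L) next
      if (length(bonded_atoms(mol, n_term)) != 1) next
      if (order_of(n_mid, n_term) != 2 || order_of(n_mid, n_att) != 2) next
      att_nb <- setdiff(bonded_atoms(mol, n_att), n_mid)
      if (!length(att_nb) || any(el[att_nb] == "H")) next
      hits[[length(hits) + 1]] <- data.frame(
        n_attached = n_att, n_mid = n_mid, n_term = n_term)
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(n_attached = integer(), n_mid = integer(),
                  n_term = integer())
}

.strip_coordinates <- function(mol) {
  mol$atoms$x <- NA_real_; mol$atoms$y <- NA_real_; mol$atoms$z <- NA_real_
  mol
}

#' Propargylate a carboxylic acid
#'
#' Converts R-COOH into the prop-2-yn-1-yl ester R-COO-CH2-C#CH (the
#' alkyne handle for click conjugation). The molecule must contain exactly
#' one carboxylic acid group.
#'
#' @param acid a \code{molecule} with explicit hydrogens.
#' @return the propargyl ester \code{molecule} (without coordinates).
#' @export
propargylate <- function(acid) {
  stopifnot(inherits(acid, "molecule"))
  acids <- .find_carboxylic_acids(acid)
  if (nrow(acids) == 0) stop("no carboxylic acid group in ", sQuote(acid$id))
  if (nrow(acids) > 1) {
    stop("multiple carboxylic acid groups in ", sQuote(acid$id),
         "; esterification is ambiguous")
  }
  atoms <- acid$atoms
  bonds <- acid$bonds
  h_idx <- acids$h[1]
  o_idx <- acids$o_single[1]
  n0 <- nrow(atoms)
  new_atoms <- data.frame(
    element = c("C", "H", "H", "C", "C", "H"),
    Z = .atomic_number[c("C", "H", "H", "C", "C", "H")],
    x = NA_real_, y = NA_real_, z = NA_real_, formal_charge = 0L)
  ch2 <- n0 + 1L; h1 <- n0 + 2L; h2 <- n0 + 3L
  c_int <- n0 + 4L; c_term <- n0 + 5L; h3 <- n0 + 6L
  atoms <- rbind(atoms, new_atoms)
  bonds <- rbind(bonds,
                 data.frame(i = c(o_idx, ch2, ch2, ch2, c_int, c_term),
                            j = c(ch2, h1, h2, c_int, c_term, h3),
                            order = c(1L, 1L, 1L, 1L, 3L, 1L)))
  # drop the acid proton and remap indices
  keep <- setdiff(seq_len(nrow(atoms)), h_idx)
  remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
  bonds <- bonds[bonds$i != h_idx & bonds$j != h_idx, ]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  molecule(atoms[keep, c("element", "x", "y", "z", "formal_charge")], bonds,
           id = paste0(acid$id, "-propargyl"))
}

#' Click conjugation: azide-alkyne cycloaddition
#'
#' Joins a terminal alkyne and an organic azide into the
#' 1,4-disubstituted 1,2,3-triazole (the copper(I)-selective regioisomer).
#' Every atom of both reactants is conserved.
#'
#' @param alkyne a \code{molecule} with exactly one terminal alkyne.
#' @param azide a \code{molecule} with exactly one organic azide group.
#' @param id label of the product.
#' @return the triazole conjugate \code{molecule} (without coordinates).
#' @export
click_conjugate <- function(alkyne, azide, id = NULL) {
  stopifnot(inherits(alkyne, "molecule"), inherits(azide, "molecule"))
  alks <- .find_terminal_alkynes(alkyne)
  if (nrow(alks) == 0) stop("no terminal alkyne in ", sQuote(alkyne$id))
  if (nrow(alks) > 1) {
    stop("multiple terminal alkynes in ", sQuote(alkyne$id),
         "; disambiguate before conjugation")
  }
  azs <- .find_azides(azide)
  if (nrow(azs) == 0) stop("no organic azide group in ", sQuote(azide$id))
  if (nrow(azs) > 1) {
    stop("multiple azide groups in ", sQuote(azide$id),
         "; disambiguate before conjugation")
  }
  n_alk <- n_atoms(alkyne)
  atoms <- rbind(alkyne$atoms, azide$atoms)
  az_bonds <- azide$bonds
  az_bonds$i <- az_bonds$i + n_alk
  az_bonds$j <- az_bonds$j + n_alk
  bonds <- rbind(alkyne$bonds, az_bonds)
  c4 <- alks$c_internal[1]; c5 <- alks$c_terminal[1]
  n1 <- azs$n_attached[1] + n_alk
  n2 <- azs$n_mid[1] + n_alk
  n3 <- azs$n_term[1] + n_alk
  # triple bond becomes the ring C4=C5 double bond
  tb <- which((bonds$i == c4 & bonds$j == c5) |
                (bonds$i == c5 & bonds$j == c4))
  bonds$order[tb] <- 2L
  # N1-N2 relaxes to a single bond; N2=N3 stays double
  nn <- which((bonds$i == n1 & bonds$j == n2) |
                (bonds$i == n2 & bonds$j == n1))
  bonds$order[nn] <- 1L
  bonds <- rbind(bonds, data.frame(i = c(n3, c5), j = c(c4, n1),
                                   order = c(1L, 1L)))
  atoms$formal_charge[c(n2, n3)] <- 0L
  if (is.null(id)) id <- paste0(alkyne$id, "+", azide$id)
  out <- molecule(atoms[, c("element", "x", "y", "z", "formal_charge")],
                  bonds, id = id)
  .strip_coordinates(out)
}

#' Enumerate a click conjugate library
#'
#' Crosses every alkyne scaffold with every azide and de-duplicates the
#' products by canonical structure.
#'
#' @param scaffolds list of terminal-alkyne \code{molecule}s.
#' @param azides list of azide \code{molecule}s.
#' @return list of compound records (\code{id}, \code{molecule},
#'   \code{formula}, \code{mass}, \code{role = "conjugate"},
#'   \code{smiles}), one per unique product.
#' @export
enumerate_library <- function(scaffolds, azides) {
  if (!length(scaffolds) || !length(azides)) {
    stop("scaffold and azide lists must be non-empty")
  }
  records <- list()
  seen <- character()
  for (s in scaffolds) for (a in azides) {
    prod <- click_conjugate(s, a)
    can <- to_canonical_smiles(prod)
    if (can %in% seen) next
    seen <- c(seen, can)
    f <- molecular_formula(prod)
    records[[length(records) + 1]] <- list(
      id = prod$id, molecule = prod, formula = f,
      mass = monoisotopic_mass(f), role = "conjugate", smiles = can)
  }
  records
}

#' Export a conjugate library as CSV (and optionally SDF)
#'
#' @param library list of records from \code{\link{enumerate_library}}.
#' @param csv_file path for the CSV manifest.
#' @param sdf_file optional path for a multi-record SDF.
#' @return the CSV path, invisibly.
#' @export
write_library <- function(library, csv_file, sdf_file = NULL) {
  man <- do.call(rbind, lapply(library, function(r) {
    data.frame(id = r$id, smiles = r$smiles, formula = r$formula,
               mass = r$mass, role = r$role)
  }))
  utils::write.csv(man, csv_file, row.names = FALSE)
  if (!is.null(sdf_file)) {
    blocks <- vapply(library, function(r) write_sdf(r$molecule), character(1))
    writeLines(paste(blocks, collapse = "\n"), sdf_file)
  }
  invisible(csv_file)
}
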