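# Packaged compound set: ibuprofen (1), indomethacin (6), their propargyl
# esters (3, 7) and the fourteen 1-aryl-triazolyl conjugates (5a-g, 8a-g).
# Structures were transcribed from the systematic product names into SMILES;
# the high-resolution MS formula recorded for each compound guards the
# transcription.

.aryl_azide_substituents <- c(
  a = "2-Cl", b = "4-Cl", c = "4-F", d = "4-CH3",
  e = "2-OCH3", f = "4-OCH3", g = "4-NO2")

.fixture_table <- function() {
  ibu <- "CC(C)Cc1ccc(cc1)C(C)C(=O)O"
  ind <- "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1"
  ibu_yne <- "CC(C)Cc1ccc(cc1)C(C)C(=O)OCC#C"
  ind_yne <- "COc1ccc2c(c1)c(CC(=O)OCC#C)c(C)n2C(=O)c1ccc(Cl)cc1"
  aryl <- c(a = "c2ccccc2Cl", b = "c2ccc(Cl)cc2", c = "c2ccc(F)cc2",
            d = "c2ccc(C)cc2", e = "c2ccccc2OC", f = "c2ccc(OC)cc2",
            g = "c2ccc([N+](=O)[O-])cc2")
  tri5 <- sprintf("CC(C)Cc1ccc(cc1)C(C)C(=O)OCc3cn(-%s)nn3", aryl)
  tri8 <- sprintf(
    "COc1ccc4c(c1)c(CC(=O)OCc3cn(-%s)nn3)c(C)n4C(=O)c1ccc(Cl)cc1", aryl)
  data.frame(
    id = c("1", "3", paste0("5", letters[1:7]),
           "6", "7", paste0("8", letters[1:7])),
    smiles = c(ibu, ibu_yne, tri5, ind, ind_yne, tri8),
    formula = c("C13H18O2", "C16H20O2",
                "C22H24ClN3O2", "C22H24ClN3O2", "C22H24FN3O2", "C23H27N3O2",
                "C23H27N3O3", "C23H27N3O3", "C22H24N4O4",
                "C19H16ClNO4", "C22H18ClNO4",
                "C28H22Cl2N4O4", "C28H22Cl2N4O4", "C28H22ClFN4O4",
                "C29H25ClN4O4", "C29H25ClN4O5", "C29H25ClN4O5",
                "C28H22ClN5O6"),
    role = c("reference drug", "precursor", rep("conjugate", 7),
             "reference drug", "precursor", rep("conjugate", 7)),
    stringsAsFactors = FALSE)
}

#' Load the packaged NSAID-triazole compound set
#'
#' Returns the 18 study compounds: ibuprofen (1), its propargyl ester (3),
#' ibuprofen-triazole conjugates 5a-g, indomethacin (6), its propargyl ester
#' (7) and indomethacin-triazole conjugates 8a-g. Each record's formula,
#' recomputed from the parsed structure, is checked against the recorded
#' high-resolution MS formula before the set is returned.
#'
#' @return list of compound records, each a list with elements \code{id},
#'   \code{molecule}, \code{formula} and \code{role}.
#' @export
load_fixture_set <- function() {
  tab <- .fixture_table()
  records <- lapply(seq_len(nrow(tab)), function(k) {
    mol <- parse_structure(tab$smiles[k], "smiles", id = tab$id[k])
    got <- molecular_formula(mol)
    if (got != tab$formula[k]) {
      stop(sprintf("fixture %s: formula %s from structure != recorded %s",
                   tab$id[k], got, tab$formula[k]))
    }
    list(id = tab$id[k], molecule = mol, formula = tab$formula[k],
         role = tab$role[k])
  })
  names(records) <- tab$id
  records
}

#' Compound manifest as a data frame
#'
#' @return data.frame with columns \code{id}, \code{smiles}, \code{formula},
#'   \code{role} for the packaged compound set.
#' @export
fixture_manifest <- function() .fixture_table()

#' Write / read a compound manifest CSV
#'
#' @param manifest data.frame with columns id, smiles, formula, role.
#' @param file path to the CSV.
#' @return \code{read_manifest} returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, file) {
  stopifnot(all(c("id", "smiles") %in% names(manifest)))
  utils::write.csv(manifest, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  man <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(man))) {
    stop("manifest must have columns 'id' and 'smiles'")
  }
  man$id <- as.character(man$id)
  man
}
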