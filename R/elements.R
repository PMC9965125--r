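# Element-level parameter tables shared across modules.
# All tabulated values are standard literature constants; they are the
# configuration surface of the descriptor engines, not fitted quantities.

# monoisotopic masses of the most abundant isotope (Da)
.monoisotopic <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473
)

# atomic numbers for the supported elements
.atomic_number <- c(
  H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L,
  Cl = 17L, Br = 35L, I = 53L
)

# Bondi van der Waals radii (Angstrom)
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

# valence electron counts (extended Hueckel core charges)
.valence_electrons <- c(
  H = 1L, C = 4L, N = 5L, O = 6L, F = 7L, S = 6L, Cl = 7L, Br = 7L, I = 7L
)

#' Monoisotopic mass of an elemental formula
#'
#' Sums most-abundant-isotope masses for a Hill-notation formula such as
#' \code{"C22H24ClN3O2"}. Neutral-formula masses are reported (electron mass
#' ignored), matching the convention of printed high-resolution MS
#' "calculated" values for M+ ions.
#'
#' @param formula elemental formula string, e.g. \code{"C16H20O2"}.
#' @return mass in Da, rounded to 4 decimal places.
#' @examples
#' monoisotopic_mass("C16H20O2")  # 244.1463
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.monoisotopic))
  if (length(unknown)) {
    stop("no monoisotopic mass tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  }
  round(sum(.monoisotopic[names(counts)] * counts), 4)
}

#' Parse an elemental formula into element counts
#'
#' @param formula formula string (element symbols with optional counts).
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula: ", formula)
  }
  el <- sub("[0-9]*$", "", tokens)
  n <- as.integer(sub("^[A-Za-z]+", "", paste0(tokens, "")))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  storage.mode(counts) <- "integer"
  counts[order(names(counts))]
}

#' Format element counts as a Hill-notation formula
#'
#' Carbon first, hydrogen second, remaining elements alphabetical.
#'
#' @param counts named integer vector of element counts.
#' @return formula string.
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  els <- names(counts)
  rest <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), rest)
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}
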