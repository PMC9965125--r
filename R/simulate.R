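# Synthetic data with the statistical structure the modelling stages
# assume: correlated descriptor blocks with a known sparse linear response,
# and substituted aryl-azide panels for library enumeration.

#' Specify a synthetic linear QSAR dataset
#'
#' @param n number of compounds.
#' @param p number of descriptors.
#' @param informative indices (or names) of the descriptors carrying signal.
#' @param coefficients true coefficients of the informative descriptors.
#' @param intercept true intercept.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param transform response transform tag recorded in the dataset.
#' @param rho exchangeable correlation among descriptors (default 0.3,
#'   a realistic mild inter-descriptor correlation).
#' @param seed RNG seed.
#' @return object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(n = 50L, p = 10L, informative = 1:3,
                            coefficients = c(1.5, -2, 1), intercept = 0.5,
                            noise_sd = 0.1,
                            transform = c("identity", "reciprocal"),
                            rho = 0.3, seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(noise_sd >= 0, abs(rho) < 1,
            length(informative) == length(coefficients),
            all(informative >= 1), all(informative <= p))
  structure(list(n = as.integer(n), p = as.integer(p),
                 informative = as.integer(informative),
                 coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd, transform = transform, rho = rho,
                 seed = as.integer(seed)), class = "simulation_spec")
}

#' Generate a synthetic descriptor matrix with a known linear response
#'
#' Descriptors are drawn from a multivariate normal with exchangeable
#' correlation \code{rho}; the response is the stated linear combination of
#' the informative descriptors plus Gaussian noise, then tagged with the
#' requested transform.
#'
#' @param spec a \code{simulation_spec}.
#' @return a \code{descriptor_matrix}; the true generating parameters are
#'   attached as the \code{"truth"} attribute.
#' @export
generate_linear_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  # exchangeable correlation via a shared latent factor:
  # x_j = sqrt(rho) z0 + sqrt(1 - rho) z_j  (rho >= 0)
  if (spec$rho >= 0) {
    z0 <- stats::rnorm(spec$n)
    Z <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p)
    X <- sqrt(spec$rho) * z0 + sqrt(1 - spec$rho) * Z
  } else {
    sigma <- matrix(spec$rho, spec$p, spec$p)
    diag(sigma) <- 1
    L <- chol(sigma)
    X <- matrix(stats::rnorm(spec$n * spec$p), spec$n, spec$p) %*% L
  }
  colnames(X) <- paste0("d", seq_len(spec$p))
  lin <- spec$intercept +
    drop(X[, spec$informative, drop = FALSE] %*% spec$coefficients)
  y_lin <- lin + stats::rnorm(spec$n, sd = spec$noise_sd)
  y <- if (spec$transform == "reciprocal") 1 / y_lin else y_lin
  out <- descriptor_matrix(X, ids = paste0("cmpd", seq_len(spec$n)),
                           response = y, response_name = "synthetic",
                           transform = spec$transform)
  attr(out, "truth") <- list(
    informative = colnames(X)[spec$informative],
    coefficients = spec$coefficients, intercept = spec$intercept,
    noise_sd = spec$noise_sd)
  out
}

# registered aryl substituent vocabulary: SMILES fragments placed at ring
# positions 2, 3 or 4 of phenyl azide
.substituent_vocabulary <- c(
  H = "", Cl = "Cl", F = "F", Br = "Br", CH3 = "C", OCH3 = "OC",
  NO2 = "[N+](=O)[O-]", CF3 = "C(F)(F)F"
)

.azide_smiles <- function(position, group) {
  if (!group %in% names(.substituent_vocabulary)) {
    stop("unknown substituent group ", sQuote(group), "; registered: ",
         paste(names(.substituent_vocabulary), collapse = ", "))
  }
  frag <- .substituent_vocabulary[[group]]
  if (group == "H" || frag == "") {
    return("[N-]=[N+]=Nc1ccccc1")
  }
  ring <- switch(as.character(position),
                 "2" = sprintf("c1ccccc1%s", frag),
                 "3" = sprintf("c1cccc(%s)c1", frag),
                 "4" = sprintf("c1ccc(%s)cc1", frag),
                 stop("azide substituent position must be 2, 3 or 4"))
  sprintf("[N-]=[N+]=N%s", ring)
}

#' Default aryl azide panel of the conjugate library
#'
#' The seven-membered panel used to enumerate the triazole conjugates:
#' 2-Cl, 4-Cl, 4-F, 4-CH3, 2-OCH3, 4-OCH3 and 4-NO2 phenyl azides.
#'
#' @return data.frame with columns \code{position}, \code{group}.
#' @export
default_azide_panel <- function() {
  data.frame(position = c(2L, 4L, 4L, 4L, 2L, 4L, 4L),
             group = c("Cl", "Cl", "F", "CH3", "OCH3", "OCH3", "NO2"),
             stringsAsFactors = FALSE)
}

#' Generate a panel of substituted phenyl azides
#'
#' @param substituents data.frame with columns \code{position} (2, 3 or 4)
#'   and \code{group} (from the registered substituent vocabulary); defaults
#'   to the seven-azide panel of \code{\link{default_azide_panel}}.
#' @return list of azide \code{molecule}s with explicit hydrogens.
#' @export
generate_azide_panel <- function(substituents = default_azide_panel()) {
  stopifnot(all(c("position", "group") %in% names(substituents)))
  lapply(seq_len(nrow(substituents)), function(k) {
    pos <- substituents$position[k]; grp <- substituents$group[k]
    id <- if (grp == "H") "phenyl azide" else sprintf("%d-%s phenyl azide", pos, grp)
    parse_structure(.azide_smiles(pos, grp), "smiles", id = id)
  })
}
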