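# Assembly of the per-compound descriptor vector and the compound-by-
# descriptor matrix, with CSV import/export and a provenance sidecar.

#' Names of all registered descriptors
#'
#' @return character vector: the CPSA catalogue followed by the electronic
#'   catalogue.
#' @export
descriptor_catalogue <- function() {
  c(names(.cpsa_catalogue()), names(.electronic_catalogue()))
}

#' Compute the full descriptor vector for one compound
#'
#' Embeds the molecule if needed, assigns charges and surface areas,
#' builds the electronic structure and evaluates every requested
#' descriptor.
#'
#' @param mol a \code{molecule}.
#' @param descriptors names from \code{\link{descriptor_catalogue}}.
#' @param probe,n_points surface parameters.
#' @param scheme charge scheme.
#' @param seed embedding seed (recorded; the embedding is deterministic).
#' @return named numeric vector with a provenance attribute.
#' @export
compute_descriptor_vector <- function(mol,
                                      descriptors = descriptor_catalogue(),
                                      probe = 1.4, n_points = 960L,
                                      scheme = "gasteiger", seed = 1L) {
  unknown <- setdiff(descriptors, descriptor_catalogue())
  if (length(unknown)) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "))
  }
  if (!has_coordinates(mol)) mol <- embed_3d(mol, seed = seed)
  cpsa_names <- intersect(descriptors, names(.cpsa_catalogue()))
  elec_names <- intersect(descriptors, names(.electronic_catalogue()))
  vals <- numeric(0)
  if (length(cpsa_names)) {
    vals <- c(vals, cpsa_descriptors(mol, descriptors = cpsa_names,
                                     probe = probe, n_points = n_points,
                                     scheme = scheme))
  }
  if (length(elec_names)) {
    vals <- c(vals, electronic_descriptors(mol, descriptors = elec_names))
  }
  vals <- vals[descriptors]
  attr(vals, "provenance") <- list(
    charge_scheme = scheme, probe = probe, radii_set = "bondi",
    n_points = as.integer(n_points), electronic_method = "extended_hueckel",
    embed_seed = as.integer(seed))
  vals
}

#' Compute a descriptor matrix for a compound set
#'
#' @param compounds list of compound records (as from
#'   \code{\link{load_fixture_set}} or \code{\link{enumerate_library}}) or
#'   a list of \code{molecule}s.
#' @param descriptors,probe,n_points,scheme,seed see
#'   \code{\link{compute_descriptor_vector}}.
#' @param on_error \code{"stop"} or \code{"collect"}: with "collect",
#'   per-compound failures are gathered and reported; the run fails only if
#'   every compound fails.
#' @return data.frame (compounds x descriptors, rownames = compound ids)
#'   with a provenance attribute and, when \code{on_error = "collect"}, a
#'   \code{"failures"} attribute naming failed compounds.
#' @export
compute_descriptor_table <- function(compounds,
                                     descriptors = descriptor_catalogue(),
                                     probe = 1.4, n_points = 960L,
                                     scheme = "gasteiger", seed = 1L,
                                     on_error = c("stop", "collect")) {
  on_error <- match.arg(on_error)
  if (!length(compounds)) stop("empty compound set")
  mols <- lapply(compounds, function(x) {
    if (inherits(x, "molecule")) x else x$molecule
  })
  ids <- vapply(mols, function(m) m$id, character(1))
  rows <- vector("list", length(mols))
  failures <- character()
  for (k in seq_along(mols)) {
    res <- if (on_error == "stop") {
      compute_descriptor_vector(mols[[k]], descriptors, probe, n_points,
                                scheme, seed)
    } else {
      tryCatch(
        compute_descriptor_vector(mols[[k]], descriptors, probe, n_points,
                                  scheme, seed),
        error = function(e) {
          failures <<- c(failures, sprintf("%s: %s", ids[k],
                                           conditionMessage(e)))
          NULL
        })
    }
    rows[[k]] <- res
  }
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) {
    stop("descriptor computation failed for every compound:\n",
         paste(failures, collapse = "\n"))
  }
  tab <- as.data.frame(do.call(rbind, rows[ok]))
  rownames(tab) <- ids[ok]
  attr(tab, "provenance") <- attr(rows[ok][[1]], "provenance")
  if (on_error == "collect") attr(tab, "failures") <- failures
  tab
}

#' Write / read a descriptor matrix CSV with a provenance sidecar
#'
#' The CSV holds one row per compound (id column first, header mandatory);
#' provenance is written next to it as \code{<file>.provenance.yml}.
#'
#' @param table data.frame from \code{\link{compute_descriptor_table}}.
#' @param file CSV path.
#' @return \code{read_descriptor_csv} returns the data.frame with its
#'   provenance attribute restored (when the sidecar exists).
#' @export
write_descriptor_csv <- function(table, file) {
  out <- data.frame(id = rownames(table), table, check.names = FALSE)
  utils::write.csv(out, file, row.names = FALSE)
  prov <- attr(table, "provenance")
  if (!is.null(prov)) {
    yaml::write_yaml(prov, paste0(file, ".provenance.yml"))
  }
  invisible(file)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(file) {
  tab <- utils::read.csv(file, check.names = FALSE)
  if (!"id" %in% names(tab)) stop("descriptor CSV must have an 'id' column")
  rownames(tab) <- tab$id
  tab$id <- NULL
  sidecar <- paste0(file, ".provenance.yml")
  if (file.exists(sidecar)) {
    attr(tab, "provenance") <- yaml::read_yaml(sidecar)
  }
  tab
}
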