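# Arithmetic layer over the pharmacology tables: edema inhibition,
# relative potency, cyclooxygenase selectivity and structure-activity
# pair contrasts. Only values printed in the study's running text are
# packaged; unprinted cells are absent, never imputed.

#' Percent inhibition of edema
#'
#' @param control_edema mean edema of the control group (> 0).
#' @param treated_edema mean edema of the treated group (>= 0).
#' @return percent inhibition, \code{100 (control - treated) / control}.
#' @export
percent_inhibition <- function(control_edema, treated_edema) {
  if (any(control_edema <= 0)) stop("control edema must be positive")
  if (any(treated_edema < 0)) stop("treated edema must be non-negative")
  100 * (control_edema - treated_edema) / control_edema
}

#' Relative potency versus a reference drug
#'
#' @param test_inhibition inhibition of the test compound.
#' @param reference_inhibition inhibition of the reference drug (> 0).
#' @return percent potency, \code{100 test / reference}.
#' @export
relative_potency <- function(test_inhibition, reference_inhibition) {
  if (any(reference_inhibition <= 0)) {
    stop("reference inhibition must be positive")
  }
  100 * test_inhibition / reference_inhibition
}

#' COX selectivity index
#'
#' \code{SI = IC50(COX-1) / IC50(COX-2)}; values above 1 indicate
#' COX-2 selectivity.
#'
#' @param ic50_cox1,ic50_cox2 half-maximal inhibitory concentrations
#'   (micromolar, > 0).
#' @return dimensionless selectivity index.
#' @export
selectivity_index <- function(ic50_cox1, ic50_cox2) {
  if (any(ic50_cox1 <= 0) || any(ic50_cox2 <= 0)) {
    stop("IC50 values must be positive")
  }
  ic50_cox1 / ic50_cox2
}

#' Packaged bioactivity table
#'
#' Long-format table of the potency, edema-inhibition, IC50 and
#' selectivity-index values printed in the study's text. Each endpoint has
#' exactly one designated reference drug.
#'
#' @return data.frame with columns \code{id}, \code{endpoint}, \code{value},
#'   \code{is_reference}.
#' @export
bioactivity_table <- function() {
  rows <- rbind(
    # carrageenan paw edema, % potency vs indomethacin = 100
    data.frame(id = c("3", "5a", "5b", "5d", "5e", "1", "6"),
               endpoint = "anti_inflammatory_potency",
               value = c(105.8, 117.6, 116.5, 93.8, 109.1, 97.2, 100),
               is_reference = c(rep(FALSE, 6), TRUE)),
    # % inhibition of edema after 24 h
    data.frame(id = c("5a", "5e", "1", "8a", "6"),
               endpoint = "edema_inhibition_24h",
               value = c(22.5, 42.1, 11.2, 33.3, 12.0),
               is_reference = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    # acetic acid writhing, % potency vs indomethacin = 100
    data.frame(id = c("5a", "5b", "5c", "5e", "5f", "8a", "8b", "8e", "8f",
                      "8g", "1", "6"),
               endpoint = "peripheral_analgesic_potency",
               value = c(116.0, 121.9, 116.0, 88.2, 111.4, 68.7, 64.5,
                         112.5, 93.0, 134.1, 81.5, 100),
               is_reference = c(rep(FALSE, 11), TRUE)),
    # hot plate, % potency vs indomethacin = 100
    data.frame(id = c("5a", "5b", "5e", "5f", "8b", "8c", "8d", "8f",
                      "1", "6"),
               endpoint = "central_analgesic_potency",
               value = c(96.5, 48.0, 49.6, 0.4, 17.2, 85.1, 86.0, 117.7,
                         96.1, 100),
               is_reference = c(rep(FALSE, 9), TRUE)),
    # COX-1 IC50 (micromolar)
    data.frame(id = c("5e", "1"),
               endpoint = "cox1_ic50",
               value = c(5.417, 13.16),
               is_reference = c(FALSE, TRUE)),
    # selectivity index IC50(COX-1)/IC50(COX-2)
    data.frame(id = c("3", "5a", "5b", "5d", "5e", "1"),
               endpoint = "selectivity_index",
               value = c(2.262, 23.096, 9.619, 2.158, 0.387, 0.106),
               is_reference = c(rep(FALSE, 5), TRUE))
  )
  rownames(rows) <- NULL
  rows
}

#' Structure-activity pair contrast report
#'
#' For each (id, id, label) pair, reports the signed difference of the
#' endpoint values and a direction verdict. Pairs referencing a compound
#' without a printed value for the endpoint raise an error naming it.
#'
#' @param table long-format bioactivity table
#'   (see \code{\link{bioactivity_table}}).
#' @param pairs data.frame with columns \code{id_a}, \code{id_b},
#'   \code{endpoint}, \code{label}.
#' @return data.frame with the pair ids, values, signed difference
#'   (\code{value_a - value_b}) and verdict (\code{"a > b"}, \code{"b > a"}
#'   or \code{"tie"}), in the order given.
#' @export
sar_pair_report <- function(table, pairs) {
  stopifnot(all(c("id", "endpoint", "value") %in% names(table)),
            all(c("id_a", "id_b", "endpoint") %in% names(pairs)))
  if (is.null(pairs$label)) pairs$label <- ""
  lookup <- function(id, endpoint) {
    hit <- table$value[table$id == id & table$endpoint == endpoint]
    if (!length(hit)) {
      stop("no printed value for compound ", sQuote(id), " on endpoint ",
           sQuote(endpoint))
    }
    hit[[1]]
  }
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    va <- lookup(pairs$id_a[k], pairs$endpoint[k])
    vb <- lookup(pairs$id_b[k], pairs$endpoint[k])
    diff <- va - vb
    data.frame(id_a = pairs$id_a[k], id_b = pairs$id_b[k],
               endpoint = pairs$endpoint[k], label = pairs$label[k],
               value_a = va, value_b = vb, difference = diff,
               verdict = if (diff > 0) "a > b" else if (diff < 0) "b > a"
               else "tie")
  })
  do.call(rbind, out)
}
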