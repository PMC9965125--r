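# Multilinear QSAR modelling: ordinary least squares over selected
# descriptor columns, leave-one-out / leave-many-out cross-validation and
# best-multilinear-regression subset search.

#' Construct a descriptor matrix
#'
#' @param values numeric matrix or data.frame (compounds x descriptors).
#' @param ids compound identifiers (rownames used when missing).
#' @param response numeric response vector (one value per compound).
#' @param response_name label for the response.
#' @param transform \code{"identity"} fits the response as-is;
#'   \code{"reciprocal"} fits \code{1/y} (predictions are inverted back).
#' @return object of class \code{"descriptor_matrix"}.
#' @export
descriptor_matrix <- function(values, ids = rownames(values), response,
                              response_name = "response",
                              transform = c("identity", "reciprocal")) {
  transform <- match.arg(transform)
  X <- as.matrix(values)
  storage.mode(X) <- "double"
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  stopifnot(length(ids) == nrow(X), length(response) == nrow(X))
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("d", seq_len(ncol(X)))
  }
  structure(list(values = X, ids = as.character(ids),
                 response = as.numeric(response),
                 response_name = response_name, transform = transform),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor matrix> %d compounds x %d descriptors, response %s (%s)\n",
              nrow(x$values), ncol(x$values), x$response_name, x$transform))
  invisible(x)
}

.transformed_response <- function(X) {
  if (X$transform == "reciprocal") {
    if (any(X$response == 0)) stop("reciprocal transform undefined at y = 0")
    1 / X$response
  } else {
    X$response
  }
}

.design <- function(X, columns) {
  missing_cols <- setdiff(columns, colnames(X$values))
  if (length(missing_cols)) {
    stop("descriptor column(s) not present: ",
         paste(missing_cols, collapse = ", "))
  }
  M <- X$values[, columns, drop = FALSE]
  if (anyNA(M)) stop("missing values in selected descriptor columns")
  M
}

#' Fit an ordinary least squares QSAR model
#'
#' @param X a \code{descriptor_matrix}.
#' @param columns descriptor names to fit.
#' @return object of class \code{"qsar_model"} with coefficients, intercept,
#'   per-coefficient t-values, R2, F, s2, and slots for cross-validated R2.
#' @export
fit_ols <- function(X, columns) {
  M <- .design(X, columns)
  y <- .transformed_response(X)
  n <- nrow(M); k <- ncol(M)
  if (n <= k + 1) stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")")
  D <- cbind(`(Intercept)` = 1, M)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop_cols <- colnames(D)[qrD$pivot[seq(qrD$rank + 1, ncol(D))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(setdiff(drop_cols, "(Intercept)"), collapse = ", "))
  }
  coef <- qr.coef(qrD, y)
  fitted <- drop(D %*% coef)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  s2 <- rss / (n - k - 1)
  fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  XtXinv <- chol2inv(qr.R(qrD))
  se <- sqrt(pmax(diag(XtXinv), 0) * s2)
  tvals <- coef / se
  structure(list(
    descriptors = columns, coefficients = coef[-1], intercept = coef[[1]],
    t_values = tvals[-1], t_intercept = tvals[[1]],
    se = se[-1], r2 = r2, f = fstat, s2 = s2, rss = rss, tss = tss,
    n = n, k = k, fitted = fitted, residuals = resid,
    r2cv_loo = NA_real_, r2cv_lmo = NA_real_,
    transform = X$transform, response_name = X$response_name,
    training_ids = X$ids), class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<QSAR model> %s (%s), %d descriptors, n = %d\n",
              x$response_name, x$transform, x$k, x$n))
  tab <- data.frame(coefficient = c(x$intercept, x$coefficients),
                    t = c(x$t_intercept, x$t_values),
                    row.names = c("(Intercept)", x$descriptors))
  print(round(tab, 5))
  cat(sprintf("R2 = %.4f, F = %.2f, s2 = %.5g", x$r2, x$f, x$s2))
  if (!is.na(x$r2cv_loo)) cat(sprintf(", R2cvOO = %.4f", x$r2cv_loo))
  if (!is.na(x$r2cv_lmo)) cat(sprintf(", R2cvMO = %.4f", x$r2cv_lmo))
  cat("\n")
  invisible(x)
}

#' Leave-one-out cross-validated R2
#'
#' PRESS-based q2 via the hat-matrix shortcut: each deleted residual is
#' \code{e_i / (1 - h_ii)}, so no refitting is needed.
#'
#' @param X a \code{descriptor_matrix}.
#' @param columns descriptor names.
#' @return leave-one-out q2 (\code{1 - PRESS/TSS}).
#' @export
loo_cv <- function(X, columns) {
  M <- .design(X, columns)
  y <- .transformed_response(X)
  n <- nrow(M); k <- ncol(M)
  if (n < k + 3) stop("need n >= k + 3 for leave-one-out validation")
  D <- cbind(1, M)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient design in loo_cv")
  h <- rowSums(qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]^2)
  resid <- y - drop(D %*% qr.coef(qrD, y))
  press <- sum((resid / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Leave-many-out cross-validated R2
#'
#' Compounds are randomly partitioned into \code{n_groups} folds; each fold
#' is left out once per repeat and predicted from the remaining compounds.
#' q2 pools the PRESS within a repeat and averages over repeats.
#'
#' @param X a \code{descriptor_matrix}.
#' @param columns descriptor names.
#' @param n_groups number of folds (default 3: leave-one-third-out).
#' @param n_repeats number of random partitions averaged.
#' @param seed RNG seed making the partition sequence reproducible.
#' @return leave-many-out q2.
#' @export
lmo_cv <- function(X, columns, n_groups = 3L, n_repeats = 200L, seed = 1L) {
  M <- .design(X, columns)
  y <- .transformed_response(X)
  n <- nrow(M); k <- ncol(M)
  if (n_groups < 2) stop("n_groups must be at least 2")
  # n_groups == n is the degenerate leave-one-out reduction
  if (n_groups != n && n < n_groups * (k + 2)) {
    stop("folds too small: need n >= n_groups * (k + 2)")
  }
  tss <- sum((y - mean(y))^2)
  rng <- .seeded_rng(seed)
  q2 <- vapply(seq_len(n_repeats), function(rep) {
    fold <- rng$sample(rep(seq_len(n_groups), length.out = n))
    press <- 0
    for (g in seq_len(n_groups)) {
      test <- which(fold == g)
      train <- which(fold != g)
      Dtr <- cbind(1, M[train, , drop = FALSE])
      coef <- qr.coef(qr(Dtr), y[train])
      pred <- drop(cbind(1, M[test, , drop = FALSE]) %*% coef)
      press <- press + sum((y[test] - pred)^2)
    }
    1 - press / tss
  }, numeric(1))
  mean(q2)
}

# localised RNG so model validation never disturbs the caller's RNG state
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  list(sample = function(x) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    out <- sample(x)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  })
}

#' Best multilinear regression descriptor selection
#'
#' Finds the k-descriptor OLS model maximising R2. The search is exhaustive
#' over all subsets when their number is at most \code{max_exhaustive};
#' otherwise forward stepwise selection is used after excluding one of each
#' descriptor pair with absolute correlation above \code{collinearity_limit}.
#' Ties are broken by higher leave-one-out q2, then by lexicographic column
#' order. Cross-validation statistics are attached to the returned model.
#'
#' @param X a \code{descriptor_matrix}.
#' @param k number of descriptors to select.
#' @param max_exhaustive subset-count threshold for the exhaustive search.
#' @param collinearity_limit absolute-correlation prefilter for stepwise mode.
#' @param cv_seed seed for the leave-many-out statistic.
#' @return the selected \code{qsar_model} with \code{r2cv_loo} and
#'   \code{r2cv_lmo} filled in.
#' @export
bmlr_select <- function(X, k = 3L, max_exhaustive = 1e5,
                        collinearity_limit = 0.95, cv_seed = 1L) {
  p <- ncol(X$values)
  cols <- colnames(X$values)
  if (p < k) stop("fewer descriptors (", p, ") than requested k = ", k)
  n_subsets <- choose(p, k)
  candidates <- if (n_subsets <= max_exhaustive) {
    utils::combn(cols, k, simplify = FALSE)
  } else {
    .stepwise_candidates(X, k, collinearity_limit)
  }
  best <- NULL; best_cols <- NULL; best_loo <- -Inf
  for (sub in candidates) {
    m <- tryCatch(fit_ols(X, sub), error = function(e) NULL)
    if (is.null(m)) next
    if (is.null(best) || m$r2 > best$r2 + 1e-12) {
      best <- m; best_cols <- sub; best_loo <- NA
    } else if (abs(m$r2 - best$r2) <= 1e-12) {
      # tie: higher LOO q2, then lexicographic order
      if (is.na(best_loo)) best_loo <- loo_cv(X, best_cols)
      cand_loo <- loo_cv(X, sub)
      replace <- cand_loo > best_loo + 1e-12 ||
        (abs(cand_loo - best_loo) <= 1e-12 &&
           paste(sub, collapse = ",") < paste(best_cols, collapse = ","))
      if (replace) { best <- m; best_cols <- sub; best_loo <- cand_loo }
    }
  }
  if (is.null(best)) stop("no full-rank descriptor subset of size ", k)
  best$r2cv_loo <- loo_cv(X, best_cols)
  best$r2cv_lmo <- tryCatch(
    lmo_cv(X, best_cols, seed = cv_seed), error = function(e) NA_real_)
  best
}

# forward stepwise candidate list after a pairwise collinearity prefilter
.stepwise_candidates <- function(X, k, collinearity_limit) {
  cols <- colnames(X$values)
  cmat <- suppressWarnings(abs(stats::cor(X$values)))
  cmat[!is.finite(cmat)] <- 0
  keep <- character()
  for (cl in cols) {
    if (!length(keep) || all(cmat[cl, keep] <= collinearity_limit)) {
      keep <- c(keep, cl)
    }
  }
  current <- character()
  for (step in seq_len(k)) {
    remaining <- setdiff(keep, current)
    r2s <- vapply(remaining, function(cl) {
      m <- tryCatch(fit_ols(X, c(current, cl)), error = function(e) NULL)
      if (is.null(m)) -Inf else m$r2
    }, numeric(1))
    if (all(!is.finite(r2s))) stop("stepwise selection found no full-rank model")
    current <- c(current, remaining[which.max(r2s)])
  }
  list(current)
}

#' Predict the response for new descriptor values
#'
#' @param object a \code{qsar_model}.
#' @param newdata named numeric vector, or data.frame/matrix with one row
#'   per compound, containing every model descriptor.
#' @param ... unused.
#' @return predicted response on the original (untransformed) scale.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  missing_cols <- setdiff(object$descriptors, colnames(newdata))
  if (length(missing_cols)) {
    stop("missing descriptor(s) in new data: ",
         paste(missing_cols, collapse = ", "))
  }
  lin <- object$intercept +
    drop(newdata[, object$descriptors, drop = FALSE] %*% object$coefficients)
  if (object$transform == "reciprocal") {
    if (any(lin == 0)) stop("reciprocal model: zero linear predictor")
    1 / lin
  } else {
    lin
  }
}

#' Serialise / restore a QSAR model as structured text
#'
#' @param model a \code{qsar_model}.
#' @param file path to a YAML file.
#' @return \code{read_qsar_model} returns the restored \code{qsar_model}.
#' @export
write_qsar_model <- function(model, file) {
  payload <- model[c("descriptors", "coefficients", "intercept", "t_values",
                     "se", "r2", "f", "s2", "n", "k", "r2cv_loo", "r2cv_lmo",
                     "transform", "response_name", "training_ids")]
  payload$coefficients <- as.list(payload$coefficients)
  payload$t_values <- as.list(payload$t_values)
  payload$se <- as.list(payload$se)
  yaml::write_yaml(payload, file, precision = 15L)
  invisible(file)
}

#' @rdname write_qsar_model
#' @export
read_qsar_model <- function(file) {
  payload <- yaml::read_yaml(file)
  payload$coefficients <- unlist(payload$coefficients)
  payload$t_values <- unlist(payload$t_values)
  payload$se <- unlist(payload$se)
  structure(payload, class = "qsar_model")
}
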