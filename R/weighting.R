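#' Wave-average and standardize the subjective scales
#'
#' Each of the five scales is averaged within person across its observed
#' young-adulthood waves and then z-scored over the sample, yielding the
#' standardized benchmark outcomes used throughout selection, PCA and
#' weighting.
#'
#' @param cohort A completed cohort (one imputation copy): every respondent
#'   must have at least one observed wave per scale.
#' @return An `n x 5` numeric matrix with columns `fl, pd, wr, sa, ls`,
#'   each with mean 0 and SD 1.
#' @export
preprocess_scales <- function(cohort) {
  out <- matrix(NA_real_, nrow(cohort), 5,
                dimnames = list(NULL, CATI_SCALES))
  for (j in CATI_SCALES) {
    cols <- scale_wave_columns(cohort, j)
    if (length(cols) == 0) stop("no wave columns found for scale ", j,
                                call. = FALSE)
    vals <- as.matrix(cohort[cols])
    avg <- rowMeans(vals, na.rm = TRUE)
    if (anyNA(avg) || any(!is.finite(avg))) {
      stop("scale ", j, " has respondents with no observed waves",
           call. = FALSE)
    }
    s <- sd(avg)
    if (s < .Machine$double.eps) {
      stop("scale ", j, " has zero variance", call. = FALSE)
    }
    out[, j] <- (avg - mean(avg)) / s
  }
  out
}

new_loading_vector <- function(loadings, eigenvalues) {
  structure(list(loadings = loadings, eigenvalues = eigenvalues),
            class = "cati_loadings")
}

#' First principal component of the subjective scales
#'
#' Eigendecomposition of the 5 x 5 correlation matrix of the standardized
#' scales.  The first eigenvector is returned sign-fixed so flourishing
#' loads positively; all five eigenvalues are returned (they sum to 5).  A
#' warning is emitted if the second eigenvalue also exceeds 1, since the
#' single-component design is then questionable under Kaiser's criterion.
#'
#' @param scales An `n x 5` standardized matrix from [preprocess_scales()],
#'   or a precomputed 5 x 5 correlation matrix.
#' @return A `cati_loadings` object: `loadings` (unit norm, named by scale)
#'   and `eigenvalues` (descending).
#' @export
pca_first_component <- function(scales) {
  if (is.matrix(scales) && nrow(scales) == 5 && ncol(scales) == 5 &&
      isTRUE(all.equal(unname(diag(scales)), rep(1, 5)))) {
    R <- scales
  } else {
    if (nrow(scales) < 6) stop("need at least 6 observations", call. = FALSE)
    R <- cor(scales)
  }
  if (anyNA(R)) stop("correlation matrix has missing entries", call. = FALSE)
  eig <- eigen(R, symmetric = TRUE)
  if (eig$values[5] < 1e-10) {
    stop("rank-deficient scale correlation matrix", call. = FALSE)
  }
  v <- eig$vectors[, 1]
  names(v) <- CATI_SCALES
  if (v["fl"] < 0) v <- -v
  if (eig$values[2] > 1) {
    warning("second eigenvalue exceeds 1; Kaiser's criterion would retain ",
            "more than one component", call. = FALSE)
  }
  new_loading_vector(v, eig$values)
}

#' @export
print.cati_loadings <- function(x, ...) {
  cat("First-principal-component loadings (eigenvalue",
      sprintf("%.3f):\n", x$eigenvalues[1]))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Double-weighting aggregation of coefficients into index weights
#'
#' For each component z, the raw weight is the mean over the five subjective
#' scales of the absolute product of the scale's first-principal-component
#' loading and the component's pooled regression coefficient on that scale
#' (0 where the component was removed); weights are then normalized to sum
#' to 1.  The divisor stays 5 even for components surviving in fewer than
#' five equations, and absolute values prevent the oppositely signed
#' distress/worry/anxiety terms from cancelling the flourishing/life
#' satisfaction terms.
#'
#' @param loadings A `cati_loadings` object (or named 5-vector of loadings).
#' @param coefs A `5 x n_components` coefficient matrix (rows `fl, pd, wr,
#'   sa, ls`), zeros for removed components, or a `cati_coefmat` from
#'   [select_components()].
#' @return A `cati_weights` object: data frame with `component`, `raw`
#'   (pre-normalization) and `weight` (sums to 1).
#' @export
compute_weights <- function(loadings, coefs) {
  lam <- if (inherits(loadings, "cati_loadings")) loadings$loadings
         else loadings
  if (inherits(coefs, "cati_coefmat")) coefs <- coefs$beta
  stopifnot(length(lam) == nrow(coefs))
  if (!is.null(rownames(coefs)) && all(rownames(coefs) %in% CATI_SCALES) &&
      nrow(coefs) == 5) {
    coefs <- coefs[CATI_SCALES, , drop = FALSE]
    lam <- lam[CATI_SCALES]
  }
  raw <- colMeans(abs(coefs * lam)) # loadings recycle down the 5 rows
  if (sum(raw) <= 0) {
    stop("no informative components: all raw weights are zero",
         call. = FALSE)
  }
  out <- data.frame(component = colnames(coefs) %||%
                      paste0("comp", seq_along(raw)),
                    raw = unname(raw),
                    weight = unname(raw / sum(raw)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cati_weights", "data.frame")
  out
}

#' Score respondents with a weight vector
#'
#' The index score is the dot product of a respondent's 0/1 component
#' vector with the normalized weights, so scores lie in `[0, 1]`; a
#' standardized variant (mean 0, SD 1 over the sample) is also returned for
#' the validity models.
#'
#' @param components An `n x K` complete 0/1 matrix (or data frame / cohort
#'   whose `comp_*` columns are used) with columns matching
#'   `weights$component`.
#' @param weights A `cati_weights` object.
#' @return Data frame of class `cati_scores`: `id`, `cati`, `cati_std`.
#' @export
score_index <- function(components, weights) {
  M <- component_matrix(components, weights$component)
  cati <- drop(M %*% weights$weight)
  std <- (cati - mean(cati)) / sd(cati)
  out <- data.frame(id = seq_along(cati), cati = cati, cati_std = std)
  if (is.data.frame(components) && "id" %in% names(components)) {
    out$id <- components$id
  }
  class(out) <- c("cati_scores", "data.frame")
  out
}

component_matrix <- function(components, needed) {
  if (is.data.frame(components)) {
    cols <- paste0("comp_", needed)
    cols <- ifelse(cols %in% names(components), cols, needed)
    missing_cols <- setdiff(cols, names(components))
    if (length(missing_cols)) {
      stop("components not found in data: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    M <- as.matrix(components[cols])
  } else {
    M <- as.matrix(components)
    missing_cols <- setdiff(needed, colnames(M))
    if (length(missing_cols)) {
      stop("components not found in matrix: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    M <- M[, needed, drop = FALSE]
  }
  if (anyNA(M)) stop("component matrix must be complete", call. = FALSE)
  M
}

#' Equal-weight comparator index
#'
#' Recreates the conventional count-based index: the number of positive
#' components a child has (equivalently, equal weighting), standardized
#' over the sample.
#'
#' @param components Complete 0/1 matrix, data frame or cohort.
#' @param component_list Character vector of component names to count.
#' @return Data frame of class `cati_scores`: `id`, `cati` (raw count) and
#'   `cati_std`.
#' @export
equal_weight_index <- function(components, component_list) {
  if (length(component_list) == 0) {
    stop("component list must be non-empty", call. = FALSE)
  }
  M <- component_matrix(components, component_list)
  raw <- rowSums(M)
  out <- data.frame(id = seq_along(raw), cati = raw,
                    cati_std = (raw - mean(raw)) / sd(raw))
  if (is.data.frame(components) && "id" %in% names(components)) {
    out$id <- components$id
  }
  class(out) <- c("cati_scores", "data.frame")
  out
}

#' @export
print.cati_weights <- function(x, digits = 3, ...) {
  cat("Normalized index weights (sum to 1):\n")
  print(data.frame(component = x$component,
                   weight = round(x$weight, digits)), row.names = FALSE)
  invisible(x)
}
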