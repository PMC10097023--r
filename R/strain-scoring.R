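#' Probiotic assay arithmetic
#'
#' Gastrointestinal survival is the percentage of viable cells remaining
#' after simulated gastric and intestinal transit; self-aggregation and
#' surface hydrophobicity are percentage drops in absorbance,
#' \eqn{(1 - A/A_0) \times 100}.
#'
#' @param viable_before,viable_after CFU counts before/after transit.
#' @param a0 initial absorbance; `a5` absorbance after 5 h settling; `a1`
#'   aqueous-phase absorbance after solvent partitioning.
#' @name strain_assays
NULL

#' @rdname strain_assays
#' @export
gi_survival_rate <- function(viable_before, viable_after) {
  if (any(viable_before <= 0)) stopf("`viable_before` must be > 0")
  if (any(viable_after < 0)) stopf("`viable_after` must be >= 0")
  100 * viable_after / viable_before
}

#' @rdname strain_assays
#' @export
self_aggregation <- function(a0, a5) {
  if (any(a0 <= 0)) stopf("`a0` must be > 0")
  if (any(a5 < 0)) stopf("absorbance must be >= 0")
  (1 - a5 / a0) * 100
}

#' @rdname strain_assays
#' @export
hydrophobicity <- function(a0, a1) {
  self_aggregation(a0, a1)
}

indicator_cols <- c("gi_survival", "self_aggregation", "hydrophobicity")

get_indicator_matrix <- function(table) {
  df <- as.data.frame(table)
  cols <- if (all(indicator_cols %in% names(df))) {
    indicator_cols
  } else {
    names(df)[vapply(df, is.numeric, logical(1))]
  }
  x <- as.matrix(df[, cols, drop = FALSE])
  if (ncol(x) < 2) stopf("need >= 2 numeric indicators")
  if (any(!is.finite(x))) stopf("indicators must be finite")
  rownames(x) <- if ("strain" %in% names(df)) df$strain else rownames(df)
  x
}

#' Standardise strain indicators to z-scores
#'
#' @param table a `strain_property_table` (or any data.frame of numeric
#'   indicators).
#' @return strains x indicators matrix with column mean 0 and sd 1.
#' @export
standardize_indicators <- function(table) {
  x <- get_indicator_matrix(table)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) stopf("constant indicator '%s'", colnames(x)[sds == 0][1])
  scale(x)
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Overall KMO statistic
#' \deqn{KMO = \sum_{i \ne j} r_{ij}^2 / (\sum_{i \ne j} r_{ij}^2 +
#'   \sum_{i \ne j} u_{ij}^2)}
#' where \eqn{u_{ij}} are the partial correlations obtained from the inverse
#' of the correlation matrix. Values above 0.6 conventionally indicate that
#' a PCA-based composite score is adequate.
#'
#' @param table a strain property table (>= 3 strains, >= 2 indicators) or a
#'   correlation matrix.
#' @return KMO statistic in [0, 1].
#' @export
kmo <- function(table) {
  r <- if (is.matrix(table) && nrow(table) == ncol(table) &&
           isTRUE(all.equal(unname(diag(table)), rep(1, ncol(table))))) {
    table
  } else {
    x <- get_indicator_matrix(table)
    if (nrow(x) < 3) stopf("need >= 3 strains")
    stats::cor(x)
  }
  s <- tryCatch(solve(r), error = function(e) {
    stopf("correlation matrix is singular; KMO undefined")
  })
  u <- -s / sqrt(outer(diag(s), diag(s)))
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(u[off]^2))
}

#' Principal components of the indicator correlation matrix
#'
#' Eigen-decomposes the correlation matrix of the standardised indicators;
#' roots are sorted in decreasing order, the smallest number of components
#' whose cumulative explained variance reaches `cum_threshold` is retained,
#' and loadings are eigenvectors scaled by the square root of their root,
#' sign-oriented so the largest-magnitude loading of each component is
#' positive. The sum of squared loadings of a component equals its
#' characteristic root.
#'
#' @param table a strain property table.
#' @param cum_threshold cumulative explained-variance threshold (default
#'   0.90).
#' @return object of class `pca_score`: `roots`, `explained_variance`,
#'   `cumulative`, `loadings` (indicators x retained components), `X`
#'   (standardised data), `n_retained`.
#' @export
pca_components <- function(table, cum_threshold = 0.90) {
  x <- standardize_indicators(table)
  if (nrow(x) < ncol(x)) stopf("fewer strains than indicators")
  r <- stats::cor(x)
  e <- eigen(r, symmetric = TRUE)
  roots <- e$values
  v <- roots / ncol(x)
  m <- which(cumsum(v) >= cum_threshold - 1e-12)[1]
  if (is.na(m)) m <- length(v)
  load <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(roots[seq_len(m)], 0)), m)
  for (c_i in seq_len(m)) {
    if (load[which.max(abs(load[, c_i])), c_i] < 0) load[, c_i] <- -load[, c_i]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(m)))
  structure(list(
    roots = roots, explained_variance = v,
    cumulative = sum(v[seq_len(m)]), loadings = load, X = x,
    n_retained = m
  ), class = "pca_score")
}

#' Composite quantitative strain score and ranking
#'
#' The composite score weights each retained component's indicator-loading
#' contrast by its share of the cumulative explained variance:
#' \deqn{F_{sum} = \sum_{c=1}^{m} \frac{v_c}{M} \sum_i \ell_{ic} X_i}
#' with \eqn{v_c} the component's explained variance, \eqn{M} the cumulative
#' explained variance of the retained components, \eqn{\ell_{ic}} the
#' loadings and \eqn{X_i} the standardised indicator values. Strains are
#' ranked by score, descending, ties broken by strain id. With
#' `score_coefficients = TRUE` the loadings are replaced by the regression
#' score coefficients \eqn{\ell_{ic} / root_c}.
#'
#' @param pca a `pca_score` from [pca_components()].
#' @param X optional standardised matrix overriding `pca$X` (must have the
#'   same indicators).
#' @param score_coefficients use score coefficients instead of raw loadings.
#' @return data.frame: strain, f_sum, rank (sorted by rank).
#' @export
composite_score <- function(pca, X = NULL, score_coefficients = FALSE) {
  stopifnot(inherits(pca, "pca_score"))
  if (is.null(X)) X <- pca$X
  if (ncol(X) != nrow(pca$loadings)) stopf("indicator dimension mismatch")
  w <- pca$explained_variance[seq_len(pca$n_retained)] / pca$cumulative
  load <- pca$loadings
  if (score_coefficients) {
    load <- sweep(load, 2, pca$roots[seq_len(pca$n_retained)], `/`)
  }
  f <- as.numeric(X %*% load %*% w)
  out <- data.frame(strain = rownames(X), f_sum = f, stringsAsFactors = FALSE)
  out <- out[order(-out$f_sum, out$strain), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
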