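# Principal-components IVW: precision-weighted LD matrix, eigendecomposition,
# component selection by explained variance, transformed IVW estimate.

#' Build and decompose the precision-weighted LD matrix
#'
#' Constructs `Psi[i,j] = beta_x[i] beta_x[j] r[i,j] / (se_y[i] se_y[j])`,
#' the transformed genetic correlation matrix whose principal components
#' serve as instruments: among near-perfectly correlated variants it
#' prioritizes the one with the most precise outcome association. The matrix
#' is symmetrized before the eigendecomposition and numerically negative
#' eigenvalues (below `1e-10 * max`) are clamped to zero.
#'
#' @param data A [cismr_data] object.
#' @return An object of class `pca_decomp` with `psi`, `values` (descending)
#'   and `vectors` (orthonormal columns).
#' @export
build_psi <- function(data) {
  if (any(data$se_y == 0)) stop("zero outcome standard error")
  w <- data$beta_x / data$se_y
  psi <- outer(w, w) * data$corr
  psi <- (psi + t(psi)) / 2
  ee <- eigen(psi, symmetric = TRUE)
  vals <- ee$values
  vals[vals < 1e-10 * max(vals, 0)] <- 0
  structure(list(psi = psi, values = vals, vectors = ee$vectors,
                 snp = data$snp),
            class = "pca_decomp")
}

#' Number of components explaining a variance proportion
#'
#' The smallest `k` whose leading eigenvalues account for at least
#' `threshold` of the total; floored at 1.
#'
#' @param decomp A `pca_decomp` from [build_psi()].
#' @param threshold Proportion of variance in (0, 1].
#' @return Integer `k` with attribute `"variance_prop"`, the cumulative
#'   proportion attained.
#' @export
choose_k <- function(decomp, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  tot <- sum(decomp$values)
  if (tot <= 0) return(structure(1L, variance_prop = 1))
  cum <- cumsum(decomp$values) / tot
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(decomp$values)
  k <- max(1L, as.integer(k))
  structure(k, variance_prop = cum[k])
}

#' Principal-components IVW estimate
#'
#' Projects the summary statistics and the weighting matrix onto the first
#' `k` eigenvectors of the precision-weighted LD matrix and evaluates the
#' correlated IVW estimate in the transformed coordinates. At full rank this
#' is algebraically identical to [ivw_correlated()]; truncating `k`
#' stabilizes the inversion when the region's LD matrix is ill-conditioned.
#'
#' @param data A [cismr_data] object.
#' @param threshold Proportion of Psi variance the retained components must
#'   explain (the field convention is 0.99 or 0.999).
#' @param k Optional explicit component count overriding `threshold`.
#' @param max_condition Condition-number bound on the projected weighting
#'   matrix.
#' @return An [mr_estimate] with extras `k` and `variance_prop`.
#' @export
pca_ivw <- function(data, threshold = 0.999, k = NULL, max_condition = 1e8) {
  decomp <- build_psi(data)
  if (is.null(k)) {
    k <- choose_k(decomp, threshold)
    vp <- attr(k, "variance_prop")
  } else {
    stopifnot(k >= 1, k <= length(decomp$values))
    tot <- sum(decomp$values)
    vp <- if (tot > 0) cumsum(decomp$values)[k] / tot else 1
  }
  Wt <- decomp$vectors[, seq_len(k), drop = FALSE]
  bx <- drop(crossprod(Wt, data$beta_x))
  by <- drop(crossprod(Wt, data$beta_y))
  om <- crossprod(Wt, data$omega %*% Wt)
  om <- (om + t(om)) / 2
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  if (cond > max_condition)
    stop(sprintf("projected omega is numerically unstable: condition number %.3g",
                 cond))
  ch <- chol(om)
  oibx <- .chol_solve(ch, bx)
  prec <- sum(bx * oibx)
  if (prec <= 0) stop("all transformed variant-exposure associations are zero")
  mr_estimate(theta = sum(oibx * by) / prec, se = sqrt(1 / prec),
              method = "pca_ivw", n_instruments = length(data$snp),
              extras = list(k = as.integer(k), variance_prop = vp))
}
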