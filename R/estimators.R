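# Causal effect estimators: Wald ratio, standard IVW, correlated-instruments IVW.

Z975 <- stats::qnorm(0.975)

#' Construct a causal effect estimate
#'
#' Container for a Mendelian randomization causal effect estimate. The 95%
#' confidence interval uses the normal quantile and the p-value is two-sided
#' normal.
#'
#' @param theta Causal effect estimate (outcome units per exposure unit).
#' @param se Standard error of `theta`; must be positive.
#' @param method Provenance label, e.g. `"ivw_correlated"`.
#' @param n_instruments Number of genetic instruments used.
#' @param extras Named list of method-specific extras (e.g. the number of
#'   principal components retained).
#' @return An object of class `mr_estimate` with fields `theta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `method`, `n_instruments`, `extras`.
#' @export
mr_estimate <- function(theta, se, method, n_instruments, extras = list()) {
  if (!is.finite(theta)) stop("theta must be finite")
  if (!is.finite(se) || se <= 0) stop("se must be a positive finite number")
  p <- 2 * stats::pnorm(-abs(theta / se))
  if (p == 0) p <- .Machine$double.xmin
  structure(list(
    theta = theta, se = se,
    ci_low = theta - Z975 * se, ci_high = theta + Z975 * se,
    p_value = p, method = method,
    n_instruments = as.integer(n_instruments), extras = extras
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("MR causal effect estimate (%s, %d instrument%s)\n",
              x$method, x$n_instruments, if (x$n_instruments == 1) "" else "s"))
  cat(sprintf("  theta = %.*f  (se = %.*f)\n", digits, x$theta, digits, x$se))
  cat(sprintf("  95%% CI: (%.*f, %.*f)   p = %.3g\n",
              digits, x$ci_low, digits, x$ci_high, x$p_value))
  if (length(x$extras))
    cat("  ", paste(names(x$extras),
                    vapply(x$extras, function(e) format(e[1], digits = 4), ""),
                    sep = "=", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) c(theta = object$theta)

#' @export
vcov.mr_estimate <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("theta", "theta"))
}

#' @export
confint.mr_estimate <- function(object, parm = "theta", level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$theta - q * object$se, object$theta + q * object$se),
              1, 2, dimnames = list("theta",
                                    sprintf("%.1f %%", c((1 - level) / 2,
                                                         1 - (1 - level) / 2) * 100)))
  m
}

#' Single-instrument Wald ratio estimate
#'
#' The ratio estimate `beta_y / beta_x` with the first-order standard error
#' `se_y / |beta_x|`, which ignores uncertainty in the variant-exposure
#' association.
#'
#' @param beta_x Variant-exposure association.
#' @param se_x Its standard error (accepted for interface symmetry; unused by
#'   the first-order standard error).
#' @param beta_y Variant-outcome association.
#' @param se_y Its standard error.
#' @return An [mr_estimate].
#' @export
wald_ratio <- function(beta_x, se_x = NA_real_, beta_y, se_y) {
  if (!is.finite(beta_x) || beta_x == 0)
    stop("undefined ratio: beta_x is zero")
  mr_estimate(theta = beta_y / beta_x, se = se_y / abs(beta_x),
              method = "wald_ratio", n_instruments = 1L)
}

.stats_fields <- function(data) {
  # accept a cismr_data object or a plain list with the needed vectors
  need <- c("beta_x", "beta_y", "se_y")
  miss <- need[!need %in% names(data)]
  if (length(miss)) stop("missing fields: ", paste(miss, collapse = ", "))
  data
}

#' Standard (uncorrelated) IVW estimate
#'
#' Fixed-effect inverse-variance weighted estimate assuming independent
#' instruments: weights are the inverse outcome-association variances.
#'
#' @param data A [cismr_data] object, or any list carrying `beta_x`, `beta_y`,
#'   `se_y` vectors.
#' @return An [mr_estimate].
#' @export
ivw_standard <- function(data) {
  d <- .stats_fields(data)
  w <- d$se_y^-2
  denom <- sum(d$beta_x^2 * w)
  if (denom == 0) stop("all variant-exposure associations are zero")
  mr_estimate(theta = sum(d$beta_x * d$beta_y * w) / denom,
              se = sqrt(1 / denom),
              method = "ivw", n_instruments = length(d$beta_x))
}

# Solve omega^{-1} v for several right-hand sides via the Cholesky factor.
.chol_solve <- function(chol_upper, v) {
  backsolve(chol_upper, backsolve(chol_upper, v, transpose = TRUE))
}

#' Correlated-instruments IVW estimate
#'
#' Generalised least squares form of the IVW estimator for correlated variants:
#' `theta = (bx' O^-1 bx)^-1 bx' O^-1 by`, `se^2 = (bx' O^-1 bx)^-1`, where
#' `O` is the LD weighting matrix with entries `se_y[i] se_y[j] r[i,j]`.
#' The linear systems are solved through the Cholesky factor of `O`; an
#' ill-conditioned `O` (condition number above `max_condition`) is refused
#' rather than pseudo-inverted, since near-singular weighting matrices are the
#' known failure mode of this estimator.
#'
#' @param data A [cismr_data] object (carries the `omega` weighting matrix).
#' @param max_condition Maximum tolerated 2-norm condition number of `omega`.
#' @param variants Optional character vector of snp ids (or integer indices)
#'   restricting the estimate to a subset of instruments.
#' @return An [mr_estimate].
#' @export
ivw_correlated <- function(data, max_condition = 1e8, variants = NULL) {
  idx <- .resolve_variants(data, variants)
  bx <- data$beta_x[idx]
  by <- data$beta_y[idx]
  om <- data$omega[idx, idx, drop = FALSE]
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) <= 0) Inf else max(ev) / min(ev)
  if (cond > max_condition)
    stop(sprintf("omega is numerically unstable: condition number %.3g exceeds %.3g",
                 cond, max_condition))
  ch <- chol(om)
  oibx <- .chol_solve(ch, bx)
  prec <- sum(bx * oibx)
  if (prec <= 0) stop("all variant-exposure associations are zero")
  mr_estimate(theta = sum(oibx * by) / prec, se = sqrt(1 / prec),
              method = "ivw_correlated", n_instruments = length(idx),
              extras = list(condition = cond))
}

.resolve_variants <- function(data, variants) {
  if (is.null(variants)) return(seq_along(data$snp))
  if (is.logical(variants)) return(which(rep_len(variants, length(data$snp))))
  if (is.character(variants)) {
    idx <- match(variants, data$snp)
    if (anyNA(idx)) stop("unknown variant(s): ",
                         paste(variants[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(variants)
}
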