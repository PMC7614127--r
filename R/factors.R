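# Factor-based MR: latent factors from the rescaled LD covariance, F-LIML
# point estimation, and weak-instrument-robust AR / LM / CLR tests.

#' Fit latent genetic factors from reference LD
#'
#' Eigendecomposes the rescaled genotype covariance
#' `C = diag(s) R diag(s)` with `s[j] = sqrt(2 f[j] (1 - f[j]))` and retains
#' the first `k` eigenvectors as factor loadings. With `k = "auto"` the
#' smallest `k` explaining at least `threshold` of the trace is used.
#'
#' @param data A [cismr_data] object.
#' @param k Number of factors, or `"auto"`.
#' @param threshold Trace proportion for automatic selection.
#' @return An object of class `factor_model`: `loadings` (P x k,
#'   orthonormal columns), `k`, `dx`, `dy` (per-variant dosage variances
#'   `2 f (1 - f)`, one reference panel for both sides), `eigenvalues`.
#' @export
fit_factors <- function(data, k = "auto", threshold = 0.99) {
  f <- data$eaf
  if (anyNA(f) || any(f <= 0 | f >= 1))
    stop("effect allele frequencies in (0,1) are required for factor methods")
  d <- 2 * f * (1 - f)
  s <- sqrt(d)
  C <- outer(s, s) * data$corr
  C <- (C + t(C)) / 2
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  p <- length(f)
  if (identical(k, "auto")) {
    cum <- cumsum(vals) / sum(vals)
    k <- max(1L, which(cum >= threshold - 1e-12)[1])
  }
  k <- as.integer(k)
  if (k > p) stop("k exceeds the number of variants")
  if (k < 1) stop("k must be at least 1")
  structure(list(loadings = ee$vectors[, seq_len(k), drop = FALSE],
                 k = k, dx = d, dy = d, eigenvalues = vals),
            class = "factor_model")
}

# Moment pieces shared by F-LIML and the weak-IV tests:
#   g(theta) = B - theta A with A = (1/P) L'D bx, B = (1/P) L'D by,
#   V(theta) = M_Y + theta^2 M_X, M_* = (1/P^2) L'D Omega_* D L.
.factor_moments <- function(data, model) {
  p <- length(data$snp)
  L <- model$loadings
  d <- model$dx
  Td <- d * L                      # D L (rows scaled)
  A <- drop(crossprod(Td, data$beta_x)) / p
  B <- drop(crossprod(Td, data$beta_y)) / p
  ox <- outer(data$se_x, data$se_x) * data$corr
  oy <- data$omega
  MX <- crossprod(Td, ox %*% Td) / p^2
  MY <- crossprod(Td, oy %*% Td) / p^2
  list(A = A, B = B, MX = (MX + t(MX)) / 2, MY = (MY + t(MY)) / 2,
       k = model$k, p = p)
}

.chol_or_stop <- function(m, what) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) stop(sprintf("%s is singular", what))
  ch
}

# AR quadratic form at theta
.ar_quad <- function(mom, theta) {
  gv <- mom$B - theta * mom$A
  V <- mom$MY + theta^2 * mom$MX
  ch <- .chol_or_stop(V, "the moment variance matrix")
  s <- backsolve(ch, gv, transpose = TRUE)
  sum(s * s)
}

#' Factor-LIML causal effect estimate
#'
#' Minimizes the continuously-updated quadratic criterion
#' `Q(theta) = g(theta)' V(theta)^-1 g(theta)` where
#' `g(theta) = (1/P) L' D (beta_y - theta beta_x)` is the factor moment and
#' `V(theta)` its delta-method variance built from the summary standard
#' errors and reference LD. A coarse grid brackets the minimum, which is
#' then refined by golden-section/parabolic search; the standard error comes
#' from the criterion curvature `(A' V(theta)^-1 A)^-1`.
#'
#' @param data A [cismr_data] object.
#' @param model A `factor_model`; by default fitted with `k = "auto"`.
#' @param interval Search interval for theta.
#' @return An [mr_estimate] with extra `k`.
#' @export
f_liml <- function(data, model = NULL, interval = c(-2, 2)) {
  if (is.null(model)) model <- fit_factors(data)
  mom <- .factor_moments(data, model)
  if (sqrt(sum(mom$A^2)) < 1e-12 * max(sqrt(sum(mom$B^2)), 1))
    stop("unidentified: all transformed variant-exposure associations are zero")
  qfun <- function(th) .ar_quad(mom, th)
  grid <- seq(interval[1], interval[2], length.out = 201)
  qs <- vapply(grid, qfun, 0)
  i <- which.min(qs)
  if (i == 1 || i == length(grid)) {
    wide <- 10 * max(abs(interval))
    grid <- seq(-wide, wide, length.out = 401)
    qs <- vapply(grid, qfun, 0)
    i <- which.min(qs)
    i <- min(max(i, 2L), length(grid) - 1L)
  }
  opt <- stats::optimize(qfun, lower = grid[i - 1], upper = grid[i + 1],
                         tol = 1e-9)
  theta <- opt$minimum
  V <- mom$MY + theta^2 * mom$MX
  ch <- .chol_or_stop(V, "the moment variance matrix")
  a <- backsolve(ch, mom$A, transpose = TRUE)
  prec <- sum(a * a)
  if (prec <= 0) stop("unidentified")
  mr_estimate(theta = theta, se = sqrt(1 / prec), method = "f_liml",
              n_instruments = length(data$snp),
              extras = list(k = model$k))
}

# Core statistics for the weak-IV tests at a hypothesized theta0:
# Qs (AR), Qt (identification), Qst (cross term), following the
# score/conditional-test construction with
# D-tilde = G - Cov(g, G) V^-1 g, G = -A, Cov(g, G) = theta0 MX.
.weakiv_core <- function(mom, theta0) {
  gv <- mom$B - theta0 * mom$A
  V <- mom$MY + theta0^2 * mom$MX
  ch <- .chol_or_stop(V, "the moment variance matrix")
  s <- backsolve(ch, gv, transpose = TRUE)
  qs <- sum(s * s)
  vinv_g <- backsolve(ch, s)
  Dt <- -mom$A - theta0 * drop(mom$MX %*% vinv_g)
  VMX <- backsolve(ch, backsolve(ch, mom$MX, transpose = TRUE))
  VD <- mom$MX - theta0^2 * crossprod(mom$MX, VMX)
  VD <- (VD + t(VD)) / 2
  chd <- .chol_or_stop(VD, "the identification variance matrix")
  tv <- backsolve(chd, Dt, transpose = TRUE)
  qt <- sum(tv * tv)
  qst <- sum(s * tv)
  list(qs = qs, qt = qt, qst = qst, k = mom$k)
}

.weakiv_result <- function(stat, p, test, theta0, k) {
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(statistic = stat, p_value = p, test = test,
                 theta0 = theta0, k = k),
            class = "weak_iv_test")
}

#' @export
print.weak_iv_test <- function(x, ...) {
  cat(sprintf("%s test of theta = %g: statistic %.4g (k = %d), p = %.4g\n",
              x$test, x$theta0, x$statistic, x$k, x$p_value))
  invisible(x)
}

#' Weak-instrument-robust tests of a hypothesized causal effect
#'
#' `ar_test` is the Anderson-Rubin statistic `g' V^-1 g` referred to
#' chi-square with `k` degrees of freedom; `lm_test` is the
#' Kleibergen score statistic (chi-square, 1 df); `clr_test` is the
#' conditional likelihood ratio combining the two, with its p-value computed
#' by seeded Monte Carlo from the conditional distribution given the
#' identification statistic. At `k = 1` the three statistics coincide and
#' the CLR p-value is computed exactly from chi-square(1).
#'
#' @param data A [cismr_data] object.
#' @param model A `factor_model` (default: fitted with `k = "auto"`).
#' @param theta0 Hypothesized causal effect.
#' @param draws Monte Carlo draws for the CLR conditional p-value.
#' @param seed Seed for the Monte Carlo draws.
#' @return A `weak_iv_test` with `statistic`, `p_value`, `test`, `theta0`,
#'   `k`.
#' @export
ar_test <- function(data, model = NULL, theta0) {
  if (is.null(model)) model <- fit_factors(data)
  mom <- .factor_moments(data, model)
  qs <- .ar_quad(mom, theta0)
  .weakiv_result(qs, stats::pchisq(qs, df = mom$k, lower.tail = FALSE),
                 "AR", theta0, mom$k)
}

#' @rdname ar_test
#' @export
lm_test <- function(data, model = NULL, theta0) {
  if (is.null(model)) model <- fit_factors(data)
  core <- .weakiv_core(.factor_moments(data, model), theta0)
  stat <- if (core$qt > 0) core$qst^2 / core$qt else 0
  .weakiv_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 "LM", theta0, core$k)
}

.clr_stat <- function(core) {
  with(core, 0.5 * (qs - qt + sqrt(pmax((qs + qt)^2 -
                                          4 * (qs * qt - qst^2), 0))))
}

# conditional null distribution of the CLR statistic given qt
.clr_null <- function(qt, k, z1, z2) {
  s <- z1 + z2
  0.5 * (s - qt + sqrt(pmax((s + qt)^2 - 4 * z2 * qt, 0)))
}

#' @rdname ar_test
#' @export
clr_test <- function(data, model = NULL, theta0, draws = 10000, seed = 1) {
  if (is.null(model)) model <- fit_factors(data)
  core <- .weakiv_core(.factor_moments(data, model), theta0)
  lr <- .clr_stat(core)
  if (core$k == 1) {
    p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  } else {
    p <- .with_seed(seed, {
      z1 <- stats::rchisq(draws, 1)
      z2 <- stats::rchisq(draws, core$k - 1)
      (1 + sum(.clr_null(core$qt, core$k, z1, z2) >= lr)) / (draws + 1)
    })
  }
  .weakiv_result(lr, p, "CLR", theta0, core$k)
}

#' CLR confidence set by test inversion
#'
#' Evaluates the CLR p-value on a grid of hypothesized effects and returns
#' the set where it is at least `level`, as interval endpoints. The Monte
#' Carlo chi-square draws are shared across grid points so the p-value curve
#' is smooth in theta. The set may be empty, disjoint, or unbounded within
#' the grid (flagged).
#'
#' @param data A [cismr_data] object.
#' @param model A `factor_model` (default: `k = "auto"`).
#' @param grid Grid of theta values to test.
#' @param level Significance level (the set keeps `p >= level`).
#' @param draws,seed Monte Carlo settings shared across the grid.
#' @return An object of class `clr_set`: `intervals` (two-column matrix of
#'   endpoints), `unbounded` flag, `grid`, `p_values`.
#' @export
clr_confidence_set <- function(data, model = NULL,
                               grid = seq(-2, 2, length.out = 801),
                               level = 0.05, draws = 10000, seed = 1) {
  if (is.null(model)) model <- fit_factors(data)
  mom <- .factor_moments(data, model)
  k <- mom$k
  pv <- .with_seed(seed, {
    z1 <- stats::rchisq(draws, 1)
    z2 <- if (k > 1) stats::rchisq(draws, k - 1) else numeric(draws)
    vapply(grid, function(th) {
      core <- .weakiv_core(mom, th)
      lr <- .clr_stat(core)
      if (k == 1) stats::pchisq(lr, df = 1, lower.tail = FALSE)
      else (1 + sum(.clr_null(core$qt, k, z1, z2) >= lr)) / (draws + 1)
    }, 0)
  })
  acc <- pv >= level
  runs <- rle(acc)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- cbind(lower = grid[starts[runs$values]],
              upper = grid[ends[runs$values]])
  unbounded <- length(acc) > 0 && (acc[1] || acc[length(acc)])
  structure(list(intervals = iv, unbounded = unbounded,
                 grid = grid, p_values = pv, level = level),
            class = "clr_set")
}

#' @export
print.clr_set <- function(x, ...) {
  if (!nrow(x$intervals)) {
    cat("CLR confidence set: empty on the grid\n")
  } else {
    cat(sprintf("CLR %.0f%% confidence set:%s\n", 100 * (1 - x$level),
                if (x$unbounded) " (unbounded within grid)" else ""))
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("  (%.4g, %.4g)\n", x$intervals[i, 1], x$intervals[i, 2]))
  }
  invisible(x)
}
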