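# JAM: Bayesian stochastic-search variable selection from marginal summary
# statistics, with model-averaged IVW causal estimation.
#
# The exposure model X ~ N(G b, sigma_x^2 I) is fitted through the sufficient
# statistics z = G'X (approximated from marginal betas under HWE) and
# G'G (approximated from reference LD), under a conjugate
# normal-inverse-gamma g-prior for (b, sigma_x^2) and a beta-binomial prior
# on the model indicator, so the marginal evidence of every variant subset is
# available in closed form.

#' JAM configuration
#'
#' @param preprune_rho Correlation threshold for the LD-pruning pre-step run
#'   before the stochastic search (no significance threshold is applied).
#' @param g g-prior scale; `NULL` means unit information (`g = N1`).
#' @param bb_a,bb_b Beta-binomial model-prior hyperparameters; `bb_b = NULL`
#'   means the number of (pre-pruned) variants, giving a prior mean model
#'   size of about one.
#' @param iterations Total reversible-jump MCMC iterations.
#' @param burn_in Discarded prefix; defaults to 10% of `iterations`.
#' @param seed RNG seed for the chain; `NULL` uses (and advances) the current
#'   RNG state.
#' @param a0,b0 Inverse-gamma residual-variance hyperparameters (shape, rate).
#' @return A `jam_config` list.
#' @export
jam_config <- function(preprune_rho = 0.9, g = NULL, bb_a = 1, bb_b = NULL,
                       iterations = 1e6, burn_in = floor(iterations / 10),
                       seed = NULL, a0 = 0.01, b0 = 0.01) {
  stopifnot(iterations > burn_in, burn_in >= 0, bb_a > 0,
            is.null(bb_b) || bb_b > 0, is.null(g) || g > 0)
  structure(list(preprune_rho = preprune_rho, g = g, bb_a = bb_a, bb_b = bb_b,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), seed = seed,
                 a0 = a0, b0 = b0),
            class = "jam_config")
}

#' JAM sufficient statistics
#'
#' Computes `z[j] = 2 f[j] (1 - f[j]) N1 beta_x[j]` and the scaled
#' cross-product matrix
#' `xtx[i,j] = N1 r[i,j] sqrt(2 f[i](1-f[i])) sqrt(2 f[j](1-f[j]))`
#' approximating `G'X` and `G'G` for centered genotypes under
#' Hardy-Weinberg equilibrium, with the exposure trait standardized
#' (`y'y = N1`).
#'
#' @param data A [cismr_data] object with `eaf` and `n_x` available.
#' @return A `jam_suff` list with `z`, `xtx`, `chol` (upper-triangular factor
#'   of `xtx`, when it exists), `n1`, `yty` and `p`.
#' @export
jam_sufficient_stats <- function(data) {
  n1 <- data$n_x[1]
  if (is.na(n1)) stop("exposure sample size (n_x) is required for JAM")
  f <- data$eaf
  if (anyNA(f) || any(f <= 0 | f >= 1))
    stop("effect allele frequencies in (0,1) are required for JAM")
  d <- 2 * f * (1 - f)
  sq <- sqrt(d)
  xtx <- n1 * outer(sq, sq) * data$corr
  dimnames(xtx) <- list(data$snp, data$snp)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  structure(list(z = d * n1 * data$beta_x, xtx = xtx, chol = ch,
                 n1 = n1, yty = n1, p = length(f), snp = data$snp),
            class = "jam_suff")
}

#' Log model evidence of a variant subset
#'
#' Closed-form log marginal likelihood of the summary-data linear model
#' restricted to the subset `gamma`, with the regression coefficients and
#' residual variance integrated out under the conjugate NIG g-prior, plus the
#' log beta-binomial prior mass of the subset. The empty subset (null model)
#' is allowed. A singular or ill-conditioned `xtx` submatrix (condition
#' number above 1e8) makes the model unvisitable: `-Inf` is returned.
#'
#' @param gamma Integer indices of the subset (possibly empty).
#' @param suff A `jam_suff` from [jam_sufficient_stats()].
#' @param config A [jam_config()].
#' @return Log posterior mass (up to the normalizing constant over models).
#' @export
jam_log_evidence <- function(gamma, suff, config = jam_config()) {
  k <- length(gamma)
  g <- if (is.null(config$g)) suff$n1 else config$g
  bb_b <- if (is.null(config$bb_b)) suff$p else config$bb_b
  quad <- 0
  if (k > 0) {
    xs <- suff$xtx[gamma, gamma, drop = FALSE]
    ch <- tryCatch(chol(xs), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    dg <- diag(ch)
    if ((max(dg) / min(dg))^2 > 1e8) return(-Inf)
    v <- backsolve(ch, suff$z[gamma], transpose = TRUE)
    quad <- sum(v * v)
  }
  rss <- suff$yty - g / (1 + g) * quad
  if (rss <= 0) rss <- 1e-8 * suff$yty
  n <- suff$n1
  lml <- -0.5 * n * log(2 * pi) +
    config$a0 * log(config$b0) - lgamma(config$a0) +
    lgamma(config$a0 + n / 2) -
    0.5 * k * log1p(g) -
    (config$a0 + n / 2) * log(config$b0 + rss / 2)
  lprior <- lbeta(config$bb_a + k, bb_b + suff$p - k) -
    lbeta(config$bb_a, bb_b)
  lml + lprior
}

# run a function with a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Reversible-jump stochastic search over variant subsets
#'
#' Runs the JAM reversible-jump MCMC: the chain starts from the single
#' variant with the smallest exposure p-value and proposes, with equal
#' probability among the moves feasible at the current state, adding a
#' variant, deleting one, or swapping a member for a non-member, accepting by
#' Metropolis-Hastings on the evidence difference with the proposal-asymmetry
#' correction. Post burn-in visit frequencies define the model posterior.
#' When `config$preprune_rho < 1` the region is first LD-pruned at that
#' threshold (no significance threshold) to keep the cross-product matrix
#' invertible.
#'
#' @param data A [cismr_data] object.
#' @param config A [jam_config()].
#' @return An object of class `jam_posterior`: `model_probs` (named by
#'   comma-separated member indices into `variants`; `""` is the null model),
#'   `inclusion_probs` (per variant), `accept_rate`, `variants` (ids kept
#'   after pre-pruning), `n_models`, and the `config` used.
#' @export
jam_rjmcmc <- function(data, config = jam_config()) {
  keep <- data$snp
  if (!is.null(config$preprune_rho) && config$preprune_rho < 1) {
    sel <- ld_prune(data, rho = config$preprune_rho, tau = NULL)
    keep <- data$snp[data$snp %in% sel$selected]
  }
  sub <- data[keep]
  suff <- jam_sufficient_stats(sub)
  p <- suff$p
  ev <- function(gam) jam_log_evidence(gam, suff, config)

  .with_seed(config$seed, {
    gam <- which.min(sub$p_x)
    cur_ev <- ev(gam)
    if (!is.finite(cur_ev)) {
      gam <- integer()
      cur_ev <- ev(gam)
    }
    if (!is.finite(cur_ev)) stop("all models unvisitable")
    cache <- new.env(hash = TRUE, parent = emptyenv())
    counts <- new.env(hash = TRUE, parent = emptyenv())
    # environments cannot hold a "" name; the null model gets a sentinel key
    key <- function(g) if (length(g)) paste(g, collapse = ",") else ".null"
    cur_key <- key(gam)
    assign(cur_key, cur_ev, envir = cache)
    incl <- numeric(p)
    n_acc <- 0L
    n_rec <- 0L
    n_moves <- function(k) (k > 0) + (k < p) + (k > 0 && k < p)

    for (it in seq_len(config$iterations)) {
      k <- length(gam)
      nm <- n_moves(k)
      mv <- c(if (k < p) "add", if (k > 0) "del",
              if (k > 0 && k < p) "swap")[sample.int(nm, 1L)]
      if (mv == "add") {
        absent <- setdiff(seq_len(p), gam)
        j <- absent[sample.int(length(absent), 1L)]
        new <- sort(c(gam, j))
        lq <- -log(nm) - log(p - k)            # forward
        lr <- -log(n_moves(k + 1)) - log(k + 1) # reverse (delete)
      } else if (mv == "del") {
        j <- gam[sample.int(k, 1L)]
        new <- setdiff(gam, j)
        lq <- -log(nm) - log(k)
        lr <- -log(n_moves(k - 1)) - log(p - k + 1)
      } else {
        i <- gam[sample.int(k, 1L)]
        absent <- setdiff(seq_len(p), gam)
        j <- absent[sample.int(length(absent), 1L)]
        new <- sort(c(setdiff(gam, i), j))
        lq <- -log(nm) - log(k) - log(p - k)
        lr <- lq  # same dimensions both ways
      }
      new_key <- key(new)
      new_ev <- get0(new_key, envir = cache, ifnotfound = NULL)
      if (is.null(new_ev)) {
        new_ev <- ev(new)
        assign(new_key, new_ev, envir = cache)
      }
      if (is.finite(new_ev) &&
          log(stats::runif(1)) < new_ev - cur_ev + lr - lq) {
        gam <- new; cur_ev <- new_ev; cur_key <- new_key
        n_acc <- n_acc + 1L
      }
      if (it > config$burn_in) {
        n_rec <- n_rec + 1L
        cnt <- get0(cur_key, envir = counts, ifnotfound = 0)
        assign(cur_key, cnt + 1, envir = counts)
        if (length(gam)) incl[gam] <- incl[gam] + 1
      }
    }
    keys <- ls(counts, all.names = TRUE)
    probs <- vapply(keys, function(k) get(k, envir = counts), 0) / n_rec
    names(probs) <- ifelse(keys == ".null", "", keys)
    probs <- sort(probs, decreasing = TRUE)
    names(incl) <- sub$snp
    structure(list(model_probs = probs, inclusion_probs = incl / n_rec,
                   accept_rate = n_acc / config$iterations,
                   variants = sub$snp, n_models = length(probs),
                   config = config),
              class = "jam_posterior")
  })
}

#' @export
print.jam_posterior <- function(x, n = 5, ...) {
  cat(sprintf("JAM posterior over %d variants: %d models visited, accept rate %.2f\n",
              length(x$variants), x$n_models, x$accept_rate))
  top <- utils::head(x$model_probs, n)
  lab <- vapply(names(top), function(k) {
    if (!nzchar(k)) return("(null model)")
    paste(x$variants[as.integer(strsplit(k, ",")[[1]])], collapse = "+")
  }, "")
  for (i in seq_along(top))
    cat(sprintf("  %5.3f  %s\n", top[i], lab[i]))
  invisible(x)
}

#' Model-averaged causal effect estimate from a JAM posterior
#'
#' For every non-empty visited model the correlated-IVW estimate restricted
#' to its variants is computed; the posterior-weighted mean gives the
#' aggregate effect and the law of total variance gives its standard error
#' (within-model variance plus between-model spread). Weights are
#' renormalized over non-empty models; the null-model mass is reported in
#' the extras.
#'
#' @param posterior A `jam_posterior` from [jam_rjmcmc()].
#' @param data The [cismr_data] the posterior was computed from.
#' @return An [mr_estimate] with extras `empty_mass`, `mean_model_size` and
#'   `accept_rate`.
#' @export
jam_model_average <- function(posterior, data) {
  keys <- names(posterior$model_probs)
  nonempty <- keys[nzchar(keys)]
  if (!length(nonempty)) stop("no instruments selected")
  w <- posterior$model_probs[nonempty]
  w <- w / sum(w)
  th <- se <- numeric(length(nonempty))
  sz <- integer(length(nonempty))
  for (i in seq_along(nonempty)) {
    ids <- posterior$variants[as.integer(strsplit(nonempty[i], ",")[[1]])]
    est <- ivw_correlated(data, variants = ids)
    th[i] <- est$theta; se[i] <- est$se; sz[i] <- length(ids)
  }
  theta <- sum(w * th)
  v <- sum(w * (se^2 + th^2)) - theta^2
  v <- max(v, .Machine$double.eps)
  empty <- posterior$model_probs[match("", keys)]
  mr_estimate(theta = theta, se = sqrt(v), method = "jam",
              n_instruments = round(sum(w * sz)),
              extras = list(empty_mass = if (is.na(empty)) 0 else unname(empty),
                            mean_model_size = sum(w * sz),
                            accept_rate = posterior$accept_rate))
}

#' Fit JAM: stochastic search plus model-averaged estimation
#'
#' @param data A [cismr_data] object.
#' @param config A [jam_config()].
#' @return An [mr_estimate]; the `jam_posterior` is attached as attribute
#'   `"posterior"`.
#' @export
jam_fit <- function(data, config = jam_config()) {
  post <- jam_rjmcmc(data, config)
  est <- jam_model_average(post, data)
  attr(est, "posterior") <- post
  est
}

#' Map a log-odds ratio to the linear-regression scale
#'
#' First-order mapping of a binary-trait log-odds ratio to the effect that a
#' linear regression of the 0/1 outcome on the dosage would estimate:
#' `beta_linear = beta * cf * (1 - cf)` with `cf` the case fraction. Used to
#' feed binary-outcome summary statistics to linear summary-data machinery.
#'
#' @param beta Log-odds ratio per allele.
#' @param eaf,n Accepted for interface compatibility; the first-order mapping
#'   does not use them.
#' @param case_fraction Proportion of cases in (0, 1).
#' @return Effect on the linear (0/1 outcome) scale.
#' @export
logodds_to_linear <- function(beta, eaf = NULL, n = NULL, case_fraction) {
  stopifnot(case_fraction > 0, case_fraction < 1)
  beta * case_fraction * (1 - case_fraction)
}
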