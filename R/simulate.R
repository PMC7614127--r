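# Synthetic gene-region generator and two-sample summary-data simulator.
#
# A region is a set of LD blocks of correlated biallelic variants. Haplotypes
# are generated by thresholding a latent Gaussian vector (with the block's
# target correlation) at the allele-frequency quantile; dosages are the sum
# of two independent haplotypes. A large reference pool of individuals is
# generated once per scenario; each replicate bootstraps exposure and outcome
# samples from the pool, mirroring a two-sample design with a shared
# reference panel (from which the LD matrix is also computed).

#' Specify a synthetic LD region
#'
#' Two within-block structures are available. With `cluster_sizes = NULL`
#' (the default) a block has autoregressive decay: variants `i`, `j` in a
#' block have latent correlation `decay^|i-j|`. With `cluster_sizes` set,
#' each block is partitioned into clusters of near-duplicate variants:
#' within-cluster latent correlation `within_r`, across-cluster (same block)
#' `between_r`. The clustered form mimics the extreme redundancy of real
#' gene-region LD, where dozens of variants tag the same haplotype almost
#' perfectly and the region's correlation matrix has far fewer effective
#' dimensions than variants.
#'
#' @param p Number of variants.
#' @param block_sizes Sizes of the LD blocks (must sum to `p`).
#' @param decay Within-block latent correlation between adjacent variants;
#'   scalar or one value per block. Ignored when `cluster_sizes` is given.
#' @param cluster_sizes Integer vector partitioning each block into
#'   near-duplicate clusters (recycled across blocks; must sum to the block
#'   size), or `NULL` for autoregressive blocks.
#' @param within_r,between_r Latent correlations within and across clusters
#'   of a block (clustered form only).
#' @param maf Per-variant minor (= effect) allele frequencies, all at least
#'   0.01; default an even spread over `[0.05, 0.5]` (autoregressive form)
#'   or constant within block (clustered form, since near-perfect LD implies
#'   near-equal allele frequencies).
#' @return An object of class `region_spec` with the block partition and the
#'   latent `target_corr` matrix.
#' @export
region_spec <- function(p = 60, block_sizes = rep(10, 6), decay = 0.95,
                        cluster_sizes = NULL, within_r = 0.998,
                        between_r = 0.6, maf = NULL) {
  stopifnot(sum(block_sizes) == p)
  clustered <- !is.null(cluster_sizes)
  if (is.null(maf)) {
    maf <- if (clustered)
      rep(seq(0.1, 0.45, length.out = length(block_sizes)),
          times = block_sizes)
    else seq(0.05, 0.5, length.out = p)
  }
  stopifnot(length(maf) == p, all(maf >= 0.01), all(maf <= 0.5))
  decay <- rep_len(decay, length(block_sizes))
  stopifnot(all(decay >= 0), all(decay <= 1))
  corr <- matrix(0, p, p)
  off <- 0L
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]
    idx <- off + seq_len(sz)
    if (clustered) {
      stopifnot(sum(cluster_sizes) == sz, within_r > between_r,
                within_r < 1, between_r >= 0)
      cl <- rep(seq_along(cluster_sizes), times = cluster_sizes)
      blk <- matrix(between_r, sz, sz)
      blk[outer(cl, cl, "==")] <- within_r
      corr[idx, idx] <- blk
    } else {
      corr[idx, idx] <- decay[b]^abs(outer(seq_len(sz), seq_len(sz), "-"))
    }
    off <- off + sz
  }
  diag(corr) <- 1
  snp <- sprintf("snp_%03d", seq_len(p))
  dimnames(corr) <- list(snp, snp)
  if (max(corr[upper.tri(corr)]) < 1 &&
      inherits(tryCatch(chol(corr), error = identity), "error"))
    stop("target correlation matrix is not positive definite")
  structure(list(p = p, block_sizes = block_sizes, decay = decay,
                 cluster_sizes = cluster_sizes, maf = maf,
                 target_corr = corr, snp = snp),
            class = "region_spec")
}

# Dosage (phi) correlation of two equal-frequency thresholded haplotypes as a
# function of the latent Gaussian correlation.
.phi_from_latent <- function(r, f) {
  q <- stats::qnorm(f)
  p11 <- f^2 + stats::integrate(function(t)
    exp(-q^2 / (1 + t)) / (2 * pi * sqrt(1 - t^2)),
    0, r, rel.tol = 1e-10)$value
  (p11 - f^2) / (f * (1 - f))
}

.tetra_cache <- new.env(parent = emptyenv())

# Latent correlation needed for a target dosage correlation at frequency f
# (dichotomization attenuates, so the latent value always exceeds the target).
.latent_for_dosage <- function(target, f) {
  if (target <= 0) return(target)
  key <- sprintf("%.8f_%.8f", target, f)
  hit <- get0(key, envir = .tetra_cache)
  if (!is.null(hit)) return(hit)
  val <- stats::uniroot(function(r) .phi_from_latent(r, f) - target,
                        lower = target, upper = 1 - 1e-9,
                        tol = 1e-9)$root
  assign(key, val, envir = .tetra_cache)
  val
}

# one haplotype matrix: latent MVN per block, thresholded at the MAF quantile
.haplotypes <- function(region, n) {
  out <- matrix(0, n, region$p)
  off <- 0L
  for (b in seq_along(region$block_sizes)) {
    sz <- region$block_sizes[b]
    idx <- off + seq_len(sz)
    blk <- region$target_corr[idx, idx]
    if (!is.null(region$cluster_sizes)) {
      # clustered blocks state their targets on the dosage scale; invert the
      # dichotomization so realized dosage correlations match (equal MAF
      # within a block makes this a per-level 1-D inversion)
      f <- region$maf[idx[1]]
      lv <- unique(blk[upper.tri(blk)])
      for (v in lv) blk[blk == v & row(blk) != col(blk)] <-
          .latent_for_dosage(v, f)
    }
    z <- matrix(stats::rnorm(n * sz), n, sz)
    if (any(blk[upper.tri(blk)] != 0)) {
      if (any(blk[upper.tri(blk)] >= 1)) {
        z <- matrix(z[, 1], n, sz)   # perfect-correlation limit
      } else {
        z <- z %*% chol(blk)
      }
    }
    thr <- stats::qnorm(region$maf[idx])
    out[, idx] <- z < rep(thr, each = n)
    off <- off + sz
  }
  out
}

#' Generate genotype dosages for a region
#'
#' Dosages are the sum of two independent haplotypes, each obtained by
#' thresholding a latent Gaussian vector with the region's target correlation
#' at the allele-frequency quantile. Realized dosage correlations are
#' slightly attenuated relative to the latent ones (dichotomization); the
#' reference LD used by the methods is always computed from dosages, so this
#' is immaterial downstream.
#'
#' @param region A [region_spec()].
#' @param n Number of individuals.
#' @param seed Optional seed (the caller's RNG stream is restored).
#' @return An `n x p` numeric matrix of dosages in \{0, 1, 2\} with variant
#'   column names.
#' @export
generate_genotypes <- function(region, n, seed = NULL) {
  .with_seed(seed, {
    g <- .haplotypes(region, n) + .haplotypes(region, n)
    colnames(g) <- region$snp
    g
  })
}

# precompute pool pieces reused across replicates
.pool_prep <- function(pool) {
  if (inherits(pool, "genotype_pool")) return(pool)
  structure(list(g = pool, gsq = pool^2, n = nrow(pool), p = ncol(pool),
                 f = colMeans(pool) / 2, snp = colnames(pool)),
            class = "genotype_pool")
}

# per-variant simple-regression summary statistics for a bootstrap sample
# drawn from the pool, via pool-length weighted cross-products (no per-sample
# genotype matrix is materialized).
.marginal_stats <- function(prep, idx, y) {
  n <- length(idx)
  cnt <- tabulate(idx, prep$n)
  rs <- rowsum(y, idx)
  wy <- numeric(prep$n)
  wy[as.integer(rownames(rs))] <- rs[, 1]
  S <- crossprod(prep$g, cbind(cnt, wy))
  sg <- S[, 1]
  sgy <- S[, 2]
  sgg_raw <- drop(crossprod(prep$gsq, cnt))
  gbar <- sg / n
  ybar <- sum(y) / n
  sgg <- sgg_raw - n * gbar^2
  sxy <- sgy - n * gbar * ybar
  syy <- sum(y * y) - n * ybar^2
  beta <- sxy / sgg
  s2 <- pmax((syy - beta * sxy) / (n - 2), .Machine$double.xmin)
  se <- sqrt(s2 / sgg)
  p <- pmax(2 * stats::pt(-abs(beta / se), df = n - 2), .Machine$double.xmin)
  list(beta = beta, se = se, p = p)
}

#' Define a simulation scenario
#'
#' Packages the data-generating conditions of the two emulated gene regions:
#' a dense high-LD region ("shbg"-like, latent decay 0.95, causal effects
#' `|N(0, 0.2)| + 0.1`, 3% of exposure variance explained when instruments
#' are strong) and a moderately correlated region ("hmgcr"-like, decay 0.85,
#' effects `|N(0, 0.03)| + 0.03`, 2% variance explained). The weak-instrument
#' version of either scenario divides the explained variance by ten. The
#' exposure GWAS has `n1` individuals, the outcome GWAS `n2`, both
#' bootstrapped from a reference pool of `nref` individuals from which the
#' LD matrix is also computed. Confounding uses unit loadings with the noise
#' variance set so the exposure has unit variance.
#'
#' @param region `"shbg"` or `"hmgcr"` (or a [region_spec()] for a custom
#'   region).
#' @param instruments `"strong"` or `"weak"`.
#' @param theta True causal effect.
#' @param n1,n2,nref Sample sizes (exposure, outcome, reference pool).
#' @param n_causal Number of causal variants (placed one per block).
#' @param vg Proportion of exposure variance explained by the causal
#'   variants; `NULL` takes the scenario default.
#' @param reps Default replicate count for benchmarks.
#' @param tau GWAS significance threshold carried to pruning-type selectors;
#'   `NULL` takes 5e-8 (strong) or 1e-3 (weak).
#' @return A `scenario_config` list.
#' @export
mr_scenario <- function(region = c("shbg", "hmgcr"),
                        instruments = c("strong", "weak"),
                        theta = 0, n1 = 10000, n2 = 180000, nref = 50000,
                        n_causal = 6, vg = NULL, reps = 1000, tau = NULL) {
  instruments <- match.arg(instruments)
  if (is.character(region)) {
    region <- match.arg(region)
    name <- region
    region <- switch(region,
                     shbg = region_spec(cluster_sizes = c(6, 4),
                                        within_r = 0.998, between_r = 0.6),
                     hmgcr = region_spec(cluster_sizes = c(6, 4),
                                         within_r = 0.998, between_r = 0.8))
    eff <- switch(name, shbg = c(s = 0.2, c = 0.1),
                  hmgcr = c(s = 0.03, c = 0.03))
    vg0 <- switch(name, shbg = 0.03, hmgcr = 0.02)
  } else {
    stopifnot(inherits(region, "region_spec"))
    name <- "custom"
    eff <- c(s = 0.2, c = 0.1)
    vg0 <- 0.03
  }
  if (is.null(vg)) vg <- if (instruments == "strong") vg0 else vg0 / 10
  if (is.null(tau)) tau <- if (instruments == "strong") 5e-8 else 1e-3
  nb <- length(region$block_sizes)
  stopifnot(n_causal >= 1, n_causal <= nb)
  starts <- cumsum(c(0, region$block_sizes))[seq_len(nb)]
  causal_idx <- (starts + ceiling(region$block_sizes / 2))[seq_len(n_causal)]
  structure(list(name = sprintf("%s-%s", name, instruments),
                 region = region, causal_idx = causal_idx,
                 effect_s = unname(eff["s"]), effect_c = unname(eff["c"]),
                 vg = vg, theta = theta, n1 = n1, n2 = n2, nref = nref,
                 reps = reps, tau = tau, instruments = instruments),
            class = "scenario_config")
}

#' Draw causal effect sizes for a scenario
#'
#' Causal effects are `|N(0, s)| + c` for the risk-increasing allele (zero at
#' non-causal variants) and are then rescaled so that the variance of the
#' genetic score `G b` equals `vg` under the supplied dosage covariance,
#' pinning the proportion of exposure variance the instruments explain.
#'
#' @param config A [mr_scenario()] configuration.
#' @param causal_cov Covariance matrix of the causal-variant dosages (from
#'   the reference pool).
#' @return Length-p effect vector (non-causal entries exactly zero).
#' @export
draw_effects <- function(config, causal_cov) {
  k <- length(config$causal_idx)
  b <- abs(stats::rnorm(k, 0, config$effect_s)) + config$effect_c
  v0 <- drop(crossprod(b, causal_cov %*% b))
  b <- b * sqrt(config$vg / v0)
  out <- numeric(config$region$p)
  out[config$causal_idx] <- b
  out
}

#' Overall F statistic of the oracle regression
#'
#' Least-squares regression of the exposure on the causal dosages with an
#' intercept; `F <= 10` is the usual rule of thumb for weak instruments.
#'
#' @param x Trait vector.
#' @param g n x k dosage matrix of the causal variants.
#' @return The overall F statistic.
#' @export
oracle_f_stat <- function(x, g) {
  g <- as.matrix(g)
  n <- length(x)
  k <- ncol(g)
  stopifnot(n > k + 1)
  fit <- stats::.lm.fit(cbind(1, g), x)
  if (fit$rank < k + 1) stop("collinear causal variant set")
  rss <- sum(fit$residuals^2)
  tss <- sum((x - mean(x))^2)
  ((tss - rss) / k) / (rss / (n - k - 1))
}

#' Simulate one two-sample replicate
#'
#' Draws bootstrap exposure and outcome samples from the reference pool,
#' generates the exposure `X = G b + U + eX` and the outcome
#' `Y = theta X + U + eY` with `U, eX, eY ~ N(0, sigma0^2)` iid and
#' `sigma0^2 = (1 - vg)/2` (so `Var(X) = 1`), computes per-variant
#' simple-regression summary statistics for each sample, and returns the
#' harmonized dataset together with the oracle F statistic of the exposure
#' on the causal dosages. The exposure-side noise entering the outcome
#' sample is drawn as a single normal with the analytically summed variance.
#'
#' @param config A [mr_scenario()] configuration.
#' @param rep_seed Optional seed for the replicate (restores the caller's
#'   RNG stream).
#' @param pool Reference genotype pool (matrix from [generate_genotypes()] or
#'   a prepared pool); `NULL` generates one of size `config$nref`.
#' @param ld Optional precomputed [ld_reference]; `NULL` computes it from
#'   the pool.
#' @return A list with `data` ([cismr_data]), `oracle_f`, `b` (true effect
#'   vector) and `causal_idx`.
#' @export
simulate_two_sample <- function(config, rep_seed = NULL, pool = NULL,
                                ld = NULL) {
  .with_seed(rep_seed, {
    if (is.null(pool))
      pool <- generate_genotypes(config$region, config$nref)
    prep <- .pool_prep(pool)
    if (is.null(ld))
      ld <- ld_reference(stats::cor(prep$g), snp = prep$snp, n_ref = prep$n)
    ci <- config$causal_idx
    poolc <- prep$g[, ci, drop = FALSE]
    b <- draw_effects(config, stats::cov(poolc))
    q <- drop(poolc %*% b[ci])
    s0sq <- (1 - config$vg) / 2
    theta <- config$theta

    idx1 <- sample.int(prep$n, config$n1, replace = TRUE)
    x1 <- q[idx1] + stats::rnorm(config$n1, 0, sqrt(2 * s0sq))
    m1 <- .marginal_stats(prep, idx1, x1)

    idx2 <- sample.int(prep$n, config$n2, replace = TRUE)
    vnoise <- ((theta + 1)^2 + theta^2 + 1) * s0sq
    y2 <- theta * q[idx2] + stats::rnorm(config$n2, 0, sqrt(vnoise))
    m2 <- .marginal_stats(prep, idx2, y2)

    of <- oracle_f_stat(x1, poolc[idx1, , drop = FALSE])
    data <- cismr_data(snp = prep$snp, eaf = prep$f,
                       beta_x = m1$beta, se_x = m1$se, p_x = m1$p,
                       beta_y = m2$beta, se_y = m2$se,
                       n_x = config$n1, n_y = config$n2,
                       corr = ld$corr, n_ref = ld$n_ref)
    list(data = data, oracle_f = of, b = b, causal_idx = ci)
  })
}

#' Oracle F statistics across replicates
#'
#' Fast exposure-only path: per replicate, bootstrap an exposure sample from
#' the pool, draw effects, simulate the exposure and record the overall F of
#' its regression on the causal dosages.
#'
#' @param config A [mr_scenario()] configuration.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @return Numeric vector of `reps` F statistics.
#' @export
simulate_oracle_f <- function(config, reps = config$reps, seed = 1) {
  .with_seed(seed, {
    pool <- generate_genotypes(config$region, config$nref)
    ci <- config$causal_idx
    poolc <- pool[, ci, drop = FALSE]
    cc <- stats::cov(poolc)
    s0sq <- (1 - config$vg) / 2
    vapply(seq_len(reps), function(r) {
      b <- draw_effects(config, cc)
      idx1 <- sample.int(nrow(pool), config$n1, replace = TRUE)
      gc1 <- poolc[idx1, , drop = FALSE]
      x1 <- drop(gc1 %*% b[ci]) + stats::rnorm(config$n1, 0, sqrt(2 * s0sq))
      oracle_f_stat(x1, gc1)
    }, 0)
  })
}
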