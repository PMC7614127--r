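# Shared fixtures: toy harmonized datasets built in code, and a cache of
# reference genotype pools so simulation-heavy tests do not regenerate them.

toy_data <- function(beta_x, beta_y, se_x = NULL, se_y = NULL, corr = NULL,
                     eaf = 0.3, n_x = 10000, n_y = 50000) {
  p <- length(beta_x)
  if (is.null(se_x)) se_x <- rep(0.02, p)
  if (is.null(se_y)) se_y <- rep(0.01, p)
  if (is.null(corr)) corr <- diag(p)
  cismr_data(snp = sprintf("s%02d", seq_len(p)),
             eaf = rep_len(eaf, p),
             beta_x = beta_x, se_x = rep_len(se_x, p),
             p_x = pmax(2 * pnorm(-abs(beta_x / rep_len(se_x, p))),
                        .Machine$double.xmin),
             beta_y = beta_y, se_y = rep_len(se_y, p),
             n_x = n_x, n_y = n_y, corr = corr)
}

# random PSD correlation matrix from low-rank loadings plus a ridge
random_corr <- function(p, rank = 3, ridge = 0.3) {
  L <- matrix(rnorm(p * rank), p, rank)
  stats::cov2cor(tcrossprod(L) + diag(p) * ridge)
}

# deterministic strong-signal toy region: 5 correlated variants, 1 causal
toy_region_data <- function(seed = 1, p = 5, theta = 0) {
  set.seed(seed)
  corr <- 0.4^abs(outer(seq_len(p), seq_len(p), "-"))
  bx_true <- c(0.25, rep(0.02, p - 1))
  se_x <- rep(0.01, p)
  se_y <- rep(0.01, p)
  bx <- drop(corr %*% bx_true) + rnorm(p, 0, se_x)
  by <- theta * drop(corr %*% bx_true) + rnorm(p, 0, se_y)
  toy_data(bx, by, se_x, se_y, corr)
}

# scenario pool cache shared across test files
.pool_env <- new.env(parent = emptyenv())

cached_pool <- function(cfg, seed = 990) {
  key <- sprintf("%s_%d_%d", cfg$name, cfg$nref, seed)
  hit <- get0(key, envir = .pool_env)
  if (!is.null(hit)) return(hit)
  pool <- generate_genotypes(cfg$region, cfg$nref, seed = seed)
  prep <- cismr:::.pool_prep(pool)
  ld <- ld_reference(stats::cor(prep$g), snp = prep$snp, n_ref = prep$n)
  val <- list(prep = prep, ld = ld)
  # keep at most two pools alive to bound memory
  keys <- ls(.pool_env)
  if (length(keys) >= 2) rm(list = keys[1], envir = .pool_env)
  assign(key, val, envir = .pool_env)
  val
}

sim_rep <- function(cfg, r, pool) {
  simulate_two_sample(cfg, rep_seed = 10000 + r, pool = pool$prep,
                      ld = pool$ld)
}
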