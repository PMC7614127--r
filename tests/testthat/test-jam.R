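# JAM: sufficient statistics, model evidence, reversible-jump search,
# model averaging, binary-trait mapping.

jam_toy <- function(seed = 21, p = 5, strong = 1) {
  set.seed(seed)
  corr <- 0.3^abs(outer(seq_len(p), seq_len(p), "-"))
  n1 <- 5000
  f <- rep(0.3, p)
  d2 <- 2 * f * (1 - f)
  bx_true <- numeric(p); bx_true[strong] <- 0.15
  se_x <- sqrt(1 / (n1 * d2))
  bx <- drop(corr %*% bx_true) + rnorm(p, 0, se_x)
  toy_data(bx, beta_y = 0.05 * bx, se_x = se_x, se_y = 0.01,
           corr = corr, eaf = 0.3, n_x = n1)
}

test_that("the z transformation matches direct substitution", {
  d <- toy_data(beta_x = 0.2, beta_y = 0, eaf = 0.5, n_x = 100)
  suff <- jam_sufficient_stats(d)
  expect_equal(unname(suff$z), 2 * 0.5 * 0.5 * 100 * 0.2)  # = 10

  d0 <- toy_data(beta_x = 0, beta_y = 0, eaf = 0.5, n_x = 100)
  expect_equal(unname(jam_sufficient_stats(d0)$z), 0)

  # z scales with 2 f (1 - f): f = 0.1 vs 0.5 gives ratio 0.18/0.5
  da <- toy_data(beta_x = 0.2, beta_y = 0, eaf = 0.1, n_x = 100)
  expect_equal(unname(jam_sufficient_stats(da)$z) /
                 unname(jam_sufficient_stats(d)$z), 0.36)

  expect_equal(unname(diag(suff$xtx)), 100 * 2 * 0.5 * 0.5)
  dn <- toy_data(beta_x = 0.2, beta_y = 0, n_x = NA)
  expect_error(jam_sufficient_stats(dn), "sample size")
})

test_that("evidence prefers the null model on null data and rejects singular sets", {
  d <- toy_data(beta_x = rep(0, 4), beta_y = rep(0, 4), n_x = 2000)
  suff <- jam_sufficient_stats(d)
  cfg <- jam_config()
  e0 <- jam_log_evidence(integer(), suff, cfg)
  for (j in 1:4)
    expect_gt(e0, jam_log_evidence(j, suff, cfg))

  corr <- diag(3); corr[1, 2] <- corr[2, 1] <- 1
  ddup <- toy_data(beta_x = c(0.1, 0.1, 0.05), beta_y = rep(0, 3),
                   corr = corr, n_x = 2000)
  sd2 <- jam_sufficient_stats(ddup)
  expect_identical(jam_log_evidence(c(1, 2), sd2, cfg), -Inf)
  expect_true(is.finite(jam_log_evidence(c(1, 3), sd2, cfg)))
})

test_that("evidence is invariant to variant relabeling", {
  d <- jam_toy()
  suff <- jam_sufficient_stats(d)
  perm <- c(3, 5, 1, 2, 4)
  dp <- d[perm]
  suffp <- jam_sufficient_stats(dp)
  cfg <- jam_config()
  for (gam in list(1L, c(1L, 4L), c(2L, 3L, 5L))) {
    gam_p <- match(gam, perm)
    expect_equal(jam_log_evidence(gam, suff, cfg),
                 jam_log_evidence(gam_p, suffp, cfg), tolerance = 1e-10)
  }
})

test_that("RJMCMC visit frequencies match exhaustive enumeration (P = 5)", {
  d <- jam_toy(seed = 22)
  cfg <- jam_config(preprune_rho = 1, iterations = 200000, burn_in = 20000,
                    seed = 7)
  suff <- jam_sufficient_stats(d)
  subsets <- lapply(0:31, function(m) which(bitwAnd(m, 2^(0:4)) > 0))
  lev <- vapply(subsets, jam_log_evidence, 0, suff = suff, config = cfg)
  pri <- exp(lev - max(lev)); pri <- pri / sum(pri)
  names(pri) <- vapply(subsets, paste, "", collapse = ",")

  post <- jam_rjmcmc(d, cfg)
  phat <- setNames(numeric(length(pri)), names(pri))
  phat[names(post$model_probs)] <- post$model_probs
  tv <- 0.5 * sum(abs(phat - pri))
  expect_lt(tv, 0.03)
  expect_equal(sum(post$model_probs), 1, tolerance = 1e-9)
})

test_that("the chain is deterministic given a seed and finds the causal variant", {
  d <- jam_toy(seed = 23, strong = 2)
  cfg <- jam_config(preprune_rho = 1, iterations = 20000, burn_in = 2000,
                    seed = 99)
  p1 <- jam_rjmcmc(d, cfg)
  p2 <- jam_rjmcmc(d, cfg)
  expect_identical(p1, p2)
  expect_equal(which.max(p1$inclusion_probs), 2L, ignore_attr = TRUE)

  # inclusion probabilities are exactly the marginals of the model posterior
  marg <- numeric(5)
  for (k in names(p1$model_probs)) {
    if (!nzchar(k)) next
    idx <- as.integer(strsplit(k, ",")[[1]])
    marg[idx] <- marg[idx] + p1$model_probs[[k]]
  }
  expect_equal(unname(p1$inclusion_probs), marg, tolerance = 1e-12)
})

test_that("model averaging follows the law of total variance", {
  d <- toy_data(beta_x = c(1, 1), beta_y = c(1, 3), se_y = c(1, 1),
                n_x = 1000)
  post <- structure(list(model_probs = c("1" = 0.5, "2" = 0.5),
                         variants = d$snp, accept_rate = 1, n_models = 2),
                    class = "jam_posterior")
  est <- jam_model_average(post, d)
  expect_equal(est$theta, 2)          # single-variant thetas are 1 and 3
  expect_equal(est$se, sqrt(2))       # 0.5(1+1) + 0.5(1+9) - 4 = 2

  # degenerate posterior equals the model's own correlated IVW
  post1 <- structure(list(model_probs = setNames(c(0.7, 0.3), c("1,2", "")),
                          variants = d$snp, accept_rate = 1, n_models = 2),
                     class = "jam_posterior")
  est1 <- jam_model_average(post1, d)
  ref <- ivw_correlated(d, variants = d$snp)
  expect_equal(est1$theta, ref$theta)
  expect_equal(est1$se, ref$se)
  expect_equal(est1$extras$empty_mass, 0.3)

  post0 <- structure(list(model_probs = setNames(1, ""), variants = d$snp),
                     class = "jam_posterior")
  expect_error(jam_model_average(post0, d), "no instruments")
})

test_that("log-odds mapping matches a logistic/linear simulation", {
  expect_equal(logodds_to_linear(0, case_fraction = 0.3), 0)
  expect_equal(logodds_to_linear(1, case_fraction = 0.5), 0.25)

  set.seed(41)
  n <- 60000
  g <- rbinom(n, 2, 0.3)
  beta <- 0.15
  pr <- plogis(-0.1 + beta * g)
  y <- rbinom(n, 1, pr)
  b_logit <- coef(glm(y ~ g, family = binomial))[2]
  b_lin <- coef(lm(y ~ g))[2]
  expect_equal(unname(logodds_to_linear(b_logit, case_fraction = mean(y))),
               unname(b_lin), tolerance = 0.1)
})

test_that("the averaged estimate is robust to the pre-pruning threshold", {
  cfg <- mr_scenario("shbg", "strong", theta = 0.1)
  pool <- cached_pool(cfg)
  sim <- sim_rep(cfg, 1, pool)
  ests <- lapply(c(0.6, 0.8, 0.9, 0.95), function(r)
    jam_fit(sim$data, jam_config(preprune_rho = r, iterations = 3000,
                                 burn_in = 300, seed = 5)))
  th <- vapply(ests, `[[`, 0, "theta")
  se <- vapply(ests, `[[`, 0, "se")
  expect_lt(max(th) - min(th), max(se))
})
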