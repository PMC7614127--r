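# Synthetic region generator, effect drawing, two-sample simulation and the
# benchmark harness.

test_that("genotype generation is deterministic and honors the LD structure", {
  region <- region_spec(p = 4, block_sizes = c(2, 2), decay = c(1, 0),
                        maf = c(0.3, 0.3, 0.2, 0.4))
  g1 <- generate_genotypes(region, 500, seed = 3)
  g2 <- generate_genotypes(region, 500, seed = 3)
  expect_identical(g1, g2)
  # decay 1: duplicated columns within the block
  expect_identical(g1[, 1], g1[, 2])

  region0 <- region_spec(p = 2, block_sizes = 2, decay = 0,
                         maf = c(0.2, 0.4))
  g0 <- generate_genotypes(region0, 10000, seed = 4)
  expect_lt(abs(cor(g0[, 1], g0[, 2])), 0.05)

  # realized allele frequencies match the spec within sampling error
  region2 <- region_spec()
  gg <- generate_genotypes(region2, 20000, seed = 5)
  se3 <- 3 * sqrt(2 * region2$maf * (1 - region2$maf) / 20000)
  expect_true(all(abs(colMeans(gg) - 2 * region2$maf) < se3 + 0.01))
})

test_that("clustered regions realize their dosage-scale correlation targets", {
  region <- region_spec(p = 10, block_sizes = 10, cluster_sizes = c(6, 4),
                        within_r = 0.998, between_r = 0.6,
                        maf = rep(0.3, 10))
  g <- generate_genotypes(region, 30000, seed = 6)
  cc <- cor(g)
  expect_equal(cc[1, 2], 0.998, tolerance = 0.005)
  expect_equal(cc[1, 8], 0.6, tolerance = 0.05)
})

test_that("effect drawing pins the explained variance and zeroes non-causal entries", {
  cfg <- mr_scenario("shbg", "strong")
  pool <- generate_genotypes(cfg$region, 10000, seed = 11)
  cc <- cov(pool[, cfg$causal_idx])
  set.seed(2)
  b <- draw_effects(cfg, cc)
  expect_true(all(b[-cfg$causal_idx] == 0))
  expect_true(all(b[cfg$causal_idx] > 0))
  expect_equal(drop(t(b[cfg$causal_idx]) %*% cc %*% b[cfg$causal_idx]),
               cfg$vg, tolerance = 1e-10)

  # degenerate half-normal (s = 0): all causal effects equal
  cfg0 <- cfg
  cfg0$effect_s <- 0
  b0 <- draw_effects(cfg0, cc)
  expect_equal(length(unique(round(b0[cfg0$causal_idx] /
                                     max(b0[cfg0$causal_idx]), 6))), 1)

  # realized explained-variance fraction close to vg in a fresh sample
  x <- drop(pool %*% b) + rnorm(10000, 0, sqrt(1 - cfg$vg))
  frac <- var(drop(pool %*% b)) / var(x)
  expect_equal(frac, cfg$vg, tolerance = 0.1 * cfg$vg + 0.01)
})

test_that("the two-sample simulator is seeded and produces coherent summaries", {
  cfg <- mr_scenario("shbg", "strong", theta = 0.1, n1 = 2000, n2 = 4000,
                     nref = 4000)
  s1 <- simulate_two_sample(cfg, rep_seed = 8)
  s2 <- simulate_two_sample(cfg, rep_seed = 8)
  expect_identical(s1$data$beta_x, s2$data$beta_x)
  expect_identical(s1$data$beta_y, s2$data$beta_y)
  expect_identical(s1$oracle_f, s2$oracle_f)
  expect_s3_class(s1$data, "cismr_data")
  expect_true(all(s1$data$se_x > 0) && all(s1$data$se_y > 0))
  # exposure sample is twice as small, so se_x should be roughly larger
  expect_gt(median(s1$data$se_x / s1$data$se_y), 1)
})

test_that("oracle F matches its noncentral closed form", {
  # E[F] ~ 1 + n vg / ((1 - vg) k)
  cfg <- mr_scenario("shbg", "strong", n1 = 3000, vg = 0.01, nref = 20000)
  fs <- simulate_oracle_f(cfg, reps = 400, seed = 13)
  expected <- 1 + 3000 * 0.01 / (0.99 * 6)
  mcse <- sd(fs) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - expected), 2 * mcse)

  # exposure independent of the causal set: central F with mean ~ 1
  cfg0 <- mr_scenario("shbg", "strong", n1 = 3000, vg = 1e-6, nref = 20000)
  fs0 <- simulate_oracle_f(cfg0, reps = 400, seed = 14)
  expect_lt(abs(mean(fs0) - 1), 2 * sd(fs0) / sqrt(length(fs0)) + 1e-3)

  x <- rnorm(50)
  g <- cbind(x, x)
  expect_error(oracle_f_stat(rnorm(50), g), "collinear")
})

test_that("benchmark aggregation arithmetic is exact", {
  rec <- list(label = "m", theta = c(0.1, 0.2, 0.15), se = c(1, 1, 1),
              reject = c(TRUE, FALSE, TRUE), cover = c(TRUE, TRUE, FALSE),
              is_test = rep(FALSE, 3))
  row <- cismr:::.benchmark_aggregate(rec, theta = 0.1)
  expect_equal(row$coverage, 2 / 3)
  expect_equal(row$power, 2 / 3)
  expect_equal(row$median_theta, 0.15)
  expect_equal(row$n_fail, 0)

  # an oracle method: always covers, always rejects
  rec2 <- list(label = "oracle", theta = rep(0.1, 3), se = rep(1e-9, 3),
               reject = rep(TRUE, 3), cover = rep(TRUE, 3),
               is_test = rep(FALSE, 3))
  row2 <- cismr:::.benchmark_aggregate(rec2, theta = 0.1)
  expect_equal(row2$coverage, 1)
  expect_equal(row2$power, 1)
})

test_that("the benchmark harness runs a small battery end to end", {
  cfg <- mr_scenario("hmgcr", "strong", theta = 0.05, n1 = 2000, n2 = 4000,
                     nref = 4000, tau = 1e-3)
  tab <- run_benchmark(cfg, methods = c("top-snp", "prune:0.5", "pca:0.99",
                                        "fliml", "clr"),
                       reps = 3, seed = 5, clr_draws = 500)
  expect_s3_class(tab, "benchmark_table")
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$reps_used + tab$n_fail == 3))
  expect_true(is.na(tab$median_theta[tab$method == "clr"]))
  expect_true(all(is.finite(tab$median_theta[tab$method != "clr"])))
  expect_gt(attr(tab, "mean_oracle_f"), 1)
  expect_output(print(tab), "hmgcr")
})
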