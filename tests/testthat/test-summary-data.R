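# Summary-statistics I/O, LD reading, and two-sample harmonization.

write_stats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

example_stats <- function() {
  data.frame(snp = c("rs1", "rs2", "rs3"), chr = "1", pos = c(100, 200, 300),
             ea = c("A", "C", "G"), nea = c("G", "T", "T"),
             eaf = c(0.21, 0.5, 0.33), beta = c(0.1234, -0.05, 0.007),
             se = c(0.01, 0.02, 0.015), pval = c(1e-8, 0.01, 0.64),
             n = 10000)
}

test_that("summary statistics survive a write/read round trip exactly", {
  path <- write_stats_file(example_stats())
  ss <- read_summary_stats(path, role = "exposure")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3)
  expect_identical(attr(ss, "role"), "exposure")
  out <- tempfile(fileext = ".tsv")
  write_summary_stats(ss, out)
  ss2 <- read_summary_stats(out, role = "exposure")
  for (col in c("eaf", "beta", "se", "pval", "n"))
    expect_identical(ss[[col]], ss2[[col]])
})

test_that("malformed files and rows are reported precisely", {
  df <- example_stats()
  df$se <- NULL
  expect_error(read_summary_stats(write_stats_file(df)), "se")

  df2 <- example_stats()
  df2$eaf[2] <- 1.2
  ss <- read_summary_stats(write_stats_file(df2))
  expect_equal(nrow(ss), 2)
  rep <- attr(ss, "parse_report")
  expect_equal(rep$snp, "rs2")
  expect_equal(rep$reason, "eaf_out_of_range")
  expect_equal(rep$line, 3)  # header is line 1

  df3 <- example_stats()
  df3$beta <- as.character(df3$beta)
  df3$beta[3] <- "oops"
  expect_error(read_summary_stats(write_stats_file(df3)), "line 4")
})

test_that("square and long LD formats agree and violations are hard errors", {
  sq <- tempfile()
  writeLines(c("rs1\trs2", "1 0", "0 1"), sq)
  ld <- read_ld_matrix(sq)
  expect_equal(unname(ld$corr), diag(2))
  expect_equal(ld$snp, c("rs1", "rs2"))

  lg <- tempfile()
  writeLines(c("id1 id2 r", "rsA rsB 0.3"), lg)
  ld2 <- read_ld_matrix(lg)
  expect_equal(ld2$corr["rsA", "rsB"], 0.3)
  expect_equal(ld2$corr["rsB", "rsA"], 0.3)

  bad <- tempfile()
  writeLines(c("rs1\trs2", "1 0.5", "0.4 1"), bad)
  expect_error(read_ld_matrix(bad), "asymmetric")

  tiny <- tempfile()  # asymmetry below tolerance is averaged away
  writeLines(c("rs1 rs2", "1 0.50000004", "0.49999996 1"), tiny)
  expect_equal(read_ld_matrix(tiny)$corr["rs1", "rs2"], 0.5)

  nd <- tempfile()
  writeLines(c("rs1 rs2", "1.1 0", "0 1"), nd)
  expect_error(read_ld_matrix(nd), "diagonal")

  nsq <- tempfile()
  writeLines(c("rs1 rs2 rs3", "1 0 0", "0 1 0"), nsq)
  expect_error(read_ld_matrix(nsq), "square")
})

test_that("LD from genotypes: perfect correlates, independence, constant columns", {
  g <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 1, 0, 2))
  expect_equal(ld_from_genotypes(g)$corr["a", "b"], 1)

  set.seed(5)
  gi <- cbind(x = rbinom(10000, 2, 0.3), y = rbinom(10000, 2, 0.4))
  expect_lt(abs(ld_from_genotypes(gi)$corr["x", "y"]), 0.05)
  expect_equal(ld_from_genotypes(gi)$n_ref, 10000)

  gz <- cbind(x = c(1, 2, 0, 1), z = rep(0, 4))
  expect_error(ld_from_genotypes(gz), "z")
})

test_that("harmonization aligns alleles, builds omega, and drops mismatches", {
  ex <- structure(example_stats(), role = "exposure",
                  class = c("summary_stats", "data.frame"))
  ld <- ld_reference(diag(3), snp = ex$snp)

  # identical coding: nothing changes, nothing dropped
  ou <- ex
  attr(ou, "role") <- "outcome"
  h <- harmonize(ex, ou, ld)
  expect_equal(h$beta_y, ex$beta)
  expect_equal(nrow(h$dropped), 0)

  # swapped alleles on one variant: beta flipped; allele-aware LD flips too
  ou2 <- ou
  ou2$ea[2] <- ex$nea[2]; ou2$nea[2] <- ex$ea[2]
  ou2$eaf[2] <- 1 - ex$eaf[2]
  corr <- matrix(c(1, 0.4, 0, 0.4, 1, 0.2, 0, 0.2, 1), 3)
  ld2 <- ld_reference(corr, snp = ex$snp, ea = ou2$ea, nea = ou2$nea)
  h2 <- harmonize(ex, ou2, ld2)
  expect_equal(h2$beta_y[2], -ex$beta[2])
  expect_equal(h2$corr[1, 2], -0.4)
  expect_equal(h2$corr[2, 3], -0.2)
  expect_equal(diag(h2$corr), rep(1, 3), ignore_attr = TRUE)

  # incompatible allele pair is dropped with a reason
  ou3 <- ou
  ou3$ea[3] <- "A"; ou3$nea[3] <- "C"
  h3 <- harmonize(ex, ou3, ld)
  expect_equal(length(h3$snp), 2)
  expect_true(any(h3$dropped$snp == "rs3" &
                    h3$dropped$reason == "allele_mismatch"))

  expect_error(harmonize(ex, ou[0, ], ld), "no variants")
})

test_that("omega is diag(se_y) R diag(se_y), by hand on a 2-SNP example", {
  d <- toy_data(beta_x = c(0.1, 0.2), beta_y = c(0.01, 0.02),
                se_y = c(1, 2), corr = matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(unname(d$omega), matrix(c(1, 1, 1, 4), 2))
})

test_that("allele flips are involutive and palindromic variants droppable", {
  ex <- structure(example_stats(), role = "exposure",
                  class = c("summary_stats", "data.frame"))
  ou <- ex
  attr(ou, "role") <- "outcome"
  flip <- function(s, i) {
    tmp <- s$ea[i]; s$ea[i] <- s$nea[i]; s$nea[i] <- tmp
    s$beta[i] <- -s$beta[i]; s$eaf[i] <- 1 - s$eaf[i]
    s
  }
  ld <- ld_reference(diag(3), snp = ex$snp)
  h0 <- harmonize(ex, ou, ld)
  h2 <- harmonize(ex, flip(flip(ou, 2), 2), ld)
  for (fld in c("snp", "eaf", "beta_x", "se_x", "beta_y", "se_y", "corr",
                "omega"))
    expect_equal(h2[[fld]], h0[[fld]])

  exp_pal <- example_stats()
  exp_pal$ea[1] <- "A"; exp_pal$nea[1] <- "T"
  ep <- structure(exp_pal, role = "exposure",
                  class = c("summary_stats", "data.frame"))
  op <- ep; attr(op, "role") <- "outcome"
  hp <- harmonize(ep, op, ld_reference(diag(3), snp = ep$snp),
                  drop_palindromic = TRUE)
  expect_equal(length(hp$snp), 2)
  expect_true("palindromic" %in% hp$dropped$reason)
})

test_that("omega stays PSD under diagonal congruence of a PSD correlation", {
  set.seed(77)
  for (rep in 1:5) {
    p <- 7
    d <- toy_data(beta_x = rnorm(p), beta_y = rnorm(p),
                  se_y = runif(p, 0.2, 3), corr = random_corr(p))
    ev <- eigen(d$omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})
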