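# Benchmark harness: run a battery of cis-MR methods over simulated
# replicates and tabulate medians, type-I error, coverage and power.

# parse "prune:0.3" style method strings
.parse_methods <- function(methods) {
  lapply(methods, function(m) {
    parts <- strsplit(m, ":", fixed = TRUE)[[1]]
    name <- parts[1]
    known <- c("top-snp", "ivw", "prune", "cojo", "pca", "jam", "fliml", "clr")
    if (!name %in% known)
      stop("unknown method: ", name,
           " (known: ", paste(known, collapse = ", "), ")")
    tuning <- if (length(parts) > 1) as.numeric(parts[2]) else NA_real_
    list(name = name, tuning = tuning, label = m)
  })
}

.method_defaults <- c(prune = 0.3, cojo = 0.9, pca = 0.999, jam = 0.9)

# run one method on one simulated dataset; returns c(theta, se, lo, hi, p)
# or for clr a reject/cover pair computed by direct testing.
.run_method <- function(spec, data, config, fm, opts) {
  tun <- spec$tuning
  if (is.na(tun) && spec$name %in% names(.method_defaults))
    tun <- .method_defaults[[spec$name]]
  switch(spec$name,
    "top-snp" = {
      i <- which.min(data$p_x)
      wald_ratio(data$beta_x[i], data$se_x[i], data$beta_y[i], data$se_y[i])
    },
    "ivw" = ivw_standard(data),
    "prune" = {
      sel <- ld_prune(data, rho = tun, tau = config$tau)
      if (!length(sel$selected)) stop("empty selection")
      ivw_correlated(data, variants = sel$selected)
    },
    "cojo" = {
      sel <- cojo_select(data, rho = tun, tau = config$tau)
      if (!length(sel$selected)) stop("empty selection")
      ivw_correlated(data, variants = sel$selected)
    },
    "pca" = pca_ivw(data, threshold = tun),
    "jam" = jam_fit(data, jam_config(preprune_rho = tun,
                                     iterations = opts$jam_iterations,
                                     burn_in = opts$jam_burn,
                                     seed = opts$seed)),
    "fliml" = f_liml(data, model = fm),
    "clr" = {
      p0 <- clr_test(data, fm, theta0 = 0,
                     draws = opts$clr_draws, seed = opts$seed)$p_value
      pt <- clr_test(data, fm, theta0 = config$theta,
                     draws = opts$clr_draws, seed = opts$seed)$p_value
      structure(list(reject = p0 < 0.05, cover = pt >= 0.05),
                class = "clr_row")
    })
}

# aggregate per-method replicate records into one table row
.benchmark_aggregate <- function(rec, theta) {
  ok <- !is.na(rec$theta) | rec$is_test
  used <- sum(ok)
  data.frame(
    method = rec$label,
    median_theta = if (rec$is_test[1]) NA_real_ else
      stats::median(rec$theta, na.rm = TRUE),
    median_se = if (rec$is_test[1]) NA_real_ else
      stats::median(rec$se, na.rm = TRUE),
    type1 = if (theta == 0) mean(rec$reject, na.rm = TRUE) else NA_real_,
    coverage = mean(rec$cover, na.rm = TRUE),
    power = if (theta != 0) mean(rec$reject, na.rm = TRUE) else NA_real_,
    reps_used = sum(!is.na(rec$reject)),
    n_fail = sum(is.na(rec$reject)),
    stringsAsFactors = FALSE
  )
}

#' Run the simulation benchmark for a battery of methods
#'
#' Per replicate, simulates a two-sample dataset under `config` (all methods
#' see the same data within a replicate) and applies every requested method;
#' aggregates median estimates and standard errors, the type-I error (for a
#' null scenario), coverage of the 95% interval, power (for a non-null
#' scenario), and the mean oracle F statistic. A method failing on a
#' replicate (e.g. empty selection, ill-conditioned weighting matrix) is
#' excluded from that replicate with the failure counted; a method failing
#' everywhere yields an NA row rather than an error.
#'
#' @param config A [mr_scenario()] configuration.
#' @param methods Character vector of method specs: `"top-snp"`, `"ivw"`,
#'   `"prune:<rho>"`, `"cojo:<rho>"`, `"pca:<threshold>"`, `"jam:<rho>"`,
#'   `"fliml"`, `"clr"`.
#' @param reps Number of replicates.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param jam_iterations,jam_burn RJMCMC length for JAM rows (desk-scale
#'   default; see the methods vignette).
#' @param clr_draws Monte Carlo draws per CLR p-value.
#' @param ref_per_rep If a number, redraw a reference panel of that size for
#'   every replicate (the small-reference regime) instead of using the pool.
#' @return A `benchmark_table` data frame with one row per method and
#'   attributes `mean_oracle_f`, `theta`, `reps`.
#' @export
run_benchmark <- function(config, methods = c("top-snp", "prune:0.3",
                                              "pca:0.999"),
                          reps = config$reps, seed = 1,
                          jam_iterations = 4000, jam_burn = 400,
                          clr_draws = 4000, ref_per_rep = NULL) {
  specs <- .parse_methods(methods)
  seeds <- .with_seed(seed, sample.int(2147483646L, reps + 1L))
  pool <- generate_genotypes(config$region, config$nref,
                             seed = seeds[reps + 1L])
  prep <- .pool_prep(pool)
  ld <- ld_reference(stats::cor(prep$g), snp = prep$snp, n_ref = prep$n)

  rec <- lapply(specs, function(s)
    list(label = s$label,
         theta = rep(NA_real_, reps), se = rep(NA_real_, reps),
         reject = rep(NA, reps), cover = rep(NA, reps),
         is_test = rep(s$name == "clr", reps)))
  names(rec) <- vapply(specs, `[[`, "", "label")
  oracle_f <- numeric(reps)
  need_fm <- any(vapply(specs, function(s) s$name %in% c("fliml", "clr"),
                        TRUE))

  for (r in seq_len(reps)) {
    ld_r <- ld
    if (!is.null(ref_per_rep)) {
      refg <- generate_genotypes(config$region, ref_per_rep,
                                 seed = seeds[r] %% 2147483399L + 1L)
      ld_r <- ld_from_genotypes(refg)
    }
    sim <- simulate_two_sample(config, rep_seed = seeds[r], pool = prep,
                               ld = ld_r)
    oracle_f[r] <- sim$oracle_f
    fm <- if (need_fm)
      tryCatch(fit_factors(sim$data), error = function(e) NULL) else NULL
    opts <- list(jam_iterations = jam_iterations, jam_burn = jam_burn,
                 clr_draws = clr_draws, seed = seeds[r])
    for (s in specs) {
      res <- tryCatch(.run_method(s, sim$data, config, fm, opts),
                      error = function(e) NULL)
      if (is.null(res)) next
      rr <- rec[[s$label]]
      if (inherits(res, "clr_row")) {
        rr$reject[r] <- res$reject
        rr$cover[r] <- res$cover
      } else {
        rr$theta[r] <- res$theta
        rr$se[r] <- res$se
        rr$reject[r] <- res$p_value < 0.05
        rr$cover[r] <- res$ci_low <= config$theta &
          config$theta <= res$ci_high
      }
      rec[[s$label]] <- rr
    }
  }
  tab <- do.call(rbind, lapply(rec, .benchmark_aggregate,
                               theta = config$theta))
  rownames(tab) <- NULL
  structure(tab, mean_oracle_f = mean(oracle_f), theta = config$theta,
            reps = reps, scenario = config$name,
            class = c("benchmark_table", "data.frame"))
}

#' @export
print.benchmark_table <- function(x, digits = 3, ...) {
  cat(sprintf("Benchmark: scenario %s, theta = %g, %d replicates, mean oracle F = %.1f\n",
              attr(x, "scenario"), attr(x, "theta"), attr(x, "reps"),
              attr(x, "mean_oracle_f")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
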