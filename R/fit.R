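# User-facing fitting entry point.

#' Fit a cis-MR causal effect estimate
#'
#' Single entry point dispatching to the estimation strategies of the
#' package. Selection-based methods (`"prune"`, `"cojo"`) select instruments
#' and then apply the correlated-instruments IVW estimate on the selected
#' set; `"pca"`, `"jam"` and `"fliml"` use the whole region.
#'
#' @param data A [cismr_data] object from [harmonize()] or the simulator.
#' @param method One of `"top-snp"` (Wald ratio at the smallest exposure
#'   p-value), `"ivw"` (standard IVW, independence assumed), `"ivw-corr"`
#'   (correlated IVW on all variants), `"prune"`, `"cojo"`, `"pca"`,
#'   `"jam"`, `"fliml"`.
#' @param rho Correlation threshold for `"prune"`, `"cojo"` and (as the
#'   pre-pruning threshold) `"jam"`.
#' @param tau Significance threshold for the selection-based methods
#'   (`NULL` disables it for `"prune"`).
#' @param pca_threshold Variance proportion for `"pca"`.
#' @param ... Further arguments passed to the underlying implementation
#'   (e.g. `config` for `"jam"`, `model` for `"fliml"`,
#'   `max_condition` for `"ivw-corr"`).
#' @return An [mr_estimate].
#' @examples
#' cfg <- mr_scenario("shbg", "strong", theta = 0.1, nref = 2000,
#'                    n1 = 2000, n2 = 5000)
#' sim <- simulate_two_sample(cfg, rep_seed = 1)
#' mr_fit(sim$data, "prune", rho = 0.3, tau = 1e-3)
#' @export
mr_fit <- function(data, method = c("top-snp", "ivw", "ivw-corr", "prune",
                                    "cojo", "pca", "jam", "fliml"),
                   rho = NULL, tau = 5e-8, pca_threshold = 0.999, ...) {
  method <- match.arg(method)
  switch(method,
    "top-snp" = {
      i <- which.min(data$p_x)
      est <- wald_ratio(data$beta_x[i], data$se_x[i],
                        data$beta_y[i], data$se_y[i])
      est$extras$snp <- data$snp[i]
      est
    },
    "ivw" = ivw_standard(data),
    "ivw-corr" = ivw_correlated(data, ...),
    "prune" = {
      sel <- ld_prune(data, rho = if (is.null(rho)) 0.3 else rho, tau = tau)
      if (!length(sel$selected)) stop("empty selection: no variant passes tau")
      est <- ivw_correlated(data, variants = sel$selected, ...)
      attr(est, "selection") <- sel
      est
    },
    "cojo" = {
      sel <- cojo_select(data, rho = if (is.null(rho)) 0.9 else rho,
                         tau = tau, ...)
      if (!length(sel$selected)) stop("empty selection: no variant passes tau")
      est <- ivw_correlated(data, variants = sel$selected)
      attr(est, "selection") <- sel
      est
    },
    "pca" = pca_ivw(data, threshold = pca_threshold, ...),
    "jam" = {
      args <- list(...)
      cfg <- if (!is.null(args$config)) args$config else
        jam_config(preprune_rho = if (is.null(rho)) 0.9 else rho)
      jam_fit(data, cfg)
    },
    "fliml" = f_liml(data, ...))
}
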