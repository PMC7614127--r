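# Instrument selection: greedy LD-pruning and conditional-and-joint selection.

.selection_result <- function(selected, discarded, trace, rho, tau, method) {
  structure(list(selected = selected, discarded = discarded, trace = trace,
                 rho = rho, tau = tau, method = method),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("%s selection (rho = %s, tau = %s): %d selected, %d discarded\n",
              x$method, format(x$rho), format(x$tau),
              length(x$selected), nrow(x$discarded)))
  if (length(x$selected))
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# Deterministic candidate priority: ascending p, then smaller se_x, then id.
.p_order <- function(data) order(data$p_x, data$se_x, data$snp)

#' Greedy LD-pruning of candidate instruments
#'
#' Iteratively selects the remaining variant with the smallest exposure
#' p-value (subject to the significance threshold `tau`, if set) and discards
#' all remaining variants whose absolute correlation with it is at least
#' `rho`. Ties on the p-value are broken by the smaller exposure standard
#' error, then lexicographic snp id. An empty selection is a valid result.
#'
#' @param data A [cismr_data] object.
#' @param rho Correlation threshold in (0, 1]: variants with `|r| >= rho` to a
#'   selected variant are pruned. `rho = 1` discards only perfect correlates.
#' @param tau Optional significance threshold on the exposure p-value; `NULL`
#'   disables it.
#' @return A `selection_result` with `selected` (ids in selection order),
#'   `discarded` (`snp`, `reason`: `pruned_by:<id>` or `below_tau`) and a
#'   per-iteration `trace`.
#' @export
ld_prune <- function(data, rho, tau = NULL) {
  stopifnot(rho > 0, rho <= 1)
  p <- length(data$snp)
  active <- rep(TRUE, p)
  reason <- rep(NA_character_, p)
  ord <- .p_order(data)
  selected <- character()
  trace <- list()
  for (pick in ord) {
    if (!active[pick]) next
    if (!is.null(tau) && data$p_x[pick] >= tau) {
      reason[active] <- "below_tau"
      active[active] <- FALSE
      break
    }
    active[pick] <- FALSE
    prune <- which(active & abs(data$corr[pick, ]) >= rho)
    reason[prune] <- paste0("pruned_by:", data$snp[pick])
    active[prune] <- FALSE
    selected <- c(selected, data$snp[pick])
    trace[[length(trace) + 1L]] <-
      data.frame(iter = length(selected), picked = data$snp[pick],
                 p = data$p_x[pick], n_pruned = length(prune))
  }
  disc <- which(!is.na(reason))
  .selection_result(
    selected,
    data.frame(snp = data$snp[disc], reason = reason[disc],
               stringsAsFactors = FALSE),
    if (length(trace)) do.call(rbind, trace) else NULL,
    rho, tau, "ld_prune")
}

# Joint fit of the exposure on a variant set from marginal summary statistics,
# via the summary-level normal equations with reference LD and HWE genotype
# variances 2 f (1 - f).
.cojo_joint <- function(data, idx, n, var_y, max_condition = 1e8) {
  d <- 2 * data$eaf[idx] * (1 - data$eaf[idx])
  sq <- sqrt(d)
  xtx <- n * outer(sq, sq) * data$corr[idx, idx, drop = FALSE]
  ev <- eigen(xtx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) return(NULL)
  xty <- n * d * data$beta_x[idx]
  ch <- chol(xtx)
  b <- .chol_solve(ch, xty)
  k <- length(idx)
  df <- n - k - 1
  sigma2 <- max((n * var_y - sum(b * xty)) / df, 1e-8)
  xtxinv_diag <- rowSums(backsolve(ch, diag(k))^2)
  se <- sqrt(sigma2 * xtxinv_diag)
  tt <- b / se
  list(b = b, se = se, p = 2 * stats::pt(-abs(tt), df))
}

#' Conditional-and-joint instrument selection from summary statistics
#'
#' Stepwise selection in the style of the GCTA conditional-and-joint (CoJo)
#' algorithm, reconstructed from marginal statistics and reference LD.
#' Starting from the smallest-p variant, each iteration (i) computes the
#' conditional effect of every eligible candidate given the selected set
#' (candidates correlated at `|r| >= rho` with any selected variant are
#' screened out), (ii) adds the candidate with the smallest conditional
#' p-value when it is below `tau`, (iii) refits the joint model on the
#' selected set, and (iv) drops the variant with the largest joint p-value
#' when it exceeds `tau`. The loop stops when no add or drop occurs.
#'
#' @param data A [cismr_data] object with `eaf` and `n_x` available.
#' @param rho Correlation screen used both for candidate eligibility and for
#'   the collinearity guard.
#' @param tau Significance threshold on conditional and joint p-values.
#' @param var_y Assumed phenotypic variance of the exposure (1 for a
#'   standardized trait).
#' @return A `selection_result`; discard reasons are `pruned_by:<id>`,
#'   `below_tau`, `dropped_joint` or `collinear_skip`.
#' @export
cojo_select <- function(data, rho = 0.9, tau = 5e-8, var_y = 1) {
  stopifnot(rho > 0, rho <= 1, tau > 0, tau <= 1)
  n <- data$n_x[1]
  if (is.na(n)) stop("exposure sample size (n_x) is required for cojo_select")
  p <- length(data$snp)
  ord <- .p_order(data)
  start <- ord[1]
  if (data$p_x[start] >= tau) {
    return(.selection_result(character(),
                             data.frame(snp = data$snp,
                                        reason = "below_tau",
                                        stringsAsFactors = FALSE),
                             NULL, rho, tau, "cojo"))
  }
  sel <- start
  reason <- rep(NA_character_, p)
  trace <- list()
  for (it in seq_len(100L)) {
    changed <- FALSE
    # (i)-(ii) add step
    cand <- setdiff(seq_len(p), sel)
    skip <- rep(FALSE, length(cand))
    cond_p <- rep(NA_real_, length(cand))
    for (ci in seq_along(cand)) {
      j <- cand[ci]
      r <- abs(data$corr[j, sel])
      if (any(r >= rho)) { skip[ci] <- TRUE; next }
      fit <- .cojo_joint(data, c(sel, j), n, var_y)
      if (is.null(fit)) { skip[ci] <- TRUE; reason[j] <- "collinear_skip"; next }
      cond_p[ci] <- fit$p[length(fit$p)]
    }
    ok <- which(!skip & !is.na(cond_p))
    if (length(ok)) {
      best <- ok[order(cond_p[ok], data$se_x[cand[ok]], data$snp[cand[ok]])[1]]
      if (cond_p[best] < tau) {
        sel <- c(sel, cand[best])
        reason[cand[best]] <- NA_character_
        changed <- TRUE
        trace[[length(trace) + 1L]] <-
          data.frame(iter = it, action = "add", snp = data$snp[cand[best]],
                     p = cond_p[best])
      }
    }
    # (iii)-(iv) joint refit and drop step
    if (length(sel) > 1) {
      fit <- .cojo_joint(data, sel, n, var_y)
      if (!is.null(fit) && max(fit$p) > tau) {
        worst <- which.max(fit$p)
        reason[sel[worst]] <- "dropped_joint"
        trace[[length(trace) + 1L]] <-
          data.frame(iter = it, action = "drop", snp = data$snp[sel[worst]],
                     p = fit$p[worst])
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- setdiff(seq_len(p), sel)
  for (j in out) {
    if (!is.na(reason[j])) next
    r <- abs(data$corr[j, sel])
    reason[j] <- if (any(r >= rho))
      paste0("pruned_by:", data$snp[sel[which.max(r)]]) else "below_tau"
  }
  .selection_result(
    data$snp[sel],
    data.frame(snp = data$snp[out], reason = reason[out],
               stringsAsFactors = FALSE),
    if (length(trace)) do.call(rbind, trace) else NULL,
    rho, tau, "cojo")
}
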