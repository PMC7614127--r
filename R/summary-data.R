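# Summary-statistic containers, file I/O and two-sample harmonization.

.ACGT <- c("A", "C", "G", "T")

#' Read GWAS summary statistics from a tab-separated file
#'
#' The file must have a header with at least the columns `snp`, `ea`, `nea`,
#' `eaf`, `beta`, `se`, `pval` (case-insensitive; `chr`, `pos` and `n` are
#' optional, extra columns are ignored). Rows violating the per-variant
#' invariants (effect-allele frequency outside (0,1), non-positive standard
#' error, p-value outside (0,1], non-ACGT or identical alleles, duplicated
#' snp id) are dropped and listed in the parse report attached as the
#' `"parse_report"` attribute. A non-numeric `beta` or `se` is a hard error
#' reporting the offending line.
#'
#' @param path Path to the TSV file.
#' @param role Which side of the two-sample design the file describes.
#' @return A `summary_stats` data frame with columns `snp`, `chr`, `pos`,
#'   `ea`, `nea`, `eaf`, `beta`, `se`, `pval`, `n` and attributes `role` and
#'   `parse_report`.
#' @export
read_summary_stats <- function(path, role = c("exposure", "outcome")) {
  role <- match.arg(role)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  required <- c("snp", "ea", "nea", "eaf", "beta", "se", "pval")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  line <- seq_len(nrow(raw)) + 1L  # header is line 1

  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  beta <- num("beta"); se <- num("se")
  bad <- which(is.na(beta) | is.na(se))
  if (length(bad))
    stop(sprintf("non-numeric beta/se at line %d ('%s' / '%s')",
                 line[bad[1]], raw$beta[bad[1]], raw$se[bad[1]]))
  eaf <- num("eaf"); pval <- num("pval")
  n <- if ("n" %in% names(raw)) num("n") else rep(NA_real_, nrow(raw))
  ea <- toupper(trimws(raw$ea)); nea <- toupper(trimws(raw$nea))

  reason <- rep(NA_character_, nrow(raw))
  mark <- function(cond, why) {
    hit <- which(cond & is.na(reason))
    reason[hit] <<- why
  }
  mark(is.na(eaf) | eaf <= 0 | eaf >= 1, "eaf_out_of_range")
  mark(se <= 0, "nonpositive_se")
  mark(is.na(pval) | pval <= 0 | pval > 1, "pval_out_of_range")
  mark(!(ea %in% .ACGT) | !(nea %in% .ACGT), "invalid_allele")
  mark(ea == nea, "identical_alleles")
  mark(duplicated(raw$snp), "duplicate_id")

  keep <- is.na(reason)
  report <- data.frame(line = line[!keep], snp = raw$snp[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  out <- data.frame(
    snp = raw$snp[keep],
    chr = if ("chr" %in% names(raw)) raw$chr[keep] else NA_character_,
    pos = if ("pos" %in% names(raw)) as.integer(num("pos")[keep]) else NA_integer_,
    ea = ea[keep], nea = nea[keep],
    eaf = eaf[keep], beta = beta[keep], se = se[keep], pval = pval[keep],
    n = n[keep], stringsAsFactors = FALSE
  )
  structure(out, role = role, parse_report = report,
            class = c("summary_stats", "data.frame"))
}

#' Write summary statistics to a tab-separated file
#'
#' Numeric fields are printed with 17 significant digits so that a
#' read/write round trip reproduces them exactly.
#'
#' @param x A `summary_stats` data frame (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  out <- x
  for (col in c("eaf", "beta", "se", "pval", "n"))
    if (col %in% names(out) && is.numeric(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a reference LD object
#'
#' @param corr P x P matrix of pairwise genotype correlations; must be
#'   symmetric with unit diagonal and eigenvalues above -1e-8.
#' @param snp Character vector of variant ids (defaults to the matrix
#'   dimnames).
#' @param n_ref Reference panel sample size (may be `NA`).
#' @param ea,nea Optional allele codings of the reference dosages; when
#'   present, [harmonize()] aligns the matrix signs to the exposure coding.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(corr, snp = rownames(corr), n_ref = NA_real_,
                         ea = NULL, nea = NULL) {
  corr <- as.matrix(corr)
  p <- nrow(corr)
  if (ncol(corr) != p) stop("corr must be square")
  if (is.null(snp)) snp <- paste0("v", seq_len(p))
  if (anyDuplicated(snp)) stop("duplicated snp ids in LD reference")
  asym <- max(abs(corr - t(corr)))
  if (asym > 1e-6) stop(sprintf("LD matrix asymmetric beyond tolerance (%.3g)", asym))
  corr <- (corr + t(corr)) / 2
  if (max(abs(diag(corr) - 1)) > 1e-6)
    stop("LD matrix diagonal departs from 1 beyond tolerance")
  diag(corr) <- 1
  if (max(abs(corr)) > 1 + 1e-8) stop("correlations outside [-1, 1]")
  corr[corr > 1] <- 1; corr[corr < -1] <- -1
  if (p <= 500) {
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(sprintf("LD matrix is not positive semi-definite (min eigenvalue %.3g)",
                   min(ev)))
  }
  dimnames(corr) <- list(snp, snp)
  structure(list(snp = snp, corr = corr, n_ref = n_ref, ea = ea, nea = nea),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("LD reference: %d variants, n_ref = %s\n",
              length(x$snp), format(x$n_ref)))
  invisible(x)
}

#' Read an LD correlation matrix from a text file
#'
#' Two dialects are supported: a whitespace-delimited square matrix whose
#' header row lists the snp ids (an optional leading row-label column is
#' allowed), and a long three-column format `id1 id2 r` (header optional)
#' listing pairwise correlations; unlisted pairs default to zero.
#' Asymmetries up to 1e-6 are symmetrized by averaging; larger ones, a
#' non-square matrix or a diagonal departing from one are hard errors.
#'
#' @param path Path to the file.
#' @return An [ld_reference].
#' @export
read_ld_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty LD file")
  toks <- strsplit(trimws(lines), "[ \t]+")
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))

  long <- length(toks) >= 2 &&
    all(lengths(toks) == 3) &&
    all(vapply(toks[-1], function(t) !is_num(t[1]) && !is_num(t[2]) && is_num(t[3]),
               TRUE))
  if (long) {
    rows <- toks
    if (!is_num(rows[[1]][3])) rows <- rows[-1]  # header line
    ids <- unique(unlist(lapply(rows, `[`, 1:2)))
    p <- length(ids)
    m <- diag(1, p); dimnames(m) <- list(ids, ids)
    for (r in rows) {
      v <- as.numeric(r[3])
      m[r[1], r[2]] <- v
      m[r[2], r[1]] <- v
    }
    return(ld_reference(m, snp = ids))
  }

  header <- toks[[1]]
  p <- length(header)
  body <- toks[-1]
  if (length(body) != p) stop("LD matrix is not square")
  rows <- lapply(body, function(t) {
    if (length(t) == p + 1 && !is_num(t[1])) t <- t[-1]
    if (length(t) != p) stop("LD matrix is not square")
    as.numeric(t)
  })
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("non-numeric entries in LD matrix")
  dimnames(m) <- list(header, header)
  ld_reference(m, snp = header)
}

#' Compute reference LD from a genotype dosage matrix
#'
#' @param dosages n x P numeric matrix of allele dosages in `[0, 2]`, one
#'   column per variant.
#' @param snp Variant ids; defaults to the column names.
#' @return An [ld_reference] with `n_ref` set to the number of rows.
#' @export
ld_from_genotypes <- function(dosages, snp = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2) stop("need at least 2 individuals")
  if (is.null(snp)) snp <- paste0("v", seq_len(ncol(dosages)))
  sds <- apply(dosages, 2, stats::sd)
  if (any(sds == 0))
    stop("constant genotype column: ", snp[which(sds == 0)[1]])
  m <- stats::cor(dosages)
  ld_reference(m, snp = snp, n_ref = nrow(dosages))
}

#' Construct a harmonized two-sample dataset
#'
#' Low-level constructor used by [harmonize()] and by the simulator, for data
#' whose allele coding is already consistent. All vectors must share the
#' variant order of `corr`.
#'
#' @param snp,eaf,beta_x,se_x,p_x,beta_y,se_y Per-variant fields.
#' @param n_x,n_y Sample sizes (scalars or per-variant; may be `NA`).
#' @param corr P x P LD correlation matrix.
#' @param dropped Data frame `(snp, reason)` of variants removed upstream.
#' @param n_ref Reference panel size behind `corr`.
#' @return An object of class `cismr_data` carrying the summary statistics,
#'   the LD matrix and the IVW weighting matrix
#'   `omega = diag(se_y) %*% corr %*% diag(se_y)`.
#' @export
cismr_data <- function(snp, eaf, beta_x, se_x, p_x, beta_y, se_y,
                       n_x = NA_real_, n_y = NA_real_, corr,
                       dropped = data.frame(snp = character(),
                                            reason = character()),
                       n_ref = NA_real_) {
  p <- length(snp)
  stopifnot(length(eaf) == p, length(beta_x) == p, length(se_x) == p,
            length(p_x) == p, length(beta_y) == p, length(se_y) == p,
            nrow(corr) == p, ncol(corr) == p)
  if (anyDuplicated(snp)) stop("duplicated snp ids")
  if (any(!is.finite(se_x)) || any(se_x <= 0)) stop("se_x must be positive")
  if (any(!is.finite(se_y)) || any(se_y <= 0)) stop("se_y must be positive")
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1)))
    stop("eaf must lie in (0, 1)")
  corr <- as.matrix(corr)
  dimnames(corr) <- list(snp, snp)
  omega <- outer(se_y, se_y) * corr
  dimnames(omega) <- dimnames(corr)
  structure(list(
    snp = snp, eaf = eaf,
    beta_x = beta_x, se_x = se_x, p_x = p_x,
    beta_y = beta_y, se_y = se_y,
    n_x = n_x, n_y = n_y,
    corr = corr, omega = omega,
    dropped = dropped, n_ref = n_ref
  ), class = "cismr_data")
}

#' @export
print.cismr_data <- function(x, ...) {
  cat(sprintf("cis-MR dataset: %d variants (n_x = %s, n_y = %s)\n",
              length(x$snp), format(x$n_x[1]), format(x$n_y[1])))
  if (nrow(x$dropped))
    cat(sprintf("  %d variant(s) dropped during harmonization\n",
                nrow(x$dropped)))
  invisible(x)
}

# Subset a harmonized dataset to selected variants (ids or indices).
#' @export
`[.cismr_data` <- function(x, i, ...) {
  idx <- .resolve_variants(x, i)
  sc <- function(v) if (length(v) == length(x$snp)) v[idx] else v
  cismr_data(snp = x$snp[idx], eaf = sc(x$eaf),
             beta_x = x$beta_x[idx], se_x = x$se_x[idx], p_x = x$p_x[idx],
             beta_y = x$beta_y[idx], se_y = x$se_y[idx],
             n_x = x$n_x, n_y = x$n_y,
             corr = x$corr[idx, idx, drop = FALSE],
             dropped = x$dropped, n_ref = x$n_ref)
}

.is_palindromic <- function(ea, nea) {
  (ea == "A" & nea == "T") | (ea == "T" & nea == "A") |
    (ea == "C" & nea == "G") | (ea == "G" & nea == "C")
}

#' Harmonize exposure and outcome summary statistics against reference LD
#'
#' Retains the intersection of variants (in exposure-file order), aligns the
#' outcome effect allele to the exposure coding (flipping the sign of the
#' outcome beta and complementing its frequency when alleles are swapped),
#' aligns the LD matrix rows/columns likewise when the reference carries
#' allele codings, optionally drops palindromic (A/T, C/G) variants, and
#' builds the IVW weighting matrix `omega = diag(se_y) corr diag(se_y)`.
#' Variants whose allele pairs are neither identical nor swapped are dropped
#' with reason `"allele_mismatch"`.
#'
#' @param exposure,outcome `summary_stats` data frames from
#'   [read_summary_stats()].
#' @param ld An [ld_reference] covering the region.
#' @param drop_palindromic Drop A/T and C/G variants regardless of frequency?
#' @return A [cismr_data] object.
#' @export
harmonize <- function(exposure, outcome, ld, drop_palindromic = FALSE) {
  dropped <- list()
  note <- function(snp, reason) {
    if (length(snp))
      dropped[[length(dropped) + 1L]] <<-
        data.frame(snp = snp, reason = reason, stringsAsFactors = FALSE)
  }
  note(exposure$snp[!exposure$snp %in% outcome$snp], "not_in_outcome")
  note(setdiff(intersect(exposure$snp, outcome$snp), ld$snp), "not_in_ld")
  common <- exposure$snp[exposure$snp %in% outcome$snp &
                           exposure$snp %in% ld$snp]

  ex <- exposure[match(common, exposure$snp), ]
  ou <- outcome[match(common, outcome$snp), ]
  li <- match(common, ld$snp)
  corr <- ld$corr[li, li, drop = FALSE]

  same <- ou$ea == ex$ea & ou$nea == ex$nea
  swap <- ou$ea == ex$nea & ou$nea == ex$ea
  note(common[!same & !swap], "allele_mismatch")
  beta_y <- ifelse(swap, -ou$beta, ou$beta)

  if (!is.null(ld$ea)) {
    lea <- ld$ea[li]; lnea <- ld$nea[li]
    lsame <- lea == ex$ea & lnea == ex$nea
    lswap <- lea == ex$nea & lnea == ex$ea
    note(common[!lsame & !lswap & (same | swap)], "allele_mismatch_ld")
    flip <- ifelse(lswap, -1, 1)
    corr <- corr * outer(flip, flip)
    diag(corr) <- 1
    keepa <- lsame | lswap
  } else keepa <- rep(TRUE, length(common))

  keep <- (same | swap) & keepa
  if (drop_palindromic) {
    pal <- .is_palindromic(ex$ea, ex$nea)
    note(common[keep & pal], "palindromic")
    keep <- keep & !pal
  }
  if (!any(keep)) stop("no variants left after harmonization")

  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(snp = character(), reason = character())
  k <- which(keep)
  cismr_data(snp = common[k], eaf = ex$eaf[k],
             beta_x = ex$beta[k], se_x = ex$se[k], p_x = ex$pval[k],
             beta_y = beta_y[k], se_y = ou$se[k],
             n_x = ex$n[k][1], n_y = ou$n[k][1],
             corr = corr[k, k, drop = FALSE],
             dropped = dropped, n_ref = ld$n_ref)
}
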