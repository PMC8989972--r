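#' Parse a genomic region string
#'
#' Regions are written `"chr:start-end"` with a half-open interval
#' `[start, end)`; internally they become 1-based inclusive
#' `start .. end - 1`.
#'
#' @param region region string, e.g. `"2:21000000-22000000"`.
#' @return List with `chrom`, `start`, `end` (1-based inclusive).
#' @export
parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region string: ", region)
  start <- as.numeric(m[3])
  end <- as.numeric(m[4]) - 1
  if (end < start) stop("empty region: ", region)
  list(chrom = m[2], start = start, end = end)
}

#' Two-stage linear mixed-model association scan
#'
#' Stage 1 fits the null model `trait ~ covariates + conditioning genotypes`
#' with the additive relatedness component by REML. Stage 2 holds the fitted
#' covariance `V` fixed and, for each variant, computes the
#' generalized-least-squares effect `beta = (x' P x)^-1 x' P y` (with `P` the
#' REML projection, which also sweeps out the fixed effects) and a Wald
#' t-test against the residual degrees of freedom, with the residual scale
#' re-estimated per variant. When the relatedness matrix is proportional to
#' the identity this reproduces ordinary least squares exactly. Effects are
#' reported per copy of the VCF alt (effect) allele, in SD units when the
#' trait is prepared.
#'
#' @param y prepared trait vector aligned with the genotype rows.
#' @param g a [genotype_matrix] (QC-passed variants).
#' @param kinship a [relatedness_matrix] (kinship or GRM) aligned with `y`.
#' @param X optional covariate design matrix (intercept added if absent).
#' @param conditioning rsids of conditioning variants, added to the fixed
#'   effects (the paper's enriched-variant adjustment and the engine behind
#'   conditional analysis).
#' @param region optional `"chr:start-end"` region filter.
#' @param trait trait label copied into the output.
#' @param control REML control, see [vc_control()].
#' @return Data frame of association records: chrom, pos, rsid, ref, alt,
#'   eaf, beta, se, t, p, n, trait, conditioning, skipped, skip_reason.
#' @export
association_scan <- function(y, g, kinship, X = NULL,
                             conditioning = character(0), region = NULL,
                             trait = "trait", control = vc_control()) {
  stopifnot(inherits(g, "genotype_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(g$dosages)) stop("y and genotypes have different subjects")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- ensure_intercept(as.matrix(X))
  if (length(conditioning)) {
    missing <- setdiff(conditioning, colnames(g$dosages))
    if (length(missing)) stop("conditioning variant(s) not found: ",
                              paste(missing, collapse = ", "))
    gc_ <- g$dosages[, conditioning, drop = FALSE]
    gc_ <- apply(gc_, 2, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE); x
    })
    X <- cbind(X, gc_)
  }
  A <- unclass_matrix(kinship)
  ## a relatedness matrix proportional to the identity (all unrelated) makes
  ## the variance split unidentifiable; the scan then reduces to OLS, which
  ## any V proportional to the identity reproduces exactly
  null_fit <- tryCatch(
    fit_variance_components(y, list(additive = A), X,
                            method = "REML", control = control),
    error = function(e) {
      if (grepl("proportional to the identity", conditionMessage(e))) NULL
      else stop(e)
    })
  V <- if (is.null(null_fit)) diag(n) else
    null_fit$sigma2[1] * A + null_fit$sigma2["residual"] * diag(n)
  Vinv <- chol2inv(chol(V))
  VX <- Vinv %*% X
  XtVX_inv <- solve(crossprod(X, VX))
  Py <- drop(Vinv %*% y - VX %*% (XtVX_inv %*% crossprod(VX, y)))
  yPy <- sum(y * Py)
  p_fixed <- ncol(X)
  df <- n - p_fixed - 1

  variants <- g$variants
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- variants$chrom == r$chrom & variants$pos >= r$start &
      variants$pos <= r$end
  }
  variants <- variants[keep, , drop = FALSE]
  D <- g$dosages[, keep, drop = FALSE]
  m <- ncol(D)
  if (m == 0) {
    return(assoc_records(variants, numeric(0), numeric(0), numeric(0),
                         numeric(0), numeric(0), n, trait, conditioning,
                         logical(0), character(0)))
  }
  cm <- colMeans(D, na.rm = TRUE)
  for (j in seq_len(m)) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- cm[j]
  }
  eaf <- cm / 2
  qrX <- qr(X)
  resX <- qr.resid(qrX, D)              # component of x orthogonal to X
  mono <- apply(D, 2, stats::var) < 1e-12
  collin <- !mono & colMeans(resX^2) < 1e-10 * pmax(apply(D, 2, stats::var),
                                                    1e-12)
  skipped <- mono | collin
  reason <- ifelse(mono, "monomorphic", ifelse(collin, "collinear", ""))
  PD <- Vinv %*% D - VX %*% (XtVX_inv %*% crossprod(VX, D))
  xPx <- colSums(D * PD)
  xPx[skipped] <- NA_real_
  xPy <- drop(crossprod(D, Py))
  beta <- xPy / xPx
  s2v <- pmax(yPy - beta * xPy, 0) / df
  se <- sqrt(s2v / xPx)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = df)
  assoc_records(variants, eaf, beta, se, tstat, pval, n, trait, conditioning,
                skipped, reason)
}

assoc_records <- function(variants, eaf, beta, se, tstat, pval, n, trait,
                          conditioning, skipped, reason) {
  data.frame(chrom = variants$chrom, pos = variants$pos,
             rsid = variants$rsid, ref = variants$ref, alt = variants$alt,
             eaf = eaf, beta = beta, se = se, t = tstat, p = pval, n = n,
             trait = trait,
             conditioning = paste(conditioning, collapse = ","),
             skipped = skipped, skip_reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sequential conditional analysis of a locus
#'
#' Iteratively adds the most significant variant in the region to the
#' conditioning set and rescans, until no variant falls below `alpha`. The
#' ordered conditioning set is the list of independent signals at the locus.
#'
#' @inheritParams association_scan
#' @param region `"chr:start-end"` locus to dissect (typically +/- 1 Mb
#'   around the index variant).
#' @param alpha significance threshold for declaring another independent
#'   signal.
#' @param max_signals safety cap on the number of rounds (default 20).
#' @return List with `signals` (rsids in conditioning order), `scans` (list
#'   of scan data frames, one per round; the last is fully conditioned).
#' @export
conditional_scan <- function(y, g, kinship, region, X = NULL,
                             conditioning = character(0), alpha = 4.5e-10,
                             trait = "trait", max_signals = 20,
                             control = vc_control()) {
  signals <- character(0)
  scans <- list()
  repeat {
    sc <- association_scan(y, g, kinship, X = X,
                           conditioning = c(conditioning, signals),
                           region = region, trait = trait, control = control)
    scans[[length(scans) + 1]] <- sc
    ok <- !sc$skipped & !is.na(sc$p)
    if (!any(ok) || min(sc$p[ok]) >= alpha || length(signals) >= max_signals) {
      break
    }
    top <- sc$rsid[ok][which.min(sc$p[ok])]
    signals <- c(signals, top)
  }
  list(signals = signals, scans = scans)
}

#' Principal-component-based multiple-testing threshold
#'
#' Eigen-decomposes the correlation matrix of the (prepared) traits over
#' complete-case subjects and finds the smallest number of principal
#' components whose cumulative eigenvalue fraction reaches the variance
#' fraction; the adjusted significance threshold is the base genome-wide
#' level divided by that count.
#'
#' @param t a [trait_matrix] (or plain numeric matrix) of prepared traits.
#' @param variance_fraction cumulative variance to capture (default 0.95).
#' @param base_level base genome-wide significance level (default 5e-8),
#'   which is also reported as the suggestive threshold.
#' @return Object of class `threshold_result`: list with `trait_count`,
#'   `pc_count`, `significance_threshold`, `suggestive_threshold`.
#' @export
multiple_testing_threshold <- function(t, variance_fraction = 0.95,
                                       base_level = 5e-8) {
  vals <- if (inherits(t, "trait_matrix")) t$values else as.matrix(t)
  if (ncol(vals) < 2) stop("need at least 2 traits")
  cc <- stats::complete.cases(vals)
  if (sum(cc) < ncol(vals)) {
    stop("complete-case subjects (", sum(cc), ") fewer than traits (",
         ncol(vals), "); subset the traits or supply more subjects")
  }
  R <- stats::cor(vals[cc, , drop = FALSE])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= variance_fraction)[1]
  structure(list(trait_count = ncol(vals), pc_count = as.integer(k),
                 significance_threshold = base_level / k,
                 suggestive_threshold = base_level),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold_result: %d traits -> %d PCs; significance %.3g, suggestive %.3g\n",
    x$trait_count, x$pc_count, x$significance_threshold,
    x$suggestive_threshold))
  invisible(x)
}

#' Adjusted significance threshold from a PC count
#'
#' The effective-number-of-tests correction: base genome-wide level divided
#' by the number of principal components needed to explain the target
#' variance fraction of the trait panel.
#'
#' @param base_level base genome-wide level (default 5e-8).
#' @param pc_count number of principal components.
#' @return `base_level / pc_count`.
#' @export
adjusted_threshold <- function(base_level = 5e-8, pc_count) {
  stopifnot(pc_count >= 1)
  base_level / pc_count
}

#' Bonferroni replication threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of replication lookups.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Analytic power for replication-exclusion reasoning
#'
#' Power of the two-sided Wald test for a standardized additive effect:
#' the noncentrality is `beta * factor * sqrt(2 maf (1 - maf) n)` (trait in
#' SD units, genotype coded 0/1/2) and power is the mass of the shifted
#' standard normal beyond the two-sided critical values. `factor = 0.5`
#' halves the discovery effect to adjust for winner's curse.
#'
#' @param beta effect size in SD units of the trait.
#' @param maf minor-allele frequency in the replication sample, in (0, 0.5].
#' @param n replication sample size (>= 2).
#' @param alpha two-sided test level, in (0, 1).
#' @param factor winner's-curse adjustment factor, 1 (as observed) or 0.5
#'   (halved effect).
#' @return Power in (0, 1); equals `alpha` when `beta = 0`.
#' @export
replication_exclusion_power <- function(beta, maf, n, alpha = 0.05,
                                        factor = 1) {
  if (any(maf <= 0) || any(maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (any(n < 2)) stop("n must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!all(factor %in% c(1, 0.5))) stop("factor must be 1 or 0.5")
  ncp <- beta * factor * sqrt(2 * maf * (1 - maf) * n)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-zc - ncp) + stats::pnorm(ncp - zc)
}

#' Genomic-control inflation factor
#'
#' Median association chi-square divided by the null median, a standard
#' calibration diagnostic for mixed-model scans.
#'
#' @param p vector of association p-values.
#' @return `lambda_GC`.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Write a GWAS summary table
#'
#' @param records data frame from [association_scan()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
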