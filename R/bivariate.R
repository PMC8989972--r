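#' Bivariate mixed-model genetic and environmental correlation
#'
#' Fits, by maximum likelihood, the stacked two-trait model with genetic
#' covariance `[[s_g1, s_g12], [s_g12, s_g2]] (x) K` and residual covariance
#' `[[s_e1, s_e12], [s_e12, s_e2]] (x) I`, where `K` is the pedigree kinship
#' (or any relatedness) matrix. The genetic covariance `s_g12` is
#' deliberately left unconstrained (no Cholesky parameterization), so the
#' implied genetic correlation `rho_g = s_g12 / sqrt(s_g1 s_g2)` can fall
#' outside `[-1, 1]`; such estimates, common when one or both traits have low
#' heritability, are flagged `masked` and reported as missing in matrix
#' output. Out-of-range residual correlations are masked symmetrically.
#'
#' Both traits are standardized internally (correlations and heritabilities
#' are scale invariant). The eigendecomposition of `K` reduces every
#' likelihood evaluation to `n` independent 2x2 problems.
#'
#' @param y1,y2 numeric trait vectors (prepared traits) over the same
#'   subjects; pairs with a missing value in either trait are dropped.
#' @param kinship a [relatedness_matrix] aligned with the traits.
#' @param min_n minimum shared subject count (default 30).
#' @param control list: `maxit` for the optimizer (default 2000).
#' @return Object of class `bivar_fit`: list with `h2` (length 2), `sigma`
#'   (named: g1, g2, g12, e1, e2, e12), `rho_g`, `rho_e`, `loglik`, `n`,
#'   `masked`, `mask_reason`.
#' @export
fit_bivariate <- function(y1, y2, kinship, min_n = 30,
                          control = list(maxit = 2000)) {
  K <- unclass_matrix(kinship)
  ok <- !is.na(y1) & !is.na(y2)
  if (sum(ok) < min_n) stop("fewer than ", min_n, " shared observations")
  y1 <- y1[ok]; y2 <- y2[ok]
  K <- K[ok, ok, drop = FALSE]
  y1 <- (y1 - mean(y1)) / stats::sd(y1)
  y2 <- (y2 - mean(y2)) / stats::sd(y2)
  n <- length(y1)
  e <- eigen(K, symmetric = TRUE)
  d <- pmax(e$values, 0)
  U <- e$vectors
  ty1 <- drop(crossprod(U, y1))
  ty2 <- drop(crossprod(U, y2))
  tx <- drop(crossprod(U, rep(1, n)))

  nll <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(1e10)
    g1 <- exp(theta[1]); g2 <- exp(theta[2]); g12 <- theta[3]
    e1 <- exp(theta[4]); e2 <- exp(theta[5]); e12 <- theta[6]
    a <- d * g1 + e1
    b <- d * g2 + e2
    cc <- d * g12 + e12
    det_ <- a * b - cc^2
    if (any(det_ <= 1e-12) || any(a <= 0) || any(b <= 0)) return(1e10)
    ## GLS intercepts
    M11 <- sum(tx^2 * b / det_); M22 <- sum(tx^2 * a / det_)
    M12 <- -sum(tx^2 * cc / det_)
    v1 <- sum(tx * (b * ty1 - cc * ty2) / det_)
    v2 <- sum(tx * (a * ty2 - cc * ty1) / det_)
    dm <- M11 * M22 - M12^2
    if (!is.finite(dm) || dm <= 0) return(1e10)
    b1 <- (M22 * v1 - M12 * v2) / dm
    b2 <- (M11 * v2 - M12 * v1) / dm
    r1 <- ty1 - tx * b1
    r2 <- ty2 - tx * b2
    quad <- sum((b * r1^2 - 2 * cc * r1 * r2 + a * r2^2) / det_)
    out <- 0.5 * (sum(log(det_)) + quad + 2 * n * log(2 * pi))
    if (!is.finite(out)) 1e10 else out
  }

  ## starts from univariate fits and the phenotypic correlation
  uni <- function(y) {
    f <- tryCatch(fit_variance_components(y, list(g = K)),
                  error = function(e) NULL)
    if (is.null(f)) c(0.3, 0.7) else
      pmax(unname(f$sigma2) / sum(f$sigma2), 0.02)
  }
  u1 <- uni(y1); u2 <- uni(y2)
  rp <- stats::cor(y1, y2)
  start <- c(log(u1[1]), log(u2[1]), rp * sqrt(u1[1] * u2[1]),
             log(u1[2]), log(u2[2]), rp * sqrt(u1[2] * u2[2]))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = control$maxit,
                                     reltol = 1e-12))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- opt$par
  sg <- c(g1 = exp(th[1]), g2 = exp(th[2]), g12 = th[3],
          e1 = exp(th[4]), e2 = exp(th[5]), e12 = th[6])
  h2 <- c(sg["g1"] / (sg["g1"] + sg["e1"]),
          sg["g2"] / (sg["g2"] + sg["e2"]))
  names(h2) <- c("trait1", "trait2")
  masked <- FALSE; reason <- NA_character_
  if (sg["g1"] < 1e-6 || sg["g2"] < 1e-6) {
    masked <- TRUE; reason <- "zero heritability"
    rho_g <- NA_real_
  } else {
    rho_g <- unname(sg["g12"] / sqrt(sg["g1"] * sg["g2"]))
    if (abs(rho_g) > 1) { masked <- TRUE; reason <- "out of range" }
  }
  rho_e <- unname(sg["e12"] / sqrt(sg["e1"] * sg["e2"]))
  structure(list(h2 = h2, sigma = sg, rho_g = rho_g, rho_e = rho_e,
                 loglik = -opt$value, n = n, masked = masked,
                 mask_reason = reason),
            class = "bivar_fit")
}

#' @export
print.bivar_fit <- function(x, ...) {
  cat(sprintf(
    "bivar_fit (n = %d): h2 = (%.3f, %.3f), rho_g = %s, rho_e = %.3f%s\n",
    x$n, x$h2[1], x$h2[2],
    if (is.na(x$rho_g)) "NA" else sprintf("%.3f", x$rho_g), x$rho_e,
    if (x$masked) paste0(" [masked: ", x$mask_reason, "]") else ""))
  invisible(x)
}

#' Pairwise genetic and phenotypic correlation matrices
#'
#' Genetic entries come from [fit_bivariate()] with out-of-range masking
#' (masked pairs are `NA`); phenotypic entries are pairwise-complete Pearson
#' correlations. Both matrices are symmetric with unit diagonal.
#'
#' @param t a [trait_matrix] of prepared traits.
#' @param kinship a [relatedness_matrix] aligned with `t`.
#' @param pairs two-column character matrix of trait pairs (default: all
#'   distinct pairs).
#' @param min_n minimum shared observations per pair (default 30; pairs with
#'   fewer are left missing with a reason).
#' @return List with `genetic` (matrix, masked entries `NA`), `phenotypic`
#'   (matrix), and `table` (long data frame: trait1, trait2, rho_g, rho_e,
#'   h2_1, h2_2, n, masked, reason).
#' @export
correlation_matrices <- function(t, kinship, pairs = NULL, min_n = 30) {
  stopifnot(inherits(t, "trait_matrix"))
  traits <- colnames(t$values)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(traits, 2))
  }
  gen <- diag(1, length(traits))
  dimnames(gen) <- list(traits, traits)
  phe <- stats::cor(t$values, use = "pairwise.complete.obs")
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tr1 <- pairs[i, 1]; tr2 <- pairs[i, 2]
    fit <- tryCatch(
      fit_bivariate(t$values[, tr1], t$values[, tr2], kinship, min_n = min_n),
      error = function(e) e)
    if (inherits(fit, "error")) {
      gen[tr1, tr2] <- gen[tr2, tr1] <- NA
      rows[[i]] <- data.frame(trait1 = tr1, trait2 = tr2, rho_g = NA_real_,
                              rho_e = NA_real_, h2_1 = NA_real_,
                              h2_2 = NA_real_, n = NA_integer_,
                              masked = TRUE,
                              reason = conditionMessage(fit),
                              stringsAsFactors = FALSE)
      next
    }
    gen[tr1, tr2] <- gen[tr2, tr1] <- if (fit$masked) NA else fit$rho_g
    rows[[i]] <- data.frame(trait1 = tr1, trait2 = tr2,
                            rho_g = if (is.na(fit$rho_g)) NA_real_ else
                              fit$rho_g,
                            rho_e = fit$rho_e,
                            h2_1 = unname(fit$h2[1]),
                            h2_2 = unname(fit$h2[2]), n = fit$n,
                            masked = fit$masked,
                            reason = ifelse(is.na(fit$mask_reason), "",
                                            fit$mask_reason),
                            stringsAsFactors = FALSE)
  }
  list(genetic = gen, phenotypic = phe, table = do.call(rbind, rows))
}
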