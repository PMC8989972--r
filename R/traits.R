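#' Trait matrix container
#'
#' Lipid species and traditional lipid measurements for subjects, together
#' with trait metadata (lipidome class) and covariates (age, sex, technical
#' batch factors).
#'
#' @param values numeric matrix, subjects x traits, `NA` allowed.
#' @param meta data frame with columns `trait` and `class` (one row per trait
#'   column). Classes follow lipidomics usage, e.g. `TAG`, `SM`, `Cer`, plus
#'   `TRAD` for traditional lipids. Defaults to class `"unknown"`.
#' @param covariates data frame of per-subject covariates (same row order as
#'   `values`), or `NULL`.
#' @param subjects subject ids (default: rownames of `values`).
#' @return Object of class `trait_matrix`: list with `values`, `meta`,
#'   `covariates`.
#' @export
trait_matrix <- function(values, meta = NULL, covariates = NULL,
                         subjects = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("trait", seq_len(ncol(values)))
  }
  if (is.null(meta)) {
    meta <- data.frame(trait = colnames(values), class = "unknown",
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("trait", "class") %in% names(meta))) {
    stop("meta must have columns 'trait' and 'class'")
  }
  if (!setequal(meta$trait, colnames(values))) {
    stop("meta$trait must match the trait columns")
  }
  meta <- meta[match(colnames(values), meta$trait), , drop = FALSE]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != nrow(values)) {
      stop("covariates must have one row per subject")
    }
    rownames(covariates) <- as.character(subjects)
  }
  rownames(values) <- as.character(subjects)
  structure(list(values = values, meta = meta, covariates = covariates),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d subjects x %d traits (%d classes)%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$meta$class)),
              if (is.null(x$covariates)) "" else
                sprintf(", %d covariates", ncol(x$covariates))))
  invisible(x)
}

#' Subject ids of a container
#' @param x a `trait_matrix` or `genotype_matrix`.
#' @export
subject_ids <- function(x) {
  if (inherits(x, "genotype_matrix")) rownames(x$dosages)
  else rownames(x$values)
}

#' Traits belonging to a lipidome class
#' @param t a [trait_matrix].
#' @param class class label as in `t$meta$class`.
#' @return Character vector of trait names.
#' @export
class_traits <- function(t, class) t$meta$trait[t$meta$class == class]

#' Data-derived class covariance matrix S = XX' / m
#'
#' Builds the subject-by-subject sample covariance structure from a set of
#' traits (typically one lipidome class): each trait column is mean-centered
#' and scaled to unit variance (denominator n), missing values are set to the
#' column mean, and `S = X X' / m` where `m` is the number of traits. With
#' this scaling `trace(S) = n` for complete data, so the attached variance
#' component is on the same proportion-of-variance scale as heritability and
#' comparable across classes of different sizes.
#'
#' @param t a [trait_matrix] (raw or prepared values).
#' @param traits trait names to use (e.g. `class_traits(t, "TAG")`).
#' @return A [relatedness_matrix] of kind `"class_covariance"`.
#' @export
class_covariance <- function(t, traits) {
  stopifnot(inherits(t, "trait_matrix"))
  if (!length(traits)) stop("empty trait subset")
  missing <- setdiff(traits, colnames(t$values))
  if (length(missing)) stop("trait(s) not found: ",
                            paste(missing, collapse = ", "))
  X <- t$values[, traits, drop = FALSE]
  n <- nrow(X)
  X <- apply(X, 2, function(x) {
    mu <- mean(x, na.rm = TRUE)
    s2 <- mean((x - mu)^2, na.rm = TRUE)   # denominator n
    if (!is.finite(s2) || s2 <= 0) return(rep(NA_real_, length(x)))
    z <- (x - mu) / sqrt(s2)
    z[is.na(z)] <- 0
    z
  })
  bad <- colnames(X)[colSums(is.na(X)) > 0]
  if (length(bad)) stop("constant trait(s) in class: ",
                        paste(bad, collapse = ", "))
  S <- tcrossprod(X) / ncol(X)
  dimnames(S) <- list(rownames(t$values), rownames(t$values))
  relatedness_matrix(S, kind = "class_covariance")
}

#' Residualize a trait on covariates
#'
#' Least-squares residuals of one trait on a covariate design (always
#' including an intercept). Categorical covariates are expanded to indicator
#' columns against a reference level; aliased (exactly collinear) columns are
#' dropped with a warning. Subjects with a missing trait value or missing
#' covariates are dropped and recorded.
#'
#' @param t a [trait_matrix].
#' @param trait trait name.
#' @param covariates character vector of covariate terms drawn from
#'   `t$covariates`; `"age2"` expands to age squared. Alternatively a one-sided
#'   formula evaluated in the covariate table.
#' @return Named numeric vector of residuals over all subjects (`NA` for
#'   dropped subjects), with attributes `dropped` (ids) and `design_columns`.
#' @export
residualize_covariates <- function(t, trait, covariates = NULL) {
  stopifnot(inherits(t, "trait_matrix"))
  if (!trait %in% colnames(t$values)) stop("unknown trait: ", trait)
  y <- t$values[, trait]
  X <- covariate_design(t$covariates, covariates, n = length(y))
  ok <- !is.na(y) & stats::complete.cases(X)
  yk <- y[ok]
  if (sum(ok) <= ncol(X)) stop("too few complete observations for trait ",
                               trait)
  Xk <- X[ok, , drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    dropped_cols <- colnames(Xk)[qrX$pivot[(qrX$rank + 1):ncol(Xk)]]
    warning("dropping aliased design column(s): ",
            paste(dropped_cols, collapse = ", "))
    Xk <- Xk[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(Xk)
    if (qrX$rank < ncol(Xk)) {
      stop("design remains rank-deficient after dropping aliased columns: ",
           paste(colnames(Xk), collapse = ", "))
    }
  }
  r <- qr.resid(qrX, yk)
  if (mean(r^2) < 1e-12 * max(mean(yk^2), 1)) {
    stop("degenerate trait: zero residual variance for ", trait)
  }
  out <- rep(NA_real_, length(y))
  names(out) <- rownames(t$values)
  out[ok] <- r
  attr(out, "dropped") <- rownames(t$values)[!ok]
  attr(out, "design_columns") <- colnames(Xk)
  out
}

## Build a design matrix (with intercept) from the covariate table.
covariate_design <- function(cov, covariates, n) {
  if (is.null(covariates) || !length(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  if (is.null(cov)) stop("trait matrix has no covariates")
  if (inherits(covariates, "formula")) {
    return(stats::model.matrix(covariates, stats::model.frame(
      covariates, data = cov, na.action = stats::na.pass)))
  }
  terms <- covariates
  df <- list()
  for (tm in terms) {
    if (tm == "age2") {
      if (!"age" %in% names(cov)) stop("covariate 'age' not found")
      df[["age2"]] <- cov$age^2
    } else if (tm %in% names(cov)) {
      df[[tm]] <- cov[[tm]]
    } else {
      stop("covariate not found: ", tm)
    }
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  ## character columns become factors -> indicator expansion
  for (j in names(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  stats::model.matrix(~ ., data = df,
                      na.action = stats::na.pass)
}

#' Rank-based inverse normal transformation
#'
#' Blom-offset mapping `z = qnorm((r - c) / (n - 2c + 1))` with `c = 3/8` by
#' default, `r` the (average-for-ties) rank among non-missing values and `n`
#' their count. Equal inputs map to equal outputs; missing values propagate.
#'
#' @param x numeric vector (>= 3 non-missing, not all equal).
#' @param offset rank offset `c` (default Blom, 3/8).
#' @return Numeric vector of normal scores, same length/names as `x`.
#' @export
inverse_normal_transform <- function(x, offset = 3/8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("inverse normal transform requires >= 3 non-missing values")
  if (max(x[ok]) == min(x[ok])) stop("all values identical")
  r <- rank(x[ok], ties.method = "average")
  z <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  names(out) <- names(x)
  out
}

#' Prepare traits: residualize then inverse-normalize
#'
#' The study transformation applied to every trait: least-squares
#' residualization on covariates (age, age squared, sex and technical batch
#' factors for lipid species; the same minus technical factors for
#' traditional lipids) followed by rank-based inverse normal transformation.
#'
#' @param t a [trait_matrix].
#' @param covariates covariate terms for lipid species (see
#'   [residualize_covariates()]).
#' @param trad_covariates covariate terms for traits of class `"TRAD"`
#'   (default: `covariates` minus any term containing `"batch"`).
#' @param offset inverse-normal rank offset (default Blom).
#' @return A [trait_matrix] of prepared values (same shape; subjects dropped
#'   in residualization are `NA`).
#' @export
prepare_traits <- function(t, covariates = NULL, trad_covariates = NULL,
                           offset = 3/8) {
  stopifnot(inherits(t, "trait_matrix"))
  if (is.null(trad_covariates)) {
    trad_covariates <- covariates[!grepl("batch", covariates)]
  }
  out <- t$values
  for (j in seq_len(ncol(out))) {
    trait <- colnames(out)[j]
    cls <- t$meta$class[j]
    cv <- if (identical(cls, "TRAD")) trad_covariates else covariates
    r <- residualize_covariates(t, trait, cv)
    out[, j] <- inverse_normal_transform(r, offset = offset)
  }
  trait_matrix(out, meta = t$meta, covariates = t$covariates)
}

#' Read / write a phenotype table
#'
#' TSV with a subject id column followed by trait columns; covariate roles
#' and trait classes come from a sidecar YAML mapping (`traits:` name ->
#' class, `covariates:` column -> role).
#'
#' @param path phenotype TSV path.
#' @param sidecar path to the YAML sidecar; default `paste0(path, ".yaml")`
#'   if it exists.
#' @return A [trait_matrix].
#' @export
read_phenotypes <- function(path, sidecar = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (is.null(sidecar) && file.exists(paste0(path, ".yaml"))) {
    sidecar <- paste0(path, ".yaml")
  }
  meta <- NULL; cov <- NULL
  if (!is.null(sidecar)) {
    sc <- yaml::read_yaml(sidecar)
    tr <- names(sc$traits)
    meta <- data.frame(trait = tr,
                       class = unlist(sc$traits, use.names = FALSE),
                       stringsAsFactors = FALSE)
    cov_cols <- names(sc$covariates)
    cov <- df[, cov_cols, drop = FALSE]
    df <- df[, tr, drop = FALSE]
  }
  trait_matrix(as.matrix(df), meta = meta, covariates = cov, subjects = ids)
}

#' @rdname read_phenotypes
#' @param t a [trait_matrix] to write.
#' @export
write_phenotypes <- function(t, path) {
  df <- data.frame(id = rownames(t$values), t$values, check.names = FALSE)
  if (!is.null(t$covariates)) df <- cbind(df, t$covariates)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- list(traits = stats::setNames(as.list(t$meta$class), t$meta$trait),
             covariates = if (is.null(t$covariates)) list() else
               stats::setNames(as.list(rep("covariate",
                                           ncol(t$covariates))),
                               names(t$covariates)))
  yaml::write_yaml(sc, paste0(path, ".yaml"))
  invisible(path)
}
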