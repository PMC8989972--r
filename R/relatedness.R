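#' Relatedness (covariance-structure) matrix
#'
#' Container for the symmetric subject-by-subject covariance structures used
#' as random-effect covariance matrices: pedigree kinship, additive (2 *
#' kinship), dominance, SNP GRM, and data-derived lipidome-class covariance.
#'
#' @param x square numeric matrix with subject ids as dimnames (row names are
#'   used; column names are set to match).
#' @param kind one of `"kinship"`, `"additive"`, `"dominance"`, `"grm"`,
#'   `"class_covariance"`.
#' @param check validate symmetry and kind-specific invariants (default TRUE).
#' @return The matrix with class `relatedness_matrix` and attribute `kind`.
#' @export
relatedness_matrix <- function(x, kind = c("kinship", "additive", "dominance",
                                           "grm", "class_covariance"),
                               check = TRUE) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("relatedness matrix must be square")
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("S", seq_len(nrow(x)))
  }
  colnames(x) <- rownames(x)
  if (check) {
    if (max(abs(x - t(x))) > 1e-12 * max(1, max(abs(x)))) {
      stop("relatedness matrix is not symmetric")
    }
    x <- (x + t(x)) / 2
    if (kind == "kinship" && any(diag(x) < 0.5 - 1e-12)) {
      stop("kinship diagonal must be >= 0.5")
    }
    if (kind == "dominance" &&
        (min(x) < -1e-12 || max(x) > 1 + 1e-12)) {
      stop("dominance entries must lie in [0, 1]")
    }
  }
  structure(x, kind = kind, class = c("relatedness_matrix", "matrix", "array"))
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat(sprintf("relatedness_matrix [%s]: %d x %d subjects\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

## strip class/attr for plain matrix algebra
unclass_matrix <- function(x) {
  y <- as.matrix(x)
  attr(y, "kind") <- NULL
  class(y) <- c("matrix", "array")
  y
}

#' Kind of a relatedness matrix
#' @param x a [relatedness_matrix].
#' @return Character scalar.
#' @export
relatedness_kind <- function(x) attr(x, "kind")

#' Write / read a relatedness matrix
#'
#' TSV layout: first column `id`, remaining columns one per subject in order,
#' so the file round-trips ids and values. `format = "rds"` stores the object
#' as a binary RDS file instead.
#'
#' @param x a [relatedness_matrix].
#' @param path output path.
#' @param format `"tsv"` (default) or `"rds"`.
#' @return `path`, invisibly.
#' @export
save_relatedness <- function(x, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(x, path)
  } else {
    df <- data.frame(id = rownames(x), unclass_matrix(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_relatedness
#' @param kind kind to assign on reading a TSV (stored in the RDS already).
#' @export
read_relatedness <- function(path, kind = "kinship") {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) return(readRDS(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  relatedness_matrix(m, kind = kind)
}

## smallest-eigenvalue PSD check used by tests and simulators
psd_check <- function(x, rel_tol = 1e-8) {
  ev <- eigen(unclass_matrix(x), symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] >= -rel_tol * max(abs(ev[1]), 1e-300)
}

## symmetric square root with negative eigenvalues clamped to zero
matrix_sqrt <- function(x) {
  e <- eigen(unclass_matrix(x), symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}
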