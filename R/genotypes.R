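#' Genotype matrix container
#'
#' Dosages (alt-allele counts, possibly fractional) for subjects x variants,
#' with a variant table carrying 1-based positions.
#'
#' @param dosages numeric matrix, subjects in rows, variants in columns,
#'   values in \[0, 2\] or `NA`.
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `rsid` (one row per column of `dosages`).
#' @param subjects subject ids (default: rownames of `dosages`).
#' @return Object of class `genotype_matrix`: list with elements `dosages`
#'   (rownames = subjects, colnames = rsid) and `variants`.
#' @export
genotype_matrix <- function(dosages, variants, subjects = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(dosages)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "rsid")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosages)) {
    stop("variant table rows must match dosage columns")
  }
  key <- with(variants, paste(chrom, pos, ref, alt, sep = ":"))
  if (anyDuplicated(key)) {
    stop("duplicate variant record(s): ", paste(key[duplicated(key)][1]))
  }
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) {
      stop("dosages must lie in [0, 2]")
    }
  }
  rownames(dosages) <- as.character(subjects)
  colnames(dosages) <- as.character(variants$rsid)
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Number of subjects / variants
#' @param g a [genotype_matrix].
#' @export
n_variants <- function(g) ncol(g$dosages)

#' Read genotypes from a VCF file
#'
#' Uses the `DS` FORMAT field when present, otherwise counts alt alleles in
#' `GT`. Multi-allelic records must be split upstream and are rejected.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param field `"auto"` (DS if present, else GT), `"GT"` or `"DS"`.
#' @return A [genotype_matrix].
#' @export
read_vcf_genotypes <- function(path, field = c("auto", "GT", "DS")) {
  field <- match.arg(field)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic VCF records found; split them upstream (e.g. ",
         "'bcftools norm -m -any') before reading")
  }
  has_ds <- "DS" %in% rownames(vcfR::queryMETA(v, element = "FORMAT=ID",
                                               nice = FALSE)) ||
    any(grepl("\\bDS\\b", v@gt[, "FORMAT"]))
  use_ds <- field == "DS" || (field == "auto" && has_ds)
  if (use_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      a <- strsplit(col, "[/|]")
      vapply(a, function(z) {
        if (length(z) == 0 || any(z == ".") || anyNA(z)) NA_real_
        else sum(as.numeric(z) > 0)
      }, numeric(1))
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(v@gt))
  }
  rsid <- fix$ID
  rsid[is.na(rsid) | rsid == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(rsid) | rsid == "."]
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, rsid = rsid,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(ds), variants, subjects = colnames(v@gt)[-1])
}

#' Read a known/conditioning-variant list
#'
#' TSV with header columns `rsid`, `chrom`, `pos`, `ref`, `alt` and
#' optionally `trait` (the lipid the variant is known for). Used for
#' enriched-variant adjustment and literature-SNP GRMs.
#'
#' @param path TSV path.
#' @return Data frame with the columns above (`trait` filled with `NA` when
#'   absent).
#' @export
read_variant_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  names(df)[names(df) %in% c("rs_id", "rsid.")] <- "rsid"
  need <- c("rsid", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant list missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"trait" %in% names(df)) df$trait <- NA_character_
  df$pos <- as.integer(df$pos)
  df[, c(need, "trait")]
}

#' Per-variant quality control
#'
#' Filters on call rate, minor-allele frequency and Hardy-Weinberg
#' equilibrium. HWE is tested by a 1-df chi-square on genotype counts and is
#' only applicable to hard calls (all observed dosages in \{0, 1, 2\});
#' fractional-dosage variants get `NA` for the HWE p-value and are not
#' filtered on it. Applying the filter twice gives the same result as once.
#'
#' @param g a [genotype_matrix].
#' @param max_missing maximum missing-data fraction (default 0.02).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @param min_hwe_p minimum HWE p-value (default 1e-10).
#' @return List with `genotypes` (filtered [genotype_matrix]) and `report`
#'   (data frame: rsid, call_rate, maf, hwe_p, pass, reasons).
#' @export
variant_qc <- function(g, max_missing = 0.02, min_maf = 0.01,
                       min_hwe_p = 1e-10) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (ncol(d) == 0) stop("empty genotype matrix")
  n <- nrow(d)
  call_rate <- colMeans(!is.na(d))
  p_alt <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (!length(x) || any(abs(x - round(x)) > 1e-9)) return(NA_real_)
    x <- round(x)
    obs <- tabulate(x + 1L, nbins = 3L)
    p <- (obs[2] + 2 * obs[3]) / (2 * sum(obs))
    if (p <= 0 || p >= 1) return(1)
    exp_ <- sum(obs) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stats::pchisq(sum((obs - exp_)^2 / exp_), df = 1, lower.tail = FALSE)
  }, numeric(1))
  reasons <- vapply(seq_len(ncol(d)), function(j) {
    r <- character(0)
    if (1 - call_rate[j] > max_missing) r <- c(r, "missingness")
    if (is.na(maf[j]) || maf[j] < min_maf) r <- c(r, "MAF")
    if (!is.na(hwe_p[j]) && hwe_p[j] < min_hwe_p) r <- c(r, "HWE")
    paste(r, collapse = ",")
  }, character(1))
  pass <- reasons == ""
  report <- data.frame(rsid = g$variants$rsid, call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, pass = pass,
                       reasons = reasons, row.names = NULL,
                       stringsAsFactors = FALSE)
  if (!any(pass)) warning("all variants removed by QC")
  filtered <- genotype_matrix(d[, pass, drop = FALSE],
                              g$variants[pass, , drop = FALSE])
  list(genotypes = filtered, report = report)
}

#' SNP genetic relationship matrix (GRM)
#'
#' GCTA-style: each variant's dosages are standardized as
#' `w = (g - 2p) / sqrt(2 p (1 - p))` with `p` the sample alt-allele
#' frequency, missing dosages mean-imputed to `2p` beforehand, and
#' `G = W W' / m` over the `m` variants used.
#'
#' @param g a [genotype_matrix].
#' @param variant_subset rsids to use (default: all).
#' @return A [relatedness_matrix] of kind `"grm"`.
#' @export
snp_grm <- function(g, variant_subset = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (!is.null(variant_subset)) {
    missing <- setdiff(variant_subset, colnames(d))
    if (length(missing)) stop("variant(s) not in genotype matrix: ",
                              paste(missing, collapse = ", "))
    d <- d[, variant_subset, drop = FALSE]
  }
  if (ncol(d) == 0) stop("empty variant subset")
  p <- colMeans(d, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | !is.finite(p)
  if (any(mono)) {
    stop("monomorphic variant(s) in GRM subset: ",
         paste(colnames(d)[mono], collapse = ", "))
  }
  W <- sweep(d, 2, 2 * p)
  W[is.na(W)] <- 0                      # mean imputation after centering
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(W) / ncol(W)
  dimnames(G) <- list(rownames(d), rownames(d))
  relatedness_matrix(G, kind = "grm")
}
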