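## Deterministic child seeds: one stream per operation so that, e.g., adding
## variants to the genotype drop does not perturb the trait draws.
op_seed <- function(seed, op) {
  set.seed((as.integer(seed) %% 1000003L) * 2011L + op)
}

## most recent generations first (by id construction, later rows are later
## generations), preserving pedigree order within the selection
analyzed_subjects <- function(ped, analyzed) {
  if (identical(analyzed, "all") || is.null(analyzed)) return(ped$id)
  n <- nrow(ped)
  keep <- max(n - as.integer(analyzed) + 1L, 1L):n
  ped$id[keep]
}

#' Simulation configuration for the synthetic founder population
#'
#' Defaults emulate the study conditions at desk scale: a single founder
#' generation whose descendants form a closed multi-generation pedigree
#' (the real cohort's ~750 founders and 14 generations are scaled down to 80
#' founders and 6 generations), gene-dropped genotypes including rare founder
#' variants that can drift to high frequency, and lipid species organized in
#' classes with block-structured covariance plus composite traditional-lipid
#' traits assembled from additive, dominance and class variance fractions.
#'
#' @param seed integer seed; fully determines all outputs.
#' @param n_founders founder count (>= 2).
#' @param generations number of generations including the founders (>= 1).
#' @param mean_sibship mean number of offspring per couple (Poisson).
#' @param mating `"random"` (random pairing within a generation) or
#'   `"cousin"` (mate choice weighted toward relatives, producing inbreeding).
#' @param variants data frame `freq`, `n`: `n` biallelic variants with
#'   founder allele frequency `freq`, each dropped independently.
#' @param enriched data frame `copies`, `beta`, `trait`: rare founder
#'   variants seeded as exact allele-copy counts in founders (so the final
#'   frequency drifts across replicates), with a fixed effect `beta` (SD
#'   units) on the named trait (`NA` for no effect; `trait = ""` targets the
#'   first species).
#' @param blocks optional list of LD blocks, each
#'   `list(n_proxies=, flip_prob=, freq=)` or with `copies=` instead of
#'   `freq`: one causal variant plus `n_proxies` proxies whose founder
#'   haplotype alleles equal the causal allele flipped with probability
#'   `flip_prob`, co-transmitted without recombination.
#' @param classes data frame `class`, `n_species`, `h2`, `block_cor`,
#'   `rho_g`: lipid species per class with narrow-sense heritability `h2`,
#'   within-class environmental block correlation `block_cor` and
#'   within-class genetic correlation `rho_g`.
#' @param composite data frame `name`, `add`, `dom` plus one `frac_<class>`
#'   column per class: composite (traditional-lipid-like) traits generated
#'   from the realized class covariance structures; the residual absorbs
#'   `1 - add - dom - sum(frac)`.
#' @param geno_missing fraction of dosages set missing at random (default 0).
#' @param analyzed number of phenotyped subjects (default 650, the study's
#'   analyzed-cohort scale): traits are generated for the most recent
#'   generations only, while the full pedigree still connects them — as in a
#'   real founder cohort where only a fraction of the pedigree is profiled.
#'   `"all"` phenotypes everyone.
#' @param mode `"prepared"` (traits on the analysis scale) or `"raw"`
#'   (covariate-contaminated and exponentiated, to exercise phenotype
#'   preparation).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 80L,
                       generations = 6L,
                       mean_sibship = 3,
                       mating = c("random", "cousin"),
                       variants = data.frame(freq = c(0.05, 0.1, 0.2, 0.35,
                                                      0.5),
                                             n = rep(40L, 5)),
                       enriched = data.frame(copies = 2L, beta = 1.2,
                                             trait = "",
                                             stringsAsFactors = FALSE),
                       blocks = NULL,
                       classes = data.frame(
                         class = c("TAG", "DAG", "PC", "SM", "Cer"),
                         n_species = c(8L, 4L, 8L, 6L, 6L),
                         h2 = 0.4, block_cor = 0.5, rho_g = 0.5),
                       composite = local({
                         d <- data.frame(name = "TG", add = 0.15, dom = 0,
                                         frac_TAG = 0.34, frac_DAG = 0.05,
                                         frac_PC = 0.05,
                                         stringsAsFactors = FALSE)
                         d
                       }),
                       geno_missing = 0,
                       analyzed = 650L,
                       mode = c("prepared", "raw")) {
  mating <- match.arg(mating)
  mode <- match.arg(mode)
  stopifnot(n_founders >= 2, generations >= 1, mean_sibship > 0)
  as_df <- function(x) {
    if (!is.null(x) && !is.data.frame(x)) as.data.frame(x,
                                                        stringsAsFactors = FALSE)
    else x
  }
  variants <- as_df(variants)
  enriched <- as_df(enriched)
  classes <- as_df(classes)
  composite <- as_df(composite)
  if (!is.null(composite)) {
    fr <- composite[, grepl("^frac_", names(composite)), drop = FALSE]
    tot <- composite$add + composite$dom +
      if (ncol(fr)) rowSums(fr) else 0
    if (any(tot > 1 + 1e-9)) {
      stop("composite variance fractions must sum to <= 1")
    }
  }
  structure(list(seed = as.integer(seed), n_founders = as.integer(n_founders),
                 generations = as.integer(generations),
                 mean_sibship = mean_sibship, mating = mating,
                 variants = variants, enriched = enriched, blocks = blocks,
                 classes = classes, composite = composite,
                 geno_missing = geno_missing, analyzed = analyzed,
                 mode = mode),
            class = "sim_config")
}

#' Simulate a multi-generation founder pedigree
#'
#' Non-overlapping generations: generation 0 are founders with balanced
#' sexes; in each later generation males and females of the previous
#' generation are paired (at random, or with probability weighted by kinship
#' under the `"cousin"` rule, which elevates mate kinship and produces
#' inbreeding) and each couple has a Poisson number of offspring.
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree] with attribute `generation` (named integer vector).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  op_seed(cfg$seed, 1L)
  nf <- cfg$n_founders
  id <- sprintf("G0_%04d", seq_len(nf))
  sex <- sample(rep(c("male", "female"), length.out = nf))
  father <- rep(NA_character_, nf)
  mother <- rep(NA_character_, nf)
  generation <- rep(0L, nf)
  prev <- seq_len(nf)
  for (g in seq_len(cfg$generations - 1L)) {
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    nc <- min(length(males), length(females))
    if (nc == 0) {
      stop("infeasible configuration: no eligible mates in generation ", g)
    }
    males <- sample(males)[seq_len(nc)]
    if (cfg$mating == "random") {
      mates <- sample(females)[seq_len(nc)]
    } else {
      ped_now <- pedigree(id, father, mother, sex)
      phi <- ped_full_kinship(ped_now)
      mates <- integer(nc)
      avail <- females
      for (i in seq_len(nc)) {
        w <- 0.02 + phi[id[males[i]], id[avail]]
        pick <- if (length(avail) == 1) 1L else
          sample(seq_along(avail), 1, prob = w)
        mates[i] <- avail[pick]
        avail <- avail[-pick]
      }
    }
    kids_f <- character(0); kids_m <- character(0)
    for (i in seq_len(nc)) {
      nk <- stats::rpois(1, cfg$mean_sibship)
      if (nk > 0) {
        kids_f <- c(kids_f, rep(id[males[i]], nk))
        kids_m <- c(kids_m, rep(id[mates[i]], nk))
      }
    }
    nk_tot <- length(kids_f)
    if (nk_tot == 0) {
      stop("infeasible configuration: generation ", g, " has no offspring")
    }
    new_id <- sprintf("G%d_%04d", g, seq_len(nk_tot))
    new_sex <- sample(rep(c("male", "female"), length.out = nk_tot))
    prev <- length(id) + seq_len(nk_tot)
    id <- c(id, new_id)
    father <- c(father, kids_f)
    mother <- c(mother, kids_m)
    sex <- c(sex, new_sex)
    generation <- c(generation, rep(g, nk_tot))
  }
  ped <- pedigree(id, father, mother, sex)
  attr(ped, "generation") <- stats::setNames(generation, id)
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are drawn at the configured frequencies (or seeded as
#' exact copy counts for enriched variants) and transmitted by fair meioses.
#' Variants in an LD block share one meiosis indicator per transmission (no
#' recombination within the block), giving proxies in strong LD with the
#' block's causal variant.
#'
#' @param ped a [pedigree] (typically from [simulate_pedigree()]).
#' @param cfg a [sim_config()].
#' @return A [genotype_matrix] over all pedigree members. Enriched variants
#'   are named `enr1, enr2, ...`; block variants `blk<b>_causal` /
#'   `blk<b>_proxy<j>`.
#' @export
gene_drop_genotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  op_seed(cfg$seed, 2L)
  n <- nrow(ped)
  founder_rows <- which(is.na(ped$father))
  nf <- length(founder_rows)
  ## assemble variant layout: independent variants, enriched, LD blocks
  freq <- rep(cfg$variants$freq, cfg$variants$n)
  m_ind <- length(freq)
  enr <- cfg$enriched
  m_enr <- if (is.null(enr)) 0L else nrow(enr)
  blocks <- cfg$blocks
  blk_sizes <- if (is.null(blocks)) integer(0) else
    vapply(blocks, function(b) as.integer(b$n_proxies) + 1L, integer(1))
  m <- m_ind + m_enr + sum(blk_sizes)
  if (m == 0) stop("no variants configured")
  ## block id per variant: independent and enriched variants are their own
  ## block; LD-block members share one
  block_id <- c(seq_len(m_ind + m_enr),
                rep(m_ind + m_enr + seq_along(blk_sizes), blk_sizes))
  n_blocks <- m_ind + m_enr + length(blk_sizes)

  ## founder haplotypes: 2 * nf rows, m columns
  H <- matrix(0L, 2L * nf, m)
  if (m_ind > 0) {
    H[, seq_len(m_ind)] <-
      matrix(stats::rbinom(2L * nf * m_ind, 1L, rep(freq, each = 2L * nf)),
             2L * nf, m_ind)
  }
  if (m_enr > 0) {
    for (j in seq_len(m_enr)) {
      cp <- enr$copies[j]
      if (cp > 2L * nf) stop("enriched variant copies (", cp,
                             ") exceed founder allele count (", 2L * nf, ")")
      H[sample(2L * nf, cp), m_ind + j] <- 1L
    }
  }
  if (length(blk_sizes)) {
    col0 <- m_ind + m_enr
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      cols <- col0 + seq_len(blk_sizes[b])
      causal <- if (!is.null(bl$copies)) {
        z <- integer(2L * nf); z[sample(2L * nf, bl$copies)] <- 1L; z
      } else {
        stats::rbinom(2L * nf, 1L, bl$freq)
      }
      H[, cols[1]] <- causal
      for (jj in seq_len(bl$n_proxies)) {
        flip <- stats::rbinom(2L * nf, 1L, bl$flip_prob)
        H[, cols[1 + jj]] <- as.integer(xor(causal, flip))
      }
      col0 <- col0 + blk_sizes[b]
    }
  }

  pat <- matrix(0L, n, m)
  mat <- matrix(0L, n, m)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  hap_of <- integer(n)                  # founder row -> haplotype row offset
  hap_of[founder_rows] <- 2L * (seq_len(nf) - 1L)
  for (i in attr(ped, "topo_order")) {
    if (is.na(fi[i])) {
      pat[i, ] <- H[hap_of[i] + 1L, ]
      mat[i, ] <- H[hap_of[i] + 2L, ]
    } else {
      sel <- (stats::runif(n_blocks) < 0.5)[block_id]
      pat[i, ] <- ifelse(sel, pat[fi[i], ], mat[fi[i], ])
      sel <- (stats::runif(n_blocks) < 0.5)[block_id]
      mat[i, ] <- ifelse(sel, pat[mi[i], ], mat[mi[i], ])
    }
  }
  dos <- pat + mat
  rsid <- c(if (m_ind) sprintf("var%04d", seq_len(m_ind)),
            if (m_enr) sprintf("enr%d", seq_len(m_enr)),
            unlist(lapply(seq_along(blk_sizes), function(b) {
              c(sprintf("blk%d_causal", b),
                sprintf("blk%d_proxy%d", b, seq_len(blk_sizes[b] - 1L)))
            })))
  chrom <- c(rep("1", m_ind), rep("2", m_enr),
             rep(as.character(2L + seq_along(blk_sizes)), blk_sizes))
  pos <- c(if (m_ind) 100000L * seq_len(m_ind),
           if (m_enr) 100000L * seq_len(m_enr),
           unlist(lapply(blk_sizes, function(s) 1000000L + 2000L * seq_len(s))))
  variants <- data.frame(chrom = chrom, pos = as.integer(pos), ref = "A",
                         alt = "G", rsid = rsid, stringsAsFactors = FALSE)
  dosn <- dos * 1.0
  if (cfg$geno_missing > 0) {
    drop_idx <- which(stats::runif(length(dosn)) < cfg$geno_missing)
    dosn[drop_idx] <- NA_real_
  }
  rownames(dosn) <- ped$id
  genotype_matrix(dosn, variants)
}

#' Simulate a class-structured lipidome on a pedigree
#'
#' Realizes the variance-component model generatively: each trait is a sum of
#' independent component draws `sqrt(frac_k) * L_k z_k`, where `L_k` is a
#' symmetric square root of the component covariance (additive `2 * kinship`,
#' dominance, realized class covariance `S`, identity residual), plus fixed
#' enriched-variant effects in SD units. Lipid species are generated first,
#' with within-class genetic correlation `rho_g` and environmental block
#' correlation `block_cor`; composite traits then draw their class components
#' through the realized class covariance matrices of those species, so the
#' configured fractions are exactly the estimands of the variance
#' decomposition. Covariates (age, sex, batch) are always attached; in
#' `mode = "raw"` the traits are additionally covariate-contaminated with
#' known coefficients and exponentiated, for exercising phenotype
#' preparation.
#'
#' @param ped a [pedigree].
#' @param g a [genotype_matrix] from [gene_drop_genotypes()] (only needed
#'   when enriched-variant effects are configured; may be `NULL`).
#' @param cfg a [sim_config()].
#' @return A [trait_matrix] with attribute `truth` (list of generative
#'   parameters: class spec, composite fractions, enriched effects, covariate
#'   coefficients).
#' @export
simulate_lipidome <- function(ped, g, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  op_seed(cfg$seed, 3L)
  ids <- analyzed_subjects(ped, cfg$analyzed)
  n <- length(ids)
  A <- unclass_matrix(additive_matrix(ped, ids))
  LA <- matrix_sqrt(A) / sqrt(mean(diag(A)))
  need_dom <- !is.null(cfg$composite) && any(cfg$composite$dom > 0)
  LD <- if (need_dom) {
    Dm <- unclass_matrix(suppressWarnings(dominance_matrix(ped, ids)))
    matrix_sqrt(Dm) / sqrt(mean(diag(Dm)))
  } else NULL

  cls <- cfg$classes
  values <- NULL
  meta <- NULL
  if (!is.null(cls) && nrow(cls)) {
    for (ci in seq_len(nrow(cls))) {
      ns <- cls$n_species[ci]
      h2 <- cls$h2[ci]
      bc <- cls$block_cor[ci]
      rg <- cls$rho_g[ci]
      u_cls <- drop(LA %*% stats::rnorm(n))
      f_cls <- stats::rnorm(n)
      block <- matrix(0, n, ns)
      for (j in seq_len(ns)) {
        gen <- sqrt(rg) * u_cls + sqrt(1 - rg) * drop(LA %*% stats::rnorm(n))
        env <- sqrt(bc) * f_cls + sqrt(1 - bc) * stats::rnorm(n)
        block[, j] <- sqrt(h2) * gen + sqrt(1 - h2) * env
      }
      colnames(block) <- sprintf("%s_%02d", cls$class[ci], seq_len(ns))
      values <- cbind(values, block)
      meta <- rbind(meta, data.frame(trait = colnames(block),
                                     class = cls$class[ci],
                                     stringsAsFactors = FALSE))
    }
  }

  comp <- cfg$composite
  if (!is.null(comp) && nrow(comp)) {
    species_tm <- trait_matrix(values, meta, subjects = ids)
    frac_cols <- grep("^frac_", names(comp), value = TRUE)
    ## rectangular square root of S = XX'/m: the standardized class matrix
    ## X / sqrt(m) itself, so class draws cost O(n m), not an n x n eigen
    Ls <- list()
    for (fc in frac_cols) {
      cl <- sub("^frac_", "", fc)
      if (any(comp[[fc]] > 0)) {
        members <- class_traits(species_tm, cl)
        if (!length(members)) {
          stop("composite trait draws on class '", cl,
               "' but no species of that class are configured")
        }
        Xc <- values[, members, drop = FALSE]
        Xc <- apply(Xc, 2, function(x) {
          z <- x - mean(x); z / sqrt(mean(z^2))
        })
        Ls[[cl]] <- Xc / sqrt(ncol(Xc))
      }
    }
    cblock <- matrix(0, n, nrow(comp))
    for (ti in seq_len(nrow(comp))) {
      y <- sqrt(comp$add[ti]) * drop(LA %*% stats::rnorm(n))
      if (comp$dom[ti] > 0) y <- y + sqrt(comp$dom[ti]) *
          drop(LD %*% stats::rnorm(n))
      tot <- comp$add[ti] + comp$dom[ti]
      for (fc in frac_cols) {
        f <- comp[[fc]][ti]
        if (f > 0) {
          L <- Ls[[sub("^frac_", "", fc)]]
          y <- y + sqrt(f) * drop(L %*% stats::rnorm(ncol(L)))
          tot <- tot + f
        }
      }
      y <- y + sqrt(max(1 - tot, 0)) * stats::rnorm(n)
      cblock[, ti] <- y
    }
    colnames(cblock) <- comp$name
    values <- cbind(values, cblock)
    meta <- rbind(meta, data.frame(trait = comp$name, class = "TRAD",
                                   stringsAsFactors = FALSE))
  }
  if (is.null(values)) stop("no traits configured")

  ## enriched-variant fixed effects, SD units per alt-allele copy
  enr <- cfg$enriched
  if (!is.null(enr) && nrow(enr) && !is.null(g)) {
    for (j in seq_len(nrow(enr))) {
      b <- enr$beta[j]
      if (is.na(b) || b == 0) next
      target <- enr$trait[j]
      if (is.na(target) || target == "") target <- colnames(values)[1]
      if (!target %in% colnames(values)) {
        stop("enriched-effect target trait not simulated: ", target)
      }
      dv <- g$dosages[ids, sprintf("enr%d", j)]
      dv[is.na(dv)] <- mean(dv, na.rm = TRUE)
      values[, target] <- values[, target] + b * dv
    }
  }

  op_seed(cfg$seed, 4L)
  age <- round(stats::runif(n, 20, 80))
  batch <- sample(sprintf("b%d", 1:4), n, replace = TRUE)
  sex <- ped$sex[match(ids, ped$id)]
  covariates <- data.frame(age = age, sex = sex, batch = batch,
                           stringsAsFactors = FALSE)
  cov_coefs <- list(age = 0.01, age2 = 2e-4, sex_male = 0.25,
                    batch = stats::setNames(c(0, 0.2, -0.15, 0.1),
                                            sprintf("b%d", 1:4)))
  if (cfg$mode == "raw") {
    shift <- cov_coefs$age * (age - 50) + cov_coefs$age2 * (age - 50)^2 +
      cov_coefs$sex_male * (sex == "male") + cov_coefs$batch[batch]
    values <- exp(0.5 * (values + shift))
  }
  out <- trait_matrix(values, meta, covariates = covariates, subjects = ids)
  attr(out, "truth") <- list(classes = cls, composite = comp, enriched = enr,
                             covariate_coefs = if (cfg$mode == "raw")
                               cov_coefs else NULL)
  out
}

#' Write a pedigree as a PED-style TSV
#'
#' Columns `id father mother sex` with `0` for missing parents and `1`/`2`
#' for male/female (`0` unknown).
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sx <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  df <- data.frame(id = ped$id,
                   father = ifelse(is.na(ped$father), "0", ped$father),
                   mother = ifelse(is.na(ped$mother), "0", ped$mother),
                   sex = sx)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write hard-call genotypes as a minimal VCF
#'
#' Dosages must be hard calls (0/1/2 or missing); written as unphased GT.
#'
#' @param g a [genotype_matrix].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(g, path) {
  d <- g$dosages
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE)) {
    stop("VCF writer requires hard calls")
  }
  gt <- matrix(c("0/0", "0/1", "1/1")[round(t(d)) + 1L],
               nrow = ncol(d))       # variants x subjects
  gt[is.na(gt)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")),
             con)
  v <- g$variants
  body <- paste(v$chrom, v$pos, v$rsid, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write the generative truth parameters of a simulated lipidome
#'
#' @param t a [trait_matrix] from [simulate_lipidome()].
#' @param path YAML output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(t, path) {
  tr <- attr(t, "truth")
  if (is.null(tr)) stop("trait matrix carries no truth attribute")
  to_plain <- function(x) if (is.data.frame(x)) as.list(x) else x
  yaml::write_yaml(lapply(tr, to_plain), path)
  invisible(path)
}
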