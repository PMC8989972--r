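#' Pipeline run configuration
#'
#' Builds (or reads from YAML) the configuration driving [run_pipeline()].
#' Thresholds default to the study settings: QC missingness 0.02, HWE 1e-10,
#' MAF 0.01, selection alpha 0.05, PC variance fraction 0.95, base
#' genome-wide level 5e-8, nominal enriched-variant adjustment level 1e-3,
#' baseline-heritability screening p < 0.01 for class decomposition.
#'
#' @param pedigree,vcf,phenotypes input paths (ignored when `simulate` is a
#'   [sim_config()], in which case inputs are generated into `outdir`).
#' @param outdir output directory (created if needed).
#' @param simulate optional [sim_config()] to generate the inputs.
#' @param covariates covariate terms for trait preparation (see
#'   [prepare_traits()]).
#' @param adjust_variants rsids of known enriched variants: traits nominally
#'   associated (p < `adjust_p`) with any of them are refit with those
#'   variants as fixed covariates.
#' @param stages character vector of stages to run, a subset of the default
#'   order.
#' @param seed integer seed for any stage-level randomness.
#' @param qc_max_missing,qc_min_maf,qc_min_hwe_p,alpha,variance_fraction,base_level,adjust_p,h2_screen_p
#'   thresholds as described above.
#' @param gwas_traits,decompose_traits,corr_traits optional trait subsets for
#'   the heavier stages (defaults: all traits for GWAS; class `TRAD` traits
#'   for decomposition; all traits for correlations).
#' @return List of class `run_config`.
#' @export
run_config <- function(pedigree = NULL, vcf = NULL, phenotypes = NULL,
                       outdir = "lipidvc_run", simulate = NULL,
                       covariates = c("age", "age2", "sex", "batch"),
                       adjust_variants = character(0),
                       stages = c("simulate", "prepare", "relatedness", "h2",
                                  "decompose", "corr", "gwas", "conditional",
                                  "thresholds"),
                       seed = 1L,
                       qc_max_missing = 0.02, qc_min_maf = 0.01,
                       qc_min_hwe_p = 1e-10, alpha = 0.05,
                       variance_fraction = 0.95, base_level = 5e-8,
                       adjust_p = 1e-3, h2_screen_p = 0.01,
                       gwas_traits = NULL, decompose_traits = NULL,
                       corr_traits = NULL) {
  cfg <- list(pedigree = pedigree, vcf = vcf, phenotypes = phenotypes,
              outdir = outdir, simulate = simulate, covariates = covariates,
              adjust_variants = adjust_variants, stages = stages,
              seed = as.integer(seed),
              qc_max_missing = qc_max_missing, qc_min_maf = qc_min_maf,
              qc_min_hwe_p = qc_min_hwe_p, alpha = alpha,
              variance_fraction = variance_fraction,
              base_level = base_level, adjust_p = adjust_p,
              h2_screen_p = h2_screen_p, gwas_traits = gwas_traits,
              decompose_traits = decompose_traits, corr_traits = corr_traits)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file with `run_config` fields; a `simulate:` block is
#'   passed to [sim_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

file_md5 <- function(paths) unname(tools::md5sum(paths))

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate (optional input
#' generation), prepare (residualize + inverse normalize), relatedness
#' (kinship, additive, dominance matrices), h2 (per-trait heritability with
#' LRT p-values and the nominal enriched-variant adjustment rule), decompose
#' (sequential lipidome-class selection for screened traits), corr
#' (genetic/phenotypic correlations), gwas (two-stage mixed-model scan),
#' conditional (sequential conditional analysis of significant loci) and
#' thresholds (PC-based multiple-testing correction). Every stage writes its
#' outputs, and the run manifest records status, output paths and MD5
#' checksums. Re-running with unchanged inputs and configuration skips
#' completed stages.
#'
#' @param cfg a [run_config()] (or path to its YAML form).
#' @param resume reuse completed stages when inputs are unchanged (default
#'   TRUE).
#' @param quiet suppress progress messages.
#' @return The manifest (list), invisibly written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_pipeline <- function(cfg, resume = TRUE, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list(stages = list())
  say <- function(...) if (!quiet) message(...)
  out <- function(...) file.path(cfg$outdir, ...)

  stage_done <- function(name, inputs) {
    st <- manifest$stages[[name]]
    if (is.null(st) || !identical(st$status, "ok")) return(FALSE)
    if (!all(file.exists(unlist(st$outputs)))) return(FALSE)
    if (!identical(unname(unlist(st$input_md5)),
                   unname(file_md5(inputs)))) return(FALSE)
    TRUE
  }
  record <- function(name, inputs, outputs) {
    manifest$stages[[name]] <<- list(
      status = "ok", inputs = inputs, input_md5 = file_md5(inputs),
      outputs = outputs, output_md5 = file_md5(outputs),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  enabled <- function(s) s %in% cfg$stages

  ## ---- simulate -----------------------------------------------------------
  ped_path <- cfg$pedigree; vcf_path <- cfg$vcf; phe_path <- cfg$phenotypes
  if (enabled("simulate") && !is.null(cfg$simulate)) {
    ped_path <- out("pedigree.ped"); vcf_path <- out("genotypes.vcf")
    phe_path <- out("phenotypes.tsv")
    outputs <- c(ped_path, vcf_path, phe_path, out("truth.yaml"))
    if (!(resume && stage_done("simulate", character(0)))) {
      say("stage simulate")
      ped <- simulate_pedigree(cfg$simulate)
      g <- gene_drop_genotypes(ped, cfg$simulate)
      tm <- simulate_lipidome(ped, g, cfg$simulate)
      write_pedigree(ped, ped_path)
      write_vcf_genotypes(g, vcf_path)
      write_phenotypes(tm, phe_path)
      write_truth(tm, out("truth.yaml"))
      record("simulate", character(0), outputs)
    } else say("stage simulate: cached")
  }
  if (is.null(ped_path) || is.null(phe_path)) {
    stop("pedigree and phenotype inputs are required (paths or a simulate config)")
  }
  ped <- parse_pedigree(ped_path)
  raw <- read_phenotypes(phe_path)
  geno <- NULL
  if (!is.null(vcf_path)) {
    geno <- read_vcf_genotypes(vcf_path)
    qc <- variant_qc(geno, cfg$qc_max_missing, cfg$qc_min_maf,
                     cfg$qc_min_hwe_p)
    geno <- qc$genotypes
    utils::write.table(qc$report, out("variant_qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    geno$dosages <- geno$dosages[rownames(raw$values), , drop = FALSE]
  }

  ## ---- prepare ------------------------------------------------------------
  prep_path <- out("prepared.tsv")
  if (enabled("prepare")) {
    if (!(resume && stage_done("prepare", phe_path))) {
      say("stage prepare")
      cv <- if (is.null(raw$covariates)) NULL else
        intersect(cfg$covariates,
                  c(names(raw$covariates), "age2"))
      prep <- prepare_traits(raw, covariates = cv)
      write_phenotypes(prep, prep_path)
      record("prepare", phe_path, c(prep_path, paste0(prep_path, ".yaml")))
    } else say("stage prepare: cached")
  }
  prep <- read_phenotypes(prep_path)
  subjects <- rownames(prep$values)

  ## ---- relatedness --------------------------------------------------------
  kin_path <- out("kinship.tsv"); add_path <- out("additive.tsv")
  dom_path <- out("dominance.tsv")
  if (enabled("relatedness")) {
    if (!(resume && stage_done("relatedness", ped_path))) {
      say("stage relatedness")
      save_relatedness(kinship_matrix(ped, subjects), kin_path)
      save_relatedness(additive_matrix(ped, subjects), add_path)
      save_relatedness(suppressWarnings(dominance_matrix(ped, subjects)),
                       dom_path)
      record("relatedness", ped_path, c(kin_path, add_path, dom_path))
    } else say("stage relatedness: cached")
  }
  A <- read_relatedness(add_path, kind = "additive")

  ## adjustment rule: traits nominally associated with any enriched variant
  adjust_sets <- adjustment_sets(prep, geno, A, cfg)

  ## ---- h2 -----------------------------------------------------------------
  h2_path <- out("heritability.tsv")
  if (enabled("h2")) {
    if (!(resume && stage_done("h2", c(prep_path, add_path)))) {
      say("stage h2")
      h2tab <- heritability_table(prep, A, geno, adjust_sets)
      utils::write.table(h2tab, h2_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("h2", c(prep_path, add_path), h2_path)
    } else say("stage h2: cached")
  }

  ## ---- decompose ----------------------------------------------------------
  if (enabled("decompose")) {
    dec_path <- out("class_decomposition.tsv")
    if (!(resume && stage_done("decompose", c(prep_path, add_path)))) {
      say("stage decompose")
      h2tab <- utils::read.table(h2_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      targets <- cfg$decompose_traits
      if (is.null(targets)) targets <- class_traits(prep, "TRAD")
      screened <- h2tab$trait[h2tab$h2_p < cfg$h2_screen_p]
      targets <- intersect(targets, screened)
      classes <- setdiff(unique(prep$meta$class), c("TRAD", "unknown"))
      cand <- lapply(classes, function(cl)
        class_covariance(prep, class_traits(prep, cl)))
      names(cand) <- classes
      rows <- list()
      audit <- list()
      for (tr in targets) {
        y <- prep$values[, tr]
        ok <- !is.na(y)
        sel <- sequential_component_selection(
          y[ok], base = list(additive = unclass_matrix(A)[ok, ok]),
          candidates = lapply(cand, function(M)
            unclass_matrix(M)[ok, ok]),
          alpha = cfg$alpha)
        lam <- sel$final_fit$lambda
        rows[[tr]] <- data.frame(trait = tr, component = names(lam),
                                 lambda = unname(lam),
                                 stringsAsFactors = FALSE)
        audit[[tr]] <- sel$trace
      }
      dec <- if (length(rows)) do.call(rbind, rows) else
        data.frame(trait = character(0), component = character(0),
                   lambda = numeric(0))
      utils::write.table(dec, dec_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(audit, out("class_decomposition_audit.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      record("decompose", c(prep_path, add_path),
             c(dec_path, out("class_decomposition_audit.json")))
    } else say("stage decompose: cached")
  }

  ## ---- corr ---------------------------------------------------------------
  if (enabled("corr")) {
    corr_path <- out("correlations.tsv")
    if (!(resume && stage_done("corr", c(prep_path, kin_path)))) {
      say("stage corr")
      kin <- read_relatedness(kin_path, kind = "kinship")
      tsub <- cfg$corr_traits
      tm <- prep
      if (!is.null(tsub)) {
        tm <- trait_matrix(prep$values[, tsub, drop = FALSE],
                           prep$meta[prep$meta$trait %in% tsub, ],
                           covariates = prep$covariates)
      }
      cm <- correlation_matrices(tm, kin)
      utils::write.table(cm$table, corr_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      save_relatedness(relatedness_matrix(cm$phenotypic,
                                          kind = "class_covariance",
                                          check = FALSE),
                       out("phenotypic_correlation.tsv"))
      record("corr", c(prep_path, kin_path),
             c(corr_path, out("phenotypic_correlation.tsv")))
    } else say("stage corr: cached")
  }

  ## ---- thresholds ---------------------------------------------------------
  thr <- NULL
  if (enabled("thresholds")) {
    thr_path <- out("thresholds.json")
    say("stage thresholds")
    thr <- multiple_testing_threshold(prep, cfg$variance_fraction,
                                      cfg$base_level)
    jsonlite::write_json(unclass(thr), thr_path, auto_unbox = TRUE,
                         digits = NA)
    record("thresholds", prep_path, thr_path)
  }

  ## ---- gwas ---------------------------------------------------------------
  gwas_path <- out("gwas.tsv")
  if (enabled("gwas") && !is.null(geno)) {
    if (!(resume && stage_done("gwas", c(prep_path, add_path)))) {
      say("stage gwas")
      traits <- cfg$gwas_traits
      if (is.null(traits)) traits <- colnames(prep$values)
      recs <- list()
      for (tr in traits) {
        y <- prep$values[, tr]
        ok <- !is.na(y)
        gsub_ <- geno
        gsub_$dosages <- geno$dosages[ok, , drop = FALSE]
        recs[[tr]] <- association_scan(
          y[ok], gsub_, relatedness_matrix(unclass_matrix(A)[ok, ok],
                                           kind = "additive", check = FALSE),
          conditioning = adjust_sets[[tr]] %||% character(0), trait = tr)
      }
      gw <- do.call(rbind, recs)
      write_gwas(gw, gwas_path)
      record("gwas", c(prep_path, add_path), gwas_path)
    } else say("stage gwas: cached")
  }

  ## ---- conditional --------------------------------------------------------
  if (enabled("conditional") && !is.null(geno) && file.exists(gwas_path)) {
    cond_path <- out("conditional_signals.tsv")
    say("stage conditional")
    gw <- utils::read.table(gwas_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    sig_level <- if (!is.null(thr)) thr$significance_threshold else
      cfg$base_level
    hits <- gw[!is.na(gw$p) & gw$p < sig_level, , drop = FALSE]
    rows <- list()
    if (nrow(hits)) {
      hits <- hits[order(hits$p), ]
      seen <- character(0)
      for (i in seq_len(nrow(hits))) {
        key <- paste(hits$trait[i], hits$chrom[i],
                     round(hits$pos[i] / 2e6))
        if (key %in% seen) next
        seen <- c(seen, key)
        region <- sprintf("%s:%d-%d", hits$chrom[i],
                          max(1, hits$pos[i] - 1e6), hits$pos[i] + 1e6 + 1)
        y <- prep$values[, hits$trait[i]]
        ok <- !is.na(y)
        gsub_ <- geno
        gsub_$dosages <- geno$dosages[ok, , drop = FALSE]
        cs <- conditional_scan(
          y[ok], gsub_,
          relatedness_matrix(unclass_matrix(A)[ok, ok], kind = "additive",
                             check = FALSE),
          region = region, alpha = sig_level, trait = hits$trait[i])
        rows[[key]] <- data.frame(
          trait = hits$trait[i], region = region,
          n_signals = length(cs$signals),
          signals = paste(cs$signals, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
    cond <- if (length(rows)) do.call(rbind, rows) else
      data.frame(trait = character(0), region = character(0),
                 n_signals = integer(0), signals = character(0))
    utils::write.table(cond, cond_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("conditional", c(prep_path, gwas_path), cond_path)
  }

  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Traits nominally associated (p < adjust_p) with any adjustment variant are
## refit with those variants as fixed covariates downstream.
adjustment_sets <- function(prep, geno, A, cfg) {
  sets <- list()
  if (is.null(geno) || !length(cfg$adjust_variants)) return(sets)
  av <- intersect(cfg$adjust_variants, colnames(geno$dosages))
  if (!length(av)) return(sets)
  for (tr in colnames(prep$values)) {
    y <- prep$values[, tr]
    ok <- !is.na(y)
    gsub_ <- geno
    gsub_$dosages <- geno$dosages[ok, av, drop = FALSE]
    gsub_$variants <- geno$variants[match(av, geno$variants$rsid), ,
                                    drop = FALSE]
    sc <- association_scan(y[ok], gsub_,
                           relatedness_matrix(unclass_matrix(A)[ok, ok],
                                              kind = "additive",
                                              check = FALSE),
                           trait = tr)
    hit <- !is.na(sc$p) & sc$p < cfg$adjust_p
    if (any(hit)) sets[[tr]] <- sc$rsid[hit]
  }
  sets
}

## Per-trait heritability with LRT against the pure-residual null, applying
## the enriched-variant adjustment as fixed effects where triggered.
heritability_table <- function(prep, A, geno, adjust_sets) {
  rows <- list()
  for (tr in colnames(prep$values)) {
    y <- prep$values[, tr]
    ok <- !is.na(y)
    X <- NULL
    adj <- adjust_sets[[tr]]
    if (!is.null(adj)) {
      X <- geno$dosages[ok, adj, drop = FALSE]
      X <- apply(X, 2, function(x) {
        x[is.na(x)] <- mean(x, na.rm = TRUE); x
      })
    }
    fit1 <- tryCatch(
      fit_variance_components(y[ok],
                              list(additive = unclass_matrix(A)[ok, ok]),
                              X = X),
      error = function(e) e)
    if (inherits(fit1, "error")) {
      rows[[tr]] <- data.frame(trait = tr, h2 = NA_real_, h2_p = NA_real_,
                               n = sum(ok), adjusted = !is.null(adj),
                               note = conditionMessage(fit1),
                               stringsAsFactors = FALSE)
      next
    }
    fit0 <- fit_variance_components(y[ok], list(), X = X)
    lrt <- lrt_compare(fit0, fit1)
    rows[[tr]] <- data.frame(trait = tr, h2 = fit1$h2, h2_p = lrt$p_value,
                             n = sum(ok), adjusted = !is.null(adj),
                             note = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
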