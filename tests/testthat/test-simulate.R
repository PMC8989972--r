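test_that("pedigree simulation respects generations and parentage structure", {
  cfg1 <- sim_config(seed = 1, n_founders = 12, generations = 1,
                     classes = NULL, composite = NULL, enriched = NULL)
  ped1 <- simulate_pedigree(cfg1)
  expect_equal(length(founders(ped1)), 12)   # one generation: all founders

  cfg <- sim_config(seed = 2, n_founders = 24, generations = 4,
                    classes = NULL, composite = NULL, enriched = NULL)
  ped <- simulate_pedigree(cfg)
  gen <- attr(ped, "generation")
  for (i in which(!is.na(ped$father))) {
    expect_equal(unname(gen[ped$father[i]]), unname(gen[ped$id[i]]) - 1L)
    expect_equal(unname(gen[ped$mother[i]]), unname(gen[ped$id[i]]) - 1L)
  }
  expect_error(simulate_pedigree(sim_config(seed = 1, n_founders = 2,
                                            generations = 8,
                                            mean_sibship = 0.05,
                                            classes = NULL,
                                            composite = NULL,
                                            enriched = NULL)),
               "infeasible|no eligible")
})

test_that("cousin-biased mating elevates mate kinship relative to random mating", {
  mean_mate_kinship <- function(mating, seed) {
    cfg <- sim_config(seed = seed, n_founders = 24, generations = 4,
                      mating = mating, classes = NULL, composite = NULL,
                      enriched = NULL)
    ped <- simulate_pedigree(cfg)
    phi <- unclass(suppressWarnings(kinship_matrix(ped)))
    couples <- unique(stats::na.omit(cbind(ped$father, ped$mother)))
    mean(phi[couples])
  }
  rnd <- vapply(1:12, function(s) mean_mate_kinship("random", s), numeric(1))
  csn <- vapply(1:12, function(s) mean_mate_kinship("cousin", s), numeric(1))
  expect_gt(mean(csn), mean(rnd))
})

test_that("gene dropping is Mendelian-consistent and seed-deterministic", {
  cfg <- sim_config(seed = 3, n_founders = 30, generations = 4,
                    variants = data.frame(freq = c(0, 0.3), n = c(5, 30)),
                    enriched = data.frame(copies = 3, beta = NA,
                                          trait = ""),
                    classes = NULL, composite = NULL, analyzed = "all")
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  d <- g$dosages
  ## founder frequency 0: all dosages zero
  expect_true(all(d[, 1:5] == 0))
  ## Mendelian consistency at every variant for every child
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  for (i in which(!is.na(fi))) {
    lower <- (d[fi[i], ] == 2) + (d[mi[i], ] == 2)
    upper <- 2 - ((d[fi[i], ] == 0) + (d[mi[i], ] == 0))
    expect_true(all(d[i, ] >= lower & d[i, ] <= upper))
  }
  ## determinism: same seed reproduces byte-identical dosages
  g2 <- gene_drop_genotypes(ped, cfg)
  expect_identical(g$dosages, g2$dosages)
  cfg3 <- cfg; cfg3$seed <- 4L
  g3 <- gene_drop_genotypes(ped, cfg3)
  expect_false(identical(g$dosages, g3$dosages))
  ## copies beyond the founder allele pool are rejected
  cfg4 <- cfg; cfg4$enriched <- data.frame(copies = 100, beta = NA,
                                           trait = "")
  expect_error(gene_drop_genotypes(ped, cfg4), "exceed")
})

test_that("founder-frequency drift is unbiased and rare variants can drift upward", {
  cfg <- sim_config(seed = 5, n_founders = 20, generations = 5,
                    mean_sibship = 2.5,
                    variants = data.frame(freq = 0.5, n = 1),
                    enriched = data.frame(copies = 1, beta = NA, trait = ""),
                    classes = NULL, composite = NULL, analyzed = "all")
  ped <- simulate_pedigree(cfg)
  gen <- attr(ped, "generation")
  last <- ped$id[gen == max(gen)]
  freqs <- matrix(NA_real_, 120, 2)
  for (r in seq_len(nrow(freqs))) {
    cfgr <- cfg; cfgr$seed <- 1000L + r
    g <- gene_drop_genotypes(ped, cfgr)
    freqs[r, 1] <- mean(g$dosages[last, 1]) / 2
    freqs[r, 2] <- mean(g$dosages[last, "enr1"]) / 2
  }
  ## martingale property: mean final frequency near the founder frequency
  expect_lt(abs(mean(freqs[, 1]) - 0.5), 3 * sd(freqs[, 1]) / sqrt(120))
  ## a single founder copy (freq 1/40) drifts: nonzero spread, and some
  ## replicate reaches several times the founder frequency
  expect_gt(sd(freqs[, 2]), 0)
  expect_gte(max(freqs[, 2]), 4 * (1 / 40))
})

test_that("simulated traits realize the configured variance structure", {
  cfg <- sim_config(seed = 6, n_founders = 40, generations = 4,
                    classes = data.frame(class = "SM", n_species = 2,
                                         h2 = 0.4, block_cor = 0.3,
                                         rho_g = 0.3),
                    composite = data.frame(name = "TG", add = 0.3, dom = 0,
                                           frac_SM = 0.2),
                    enriched = NULL, analyzed = "all")
  ped <- simulate_pedigree(cfg)
  vv <- replicate(60, {
    cfgr <- cfg; cfgr$seed <- sample.int(1e6, 1)
    tm <- simulate_lipidome(ped, NULL, cfgr)
    apply(tm$values, 2, var)
  })
  ## population variance close to 1 for every trait
  expect_true(all(abs(rowMeans(vv) - 1) < 0.05))

  ## same seed: byte-identical outputs
  t1 <- simulate_lipidome(ped, NULL, cfg)
  t2 <- simulate_lipidome(ped, NULL, cfg)
  expect_identical(t1$values, t2$values)
})

test_that("null heritability data yield near-zero estimates through the full loop", {
  cfg <- sim_config(seed = 7, n_founders = 40, generations = 4,
                    classes = data.frame(class = "SM", n_species = 1,
                                         h2 = 0, block_cor = 0, rho_g = 0),
                    composite = NULL, enriched = NULL, analyzed = "all")
  ped <- simulate_pedigree(cfg)
  A <- unclass(additive_matrix(ped))[, ]
  h2s <- vapply(1:25, function(r) {
    cfgr <- cfg; cfgr$seed <- 100L + r
    tm <- simulate_lipidome(ped, NULL, cfgr)
    fit_variance_components(tm$values[, 1], list(additive = A))$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s)), 0.06)
})

test_that("simulation writers produce readable pedigree, VCF and truth files", {
  cfg <- sim_config(seed = 8, n_founders = 16, generations = 3,
                    variants = data.frame(freq = 0.3, n = 10),
                    enriched = NULL,
                    classes = data.frame(class = "SM", n_species = 2,
                                         h2 = 0.3, block_cor = 0.3,
                                         rho_g = 0.3),
                    composite = NULL, analyzed = "all")
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  tm <- simulate_lipidome(ped, g, cfg)
  pf <- withr::local_tempfile(fileext = ".ped")
  write_pedigree(ped, pf)
  ped2 <- parse_pedigree(pf)
  expect_equal(ped2$id, ped$id)
  expect_equal(ped2$father, ped$father)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(tm, tf)
  tm2 <- read_phenotypes(tf)
  expect_equal(tm2$values, tm$values, tolerance = 1e-9)
  expect_equal(tm2$meta$class, tm$meta$class)
  yf <- withr::local_tempfile(fileext = ".yaml")
  write_truth(tm, yf)
  expect_true(file.exists(yf))
  expect_equal(yaml::read_yaml(yf)$classes$h2, 0.3)
})
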