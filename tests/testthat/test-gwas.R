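test_that("region strings parse as half-open intervals", {
  r <- parse_region("2:100-200")
  expect_equal(r$chrom, "2")
  expect_equal(r$start, 100)
  expect_equal(r$end, 199)
  expect_error(parse_region("chr2"), "malformed")
  expect_error(parse_region("2:200-100"), "empty region")
})

test_that("the mixed-model scan reduces exactly to OLS when subjects are unrelated", {
  set.seed(7)
  n <- 120
  G <- matrix(rbinom(n * 15, 2, 0.3), n, 15)
  g <- toy_genotypes(G)
  y <- rnorm(n) + 0.8 * G[, 5]
  X <- cbind(age = rnorm(n))
  K <- relatedness_matrix(diag(0.5, n), kind = "kinship", check = FALSE)
  sc <- association_scan(y, g, K, X = X)
  for (j in c(1, 5, 9)) {
    co <- summary(lm(y ~ X + G[, j]))$coefficients[3, ]
    expect_equal(sc$beta[j], unname(co[1]), tolerance = 1e-8)
    expect_equal(sc$se[j], unname(co[2]), tolerance = 1e-8)
    expect_equal(sc$p[j], unname(co[4]), tolerance = 1e-8)
  }
  expect_equal(which.min(sc$p), 5L)       # injected effect is the top hit
})

test_that("allele flips, permutations, and skip rules behave correctly", {
  set.seed(8)
  n <- 100
  A <- kronecker(diag(25), matrix(0.5, 4, 4) + diag(0.5, 4))
  K <- relatedness_matrix(A, kind = "additive", check = FALSE)
  G <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
  G[, 2] <- 0                             # monomorphic
  G[, 3] <- G[, 1]                        # duplicate of conditioning variant
  g <- toy_genotypes(G)
  L <- t(chol(A))
  y <- sqrt(0.4) * drop(L %*% rnorm(n)) + sqrt(0.6) * rnorm(n) + 0.5 * G[, 6]

  sc <- association_scan(y, g, K, conditioning = "v001")
  expect_true(sc$skipped[2] && sc$skip_reason[2] == "monomorphic")
  expect_true(sc$skipped[3] && sc$skip_reason[3] == "collinear")
  expect_true(sc$skipped[1])              # the conditioning variant itself

  ## flipping ref/alt coding flips beta and leaves p unchanged
  G2 <- G; G2[, 6] <- 2 - G[, 6]
  sc2 <- association_scan(y, toy_genotypes(G2), K, conditioning = "v001")
  expect_equal(sc2$beta[6], -sc$beta[6], tolerance = 1e-12)
  expect_equal(sc2$p[6], sc$p[6], tolerance = 1e-12)
  expect_equal(sc2$eaf[6], 1 - sc$eaf[6])

  ## joint subject permutation leaves p-values unchanged
  perm <- sample(n)
  scp <- association_scan(y[perm], toy_genotypes(G[perm, ]),
                          relatedness_matrix(A[perm, perm],
                                             kind = "additive",
                                             check = FALSE),
                          conditioning = "v001")
  expect_equal(scp$p, sc$p, tolerance = 1e-8)

  ## region filter
  scr <- association_scan(y, g, K, region = "1:1000-3001")
  expect_equal(scr$rsid, c("v001", "v002", "v003"))
})

test_that("scan p-values are calibrated under the null on a pedigree", {
  cfg <- sim_config(seed = 13, n_founders = 40, generations = 4,
                    variants = data.frame(freq = c(0.1, 0.3, 0.5),
                                          n = c(200, 200, 200)),
                    enriched = NULL, classes = NULL, composite = NULL,
                    analyzed = "all")
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  A <- additive_matrix(ped)
  set.seed(14)
  L <- matrix_sqrt(unclass(A))
  y <- sqrt(0.4) * drop(L %*% rnorm(nrow(ped))) + sqrt(0.6) * rnorm(nrow(ped))
  sc <- association_scan(y, g, A)
  p <- sc$p[!sc$skipped]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_true(genomic_inflation(p) > 0.85 && genomic_inflation(p) < 1.15)
})

test_that("conditional analysis returns an empty signal list when nothing is significant", {
  set.seed(9)
  n <- 80
  g <- toy_genotypes(matrix(rbinom(n * 5, 2, 0.4), n, 5))
  y <- rnorm(n)
  K <- relatedness_matrix(diag(0.5, n), kind = "kinship", check = FALSE)
  cs <- conditional_scan(y, g, K, region = "1:1000-6001", alpha = 1e-8)
  expect_length(cs$signals, 0)
  expect_length(cs$scans, 1)
})

test_that("PC-based thresholds count components as specified", {
  ## T perfectly correlated traits -> one PC, threshold = base level
  set.seed(10)
  base_trait <- rnorm(60)
  perf <- trait_matrix(matrix(base_trait, 60, 5) *
                         matrix(rep(c(1, 2, 3, 4, 5), each = 60), 60, 5))
  th <- multiple_testing_threshold(perf)
  expect_equal(th$pc_count, 1L)
  expect_equal(th$significance_threshold, 5e-8)

  ## 10 independent standardized traits at large n: all eigenvalues near 1,
  ## so 9 PCs explain < 95% and k = 10
  ind <- trait_matrix(matrix(rnorm(10000 * 10), 10000, 10))
  th2 <- multiple_testing_threshold(ind)
  expect_equal(th2$pc_count, 10L)
  expect_equal(th2$significance_threshold, 5e-9)
  expect_equal(th2$suggestive_threshold, 5e-8)

  expect_error(multiple_testing_threshold(
    trait_matrix(matrix(rnorm(5 * 8), 5, 8))), "fewer than traits")
})

test_that("threshold arithmetic helpers divide the base level", {
  expect_equal(adjusted_threshold(5e-8, 110), 5e-8 / 110)
  expect_equal(bonferroni_threshold(0.05, 702), 0.05 / 702)
  expect_error(adjusted_threshold(5e-8, 0))
})

test_that("analytic replication power matches its boundary cases", {
  expect_equal(replication_exclusion_power(0, 0.2, 500), 0.05,
               tolerance = 1e-12)
  ## noncentrality 10: essentially certain detection
  maf <- 0.3; n <- ceiling((10 / 0.5)^2 / (2 * maf * (1 - maf)))
  expect_gt(replication_exclusion_power(0.5, maf, n), 0.999)
  ## halving for winner's curse lowers power
  expect_lt(replication_exclusion_power(0.5, 0.05, 800, factor = 0.5),
            replication_exclusion_power(0.5, 0.05, 800, factor = 1))
  expect_error(replication_exclusion_power(0.5, 0.7, 100), "maf")
  expect_error(replication_exclusion_power(0.5, 0.1, 1), "n must")
  expect_error(replication_exclusion_power(0.5, 0.1, 100, alpha = 2),
               "alpha")
})

test_that("a large drifted-variant effect is genome-wide significant at study scale", {
  ## effect 1.2 SD at founder frequency 0.0625 (10 copies in 80 founders),
  ## scanned in ~650 analyzed subjects: significant at 4.5e-10 in >= 90%
  ## of replicates
  cfg0 <- sim_config(seed = 400,
                     variants = data.frame(freq = c(0.2, 0.4), n = c(5, 5)),
                     enriched = data.frame(copies = 10, beta = 1.2,
                                           trait = "SM_01",
                                           stringsAsFactors = FALSE),
                     classes = data.frame(class = "SM", n_species = 1,
                                          h2 = 0.4, block_cor = 0,
                                          rho_g = 0),
                     composite = NULL)
  ped <- simulate_pedigree(cfg0)
  tm0 <- simulate_lipidome(ped, gene_drop_genotypes(ped, cfg0), cfg0)
  ids <- rownames(tm0$values)
  A <- relatedness_matrix(unclass(additive_matrix(ped, ids))[, ],
                          kind = "additive", check = FALSE)
  hits <- vapply(seq_len(10), function(r) {
    cfg <- cfg0; cfg$seed <- 400L + r
    g <- gene_drop_genotypes(ped, cfg)
    tm <- simulate_lipidome(ped, g, cfg)
    g$dosages <- g$dosages[ids, , drop = FALSE]
    sc <- association_scan(tm$values[, "SM_01"], g, A, trait = "SM_01")
    isTRUE(sc$p[sc$rsid == "enr1"] < 4.5e-10)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("suggestive band partitions scan output consistently", {
  set.seed(11)
  n <- 100
  g <- toy_genotypes(matrix(rbinom(n * 30, 2, 0.3), n, 30))
  y <- rnorm(n)
  K <- relatedness_matrix(diag(0.5, n), kind = "kinship", check = FALSE)
  sc <- association_scan(y, g, K)
  sig <- 4.5e-10; sugg <- 5e-8
  p <- sc$p[!sc$skipped]
  expect_equal(sum(p < sig) + sum(p >= sig & p < sugg) + sum(p >= sugg),
               length(p))
})
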