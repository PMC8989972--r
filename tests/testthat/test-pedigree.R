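test_that("pedigree files parse, auto-add referenced parents, reject bad structure", {
  f <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F\t0\t0\t1", "M\t0\t0\t2", "C\tF\tM\t2"), f)
  ped <- parse_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_setequal(founders(ped), c("F", "M"))
  expect_equal(nrow(ped) - length(founders(ped)), 1)

  ## optional family column is tolerated and ignored
  f5 <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("FAM1\tF\t0\t0\t1", "FAM1\tM\t0\t0\t2", "FAM1\tC\tF\tM\t2"), f5)
  expect_equal(founders(parse_pedigree(f5)), founders(ped))

  ## referenced-but-absent father becomes a founder, with a warning
  f2 <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("M\t0\t0\t2", "C\tX\tM\t1"), f2)
  expect_warning(ped2 <- parse_pedigree(f2), "added as founders")
  expect_true("X" %in% founders(ped2))

  ## self-ancestry is a structural error
  f3 <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("M\t0\t0\t2", "C\tC\tM\t1"), f3)
  expect_error(parse_pedigree(f3), "cycle")

  expect_error(pedigree(c("A", "A"), sex = "male"), "duplicate")
  expect_error(pedigree(c("F", "C"), father = c(NA, "F"),
                        mother = c(NA, NA), sex = c("male", "male")),
               "both-or-neither")
  ## a mother recorded as male is inconsistent
  expect_error(pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
                        c("male", "male", "female")),
               "sex inconsistent")
})

test_that("kinship recursion reproduces textbook coefficients", {
  ped <- pedigree(c("F", "M", "A", "B"), c(NA, NA, "F", "F"),
                  c(NA, NA, "M", "M"),
                  c("male", "female", "male", "female"))
  K <- kinship_matrix(ped)
  expect_equal(K["F", "M"], 0)            # unrelated founders
  expect_equal(K["F", "A"], 0.25)         # parent-offspring
  expect_equal(K["A", "B"], 0.25)         # full sibs
  expect_equal(unname(diag(K)), rep(0.5, 4))

  ## offspring of a full-sib mating: phi(i,i) = (1 + 0.25) / 2
  ped2 <- pedigree(c("F", "M", "A", "B", "I"), c(NA, NA, "F", "F", "A"),
                   c(NA, NA, "M", "M", "B"),
                   c("male", "female", "male", "female", "male"))
  expect_equal(kinship_matrix(ped2)["I", "I"], 0.625)

  expect_error(kinship_matrix(ped, subjects = c("A", "ZZZ")),
               "not in pedigree")
})

test_that("dominance coefficients follow the fraternity formula", {
  ## full sibs: 0.5 * 0.5 + 0 = 0.25; parent-offspring 0; half sibs 0
  ped <- pedigree(c("F", "M", "M2", "A", "B", "H"),
                  c(NA, NA, NA, "F", "F", "F"),
                  c(NA, NA, NA, "M", "M", "M2"),
                  c("male", "female", "female", "male", "female", "male"))
  D <- dominance_matrix(ped)
  expect_equal(D["A", "B"], 0.25)
  expect_equal(D["F", "A"], 0)
  expect_equal(D["A", "H"], 0)            # paternal half sibs
  expect_equal(unname(diag(D)), rep(1, 6))

  ## founder-only subject set: phi = I/2, d = I
  Kf <- kinship_matrix(ped, subjects = c("F", "M", "M2"))
  expect_equal(unclass(Kf)[, ], diag(0.5, 3), ignore_attr = TRUE)
  Df <- dominance_matrix(ped, subjects = c("F", "M", "M2"))
  expect_equal(unclass(Df)[, ], diag(3), ignore_attr = TRUE)

  ## inbred individuals trigger the documented warning
  ped2 <- pedigree(c("F", "M", "A", "B", "I"), c(NA, NA, "F", "F", "A"),
                   c(NA, NA, "M", "M", "B"),
                   c("male", "female", "male", "female", "male"))
  expect_warning(dominance_matrix(ped2), "inbred")
})

test_that("additive matrix is PSD and kinship is permutation-equivariant", {
  for (seed in 1:4) {
    ped <- random_pedigree(seed, max_n = 25)
    A <- additive_matrix(ped)
    expect_true(psd_check(A))
    ids <- sample(ped$id)
    K1 <- kinship_matrix(ped)[ids, ids]
    K2 <- kinship_matrix(ped, subjects = ids)
    expect_equal(unclass(K1)[, ], unclass(K2)[, ], ignore_attr = TRUE)
  }
})

test_that("recursive kinship and dominance match gene-drop IBD sharing", {
  ## light version of the Monte-Carlo oracle check (the acceptance suite
  ## runs it at full replicate count). Kinship is exact for any pedigree,
  ## including inbred ones; the pair dominance formula is exact for
  ## non-inbred pedigrees, so its oracle uses one.
  set.seed(99)
  ped <- random_pedigree(11, max_n = 18)
  mc <- ibd_gene_drop(ped, reps = 3e4)
  K <- unclass(kinship_matrix(ped))[, ]
  se_phi <- sqrt(pmax(K * (1 - K), 1e-12) / mc$reps)
  off <- upper.tri(K)
  expect_true(all(abs(mc$phi - K)[off] <= 4 * se_phi[off] + 1e-3))

  set.seed(98)
  ped2 <- random_pedigree(12, max_n = 18, avoid_inbreeding = TRUE)
  mc2 <- ibd_gene_drop(ped2, reps = 3e4)
  D <- unclass(dominance_matrix(ped2))[, ]
  off2 <- upper.tri(D)
  se_d <- sqrt(pmax(D * (1 - D), 1e-12) / mc2$reps)
  expect_true(all(abs(mc2$dom - D)[off2] <= 4 * se_d[off2] + 1e-3))
})

test_that("double first cousins have phi = 1/8 and d = 1/16, matching gene drop", {
  ped <- double_first_cousin_pedigree()
  expect_equal(kinship_matrix(ped)["X", "Y"], 1 / 8)
  expect_equal(dominance_matrix(ped)["X", "Y"], 1 / 16)
  set.seed(5)
  mc <- ibd_gene_drop(ped, reps = 3e4)
  expect_lt(abs(mc$dom["X", "Y"] - 1 / 16),
            3 * sqrt((1 / 16) * (15 / 16) / 3e4) + 1e-3)
})

test_that("relatedness matrices round-trip through TSV", {
  ped <- random_pedigree(3, max_n = 12)
  K <- kinship_matrix(ped)
  f <- withr::local_tempfile(fileext = ".tsv")
  save_relatedness(K, f)
  K2 <- read_relatedness(f, kind = "kinship")
  expect_equal(unclass(K2)[, ], unclass(K)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(K2), rownames(K))
  expect_equal(relatedness_kind(K2), "kinship")
})
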