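## helper: duplicate of a fit posing as a one-extra-component alternative
fit1_alt_dummy <- function(fit) {
  alt <- fit
  alt$component_names <- c(fit$component_names, "extra")
  alt
}

test_that("a component proportional to the identity is rejected as non-identifiable", {
  set.seed(1)
  y <- rnorm(40)
  expect_error(fit_variance_components(y, list(dup = diag(40))),
               "proportional to the identity")
  expect_error(fit_variance_components(y, list(dup = diag(2.5, 40))),
               "proportional to the identity")
})

test_that("REML matches the balanced full-sib ANOVA closed form", {
  dat <- sib_pedigree_data(nf = 40, ns = 4, h2 = 0.5, seed = 42)
  fit <- fit_variance_components(dat$y, list(additive = dat$A))
  av <- anova(lm(dat$y ~ factor(dat$fam)))
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  sb <- (msb - msw) / 4                   # between-family variance
  expect_gt(sb, 0)                        # interior solution for this seed
  expect_equal(unname(fit$sigma2["additive"]), 2 * sb, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["residual"]), msw - sb, tolerance = 1e-6)
})

test_that("ML and REML fits differ as expected and converge deterministically", {
  dat <- sib_pedigree_data(nf = 30, ns = 4, h2 = 0.4, seed = 7)
  f1 <- fit_variance_components(dat$y, list(additive = dat$A))
  f2 <- fit_variance_components(dat$y, list(additive = dat$A))
  expect_identical(f1$sigma2, f2$sigma2)  # determinism
  fml <- fit_variance_components(dat$y, list(additive = dat$A),
                                 method = "ML")
  expect_lt(fml$loglik - f1$loglik, Inf)
  expect_true(f1$convergence$converged)
  ## ML total variance is biased down relative to REML in small samples
  expect_lte(sum(fml$sigma2), sum(f1$sigma2) + 1e-8)
})

test_that("REML is invariant to trait shifts and fixed-effect reparameterization", {
  dat <- sib_pedigree_data(nf = 30, ns = 4, h2 = 0.5, seed = 11)
  set.seed(12)
  X <- cbind(1, rnorm(dat$n), runif(dat$n))
  f1 <- fit_variance_components(dat$y, list(additive = dat$A), X = X)
  f2 <- fit_variance_components(dat$y + 100, list(additive = dat$A), X = X)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-7)
  ## invertible reparameterization of the design leaves the estimates
  ## unchanged (the REML log-likelihood itself shifts by log|det T|)
  Tm <- matrix(c(1, 0.5, -1, 0, 2, 1, 0, 0, 3), 3, 3)
  f3 <- fit_variance_components(dat$y, list(additive = dat$A), X = X %*% Tm)
  expect_equal(unname(f1$sigma2), unname(f3$sigma2), tolerance = 1e-7)
})

test_that("a truly absent dominance component is driven to the boundary", {
  ## multi-generation pedigree so that additive, dominance and residual
  ## structures are separable (full-sib-only designs are not: there
  ## D = A/2 + I/2 exactly)
  cfg <- sim_config(seed = 31, n_founders = 40, generations = 4,
                    classes = NULL, composite = NULL, enriched = NULL,
                    analyzed = "all")
  ped <- simulate_pedigree(cfg)
  A <- unclass(additive_matrix(ped))[, ]
  D <- unclass(suppressWarnings(dominance_matrix(ped)))[, ]
  set.seed(31)
  LA <- t(chol(A + 1e-8 * diag(nrow(A))))
  y <- sqrt(0.5) * drop(LA %*% rnorm(nrow(A))) + sqrt(0.5) * rnorm(nrow(A))
  fit <- fit_variance_components(y, list(additive = A, dominance = D))
  expect_equal(sum(fit$lambda), 1, tolerance = 1e-8)
  expect_true(all(fit$sigma2 >= 0))
  expect_lt(fit$lambda["dominance"], 0.15)
})

test_that("LRT statistic, mixture null, and nesting checks behave as specified", {
  dat <- sib_pedigree_data(nf = 30, ns = 4, h2 = 0.5, seed = 2)
  fit0 <- fit_variance_components(dat$y, list())
  fit1 <- fit_variance_components(dat$y, list(additive = dat$A))
  lrt <- lrt_compare(fit0, fit1)
  expect_gte(lrt$statistic, 0)
  expect_true(lrt$p_value > 0 && lrt$p_value <= 1)

  ## equal log-likelihoods give statistic 0 and p = 1
  expect_equal(lrt_compare(fit1, fit1_alt_dummy(fit1))$p_value, 1)

  ## quantile arithmetic of the 50:50 mixture: chi-square_1 tail of 0.10
  fake0 <- fit1; fake0$loglik <- 0; fake0$component_names <- character(0)
  fake1 <- fit1; fake1$loglik <- 2.706 / 2
  expect_equal(lrt_compare(fake0, fake1)$p_value, 0.05, tolerance = 1e-3)
  expect_equal(lrt_compare(fake0, fake1, null_dist = "chisq")$p_value,
               0.0999, tolerance = 1e-3)

  fml <- fit_variance_components(dat$y, list(additive = dat$A),
                                 method = "ML")
  expect_error(lrt_compare(fit0, fml), "different likelihoods")
  expect_error(lrt_compare(fit1, fit0), "extra component|nested")
})


test_that("variance proportions sum to one and define heritability", {
  fit <- list(sigma2 = c(a = 0.3, b = 0.2, residual = 0.5),
              component_names = c("a", "b"))
  class(fit) <- "varcomp_fit"
  expect_equal(unname(variance_proportions(fit)), c(0.3, 0.2, 0.5))
  expect_equal(sum(variance_proportions(fit)), 1)
  fit$sigma2 <- c(a = 0, b = 0, residual = 0)
  expect_error(variance_proportions(fit), "zero")

  dat <- sib_pedigree_data(nf = 20, ns = 4, h2 = 0, seed = 3)
  f0 <- fit_variance_components(dat$y, list())
  expect_equal(f0$h2, 0)                  # pure-residual fit
})

test_that("sequential selection returns an audit trail with monotone winning p-values", {
  set.seed(77)
  n <- 160
  mk_factor_cov <- function() {
    f <- rnorm(n)
    S <- 0.7 * tcrossprod(f) + 0.3 * diag(n)
    S * n / sum(diag(S))
    }
  S1 <- mk_factor_cov(); S2 <- mk_factor_cov(); S3 <- mk_factor_cov()
  L1 <- t(chol(S1))
  y <- sqrt(0.5) * drop(L1 %*% rnorm(n)) + sqrt(0.5) * rnorm(n)
  sel <- sequential_component_selection(
    y, base = list(), candidates = list(c1 = S1, c2 = S2, c3 = S3),
    alpha = 0.05)
  expect_true("c1" %in% sel$selected)
  tr <- sel$trace
  win <- tr[tr$selected, , drop = FALSE]
  expect_true(all(win$p_value < 0.05))
  last_step <- max(tr$step)
  if (!any(tr$selected[tr$step == last_step])) {
    expect_true(min(tr$p_value[tr$step == last_step], na.rm = TRUE) >= 0.05)
  }

  ## no candidate reaches alpha: empty selection, base model returned
  y0 <- rnorm(n)
  sel0 <- sequential_component_selection(
    y0, base = list(), candidates = list(c1 = S1, c2 = S2), alpha = 1e-6)
  expect_length(sel0$selected, 0)
  expect_equal(sel0$final_fit$component_names, character(0))
})

test_that("conditioning on a null genotype covariate leaves heritability unchanged", {
  dat <- sib_pedigree_data(nf = 40, ns = 4, h2 = 0.5, seed = 9)
  set.seed(10)
  gnull <- rbinom(dat$n, 2, 0.3)          # no simulated effect
  f0 <- fit_variance_components(dat$y, list(additive = dat$A))
  f1 <- fit_variance_components(dat$y, list(additive = dat$A),
                                X = cbind(1, gnull))
  expect_lt(abs(f0$h2 - f1$h2), 0.05)
})
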