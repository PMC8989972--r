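## Internal package helpers used by the tests, bound explicitly so the suite
## runs identically whether the package is attached or loaded as installed.
matrix_sqrt <- lipidvc:::matrix_sqrt
unclass_matrix <- lipidvc:::unclass_matrix
psd_check <- lipidvc:::psd_check
analyzed_subjects <- lipidvc:::analyzed_subjects

## Independent oracles used across the suite. These deliberately avoid the
## package's own computational paths: IBD sharing comes from label-based
## gene dropping, restricted likelihoods from a direct determinant formula
## maximized by grid refinement, and projections from normal equations.

## Monte-Carlo IBD sharing by dropping unique founder allele labels.
## Returns estimated kinship and dominance (genotype-sharing) matrices over
## all pedigree members, plus the replicate count for SE computation.
ibd_gene_drop <- function(ped, reps = 1e5) {
  n <- nrow(ped)
  ord <- attr(ped, "topo_order")
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  pat <- matrix(0L, reps, n)
  mat <- matrix(0L, reps, n)
  lab <- 0L
  for (i in ord) {
    if (is.na(fi[i])) {
      pat[, i] <- lab + 1L
      mat[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      coin <- stats::runif(reps) < 0.5
      pat[, i] <- ifelse(coin, pat[, fi[i]], mat[, fi[i]])
      coin <- stats::runif(reps) < 0.5
      mat[, i] <- ifelse(coin, pat[, mi[i]], mat[, mi[i]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  dom <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- (pat[, i] == pat[, j]) + (pat[, i] == mat[, j]) +
        (mat[, i] == pat[, j]) + (mat[, i] == mat[, j])
      phi[i, j] <- phi[j, i] <- mean(share) / 4
      both <- (pat[, i] == pat[, j] & mat[, i] == mat[, j]) |
        (pat[, i] == mat[, j] & mat[, i] == pat[, j])
      dom[i, j] <- dom[j, i] <- mean(both)
    }
  }
  list(phi = phi, dom = dom, reps = reps)
}

## Random valid pedigree of at most max_n individuals: founders first, then
## offspring whose parents are drawn from earlier individuals (acyclic by
## construction; may include inbred matings). With
## `avoid_inbreeding = TRUE`, parent pairs are resampled until unrelated, so
## every individual is non-inbred (where the pair dominance formula is
## exact).
random_pedigree <- function(seed, max_n = 30, n_founders = 6,
                            avoid_inbreeding = FALSE) {
  set.seed(seed)
  id <- sprintf("I%02d", seq_len(max_n))
  sex <- rep(c("male", "female"), length.out = max_n)
  sex[seq_len(n_founders)] <- rep(c("male", "female"),
                                  length.out = n_founders)
  father <- rep(NA_character_, max_n)
  mother <- rep(NA_character_, max_n)
  for (i in (n_founders + 1):max_n) {
    prev <- seq_len(i - 1)
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    if (avoid_inbreeding) {
      pd <- suppressWarnings(
        lipidvc::pedigree(id[prev], father[prev], mother[prev], sex[prev]))
      K <- lipidvc::kinship_matrix(pd)
      pairs <- expand.grid(f = males, m = females)
      unrel <- pairs[K[cbind(pairs$f, pairs$m)] == 0, , drop = FALSE]
      if (!nrow(unrel)) {               # fall back to a fresh founder pair
        father[i] <- mother[i] <- NA_character_
        next
      }
      pick <- unrel[sample(nrow(unrel), 1), ]
      father[i] <- id[pick$f]
      mother[i] <- id[pick$m]
    } else {
      father[i] <- id[sample(males, 1)]
      mother[i] <- id[sample(females, 1)]
    }
  }
  suppressWarnings(lipidvc::pedigree(id, father, mother, sex))
}

## Double first cousins: two sib pairs from unrelated families intermarry;
## their children share all four grandparents (classic dominance test case:
## phi = 1/8, d = 1/16).
double_first_cousin_pedigree <- function() {
  lipidvc::pedigree(
    id     = c("A", "B", "C", "D", "S1", "S2", "T1", "T2", "X", "Y"),
    father = c(NA, NA, NA, NA, "A", "A", "C", "C", "S1", "S2"),
    mother = c(NA, NA, NA, NA, "B", "B", "D", "D", "T1", "T2"),
    sex    = c("male", "female", "male", "female", "male", "male",
               "female", "female", "male", "female"))
}

## Restricted log-likelihood evaluated directly (determinant + explicit
## projection), independent of the AI-REML code path.
reml_loglik_direct <- function(sa, se, y, X, A) {
  n <- length(y)
  V <- sa * A + se * diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtVX)$modulus +
                       t(r) %*% Vi %*% r +
                       (n - ncol(X)) * log(2 * pi)))
}

## Dense 2-D grid plus refinement maximization of the restricted likelihood.
reml_grid_oracle <- function(y, X, A, n_grid = 21, rounds = 6) {
  vy <- stats::var(y)
  lo <- c(0, 1e-6 * vy)
  hi <- c(2.5 * vy, 2.5 * vy)
  best <- c(NA, NA)
  for (r in seq_len(rounds)) {
    sa_seq <- seq(lo[1], hi[1], length.out = n_grid)
    se_seq <- seq(lo[2], hi[2], length.out = n_grid)
    ll <- outer(sa_seq, se_seq,
                Vectorize(function(a, e) reml_loglik_direct(a, e, y, X, A)))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(sa_seq[idx[1]], se_seq[idx[2]])
    step <- c(sa_seq[2] - sa_seq[1], se_seq[2] - se_seq[1])
    lo <- pmax(best - 2 * step, c(0, 1e-9 * vy))
    hi <- best + 2 * step
  }
  stats::setNames(best, c("sigma_a", "sigma_e"))
}

## Balanced full-sib pedigree (nf families of ns sibs) and its block
## additive matrix, used for the ANOVA closed-form comparisons.
sib_pedigree_data <- function(nf, ns, h2 = 0.5, seed = 1) {
  set.seed(seed)
  A <- kronecker(diag(nf), matrix(0.5, ns, ns) + diag(0.5, ns))
  n <- nf * ns
  L <- chol(A)
  y <- sqrt(h2) * drop(t(L) %*% stats::rnorm(n)) +
    sqrt(1 - h2) * stats::rnorm(n)
  list(A = A, y = y, fam = rep(seq_len(nf), each = ns), n = n)
}

## small genotype fixture
toy_genotypes <- function(dosages, ids = NULL) {
  m <- ncol(dosages)
  lipidvc::genotype_matrix(
    dosages,
    data.frame(chrom = rep("1", m), pos = 1000L * seq_len(m),
               ref = rep("A", m), alt = rep("G", m),
               rsid = sprintf("v%03d", seq_len(m)),
               stringsAsFactors = FALSE),
    subjects = ids)
}
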