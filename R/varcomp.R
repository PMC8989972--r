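#' Control parameters for variance-component fitting
#'
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param grad_tol gradient-norm convergence tolerance on the internally
#'   standardized trait scale (default 1e-6).
#' @param max_iter maximum iterations (default 200).
#' @param start optional numeric vector of starting values (components then
#'   residual), on the trait-variance scale. Default: phenotypic variance
#'   split equally across components and residual.
#' @param floor_frac components below this fraction of phenotypic variance
#'   with a negative gradient are fixed at zero and flagged `boundary`.
#' @return List of control parameters.
#' @export
vc_control <- function(tol = 1e-8, grad_tol = 1e-6, max_iter = 200,
                       start = NULL, floor_frac = 1e-8) {
  list(tol = tol, grad_tol = grad_tol, max_iter = max_iter, start = start,
       floor_frac = floor_frac)
}

## Add an intercept column only if the design does not already span the
## constant vector (keeps fits invariant to invertible reparameterization).
ensure_intercept <- function(X) {
  n <- nrow(X)
  r <- qr.resid(qr(X), rep(1, n))
  if (mean(r^2) > 1e-10) X <- cbind(`(Intercept)` = 1, X)
  X
}

## Guard against a component that duplicates the residual identity: the two
## variances then enter the likelihood only through their sum.
check_identifiable <- function(K) {
  for (nm in names(K)) {
    M <- unclass_matrix(K[[nm]])
    n <- nrow(M)
    c0 <- sum(diag(M)) / n
    if (max(abs(M - diag(c0, n))) <= 1e-10 * max(abs(M), 1e-300)) {
      stop("component '", nm, "' is numerically proportional to the ",
           "identity and cannot be separated from the residual")
    }
  }
  invisible(TRUE)
}

#' Fit a variance-component mixed model by AI-REML (or ML)
#'
#' Maximizes the (restricted) Gaussian log-likelihood of
#' `y ~ N(X b, sum_k sigma2_k K_k + sigma2_e I)` under `sigma2 >= 0` using
#' average-information updates with expectation-maximization fallback steps
#' when an AI step leaves the feasible region. Components driven to the zero
#' boundary are fixed there and flagged. The fit is deterministic given the
#' inputs and control settings.
#'
#' @param y numeric response vector (one prepared trait).
#' @param K named list of [relatedness_matrix] (or plain symmetric matrices)
#'   aligned with `y`; may be empty for a pure-residual null model.
#' @param X fixed-effect design matrix (default: intercept only). An
#'   intercept column is added if absent.
#' @param method `"REML"` (default) or `"ML"`.
#' @param control see [vc_control()].
#' @return Object of class `varcomp_fit`: list with `sigma2` (named, includes
#'   `residual`), `lambda` (proportions of phenotypic variance), `h2`
#'   (additive proportion when a component is named `additive` or `kinship`),
#'   `loglik`, `method`, `se` (average-information standard errors),
#'   `convergence` (iterations, gradient norm, `boundary` flags) and
#'   bookkeeping fields used by [lrt_compare()].
#' @export
fit_variance_components <- function(y, K = list(), X = NULL,
                                    method = c("REML", "ML"),
                                    control = vc_control()) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y contains missing values; subset to complete cases")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y dimensions differ")
  X <- ensure_intercept(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  p <- ncol(X)
  k <- length(K)
  if (k > 0 && is.null(names(K))) names(K) <- paste0("K", seq_len(k))
  if (n < p + k + 2) stop("too few subjects for the requested model")
  Km <- lapply(K, unclass_matrix)
  for (nm in names(Km)) {
    if (!all(dim(Km[[nm]]) == n)) {
      stop("component '", nm, "' dimension does not match y")
    }
  }
  check_identifiable(Km)

  ## standardize internally; gradients and tolerances are then scale-free
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy <= 0) stop("y has zero variance")
  ys <- y / sdy
  ll_shift <- if (method == "REML") -(n - p) * log(sdy) else -n * log(sdy)

  cnames <- c(names(Km), "residual")
  vp <- mean(qr.resid(qx, ys)^2)

  if (k == 0) {                         # pure-residual closed form
    s2 <- if (method == "REML") sum(qr.resid(qx, ys)^2) / (n - p)
          else sum(qr.resid(qx, ys)^2) / n
    ll <- vc_loglik_direct(ys, X, list(), s2, numeric(0), method)
    fit <- new_varcomp_fit(sigma2 = stats::setNames(s2 * sdy^2, "residual"),
                           loglik = ll + ll_shift, method = method, n = n,
                           p = p, fixed_names = colnames(X),
                           component_names = character(0),
                           convergence = list(iterations = 0L,
                                              gradient_norm = 0,
                                              converged = TRUE,
                                              boundary = logical(0)),
                           se = stats::setNames(
                             sqrt(2 * s2^2 / (n - p)) * sdy^2, "residual"))
    return(fit)
  }

  floor_ <- control$floor_frac * vp
  sigma <- if (!is.null(control$start)) control$start / sdy^2
           else rep(vp / (k + 1), k + 1)
  if (length(sigma) != k + 1) stop("start values must have length ", k + 1)
  sigma <- pmax(sigma, floor_)
  active <- rep(TRUE, k + 1)            # residual is element k + 1
  trajectory <- list()
  ev <- vc_eval(sigma, Km, ys, X, method)
  converged <- FALSE
  gnorm <- NA_real_
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    d <- vc_derivs(ev, Km, ys, X, method)
    score <- d$score
    ## re-activate boundary components whose gradient turned positive
    active <- active | (score > 0 & sigma <= floor_)
    ## deactivate floored components being pushed below zero
    push_down <- sigma <= floor_ & score < 0
    active[push_down] <- FALSE
    sigma[!active] <- 0
    gnorm <- sqrt(sum(score[active]^2)) / n
    trajectory[[iter]] <- c(sigma = sigma, loglik = ev$ll)
    if (iter > 1 &&
        abs(ev$ll - ll_prev) < control$tol * (abs(ev$ll) + 1) &&
        gnorm < control$grad_tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ev$ll
    idx <- which(active)
    step <- tryCatch(solve(d$AI[idx, idx, drop = FALSE], score[idx]),
                     error = function(e) NULL)
    new_sigma <- sigma
    took <- FALSE
    if (!is.null(step)) {
      h <- 1
      for (try in 1:10) {
        cand <- sigma
        cand[idx] <- pmax(sigma[idx] + h * step, 0)  # project to feasibility
        ev_cand <- tryCatch(vc_eval(cand, Km, ys, X, method),
                            error = function(e) NULL)
        if (!is.null(ev_cand) && is.finite(ev_cand$ll) &&
            ev_cand$ll >= ev$ll - 1e-10) {
          new_sigma <- cand; ev <- ev_cand; took <- TRUE
          break
        }
        h <- h / 2
      }
    }
    if (!took) {                        # EM fallback step
      cand <- sigma
      cand[idx] <- sigma[idx] +
        sigma[idx]^2 * (d$q[idx] - d$trPK[idx]) / n
      cand[idx] <- pmax(cand[idx], floor_)
      ev_cand <- tryCatch(vc_eval(cand, Km, ys, X, method),
                          error = function(e) NULL)
      if (is.null(ev_cand) || !is.finite(ev_cand$ll)) {
        break                           # stuck; handled as non-convergence
      }
      new_sigma <- cand; ev <- ev_cand
    }
    sigma <- new_sigma
  }
  if (!converged) {
    cond <- structure(
      class = c("vc_nonconvergence", "error", "condition"),
      list(message = sprintf(
             "variance-component fit did not converge in %d iterations (gradient norm %.3g)",
             iter, gnorm),
           call = sys.call(-1), trajectory = trajectory))
    stop(cond)
  }
  d <- vc_derivs(ev, Km, ys, X, method)
  idx <- which(active)
  se <- rep(NA_real_, k + 1)
  vcov_act <- tryCatch(solve(d$AI[idx, idx, drop = FALSE]),
                       error = function(e) NULL)
  if (!is.null(vcov_act)) se[idx] <- sqrt(pmax(diag(vcov_act), 0))
  boundary <- !active | sigma <= floor_
  sigma_out <- sigma
  sigma_out[boundary & sigma <= floor_] <- 0
  new_varcomp_fit(
    sigma2 = stats::setNames(sigma_out * sdy^2, cnames),
    loglik = ev$ll + ll_shift, method = method, n = n, p = p,
    fixed_names = colnames(X), component_names = names(Km),
    convergence = list(iterations = iter, gradient_norm = gnorm,
                       converged = TRUE,
                       boundary = stats::setNames(boundary, cnames)),
    se = stats::setNames(se * sdy^2, cnames))
}

new_varcomp_fit <- function(sigma2, loglik, method, n, p, fixed_names,
                            component_names, convergence, se) {
  total <- sum(sigma2)
  lambda <- if (total > 0) sigma2 / total else rep(NA_real_, length(sigma2))
  h2 <- NA_real_
  for (nm in c("additive", "kinship")) {
    if (nm %in% names(lambda)) { h2 <- unname(lambda[nm]); break }
  }
  if (length(component_names) == 0) h2 <- 0
  structure(list(sigma2 = sigma2, lambda = lambda, h2 = h2, loglik = loglik,
                 method = method, n = n, p = p, fixed_names = fixed_names,
                 component_names = component_names, convergence = convergence,
                 se = se),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("varcomp_fit (%s, n = %d): loglik = %.4f\n",
              x$method, x$n, x$loglik))
  out <- data.frame(sigma2 = x$sigma2, lambda = x$lambda, se = x$se,
                    boundary = x$convergence$boundary[names(x$sigma2)])
  print(round(out, 5))
  invisible(x)
}

## One likelihood evaluation: Cholesky of V, projections, log-likelihood.
vc_eval <- function(sigma, Km, ys, X, method) {
  n <- length(ys)
  k <- length(Km)
  V <- diag(sigma[k + 1], n)
  for (j in seq_len(k)) if (sigma[j] != 0) V <- V + sigma[j] * Km[[j]]
  cV <- chol(V)
  Vinv <- chol2inv(cV)
  VX <- Vinv %*% X
  XtVX <- crossprod(X, VX)
  cXtVX <- chol(XtVX)
  beta <- backsolve(cXtVX, forwardsolve(t(cXtVX), crossprod(VX, ys)))
  Py <- drop(Vinv %*% ys - VX %*% beta)
  yPy <- sum(ys * Py)
  ldV <- 2 * sum(log(diag(cV)))
  if (method == "REML") {
    p <- ncol(X)
    ll <- -0.5 * (ldV + 2 * sum(log(diag(cXtVX))) + yPy +
                    (n - p) * log(2 * pi))
  } else {
    ll <- -0.5 * (ldV + yPy + n * log(2 * pi))
  }
  list(ll = ll, Vinv = Vinv, VX = VX, cXtVX = cXtVX, Py = Py)
}

## direct log-likelihood for the component-free model
vc_loglik_direct <- function(ys, X, Km, s2e, sigma, method) {
  ev <- vc_eval(c(sigma, s2e), Km, ys, X, method)
  ev$ll
}

## Scores, traces and average-information matrix at the current point.
## Order: components then residual. Uses P for REML, V^-1 for ML traces;
## the quadratic forms coincide because Py = V^-1 (y - X beta_gls).
vc_derivs <- function(ev, Km, ys, X, method) {
  n <- length(ys)
  k <- length(Km)
  Py <- ev$Py
  Vinv <- ev$Vinv
  VX <- ev$VX
  cXtVX <- ev$cXtVX
  proj <- function(M) {                 # P %*% M (columns)
    Vinv %*% M - VX %*% backsolve(cXtVX,
                                  forwardsolve(t(cXtVX), crossprod(VX, M)))
  }
  KPy <- matrix(0, n, k + 1)
  trA <- numeric(k + 1)                 # tr(V^-1 K_j)
  trB <- numeric(k + 1)                 # tr((X'V^-1X)^-1 X'V^-1 K_j V^-1 X)
  for (j in seq_len(k)) {
    KPy[, j] <- Km[[j]] %*% Py
    trA[j] <- sum(Vinv * Km[[j]])
    B <- crossprod(VX, Km[[j]] %*% VX)
    trB[j] <- sum(diag(backsolve(cXtVX, forwardsolve(t(cXtVX), B))))
  }
  KPy[, k + 1] <- Py
  trA[k + 1] <- sum(diag(Vinv))
  trB[k + 1] <- sum(diag(backsolve(cXtVX,
                                   forwardsolve(t(cXtVX), crossprod(VX)))))
  trPK <- if (method == "REML") trA - trB else trA
  q <- colSums(Py * KPy)                # y'P K_j P y
  score <- -0.5 * (trPK - q)
  PKPy <- if (method == "REML") proj(KPy) else Vinv %*% KPy
  AI <- 0.5 * crossprod(KPy, PKPy)
  list(score = score, trPK = trPK, q = q, AI = AI)
}

#' Likelihood-ratio comparison of nested variance-component fits
#'
#' The statistic is `2 * (loglik_alt - loglik_null)`, clamped at zero with a
#' warning if negative. Because the extra variance component lies on the
#' boundary of its parameter space under the null, the default null
#' distribution is the 50:50 mixture of a point mass at zero and chi-square
#' with `df` degrees of freedom (for `df` extra components, the mixture of
#' chi-square with `df - 1` and `df`); a plain chi-square is selectable.
#'
#' @param fit_null,fit_alt nested [fit_variance_components()] fits computed
#'   with the same method (and, under REML, identical fixed effects).
#' @param null_dist `"chisq_mixture"` (default) or `"chisq"`.
#' @return List with `statistic`, `df` (extra components) and `p_value`.
#' @export
lrt_compare <- function(fit_null, fit_alt,
                        null_dist = c("chisq_mixture", "chisq")) {
  null_dist <- match.arg(null_dist)
  stopifnot(inherits(fit_null, "varcomp_fit"), inherits(fit_alt, "varcomp_fit"))
  if (fit_null$method != fit_alt$method) {
    stop("fits use different likelihoods (ML vs REML)")
  }
  if (!all(fit_null$component_names %in% fit_alt$component_names)) {
    stop("models are not nested: null components must be a subset of alt")
  }
  df <- length(fit_alt$component_names) - length(fit_null$component_names)
  if (df < 1) stop("alternative must have at least one extra component")
  if (fit_null$method == "REML" &&
      !identical(fit_null$fixed_names, fit_alt$fixed_names)) {
    stop("REML likelihoods are not comparable across different fixed effects; refit with ML")
  }
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < 0) {
    if (stat < -1e-6) warning(sprintf(
      "negative LRT statistic (%.3g) clamped to 0", stat))
    stat <- 0
  }
  p <- if (null_dist == "chisq") {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else if (stat <= 0) {
    1
  } else {
    0.5 * (if (df > 1) stats::pchisq(stat, df = df - 1, lower.tail = FALSE)
           else 0) +
      0.5 * stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p)
}

#' Proportions of phenotypic variance (lambda)
#'
#' @param fit a [fit_variance_components()] fit.
#' @return Named vector `sigma2_k / sum(sigma2)`; the additive component's
#'   share is the narrow-sense heritability.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "varcomp_fit"))
  total <- sum(fit$sigma2)
  if (total <= 0) stop("all variance components are zero")
  fit$sigma2 / total
}

#' Greedy forward selection of variance components
#'
#' Starting from a base model, repeatedly fits the base plus each remaining
#' candidate component, picks the candidate with the smallest LRT p-value,
#' and adds it if `p < alpha`; stops otherwise. Ties break by candidate list
#' order; candidates whose fit fails are skipped with the reason recorded.
#'
#' @param y numeric response vector.
#' @param base named list of component matrices always included (may be
#'   empty).
#' @param candidates named list of candidate component matrices.
#' @param X fixed-effect design matrix (default intercept).
#' @param alpha inclusion threshold on the LRT p-value (default 0.05).
#' @param method,null_dist,control passed to the underlying fits and tests.
#' @return List with `selected` (names in inclusion order), `final_fit`,
#'   `trace` (data frame: step, candidate, statistic, p_value, selected,
#'   note) recording every candidate fit attempted.
#' @export
sequential_component_selection <- function(y, base = list(), candidates,
                                           X = NULL, alpha = 0.05,
                                           method = "REML",
                                           null_dist = "chisq_mixture",
                                           control = vc_control()) {
  stopifnot(length(candidates) > 0, !is.null(names(candidates)),
            alpha > 0, alpha < 1)
  current <- base
  fit_cur <- fit_variance_components(y, current, X, method, control)
  remaining <- candidates
  selected <- character(0)
  trace <- list()
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    pvals <- rep(NA_real_, length(remaining))
    stats_ <- rep(NA_real_, length(remaining))
    notes <- rep("", length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      nm <- names(remaining)[i]
      fits[[i]] <- tryCatch(
        fit_variance_components(y, c(current, remaining[i]), X, method,
                                control),
        error = function(e) e)
      if (inherits(fits[[i]], "error")) {
        notes[i] <- paste("fit failed:", conditionMessage(fits[[i]]))
        next
      }
      lrt <- lrt_compare(fit_cur, fits[[i]], null_dist)
      pvals[i] <- lrt$p_value
      stats_[i] <- lrt$statistic
    }
    win <- if (all(is.na(pvals))) NA_integer_ else which.min(pvals)
    add <- !is.na(win) && pvals[win] < alpha
    trace[[step]] <- data.frame(
      step = step, candidate = names(remaining),
      statistic = stats_, p_value = pvals,
      selected = add & seq_along(remaining) == win,
      note = notes, stringsAsFactors = FALSE)
    if (!add) break
    nm <- names(remaining)[win]
    selected <- c(selected, nm)
    current <- c(current, remaining[win])
    fit_cur <- fits[[win]]
    remaining <- remaining[-win]
  }
  list(selected = selected, final_fit = fit_cur,
       trace = do.call(rbind, trace))
}

#' Serialize variance-component fits to a summary table
#'
#' @param fits named list of [fit_variance_components()] fits (names are
#'   trait ids).
#' @param path optional TSV output path.
#' @return Data frame (trait, component, sigma2, lambda, se, loglik,
#'   converged, boundary), written to `path` when given.
#' @export
varcomp_table <- function(fits, path = NULL) {
  rows <- lapply(names(fits), function(tr) {
    f <- fits[[tr]]
    data.frame(trait = tr, component = names(f$sigma2),
               sigma2 = unname(f$sigma2), lambda = unname(f$lambda),
               se = unname(f$se), loglik = f$loglik,
               converged = f$convergence$converged,
               boundary = unname(f$convergence$boundary[names(f$sigma2)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
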