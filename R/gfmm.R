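# General finite mixture model (GFMM) for mixed-type phenotype matrices:
# class-conditional Gaussian / Bernoulli / multinomial feature likelihoods
# with covariate-dependent (multinomial-logit) class priors, fitted by EM
# with random multi-start.  Covariates enter only the class prior (the
# "1-step with covariates" configuration); feature densities are
# conditionally independent given class.

#' Initialise mixture parameters
#'
#' @param K number of classes.
#' @param schema a [feature_schema()].
#' @return A bare `mixture_params` list: `K`, `prior_coef` (3 x K matrix on
#'   (intercept, sex, age); column 1 is the zero reference class), `mean`/`sd`
#'   (K x n_continuous), `p` (K x n_binary), `cat` (list of K x L matrices).
#' @keywords internal
empty_params <- function(K, schema) {
  idx <- split(seq_len(nrow(schema)), schema$type)
  structure(list(
    K = K, schema = schema,
    j_cont = which(schema$type == "continuous"),
    j_bin = which(schema$type == "binary"),
    j_cat = which(schema$type == "categorical"),
    prior_coef = matrix(0, 3, K, dimnames = list(c("intercept", "sex", "age"), NULL)),
    mean = matrix(0, K, sum(schema$type == "continuous")),
    sd = matrix(1, K, sum(schema$type == "continuous")),
    p = matrix(0.5, K, sum(schema$type == "binary")),
    cat = lapply(which(schema$type == "categorical"), function(j) {
      L <- schema$n_levels[j]
      matrix(1 / L, K, L)
    })
  ), class = "mixture_params")
}

# Number of free parameters: (K-1) prior coefficient vectors of length 3,
# plus per class 2 per continuous, 1 per binary, L-1 per categorical.
#' Free-parameter count of a GFMM
#'
#' @param schema a [feature_schema()].
#' @param K number of classes.
#' @return Integer parameter count used by the information criteria.
#' @export
n_parameters <- function(schema, K) {
  per_class <- 2 * sum(schema$type == "continuous") +
    sum(schema$type == "binary") +
    sum(schema$n_levels[schema$type == "categorical"] - 1)
  as.integer(3 * (K - 1) + K * per_class)
}

# n x K matrix of per-class feature log densities (sum over features).
# Gaussian and Bernoulli blocks are computed as matrix products (the Gaussian
# log density is quadratic in x, so three crossproducts cover all classes);
# categorical features use level-index lookup into the log-probability table.
log_density_matrix <- function(params, X) {
  n <- nrow(X)
  K <- params$K
  ld <- matrix(0, n, K)
  smooth <- 1e-10
  if (length(params$j_cont)) {
    Xc <- X[, params$j_cont, drop = FALSE]
    inv2v <- 1 / (2 * params$sd^2)                       # K x d
    b <- params$mean / params$sd^2
    const <- rowSums(-log(params$sd) - 0.5 * log(2 * pi) -
                       params$mean^2 * inv2v)            # per class
    ld <- ld + (Xc^2) %*% t(-inv2v) + Xc %*% t(b) +
      matrix(const, n, K, byrow = TRUE)
  }
  if (length(params$j_bin)) {
    Xb <- X[, params$j_bin, drop = FALSE]
    pk <- pmin(pmax(params$p, smooth), 1 - smooth)       # K x d
    ld <- ld + Xb %*% t(log(pk) - log1p(-pk)) +
      matrix(rowSums(log1p(-pk)), n, K, byrow = TRUE)
  }
  if (length(params$j_cat)) {
    for (jj in seq_along(params$j_cat)) {
      x <- X[, params$j_cat[jj]]
      pr <- params$cat[[jj]]                             # K x L
      if (any(x < 1 | x > ncol(pr))) {
        stop("domain error: categorical level out of range for feature index ",
             params$j_cat[jj])
      }
      pr <- pr + smooth
      pr <- pr / rowSums(pr)
      ld <- ld + t(log(pr))[x, , drop = FALSE]
    }
  }
  ld
}

#' Per-row class-conditional log density
#'
#' Sum over features of the log density/mass of the row's feature values
#' under class `k` (conditional independence given class).
#'
#' @param params a `mixture_params` object.
#' @param k class index (1-based).
#' @param x a feature row: numeric vector in schema order (categorical
#'   features as integer level indices), or a one-row data.frame/matrix.
#' @return The scalar log density.
#' @export
component_log_density <- function(params, k, x) {
  if (k < 1 || k > params$K) stop("value error: class index out of range")
  X <- matrix(as.numeric(unlist(x)), nrow = 1)
  log_density_matrix(params, X)[1, k]
}

# Class-prior matrix pi_ik = softmax(Z %*% prior_coef), rows sum to 1.
prior_matrix <- function(params, Z) {
  eta <- Z %*% params$prior_coef
  eta <- eta - eta[cbind(seq_len(nrow(eta)), max.col(eta, ties.method = "first"))]
  w <- exp(eta)
  w / rowSums(w)
}

#' E-step: posterior responsibilities and observed-data log-likelihood
#'
#' Computes `gamma_ik` proportional to `pi_k(cov_i) * f_k(x_i)` and the total
#' log-likelihood via a log-sum-exp contract (no underflow for densities down
#' to `exp(-700)` and far beyond).
#'
#' @param params a `mixture_params` object.
#' @param X numeric feature matrix in schema order.
#' @param Z covariate design matrix `(intercept, sex, age)`.
#' @return List with `gamma` (n x K responsibilities, rows summing to 1) and
#'   `ll` (scalar log-likelihood).
#' @export
e_step <- function(params, X, Z) {
  ld <- log_density_matrix(params, X)
  lp <- log(prior_matrix(params, Z))
  a <- ld + lp
  m <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m))[1]
    stop("numerical error: non-finite density at row ", bad)
  }
  w <- exp(a - m)
  s <- rowSums(w)
  list(gamma = w / s, ll = sum(m + log(s)))
}

# Weighted multinomial-logit fit of responsibilities on covariates by
# damped Newton iterations; reference class 1 has zero coefficients.
# Converged when the gradient max-norm drops below `grad_tol`.
fit_prior_coef <- function(Z, gamma, init = NULL, grad_tol = 1e-8, max_iter = 100) {
  K <- ncol(gamma)
  p <- ncol(Z)
  if (K == 1) return(matrix(0, p, 1, dimnames = list(colnames(Z), NULL)))
  B <- if (is.null(init)) matrix(0, p, K) else init
  nfree <- p * (K - 1)
  obj <- function(B) {
    eta <- Z %*% B
    m <- eta[cbind(seq_len(nrow(eta)), max.col(eta, ties.method = "first"))]
    sum(gamma * eta) - sum(m + log(rowSums(exp(eta - m))))
  }
  f_old <- obj(B)
  for (it in seq_len(max_iter)) {
    eta <- Z %*% B
    eta <- eta - eta[cbind(seq_len(nrow(eta)), max.col(eta, ties.method = "first"))]
    P <- exp(eta)
    P <- P / rowSums(P)
    G <- t(Z) %*% (gamma - P)            # p x K score
    g <- as.vector(G[, -1, drop = FALSE])
    if (max(abs(g)) < grad_tol) break
    # Hessian blocks over the K-1 free classes
    H <- matrix(0, nfree, nfree)
    for (a in 2:K) {
      for (b in 2:K) {
        w <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
        H[((a - 2) * p + 1):((a - 1) * p), ((b - 2) * p + 1):((b - 1) * p)] <-
          t(Z) %*% (Z * w)
      }
    }
    step <- tryCatch(solve(H + diag(1e-10, nfree), g),
                     error = function(e) g / max(abs(diag(H)), 1))
    # damped update with step halving on the weighted log-likelihood
    lam <- 1
    repeat {
      B_new <- B
      B_new[, -1] <- B[, -1, drop = FALSE] + lam * matrix(step, p, K - 1)
      f_new <- obj(B_new)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { B_new <- B; f_new <- f_old; break }
    }
    B <- B_new
    f_old <- f_new
  }
  dimnames(B) <- list(colnames(Z), NULL)
  B
}

#' M-step: responsibility-weighted maximum-likelihood parameter updates
#'
#' Feature parameters are gamma-weighted MLEs (weighted means/variances,
#' weighted proportions, weighted level frequencies); prior coefficients
#' maximise the weighted multinomial-logit likelihood of the
#' responsibilities on `(intercept, sex, age)` via damped Newton iterations
#' (gradient max-norm below 1e-8 at convergence).
#'
#' @param X numeric feature matrix in schema order.
#' @param Z covariate design matrix.
#' @param schema a [feature_schema()].
#' @param gamma n x K responsibilities.
#' @param variance_floor minimum variance as a fraction of each feature's
#'   overall variance (see [gfmm_fit()]).
#' @param prev optional previous `mixture_params` (warm start for the prior
#'   solver).
#' @param floor_var optional precomputed per-feature variance floors
#'   (overrides `variance_floor`; used internally to avoid recomputation
#'   inside the EM loop).
#' @return Updated `mixture_params`.
#' @export
m_step <- function(X, Z, schema, gamma, variance_floor = 1e-4, prev = NULL,
                   floor_var = NULL) {
  K <- ncol(gamma)
  n <- nrow(X)
  nk <- colSums(gamma)
  if (any(nk < 1e-6 * n)) {
    stop("degenerate-class error: class ", which.min(nk),
         " has vanishing total responsibility")
  }
  params <- empty_params(K, schema)
  if (length(params$j_cont)) {
    Xc <- X[, params$j_cont, drop = FALSE]
    if (is.null(floor_var)) {
      floor_var <- pmax(variance_floor * apply(Xc, 2, stats::var), 1e-12)
    }
    S1 <- crossprod(gamma, Xc)
    S2 <- crossprod(gamma, Xc^2)
    mu <- S1 / nk
    v <- S2 / nk - mu^2
    params$mean <- unname(mu)
    params$sd <- unname(sqrt(pmax(v, rep(unname(floor_var), each = K))))
  }
  if (length(params$j_bin)) {
    params$p <- unname(crossprod(gamma, X[, params$j_bin, drop = FALSE]) / nk)
  }
  if (length(params$j_cat)) {
    for (jj in seq_along(params$j_cat)) {
      x <- X[, params$j_cat[jj]]
      L <- schema$n_levels[params$j_cat[jj]]
      M <- matrix(0, n, L)
      M[cbind(seq_len(n), x)] <- 1
      tab <- crossprod(gamma, M)
      params$cat[[jj]] <- tab / rowSums(tab)
    }
  }
  params$prior_coef <- fit_prior_coef(Z, gamma,
                                      init = if (!is.null(prev)) prev$prior_coef)
  params
}

run_em_chain <- function(X, Z, schema, K, max_iter, tol, variance_floor,
                         chain_seed, floor_var = NULL) {
  n <- nrow(X)
  if (is.null(floor_var) && any(schema$type == "continuous")) {
    Xc <- X[, schema$type == "continuous", drop = FALSE]
    floor_var <- pmax(variance_floor * apply(Xc, 2, stats::var), 1e-12)
  }
  gamma0 <- with_seed(chain_seed, {
    g <- matrix(stats::rexp(n * K), n, K)   # Dirichlet(1,...,1) rows
    g / rowSums(g)
  })
  params <- tryCatch(m_step(X, Z, schema, gamma0, floor_var = floor_var),
                     error = function(e) NULL)
  if (is.null(params)) return(list(ok = FALSE))
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  gamma <- gamma0
  for (it in seq_len(max_iter)) {
    es <- e_step(params, X, Z)
    gamma <- es$gamma
    trace <- c(trace, es$ll)
    if (is.finite(ll_old) && es$ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- es$ll
    params <- tryCatch(m_step(X, Z, schema, gamma, prev = params,
                              floor_var = floor_var),
                       error = function(e) NULL)
    if (is.null(params)) return(list(ok = FALSE))
  }
  list(ok = TRUE, params = params, gamma = gamma, ll = trace[length(trace)],
       trace = trace, converged = converged, seed = chain_seed)
}

#' Fit a GFMM by multi-start EM
#'
#' Runs `n_init` independent EM chains from random soft-responsibility
#' initialisations (Dirichlet(1,...,1) rows) and returns the chain with the
#' highest final log-likelihood.  Convergence when the per-iteration
#' log-likelihood gain drops below `tol` or `max_iter` is reached.
#'
#' @param cohort a [phenotype_cohort()] with complete feature data, or a
#'   list with elements `X` (numeric feature matrix) and `Z` (covariates).
#' @param K number of latent classes (>= 1).
#' @param n_init number of random restarts (the study default is 200;
#'   desk-scale runs use fewer).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param variance_floor minimum class variance, as a fraction of each
#'   feature's overall variance (guards against singular Gaussians).
#' @param seed integer; chain seeds are derived from it.
#' @param schema optional schema override (defaults to the cohort's).
#' @return Object of class `gfmm_fit`: `params`, `responsibilities`, `labels`
#'   (max-posterior, ties to the lowest class index), `ll`, `ll_trace`,
#'   `n_parameters`, `converged`, `seed` of the winning chain, `K`, `n`.
#' @export
gfmm_fit <- function(cohort, K, n_init = 20, max_iter = 500, tol = 1e-6,
                     variance_floor = 1e-4, seed = 1L, schema = NULL) {
  if (inherits(cohort, "phenotype_cohort")) {
    if (is.null(schema)) schema <- cohort$schema
    X <- cohort_feature_matrix(cohort, schema$name)
    Z <- cohort_covariates(cohort)
  } else {
    X <- cohort$X
    Z <- cohort$Z
    if (is.null(schema)) stop("schema required when not passing a phenotype_cohort")
  }
  if (anyNA(X)) stop("cohort contains missing feature values; apply completeness_filter first")
  n <- nrow(X)
  if (K > n) stop("value error: K exceeds the number of individuals")
  best <- NULL
  for (i in seq_len(n_init)) {
    chain <- run_em_chain(X, Z, schema, K, max_iter, tol, variance_floor,
                          chain_seed = seed * 1000L + i)
    if (!chain$ok) next
    if (is.null(best) || chain$ll > best$ll) best <- chain
  }
  if (is.null(best)) stop("fit-failure error: all EM chains degenerated")
  labels <- max.col(best$gamma, ties.method = "first")
  structure(list(
    params = best$params, responsibilities = best$gamma, labels = labels,
    ll = best$ll, ll_trace = best$trace,
    n_parameters = n_parameters(schema, K), converged = best$converged,
    seed = best$seed, K = K, n = n, schema = schema
  ), class = "gfmm_fit")
}

#' @export
print.gfmm_fit <- function(x, ...) {
  cat(sprintf("gfmm_fit: K=%d, n=%d, logLik=%.3f, %d parameters, %s\n",
              x$K, x$n, x$ll, x$n_parameters,
              if (x$converged) "converged" else "iteration cap reached"))
  cat("  class sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Predict class labels on new data with a fitted GFMM
#'
#' A frozen-parameter E-step followed by a per-row argmax; posterior ties are
#' broken deterministically toward the lowest class index.
#'
#' @param object a [gfmm_fit()] result.
#' @param cohort a [phenotype_cohort()] conforming to the fit's schema.
#' @param ... unused.
#' @return List with `labels` and `responsibilities`.
#' @export
predict.gfmm_fit <- function(object, cohort, ...) {
  sch <- object$schema
  miss <- setdiff(sch$name, cohort$schema$name)
  if (length(miss)) stop("schema error: cohort lacks feature(s): ", paste(miss, collapse = ", "))
  ty <- cohort$schema$type[match(sch$name, cohort$schema$name)]
  if (!identical(ty, sch$type)) stop("schema error: feature type mismatch")
  X <- cohort_feature_matrix(cohort, sch$name)
  Z <- cohort_covariates(cohort)
  es <- e_step(object$params, X, Z)
  list(labels = max.col(es$gamma, ties.method = "first"),
       responsibilities = es$gamma, ll = es$ll)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer label vectors of equal length.
#' @return Scalar ARI in `[-1, 1]` (1 = identical partitions up to
#'   relabeling).
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Best permutation of estimated classes onto true classes (maximum label
# agreement over all K! permutations; K is small here).
align_classes <- function(est, truth, K = max(c(est, truth))) {
  perms <- perm_matrix(K)
  best <- NULL
  best_agree <- -1
  for (r in seq_len(nrow(perms))) {
    agree <- sum(perms[r, est] == truth)
    if (agree > best_agree) {
      best_agree <- agree
      best <- perms[r, ]
    }
  }
  best
}

perm_matrix <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(K - 1)
  out <- do.call(rbind, lapply(seq_len(K), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= K - 1) sub[, pos:(K - 1), drop = FALSE]
             else sub[, 0, drop = FALSE]
    cbind(left, K, right)
  }))
  storage.mode(out) <- "integer"
  out
}
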