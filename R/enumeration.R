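# Class-enumeration diagnostics: information criteria, 3-fold
# cross-validated log-likelihood, naive pairwise likelihood-ratio tests,
# relative entropy, average posterior probability, smallest-class tracking.
# Model choice itself is a user decision informed by the table.

#' Information criteria from a log-likelihood
#'
#' `AIC = -2LL + 2p`; `BIC = -2LL + p ln n`; `CAIC = -2LL + p (ln n + 1)`;
#' `SABIC = -2LL + p ln((n + 2) / 24)`.
#'
#' @param ll log-likelihood (finite).
#' @param p free-parameter count (>= 1), see [n_parameters()].
#' @param n sample size (>= 1).
#' @return Named list with `AIC`, `BIC`, `CAIC`, `SABIC`.
#' @export
information_criteria <- function(ll, p, n) {
  if (!is.finite(ll)) stop("value error: non-finite log-likelihood")
  stopifnot(p >= 1, n >= 1)
  list(AIC = -2 * ll + 2 * p,
       BIC = -2 * ll + p * log(n),
       CAIC = -2 * ll + p * (log(n) + 1),
       SABIC = -2 * ll + p * log((n + 2) / 24))
}

#' Cross-validated log-likelihood
#'
#' For each repetition: shuffle the cohort, partition it into `n_folds`
#' folds, and for each fold fit a GFMM on the remaining folds and evaluate
#' the frozen-parameter log-likelihood on the held-out fold.  The per-rep
#' value is the held-out log-likelihood summed across all individuals
#' (every individual is held out exactly once per rep).
#'
#' @param cohort a complete [phenotype_cohort()].
#' @param K number of classes.
#' @param n_folds number of folds (default 3).
#' @param n_reps number of repetitions.
#' @param seed integer seed (governs shuffles and chain seeds).
#' @param ... passed to [gfmm_fit()] (`n_init`, `tol`, ...).
#' @return Numeric vector of length `n_reps` of held-out log-likelihoods.
#' @export
cv_log_likelihood <- function(cohort, K, n_folds = 3, n_reps = 1, seed = 1L, ...) {
  n <- nrow(cohort$data)
  if (n < n_folds * K) stop("value error: folds smaller than K")
  vapply(seq_len(n_reps), function(rep) {
    ord <- with_seed(seed + rep, sample.int(n))
    fold <- rep_len(seq_len(n_folds), n)[order(ord)]
    total <- 0
    for (f in seq_len(n_folds)) {
      train <- phenotype_cohort(cohort$data[fold != f, , drop = FALSE], cohort$schema)
      test <- phenotype_cohort(cohort$data[fold == f, , drop = FALSE], cohort$schema)
      if (sum(fold == f) < K) stop("value error: fold smaller than K")
      fit <- gfmm_fit(train, K = K, seed = seed * 100L + rep * 10L + f, ...)
      total <- total + predict(fit, test)$ll
    }
    total
  }, numeric(1))
}

#' Naive likelihood-ratio test between consecutive K
#'
#' Chi-square test on `2 (LL_K - LL_{K-1})` (clipped at 0) with degrees of
#' freedom equal to the free-parameter difference.  This is the plain
#' chi-square comparison of consecutive models; it is *not* the
#' Lo-Mendell-Rubin adjusted distribution and is anti-conservative under the
#' null — treat its p-values as descriptive.
#'
#' @param fit_km1,fit_k [gfmm_fit()] results on the same cohort with
#'   `fit_k$K == fit_km1$K + 1`.
#' @return List with `statistic`, `df`, `p`, and `naive = TRUE`.
#' @export
pairwise_lrt <- function(fit_km1, fit_k) {
  if (fit_k$K != fit_km1$K + 1) stop("usage error: fits must have consecutive K")
  if (fit_k$n != fit_km1$n) stop("usage error: fits are on different cohorts")
  if (!identical(fit_k$schema$name, fit_km1$schema$name)) {
    stop("usage error: fits use different schemas")
  }
  stat <- max(0, 2 * (fit_k$ll - fit_km1$ll))
  df <- fit_k$n_parameters - fit_km1$n_parameters
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), naive = TRUE)
}

#' Relative entropy of a responsibility matrix
#'
#' `1 - sum_i sum_k (-gamma_ik ln gamma_ik) / (n ln K)`; 1 means perfectly
#' crisp assignment, 0 means uniform posteriors.  Undefined for K = 1
#' (returns `NA`).
#'
#' @param gamma n x K responsibility matrix.
#' @return Scalar in `[0, 1]`, or `NA` for K = 1.
#' @export
relative_entropy <- function(gamma) {
  K <- ncol(gamma)
  if (K < 2) return(NA_real_)
  g <- pmin(pmax(gamma, 1e-300), 1)
  h <- -sum(g * log(g) * (gamma > 0))
  1 - h / (nrow(gamma) * log(K))
}

#' Average posterior probability per class
#'
#' For each class, the mean over its assigned members of the row-maximum
#' posterior probability.  Empty classes give `NA`.
#'
#' @param gamma n x K responsibility matrix.
#' @param labels max-posterior labels (consistent with `gamma`).
#' @return Numeric vector of length K.
#' @export
avepp <- function(gamma, labels) {
  K <- ncol(gamma)
  mx <- apply(gamma, 1, max)
  vapply(seq_len(K), function(k) {
    sel <- labels == k
    if (!any(sel)) NA_real_ else mean(mx[sel])
  }, numeric(1))
}

#' Enumerate candidate models over a range of K
#'
#' Fits each K `n_reps` times (fresh chain seeds per rep), recording the
#' log-likelihood, information criteria, relative entropy, mean AvePP,
#' smallest-class count/proportion, optional cross-validated log-likelihood,
#' and the naive LRT against the previous K within each rep.  Reported
#' values are means over reps; fit failures are recorded per cell.
#'
#' @param cohort a complete [phenotype_cohort()].
#' @param K_range integer vector of candidate K values.
#' @param n_reps replicate fits per K.
#' @param cv if `TRUE`, also compute [cv_log_likelihood()] per K/rep.
#' @param seed integer seed.
#' @param ... passed to [gfmm_fit()].
#' @return data.frame with one row per K (class `enumeration_table`).
#' @export
enumerate_models <- function(cohort, K_range, n_reps = 1, cv = FALSE,
                             seed = 1L, ...) {
  if (!length(K_range)) stop("value error: empty K range")
  K_range <- sort(unique(as.integer(K_range)))
  n <- nrow(cohort$data)
  cell <- function() matrix(NA_real_, n_reps, length(K_range),
                            dimnames = list(NULL, K_range))
  M <- list(ll = cell(), AIC = cell(), BIC = cell(), CAIC = cell(),
            SABIC = cell(), entropy = cell(), avepp = cell(),
            smallest_n = cell(), cvll = cell(), lrt_stat = cell(),
            lrt_p = cell(), failed = cell())
  for (r in seq_len(n_reps)) {
    prev_fit <- NULL
    for (ki in seq_along(K_range)) {
      K <- K_range[ki]
      fit <- tryCatch(gfmm_fit(cohort, K = K, seed = seed + 131L * r + ki, ...),
                      error = function(e) NULL)
      if (is.null(fit)) {
        M$failed[r, ki] <- 1
        prev_fit <- NULL
        next
      }
      ic <- information_criteria(fit$ll, fit$n_parameters, n)
      M$ll[r, ki] <- fit$ll
      M$AIC[r, ki] <- ic$AIC; M$BIC[r, ki] <- ic$BIC
      M$CAIC[r, ki] <- ic$CAIC; M$SABIC[r, ki] <- ic$SABIC
      M$entropy[r, ki] <- relative_entropy(fit$responsibilities)
      M$avepp[r, ki] <- mean(avepp(fit$responsibilities, fit$labels), na.rm = TRUE)
      M$smallest_n[r, ki] <- min(tabulate(fit$labels, K))
      if (cv) {
        M$cvll[r, ki] <- tryCatch(
          cv_log_likelihood(cohort, K, n_reps = 1, seed = seed + 977L * r + ki, ...),
          error = function(e) NA_real_)
      }
      if (!is.null(prev_fit) && prev_fit$K == K - 1) {
        lrt <- pairwise_lrt(prev_fit, fit)
        M$lrt_stat[r, ki] <- lrt$statistic
        M$lrt_p[r, ki] <- lrt$p
      }
      prev_fit <- fit
    }
  }
  cm <- function(x) colMeans(x, na.rm = TRUE)
  out <- data.frame(
    K = K_range,
    n_parameters = vapply(K_range, function(k) n_parameters(cohort$schema, k),
                          integer(1)),
    ll = cm(M$ll), AIC = cm(M$AIC), BIC = cm(M$BIC), CAIC = cm(M$CAIC),
    SABIC = cm(M$SABIC), cv_ll = cm(M$cvll), entropy = cm(M$entropy),
    avepp = cm(M$avepp), smallest_class_n = cm(M$smallest_n),
    smallest_class_prop = cm(M$smallest_n) / n,
    lrt_stat = cm(M$lrt_stat), lrt_p = cm(M$lrt_p),
    n_failed = colSums(M$failed, na.rm = TRUE)
  )
  rownames(out) <- NULL
  class(out) <- c("enumeration_table", "data.frame")
  out
}
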