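# Phenotype-category "affinity" profiling: per-feature one-sided enrichment
# tests of each class against the pooled other classes (or siblings),
# Benjamini-Hochberg correction per (class, direction) family, three
# feature-exclusion rules, and signed per-category affinity proportions.

#' Completeness filter
#'
#' Drops features with completeness below `feature_threshold` across the
#' proband cohort, then drops probands with any missing value in the
#' surviving features.  Siblings are retained unchanged (their unobserved
#' instruments are missing by design and are handled downstream by explicit
#' feature lists).
#'
#' @param cohort a [phenotype_cohort()].
#' @param feature_threshold minimum fraction of non-missing proband values a
#'   feature must have (default 0.90).
#' @return The filtered [phenotype_cohort()], with attributes
#'   `dropped_features` and `dropped_individuals`.
#' @export
completeness_filter <- function(cohort, feature_threshold = 0.90) {
  pro <- cohort$data$role == "proband"
  feats <- cohort_features(cohort)
  comp <- colMeans(!is.na(feats[pro, , drop = FALSE]))
  keep_f <- names(comp)[comp >= feature_threshold]
  dropped_f <- setdiff(cohort$schema$name, keep_f)
  if (!length(keep_f)) stop("empty-cohort error: no feature passes the completeness filter")
  out <- subset_features(cohort, keep_f)
  has_na <- rowSums(is.na(out$data[, keep_f, drop = FALSE])) > 0
  drop_i <- has_na & out$data$role == "proband"
  out$data <- out$data[!drop_i, , drop = FALSE]
  if (!any(out$data$role == "proband")) {
    stop("empty-cohort error: no proband has complete data on surviving features")
  }
  attr(out, "dropped_features") <- dropped_f
  attr(out, "dropped_individuals") <- sum(drop_i)
  out
}

# Vectorised enrichment statistics.  Xnum: numeric-scored features
# (continuous + categorical-as-level-index), Xbin: binary features; `labels`
# assigns each row to a test group 1..K; `bg` optionally supplies an
# explicit background matrix pair (rows not in the groups), otherwise each
# group is tested against the pooled other groups.  Returns per (feature,
# group): upper/lower p, Cohen's d (numeric), fold enrichment (binary).
enrichment_core <- function(Xnum, Xbin, labels, K, bg_num = NULL, bg_bin = NULL,
                            welch = FALSE) {
  n_by <- tabulate(labels, K)
  G <- matrix(0, length(labels), K)
  G[cbind(seq_along(labels), labels)] <- 1
  res_num <- NULL
  if (!is.null(Xnum) && ncol(Xnum)) {
    s1 <- crossprod(G, Xnum)
    s2 <- crossprod(G, Xnum^2)
    if (is.null(bg_num)) {
      tot1 <- matrix(colSums(Xnum), K, ncol(Xnum), byrow = TRUE)
      tot2 <- matrix(colSums(Xnum^2), K, ncol(Xnum), byrow = TRUE)
      o1 <- tot1 - s1; o2 <- tot2 - s2
      n_o <- length(labels) - n_by
    } else {
      o1 <- matrix(colSums(bg_num), K, ncol(Xnum), byrow = TRUE)
      o2 <- matrix(colSums(bg_num^2), K, ncol(Xnum), byrow = TRUE)
      n_o <- rep(nrow(bg_num), K)
    }
    m1 <- s1 / n_by; m2 <- o1 / n_o
    v1 <- (s2 - n_by * m1^2) / (n_by - 1)
    v2 <- (o2 - n_o * m2^2) / (n_o - 1)
    v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
    if (welch) {
      se2 <- v1 / n_by + v2 / n_o
      tstat <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n_by)^2 / (n_by - 1) + (v2 / n_o)^2 / (n_o - 1))
    } else {
      sp2 <- ((n_by - 1) * v1 + (n_o - 1) * v2) / (n_by + n_o - 2)
      tstat <- (m1 - m2) / sqrt(sp2 * (1 / n_by + 1 / n_o))
      df <- matrix(n_by + n_o - 2, K, ncol(Xnum))
    }
    zero_var <- (v1 == 0) & (v2 == 0)
    p_up <- stats::pt(tstat, df, lower.tail = FALSE)
    p_lo <- stats::pt(tstat, df, lower.tail = TRUE)
    p_up[zero_var] <- NA; p_lo[zero_var] <- NA
    sp2_d <- ((n_by - 1) * v1 + (n_o - 1) * v2) / (n_by + n_o - 2)
    d <- (m1 - m2) / sqrt(sp2_d)
    d[zero_var] <- 0
    res_num <- list(p_upper = p_up, p_lower = p_lo, d = d,
                    mean_class = m1, mean_other = m2)
  }
  res_bin <- NULL
  if (!is.null(Xbin) && ncol(Xbin)) {
    k1 <- crossprod(G, Xbin)
    if (is.null(bg_bin)) {
      ktot <- matrix(colSums(Xbin), K, ncol(Xbin), byrow = TRUE)
      k_o <- ktot - k1
      n_o <- length(labels) - n_by
    } else {
      k_o <- matrix(colSums(bg_bin), K, ncol(Xbin), byrow = TRUE)
      n_o <- rep(nrow(bg_bin), K)
    }
    p0 <- k_o / n_o
    n1 <- matrix(n_by, K, ncol(Xbin))
    # exact binomial tails of the class count against the background rate
    p_up <- stats::pbinom(k1 - 1, n1, p0, lower.tail = FALSE)
    p_lo <- stats::pbinom(k1, n1, p0, lower.tail = TRUE)
    fe <- (k1 / n1) / p0
    res_bin <- list(p_upper = p_up, p_lower = p_lo, fe = fe,
                    prev_class = k1 / n1, prev_other = p0)
  }
  list(num = res_num, bin = res_bin, n_by = n_by)
}

#' Per-feature class enrichment tests
#'
#' For every feature and class, tests class members against the pooled other
#' classes (or against siblings): binary features use the exact binomial
#' test of the class count against the background success rate (both tails
#' reported separately); continuous and categorical features (scored by
#' level index) use one-sided independent t-tests in both directions.
#' Benjamini-Hochberg correction is applied within each (class, direction)
#' family across features.  Cohen's d uses the pooled standard deviation;
#' binary fold enrichment is the class proportion over the background
#' proportion.
#'
#' @param cohort a complete [phenotype_cohort()] (probands; may include
#'   siblings when `background = "siblings"`).
#' @param labels class labels for the proband rows (1..K).
#' @param background `"other_classes"` (default) or `"siblings"`.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return data.frame of class `feature_enrichment`: one row per (feature,
#'   class) with `p_upper`, `p_lower`, `q_upper`, `q_lower`, `cohens_d`,
#'   `fold_enrichment`, feature `type` and `category`.
#' @export
feature_enrichment <- function(cohort, labels, background = c("other_classes", "siblings"),
                               welch = FALSE) {
  background <- match.arg(background)
  pro <- cohort$data$role == "proband"
  if (length(labels) != sum(pro)) stop("labels must match the proband rows")
  K <- max(labels)
  if (K < 2 && background == "other_classes") stop("need >= 2 classes")
  if (any(tabulate(labels, K) == 0)) stop("every class must be non-empty")
  sch <- cohort$schema
  num_cols <- sch$name[sch$type %in% c("continuous", "categorical")]
  bin_cols <- sch$name[sch$type == "binary"]
  Xall <- cohort_feature_matrix(cohort)
  Xnum <- Xall[pro, num_cols, drop = FALSE]
  Xbin <- Xall[pro, bin_cols, drop = FALSE]
  bg_num <- bg_bin <- NULL
  if (background == "siblings") {
    sib <- cohort$data$role == "sibling"
    if (!any(sib)) stop("no sibling rows for sibling background")
    bg_num <- Xall[sib, num_cols, drop = FALSE]
    bg_bin <- Xall[sib, bin_cols, drop = FALSE]
  }
  core <- enrichment_core(Xnum, Xbin, labels, K, bg_num, bg_bin, welch)
  rows <- list()
  if (!is.null(core$num)) {
    rows$num <- data.frame(
      feature = rep(num_cols, each = K),
      class = rep(seq_len(K), length(num_cols)),
      p_upper = as.vector(core$num$p_upper),
      p_lower = as.vector(core$num$p_lower),
      cohens_d = as.vector(core$num$d),
      fold_enrichment = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!is.null(core$bin)) {
    rows$bin <- data.frame(
      feature = rep(bin_cols, each = K),
      class = rep(seq_len(K), length(bin_cols)),
      p_upper = as.vector(core$bin$p_upper),
      p_lower = as.vector(core$bin$p_lower),
      cohens_d = NA_real_,
      fold_enrichment = as.vector(core$bin$fe),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$type <- sch$type[match(out$feature, sch$name)]
  out$category <- sch$category[match(out$feature, sch$name)]
  out$q_upper <- NA_real_
  out$q_lower <- NA_real_
  for (k in seq_len(K)) {
    sel <- out$class == k
    out$q_upper[sel] <- stats::p.adjust(out$p_upper[sel], method = "BH")
    out$q_lower[sel] <- stats::p.adjust(out$p_lower[sel], method = "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("feature_enrichment", "data.frame")
  out
}

#' Contributory-feature exclusion rules
#'
#' Excludes features failing any of three criteria: (1) no significant
#' enrichment or depletion in any class (adjusted q below `q_threshold` in
#' at least one class and direction required); (2) continuous or categorical
#' features whose Cohen's d stays within `(-d_threshold, d_threshold)`
#' across all classes; (3) binary features with fold enrichment below
#' `fe_threshold` across all classes.
#'
#' @param enrichment a [feature_enrichment()] table.
#' @param q_threshold significance threshold on adjusted q (default 0.05).
#' @param d_threshold Cohen's d magnitude threshold (default 0.2).
#' @param fe_threshold binary fold-enrichment threshold (default 1.5).
#' @return Character vector of contributory feature names.
#' @export
feature_exclusion <- function(enrichment, q_threshold = 0.05, d_threshold = 0.2,
                              fe_threshold = 1.5) {
  by_f <- split(enrichment, enrichment$feature)
  keep <- vapply(by_f, function(e) {
    sig <- any(e$q_upper < q_threshold, na.rm = TRUE) ||
      any(e$q_lower < q_threshold, na.rm = TRUE)
    if (!sig) return(FALSE)
    if (e$type[1] == "binary") {
      max(e$fold_enrichment, na.rm = TRUE) >= fe_threshold
    } else {
      max(abs(e$cohens_d), na.rm = TRUE) >= d_threshold
    }
  }, logical(1))
  names(by_f)[keep]
}

#' Class-by-category affinity matrix
#'
#' For each class and phenotype category:
#' `(number of contributory features with upper-tail q < threshold minus
#' number with lower-tail q < threshold) / number of contributory features
#' in the category` — a signed proportion in `[-1, 1]`.  Categories with no
#' contributory features give `NA` cells.
#'
#' @param enrichment a [feature_enrichment()] table.
#' @param contributory character vector from [feature_exclusion()].
#' @param category_map named character vector or two-column data.frame
#'   (`feature`, `category`); defaults to the schema categories already in
#'   `enrichment`.
#' @param q_threshold significance threshold (default 0.05).
#' @return K x 7 matrix of class `affinity_matrix` with attributes
#'   `n_enriched`, `n_depleted`, `n_contributory` (same shape / per
#'   category).
#' @export
affinity_scores <- function(enrichment, contributory, category_map = NULL,
                            q_threshold = 0.05) {
  cats <- phenotype_categories()
  if (is.null(category_map)) {
    category_map <- stats::setNames(enrichment$category, enrichment$feature)
    category_map <- category_map[!duplicated(names(category_map))]
  } else if (is.data.frame(category_map)) {
    category_map <- stats::setNames(category_map$category, category_map$feature)
  }
  miss <- setdiff(contributory, names(category_map))
  if (length(miss)) stop("contributory feature(s) missing from the category map: ",
                         paste(miss, collapse = ", "))
  K <- max(enrichment$class)
  e <- enrichment[enrichment$feature %in% contributory, , drop = FALSE]
  e$category <- unname(category_map[e$feature])
  A <- matrix(NA_real_, K, length(cats), dimnames = list(paste0("class", seq_len(K)), cats))
  n_enr <- n_dep <- matrix(0L, K, length(cats), dimnames = dimnames(A))
  n_con <- integer(length(cats))
  names(n_con) <- cats
  for (g in seq_along(cats)) {
    feats_g <- unique(e$feature[e$category == cats[g]])
    n_con[g] <- length(feats_g)
    if (!n_con[g]) next
    sub <- e[e$category == cats[g], , drop = FALSE]
    for (k in seq_len(K)) {
      sk <- sub[sub$class == k, , drop = FALSE]
      up <- sum(sk$q_upper < q_threshold, na.rm = TRUE)
      dn <- sum(sk$q_lower < q_threshold, na.rm = TRUE)
      n_enr[k, g] <- up
      n_dep[k, g] <- dn
      A[k, g] <- (up - dn) / n_con[g]
    }
  }
  structure(A, n_enriched = n_enr, n_depleted = n_dep, n_contributory = n_con,
            class = c("affinity_matrix", "matrix", "array"))
}

#' @export
print.affinity_matrix <- function(x, digits = 2, ...) {
  cat("affinity matrix (classes x categories; +1 = all contributory features",
      "enriched, -1 = all depleted)\n")
  A <- round(unclass(x), digits)
  attributes(A)[c("n_enriched", "n_depleted", "n_contributory")] <- NULL
  print(A)
  invisible(x)
}

#' Diagnosis enrichment against the sibling background
#'
#' Per class and binary diagnosis: fold enrichment = class prevalence over
#' sibling prevalence, with a one-sided (upper) exact binomial p of the
#' class count against the sibling rate, BH-corrected across the emitted
#' family.
#'
#' @param diagnoses data.frame of binary (0/1, `NA` allowed) diagnosis
#'   columns, one row per individual.
#' @param labels class labels for probands, `NA` for siblings.
#' @param sibling_flag logical vector marking sibling rows.
#' @param pseudo_rate rate substituted when the sibling prevalence is 0
#'   (the fold enrichment is then flagged infinite; default `0.5 / n_sib`).
#' @return data.frame with one row per (class, diagnosis).
#' @export
diagnosis_enrichment <- function(diagnoses, labels, sibling_flag, pseudo_rate = NULL) {
  stopifnot(nrow(diagnoses) == length(labels), length(labels) == length(sibling_flag))
  K <- max(labels, na.rm = TRUE)
  out <- list()
  for (dx in names(diagnoses)) {
    v <- diagnoses[[dx]]
    sib_v <- v[sibling_flag & !is.na(v)]
    p_sib <- mean(sib_v)
    for (k in seq_len(K)) {
      cls_v <- v[!sibling_flag & !is.na(v) & !is.na(labels) & labels == k]
      n1 <- length(cls_v); x1 <- sum(cls_v)
      rate <- p_sib
      infinite_fe <- FALSE
      if (p_sib == 0) {
        rate <- if (is.null(pseudo_rate)) 0.5 / max(length(sib_v), 1) else pseudo_rate
        infinite_fe <- TRUE
      }
      out[[length(out) + 1L]] <- data.frame(
        diagnosis = dx, class = k, n_class = n1,
        prevalence = x1 / n1, sibling_prevalence = p_sib,
        fold_enrichment = if (infinite_fe) Inf else (x1 / n1) / p_sib,
        p = stats::pbinom(x1 - 1, n1, rate, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Class-versus-sibling feature comparisons
#'
#' For each listed feature and class: class mean, normal-approximation 95%
#' confidence interval, one-sided independent t-test against siblings, and
#' BH correction across classes within each feature.
#'
#' @param cohort a [phenotype_cohort()] containing proband and sibling rows.
#' @param labels class labels for the proband rows.
#' @param features feature names (must be observed for siblings).
#' @param alternative `"greater"` (default: class exceeds siblings) or
#'   `"less"`.
#' @param welch use Welch's t.
#' @return data.frame with one row per (feature, class) plus a sibling
#'   reference row per feature.
#' @export
group_vs_sibling_tests <- function(cohort, labels, features,
                                   alternative = c("greater", "less"),
                                   welch = FALSE) {
  alternative <- match.arg(alternative)
  pro <- cohort$data$role == "proband"
  sib <- cohort$data$role == "sibling"
  stopifnot(length(labels) == sum(pro))
  K <- max(labels)
  out <- list()
  for (f in features) {
    x_all <- as.numeric(cohort$data[[f]])
    x_sib <- x_all[sib]
    x_sib <- x_sib[!is.na(x_sib)]
    if (!length(x_sib)) {
      warning("feature skipped (no sibling data): ", f)
      next
    }
    rows <- lapply(seq_len(K), function(k) {
      x_k <- x_all[pro][labels == k]
      x_k <- x_k[!is.na(x_k)]
      m <- mean(x_k)
      sd_k <- if (length(x_k) > 1) stats::sd(x_k) else 0
      sd_s <- if (length(x_sib) > 1) stats::sd(x_sib) else 0
      se <- if (length(x_k) > 1) sd_k / sqrt(length(x_k)) else 0
      tt <- if (sd_k == 0 && sd_s == 0) {
        list(p.value = NA_real_)
      } else {
        stats::t.test(x_k, x_sib, alternative = alternative, var.equal = !welch)
      }
      data.frame(feature = f, group = paste0("class", k), n = length(x_k),
                 mean = m, ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
                 p = tt$p.value, stringsAsFactors = FALSE)
    })
    m_s <- mean(x_sib)
    se_s <- if (length(x_sib) > 1) stats::sd(x_sib) / sqrt(length(x_sib)) else 0
    rows[[K + 1]] <- data.frame(feature = f, group = "sibling", n = length(x_sib),
                                mean = m_s, ci_lower = m_s - 1.96 * se_s,
                                ci_upper = m_s + 1.96 * se_s, p = NA_real_,
                                stringsAsFactors = FALSE)
    fr <- do.call(rbind, rows)
    fr$q <- NA_real_
    is_class <- fr$group != "sibling"
    fr$q[is_class] <- stats::p.adjust(fr$p[is_class], method = "BH")
    out[[f]] <- fr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
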