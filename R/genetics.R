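# Class-stratified genetic analyses: variant classification and QC filters,
# gene-set count-burden tests, odds ratios, constraint bins, developmental
# expression (trend x cell type) enrichment, median-constraint comparison,
# hypergeometric term enrichment, and polygenic-score group contrasts.

.classify_env <- new.env(parent = emptyenv())

#' Classify variants into analysis classes
#'
#' High-confidence loss of function requires one of the seven LoF
#' consequence terms (stop gained, frameshift, splice acceptor/donor,
#' start/stop lost, transcript ablation) AND LOFTEE-style `HC` confidence;
#' damaging missense requires one of the four missense-class terms
#' (missense, inframe deletion/insertion, protein altering) AND a
#' `likely_pathogenic` missense prediction; `synonymous_variant` maps to
#' synonymous; everything else (including unknown consequence strings,
#' warned once per string) is `other`.
#'
#' @param variants a variant table (data.frame with `consequence`,
#'   `lof_confidence`, `missense_class`).
#' @return The table with an added `variant_class` column in
#'   `c("LoF_HC", "missense_damaging", "synonymous", "other")`.
#' @export
classify_variants <- function(variants) {
  cons <- variants$consequence
  known <- c(LOF_TERMS, MISSENSE_TERMS, "synonymous_variant", "intron_variant",
             "intergenic_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
             "upstream_gene_variant", "downstream_gene_variant")
  unknown <- setdiff(unique(cons), known)
  for (u in unknown) {
    if (is.null(.classify_env[[u]])) {
      warning("unknown consequence string classified as 'other': ", u)
      .classify_env[[u]] <- TRUE
    }
  }
  cls <- rep("other", nrow(variants))
  cls[cons %in% LOF_TERMS &
        !is.na(variants$lof_confidence) & variants$lof_confidence == "HC"] <- "LoF_HC"
  cls[cons %in% MISSENSE_TERMS &
        !is.na(variants$missense_class) &
        variants$missense_class == "likely_pathogenic"] <- "missense_damaging"
  cls[cons == "synonymous_variant"] <- "synonymous"
  variants$variant_class <- cls
  variants
}

#' De novo variant QC filter
#'
#' Three steps, in order: (1) exclude individuals whose total de novo count
#' exceeds the roster mean + 3 SD (computed once on the input roster,
#' zero-call individuals included); (2) remove non-singleton variants (the
#' same `variant_key` seen in more than one family) from every family;
#' (3) emit per-individual counts with explicit zeros for every roster
#' member without surviving records.
#'
#' @param variants a variant table; only `origin == "denovo"` records are
#'   filtered (others pass through untouched).
#' @param roster data.frame with `individual_id` (and optionally
#'   `family_id`) covering every individual, including zero-call ones.
#' @return List with `variants` (filtered table), `counts` (data.frame
#'   `individual_id`, `n_dnv`, zeros backfilled, outliers excluded), and
#'   `excluded` (outlier individual IDs).
#' @export
filter_de_novo <- function(variants, roster) {
  if (is.null(roster) || nrow(roster) == 0) stop("value error: empty roster")
  dn <- variants[variants$origin == "denovo", , drop = FALSE]
  tab <- table(factor(dn$individual_id, levels = roster$individual_id))
  counts0 <- as.numeric(tab)
  thr <- mean(counts0) + 3 * stats::sd(counts0)
  excluded <- roster$individual_id[counts0 > thr]
  dn <- dn[!(dn$individual_id %in% excluded), , drop = FALSE]
  # non-singleton removal: variant_key seen in more than one family
  key <- if ("variant_key" %in% names(dn)) dn$variant_key
         else paste(dn$gene, dn$consequence, sep = "|")
  fam_per_key <- tapply(dn$family_id, key, function(f) length(unique(f)))
  multi <- names(fam_per_key)[fam_per_key > 1]
  dn <- dn[!(key %in% multi), , drop = FALSE]
  keep_roster <- setdiff(roster$individual_id, excluded)
  counts <- data.frame(
    individual_id = keep_roster,
    n_dnv = as.numeric(table(factor(dn$individual_id, levels = keep_roster))),
    stringsAsFactors = FALSE)
  out <- rbind(dn, variants[variants$origin != "denovo", , drop = FALSE])
  rownames(out) <- NULL
  list(variants = out, counts = counts, excluded = excluded)
}

#' Rare-inherited variant filter
#'
#' Keeps inherited records with allele frequency below the threshold
#' (default 1%).  Records with missing allele frequency are kept and flagged
#' `rare_by_absence` (absence from the population reference is read as
#' rarity); the flagged count is reported as an attribute.  De novo records
#' pass through untouched.  Idempotent.
#'
#' @param variants a variant table.
#' @param af_threshold allele-frequency cutoff (default 0.01).
#' @return The filtered table with a logical `rare_by_absence` column and
#'   attribute `n_rare_by_absence`.
#' @export
filter_rare_inherited <- function(variants, af_threshold = 0.01) {
  inh <- variants$origin == "inherited"
  af <- variants$allele_frequency
  bad <- inh & !is.na(af) & (af < 0 | af > 1)
  if (any(bad)) {
    stop("record rejected: allele frequency outside [0,1] in ", sum(bad), " record(s)")
  }
  keep <- !inh | is.na(af) | af < af_threshold
  out <- variants[keep, , drop = FALSE]
  out$rare_by_absence <- out$origin == "inherited" & is.na(out$allele_frequency)
  attr(out, "n_rare_by_absence") <- sum(out$rare_by_absence)
  rownames(out) <- NULL
  out
}

#' Per-individual variant counts with zero backfill
#'
#' Counts surviving records per individual for one variant class,
#' optionally restricted to a gene set, with explicit zeros for every
#' roster member without records.
#'
#' @param variants a classified variant table (see [classify_variants()]).
#' @param roster data.frame with `individual_id`.
#' @param variant_class one of `"LoF_HC"`, `"missense_damaging"`,
#'   `"synonymous"`, `"other"`, or `NULL` for all records.
#' @param origin `"denovo"`, `"inherited"`, or `NULL` for both.
#' @param gene_set optional character vector of genes to restrict to.
#' @return data.frame `individual_id`, `count`.
#' @export
count_variants <- function(variants, roster, variant_class = NULL, origin = NULL,
                           gene_set = NULL) {
  v <- variants
  if (!is.null(variant_class)) v <- v[v$variant_class %in% variant_class, , drop = FALSE]
  if (!is.null(origin)) v <- v[v$origin == origin, , drop = FALSE]
  if (!is.null(gene_set)) v <- v[v$gene %in% gene_set, , drop = FALSE]
  data.frame(
    individual_id = roster$individual_id,
    count = as.numeric(table(factor(v$individual_id, levels = roster$individual_id))),
    stringsAsFactors = FALSE)
}

#' Count-burden test of proband groups against siblings
#'
#' Per proband group: mean count per offspring, standard error
#' (`sd / sqrt(n)`), fold enrichment of means versus the sibling group, a
#' one-sided independent t-test (default direction: group exceeds
#' siblings), and BH correction across the proband groups.
#'
#' @param counts data.frame with `count` and `group` columns; `group` is a
#'   character/factor with the sibling level among them.
#' @param sibling_level name of the sibling group (default `"sibling"`).
#' @param alternative `"greater"` (default) or `"less"`.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return data.frame of class `burden_result`, one row per proband group
#'   plus a sibling reference row.
#' @export
burden_test <- function(counts, sibling_level = "sibling",
                        alternative = c("greater", "less"), welch = FALSE) {
  alternative <- match.arg(alternative)
  grp <- as.character(counts$group)
  sib <- counts$count[grp == sibling_level]
  if (!length(sib)) stop("sibling group is empty")
  groups <- setdiff(unique(grp), sibling_level)
  sib_mean <- mean(sib)
  rows <- lapply(groups, function(g) {
    x <- counts$count[grp == g]
    m <- mean(x)
    fe <- if (sib_mean == 0) Inf else m / sib_mean
    p <- if (stats::sd(x) == 0 && stats::sd(sib) == 0) {
      if (m == sib_mean) 0.5 else NA_real_
    } else {
      stats::t.test(x, sib, alternative = alternative,
                    var.equal = !welch)$p.value
    }
    data.frame(group = g, n = length(x), mean = m,
               se = stats::sd(x) / sqrt(length(x)),
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- rbind(res, data.frame(group = sibling_level, n = length(sib),
                               mean = sib_mean,
                               se = stats::sd(sib) / sqrt(length(sib)),
                               fold_enrichment = 1, p = NA_real_, q = NA_real_))
  rownames(res) <- NULL
  class(res) <- c("burden_result", "data.frame")
  res
}

#' Carrier odds ratios per class and gene set
#'
#' For each proband class: the 2x2 table of carrier/non-carrier (an
#' individual with at least one qualifying variant in the gene set) by
#' class/siblings; odds ratio `(a/b)/(c/d)` with a Haldane-Anscombe +0.5 on
#' every cell when any cell is zero; one-sided Fisher exact p (upper tail);
#' BH across classes.
#'
#' @param carrier logical vector, one element per individual.
#' @param group character vector of the same length: class labels and the
#'   sibling level.
#' @param sibling_level name of the control group.
#' @param alternative `"greater"` (default) or `"less"`.
#' @return data.frame of class `or_result`: per group `a, b, c, d`,
#'   `odds_ratio`, `p`, `q`.
#' @export
odds_ratio_test <- function(carrier, group, sibling_level = "sibling",
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  grp <- as.character(group)
  stopifnot(length(carrier) == length(grp))
  sib <- grp == sibling_level
  if (!any(sib)) stop("value error: sibling group has zero members")
  c_cnt <- sum(carrier[sib]); d_cnt <- sum(!carrier[sib])
  groups <- setdiff(unique(grp), sibling_level)
  rows <- lapply(groups, function(g) {
    sel <- grp == g
    if (!any(sel)) stop("value error: group has zero members: ", g)
    a <- sum(carrier[sel]); b <- sum(!carrier[sel])
    cells <- c(a, b, c_cnt, d_cnt)
    or <- if (any(cells == 0)) {
      ((a + 0.5) / (b + 0.5)) / ((c_cnt + 0.5) / (d_cnt + 0.5))
    } else (a / b) / (c_cnt / d_cnt)
    p <- stats::fisher.test(matrix(c(a, b, c_cnt, d_cnt), 2, byrow = TRUE),
                            alternative = alternative)$p.value
    data.frame(group = g, a = a, b = b, c = c_cnt, d = d_cnt,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  class(res) <- c("or_result", "data.frame")
  res
}

#' Constraint bin from a pLI score
#'
#' `high` for pLI >= 0.995, `intermediate` for 0.5 <= pLI < 0.995, `none`
#' otherwise.
#'
#' @param pli numeric vector in `[0, 1]`.
#' @return Character vector of bins.
#' @export
constraint_bin <- function(pli) {
  if (any(is.na(pli)) || any(pli < 0 | pli > 1)) {
    stop("value error: pLI must lie in [0, 1]")
  }
  ifelse(pli >= 0.995, "high", ifelse(pli >= 0.5, "intermediate", "none"))
}

#' Developmental-expression (trend x cell type) burden enrichment
#'
#' Applies the count-burden test per devDEG gene set (keyed
#' `"<trend>|<celltype>"`) for every proband class and for the pooled
#' proband group, against siblings; BH correction within each gene set.
#'
#' @param variants a classified, de novo-filtered variant table.
#' @param roster data.frame `individual_id`, `group` (class labels +
#'   sibling level) covering every analysed individual.
#' @param devdeg named list of gene vectors keyed `"<trend>|<celltype>"`.
#' @param variant_class counted class (default `"LoF_HC"`).
#' @param sibling_level control group name.
#' @return data.frame: per (group incl. `"pooled"`, trend, celltype) n,
#'   mean, se, fold enrichment, p, q.
#' @export
devdeg_enrichment <- function(variants, roster, devdeg, variant_class = "LoF_HC",
                              sibling_level = "sibling") {
  out <- list()
  for (nm in names(devdeg)) {
    genes <- devdeg[[nm]]
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    cnt <- count_variants(variants, roster, variant_class = variant_class,
                          origin = "denovo", gene_set = genes)
    cnt$group <- roster$group
    pooled <- cnt
    pooled$group <- ifelse(pooled$group == sibling_level, sibling_level, "pooled")
    if (!length(genes)) {
      out[[nm]] <- data.frame(group = NA_character_, trend = parts[1],
                              celltype = parts[2], n = 0, mean = NA_real_,
                              se = NA_real_, fold_enrichment = NA_real_,
                              p = NA_real_, q = NA_real_)
      next
    }
    bt <- burden_test(cnt, sibling_level = sibling_level)
    bp <- burden_test(pooled, sibling_level = sibling_level)
    res <- rbind(bt[bt$group != sibling_level, ],
                 bp[bp$group == "pooled", ])
    res$q <- stats::p.adjust(res$p, method = "BH")  # per gene set
    res$trend <- parts[1]
    res$celltype <- parts[2]
    out[[nm]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-tailed Mood's median test on pLI scores of two gene lists
#'
#' Pools the two groups' pLI values, takes the grand median, builds the 2x2
#' table of (above grand median / at-or-below) by group (ties count as
#' at-or-below), and evaluates a one-sided Fisher exact p in the declared
#' direction (`"greater"`: group B's pLI distribution lies above group A's).
#'
#' @param genes_a,genes_b character vectors of gene IDs (non-empty).
#' @param pli named numeric vector of pLI scores.
#' @param alternative `"greater"` (default) or `"less"`, declared direction
#'   for group B relative to group A.
#' @return List with `median_a`, `median_b`, `grand_median`, `table`, `p`,
#'   and `degenerate` flag (all values equal; p = 1).
#' @export
pli_median_test <- function(genes_a, genes_b, pli,
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  a <- pli[genes_a]; b <- pli[genes_b]
  if (!length(a) || !length(b) || anyNA(a) || anyNA(b)) {
    stop("both gene lists must be non-empty with pLI available")
  }
  pooled <- c(a, b)
  gm <- stats::median(pooled)
  tab <- matrix(c(sum(b > gm), sum(b <= gm),
                  sum(a > gm), sum(a <= gm)), 2, byrow = TRUE,
                dimnames = list(c("B", "A"), c("above", "at_or_below")))
  if (length(unique(pooled)) == 1) {
    return(list(median_a = gm, median_b = gm, grand_median = gm, table = tab,
                p = 1, degenerate = TRUE))
  }
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(median_a = stats::median(a), median_b = stats::median(b),
       grand_median = gm, table = tab, p = p, degenerate = FALSE)
}

#' Hypergeometric term enrichment
#'
#' For each term set with `K_t` background genes of which `k` overlap the
#' `n` impacted genes out of `N` background genes: fold enrichment
#' `(k/n) / (K_t/N)` and upper-tail hypergeometric `P(X >= k)`, with BH
#' correction across terms.  Results are sorted by q then fold enrichment.
#'
#' @param impacted character vector of impacted genes (subset of
#'   background, non-empty).
#' @param term_sets named list of term gene vectors (each a subset of
#'   background).
#' @param background character vector: the gene universe.
#' @return data.frame per term: `n_term`, `n_overlap`, `fold_enrichment`,
#'   `p`, `q`.
#' @export
hypergeom_enrichment <- function(impacted, term_sets, background) {
  if (!length(impacted)) stop("value error: no impacted genes")
  if (!all(impacted %in% background)) stop("impacted genes must lie in the background")
  N <- length(background)
  n <- length(unique(impacted))
  rows <- lapply(names(term_sets), function(nm) {
    term <- unique(term_sets[[nm]])
    if (!all(term %in% background)) stop("term set outside the background: ", nm)
    Kt <- length(term)
    k <- length(intersect(impacted, term))
    fe <- (k / n) / (Kt / N)
    p <- stats::phyper(k - 1, Kt, N - Kt, n, lower.tail = FALSE)
    data.frame(term = nm, n_term = Kt, n_overlap = k, fold_enrichment = fe,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$q, -res$fold_enrichment), ]
  rownames(res) <- NULL
  res
}

#' Polygenic-score group comparison
#'
#' Per trait: least-squares residualisation of the scores on (intercept,
#' sex, ancestry PCs) over all individuals; residuals centred by the
#' sibling mean and (by default) scaled by the sibling SD; per-class
#' two-sided t-test against siblings, BH across (class, trait).
#'
#' @param pgs data.frame from [generate_pgs_table()] or equivalent: columns
#'   `individual_id`, `role`, `sex`, `PC*`, and one column per trait.
#' @param labels class labels, one per `pgs` row (`NA` for siblings).
#' @param traits character vector of trait column names.
#' @param scale_by_sibling_sd if `FALSE`, centre on the sibling mean only.
#' @return data.frame per (group, trait): n, normalised mean, 95% CI, p, q.
#' @export
pgs_compare <- function(pgs, labels, traits, scale_by_sibling_sd = TRUE) {
  stopifnot(length(labels) == nrow(pgs))
  sib <- pgs$role == "sibling"
  pc_cols <- grep("^PC[0-9]+$", names(pgs), value = TRUE)
  Zc <- as.matrix(cbind(intercept = 1, sex = pgs$sex,
                        pgs[, pc_cols, drop = FALSE]))
  qr_z <- qr(Zc)
  if (qr_z$rank < ncol(Zc)) {
    dropped <- colnames(Zc)[qr_z$pivot[(qr_z$rank + 1):ncol(Zc)]]
    stop("singular covariate design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  K <- max(labels, na.rm = TRUE)
  out <- list()
  for (tr in traits) {
    y <- pgs[[tr]]
    resid <- qr.resid(qr_z, y)
    ctr <- mean(resid[sib])
    scl <- if (scale_by_sibling_sd) stats::sd(resid[sib]) else 1
    z <- (resid - ctr) / scl
    for (k in seq_len(K)) {
      x <- z[!sib & !is.na(labels) & labels == k]
      m <- mean(x)
      se <- stats::sd(x) / sqrt(length(x))
      p <- stats::t.test(x, z[sib])$p.value
      out[[paste(tr, k)]] <- data.frame(
        trait = tr, group = paste0("class", k), n = length(x),
        mean = m, ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
        p = p, stringsAsFactors = FALSE)
    }
    out[[paste(tr, "sib")]] <- data.frame(
      trait = tr, group = "sibling", n = sum(sib), mean = mean(z[sib]),
      ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$q <- NA_real_
  is_class <- res$group != "sibling"
  res$q[is_class] <- stats::p.adjust(res$p[is_class], method = "BH")
  rownames(res) <- NULL
  res
}
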