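# Orchestration: the two pipeline stages composing the phenotype analysis
# (completeness filter -> mixture fit / enumeration -> feature enrichment ->
# exclusion -> affinity) and the genetics analyses (variant QC -> burden /
# OR / constraint / devDEG / term enrichment / PGS).  The numbered scripts
# under analysis/ are thin drivers over these functions.

#' Run the phenotype stage
#'
#' Applies the completeness filter, fits the mixture model at `K` (and
#' optionally enumerates a K range first), computes feature enrichment,
#' applies the contributory-feature exclusion rules, and builds the
#' class-by-category affinity matrix.  Deterministic under a fixed seed.
#'
#' @param cohort a [phenotype_cohort()].
#' @param K number of classes for the final fit.
#' @param K_range optional integer vector; when given, an
#'   [enumerate_models()] table is included in the result.
#' @param n_init random restarts for the final fit.
#' @param completeness feature-completeness threshold.
#' @param seed integer seed.
#' @param out_dir optional directory; when given, artifacts are written as
#'   TSV/JSON (cohort kept untouched) together with a small run manifest.
#' @param ... further arguments to [gfmm_fit()].
#' @return List with `cohort` (filtered), `fit`, `labels`, `enrichment`,
#'   `contributory`, `affinity`, and optionally `enumeration`.
#' @export
run_phenotype_stage <- function(cohort, K = 4, K_range = NULL, n_init = 20,
                                completeness = 0.90, seed = 1L, out_dir = NULL,
                                ...) {
  cohort <- completeness_filter(cohort, completeness)
  enum <- NULL
  if (!is.null(K_range)) {
    enum <- enumerate_models(cohort_probands(cohort), K_range, n_init = n_init,
                             seed = seed, ...)
  }
  pro <- cohort_probands(cohort)
  fit <- gfmm_fit(pro, K = K, n_init = n_init, seed = seed, ...)
  enr <- feature_enrichment(pro, fit$labels)
  contrib <- feature_exclusion(enr)
  aff <- affinity_scores(enr, contrib)
  res <- list(cohort = cohort, fit = fit, labels = fit$labels,
              enrichment = enr, contributory = contrib, affinity = aff,
              enumeration = enum)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_json(fit, file.path(out_dir, "model.json"))
    utils::write.table(enr, file.path(out_dir, "feature_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(affinity_long(aff), file.path(out_dir, "affinity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enum)) {
      utils::write.table(enum, file.path(out_dir, "enumeration.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(out_dir, list(stage = "phenotype", K = K, n_init = n_init,
                                 seed = seed,
                                 n_probands = sum(cohort$data$role == "proband"),
                                 n_features = nrow(cohort$schema),
                                 contributory = length(contrib)))
  }
  res
}

cohort_probands <- function(cohort) {
  phenotype_cohort(cohort$data[cohort$data$role == "proband", , drop = FALSE],
                   cohort$schema)
}

#' Long (heatmap-ready) form of an affinity matrix
#'
#' @param affinity an [affinity_scores()] matrix.
#' @return data.frame `class`, `category`, `affinity`.
#' @export
affinity_long <- function(affinity) {
  data.frame(
    class = rep(rownames(affinity), ncol(affinity)),
    category = rep(colnames(affinity), each = nrow(affinity)),
    affinity = as.vector(unclass(affinity)),
    stringsAsFactors = FALSE)
}

#' Run the genetics stage
#'
#' Classifies variants, applies the de novo QC and rare-inherited filters,
#' and computes: count burdens per variant class and gene set, carrier odds
#' ratios, constraint-bin burdens, devDEG (trend x cell type) enrichment,
#' hypergeometric term enrichment of impacted genes, and polygenic-score
#' contrasts (when a PGS table is supplied).
#'
#' @param variants a variant table (e.g. [generate_variant_table()]).
#' @param cohort the matching [phenotype_cohort()].
#' @param labels class labels for the proband rows (defaults to
#'   `true_class`).
#' @param annotations a `gene_annotations` object.
#' @param pgs optional PGS table; `pgs_traits` names its trait columns.
#' @param pgs_traits character vector of trait columns in `pgs`.
#' @param af_threshold rare-inherited allele-frequency cutoff.
#' @param out_dir optional output directory for tidy TSV artifacts.
#' @return List of result tables: `burden` (per gene set x variant class),
#'   `odds_ratios`, `constraint`, `devdeg`, `term_enrichment`, `pgs`,
#'   `dnv_counts`, `excluded_individuals`.
#' @export
run_genetics_stage <- function(variants, cohort, labels = NULL, annotations,
                               pgs = NULL, pgs_traits = NULL,
                               af_threshold = 0.01, out_dir = NULL) {
  dat <- cohort$data
  if (is.null(labels)) labels <- dat$true_class[dat$role == "proband"]
  if (!any(dat$role == "proband")) stop("value error: no proband rows")
  group <- character(nrow(dat))
  group[dat$role == "sibling"] <- "sibling"
  group[dat$role == "proband"] <- as.character(labels)
  roster <- data.frame(individual_id = dat$individual_id, group = group,
                       stringsAsFactors = FALSE)
  v <- classify_variants(variants)
  dn <- filter_de_novo(v, roster)
  v_dn <- dn$variants[dn$variants$origin == "denovo", , drop = FALSE]
  v_inh <- filter_rare_inherited(v[v$origin == "inherited", , drop = FALSE],
                                 af_threshold)
  roster_kept <- roster[!(roster$individual_id %in% dn$excluded), , drop = FALSE]
  pli <- stats::setNames(annotations$pli$pli, annotations$pli$gene)
  gene_sets <- annotations$gene_sets
  bins <- constraint_bin(pli)
  gene_sets$pli_high <- names(pli)[bins == "high"]
  gene_sets$pli_intermediate <- names(pli)[bins == "intermediate"]

  burden <- list()
  ors <- list()
  specs <- expand.grid(set = names(gene_sets),
                       vc = c("LoF_HC", "missense_damaging", "synonymous"),
                       origin = c("denovo", "inherited"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    tab <- if (s$origin == "denovo") v_dn else v_inh
    cnt <- count_variants(tab, roster_kept, variant_class = s$vc,
                          origin = s$origin, gene_set = gene_sets[[s$set]])
    cnt$group <- roster_kept$group
    bt <- burden_test(cnt)
    bt$gene_set <- s$set; bt$variant_class <- s$vc; bt$origin <- s$origin
    burden[[i]] <- bt
    or <- odds_ratio_test(cnt$count > 0, cnt$group)
    or$gene_set <- s$set; or$variant_class <- s$vc; or$origin <- s$origin
    ors[[i]] <- or
  }
  burden <- do.call(rbind, burden)
  ors <- do.call(rbind, ors)

  devdeg <- devdeg_enrichment(v_dn, roster_kept, annotations$devdeg)

  impacted_by_class <- lapply(sort(unique(labels)), function(k) {
    ids <- dat$individual_id[dat$role == "proband"][labels == k]
    unique(v_dn$gene[v_dn$individual_id %in% ids &
                       v_dn$variant_class %in% c("LoF_HC", "missense_damaging")])
  })
  term <- do.call(rbind, lapply(seq_along(impacted_by_class), function(k) {
    imp <- impacted_by_class[[k]]
    if (!length(imp)) return(NULL)
    te <- hypergeom_enrichment(imp, annotations$gene_sets, annotations$pli$gene)
    te$class <- k
    te
  }))

  pgs_res <- NULL
  if (!is.null(pgs)) {
    lab_full <- rep(NA_integer_, nrow(pgs))
    m <- match(pgs$individual_id, dat$individual_id[dat$role == "proband"])
    lab_full[!is.na(m)] <- labels[m[!is.na(m)]]
    pgs_res <- pgs_compare(pgs, lab_full, pgs_traits)
  }

  res <- list(burden = burden, odds_ratios = ors, devdeg = devdeg,
              term_enrichment = term, pgs = pgs_res, dnv_counts = dn$counts,
              excluded_individuals = dn$excluded,
              n_rare_by_absence = attr(v_inh, "n_rare_by_absence"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("burden", "odds_ratios", "devdeg", "term_enrichment", "pgs")) {
      if (!is.null(res[[nm]])) {
        utils::write.table(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write_manifest(out_dir, list(stage = "genetics",
                                 n_variants = nrow(v),
                                 n_excluded = length(dn$excluded),
                                 af_threshold = af_threshold))
  }
  res
}

write_manifest <- function(out_dir, info) {
  info$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  info$package_version <- tryCatch(
    as.character(utils::packageVersion("mixphen")),
    error = function(e) NA_character_)
  jsonlite::write_json(info, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
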