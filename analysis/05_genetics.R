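#!/usr/bin/env Rscript
# Stage 5 — class-stratified genetic analyses.
#
# Runs the full genetics stage over the fitted class labels: variant
# classification, de novo QC (>3SD outlier exclusion, non-singleton
# removal, zero backfill), rare-inherited AF filter, per-gene-set count
# burdens and carrier odds ratios, constraint-bin burdens, devDEG
# (trend x cell type) enrichment, hypergeometric term enrichment of
# impacted genes, a pLI median comparison between two classes, and
# polygenic-score contrasts.

library(mixphen)

out <- "results/demo"
cohort <- read_cohort_tsv(file.path(out, "cohort.tsv"))
labels_df <- utils::read.table(file.path(out, "labels.tsv"), header = TRUE,
                               sep = "\t")
variants <- read_variants_tsv(file.path(out, "variants.tsv"))
ann <- read_annotations(file.path(out, "annotations"))
pgs <- utils::read.table(file.path(out, "pgs.tsv"), header = TRUE, sep = "\t")

# align labels to the (unfiltered) cohort probands; individuals dropped by
# the completeness filter keep their generator class for the genetic arm
lab <- labels_df$class[match(cohort$data$individual_id[cohort$data$role == "proband"],
                             labels_df$individual_id)]
lab[is.na(lab)] <- cohort$data$true_class[cohort$data$role == "proband"][is.na(lab)]

res <- run_genetics_stage(variants, cohort, labels = lab, annotations = ann,
                          pgs = pgs, pgs_traits = c("asd", "adhd", "edu"),
                          out_dir = out)
message(sprintf("de novo QC: %d individuals excluded as >3SD outliers; %d rare-by-absence inherited records",
                length(res$excluded_individuals), res$n_rare_by_absence))

b <- res$burden
top <- b[b$gene_set == "all_protein_coding" & b$variant_class == "LoF_HC" &
           b$origin == "denovo" & b$group != "sibling", ]
message("dnLoF burden per class (all protein-coding genes):")
print(top[, c("group", "n", "mean", "se", "fold_enrichment", "p", "q")],
      digits = 3)

or_hi <- res$odds_ratios[res$odds_ratios$gene_set == "pli_high" &
                           res$odds_ratios$variant_class == "LoF_HC" &
                           res$odds_ratios$origin == "denovo", ]
message("dnLoF carrier odds ratios in high-constraint genes (pLI >= 0.995):")
print(or_hi[, c("group", "a", "b", "odds_ratio", "p", "q")], digits = 3)

# pLI median comparison between the two classes with the largest dnLoF
# burden, on genes hit by dnLoF variants
v <- classify_variants(variants)
pli <- stats::setNames(ann$pli$pli, ann$pli$gene)
pro_ids <- cohort$data$individual_id[cohort$data$role == "proband"]
genes_of <- function(k) unique(v$gene[v$individual_id %in% pro_ids[lab == k] &
                                        v$variant_class == "LoF_HC"])
ord <- order(top$fold_enrichment, decreasing = TRUE)
kA <- as.integer(top$group[ord[2]]); kB <- as.integer(top$group[ord[1]])
mt <- pli_median_test(genes_of(kA), genes_of(kB), pli)
message(sprintf("pLI medians: class %d = %.2f vs class %d = %.2f (one-tailed Mood's median p = %.3g)",
                kA, mt$median_a, kB, mt$median_b, mt$p))

sig_dev <- res$devdeg[!is.na(res$devdeg$q) & res$devdeg$q < 0.05 &
                        res$devdeg$group != "sibling", ]
message(sprintf("devDEG cells with q < 0.05: %d", nrow(sig_dev)))
message("PGS contrasts (normalized to sibling mean/SD):")
print(res$pgs[res$pgs$group != "sibling",
              c("trait", "group", "mean", "p", "q")], digits = 3)
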