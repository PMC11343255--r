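#!/usr/bin/env Rscript
# Stage 3 — phenotype-category affinity profiles and external validation.
#
# Tests every feature for enrichment/depletion in each class against the
# pooled other classes, applies the three contributory-feature exclusion
# rules, builds the signed class-by-category affinity matrix, and runs the
# two external validations: binary "diagnosis" enrichment against siblings
# and class-versus-sibling comparisons on the sibling-observed features.

library(mixphen)

out <- "results/demo"
cohort <- completeness_filter(read_cohort_tsv(file.path(out, "cohort.tsv")))
labels <- utils::read.table(file.path(out, "labels.tsv"), header = TRUE,
                            sep = "\t")$class
probands <- phenotype_cohort(cohort$data[cohort$data$role == "proband", ],
                             cohort$schema)

enr <- feature_enrichment(probands, labels)
contrib <- feature_exclusion(enr)
message(sprintf("%d of %d features contributory after exclusion",
                length(contrib), nrow(cohort$schema)))
utils::write.table(enr, file.path(out, "feature_enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

aff <- affinity_scores(enr, contrib)
utils::write.table(affinity_long(aff), file.path(out, "affinity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("class-by-category affinity (rows = classes):")
print(round(unclass(aff), 2))

# external validation 1: binary co-occurring "diagnoses" simulated from the
# generator classes (not used in training), tested against siblings
set.seed(31)
dat <- cohort$data
k_of <- ifelse(dat$role == "proband", labels[match(dat$individual_id,
               probands$data$individual_id)], NA)
dx_rate <- c(0.10, 0.45, 0.35, 0.25)  # per-class diagnosis rates; sibs 0.05
dx <- data.frame(
  adhd_like = rbinom(nrow(dat), 1, ifelse(is.na(k_of), 0.05, dx_rate[k_of])))
diag_res <- diagnosis_enrichment(dx, k_of, dat$role == "sibling")
utils::write.table(diag_res, file.path(out, "diagnosis_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("diagnosis enrichment vs siblings:")
print(diag_res[, c("class", "fold_enrichment", "p", "q")], digits = 3)

# external validation 2: sibling-observed features (social/communication
# binary items and milestone ages), class vs sibling
sib_feats <- cohort$schema$name[cohort$schema$category %in%
  c("limited social/communication", "developmental delay")][1:6]
gvs <- group_vs_sibling_tests(cohort, labels, sib_feats)
utils::write.table(gvs, file.path(out, "class_vs_sibling.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("class-vs-sibling tests written for ", length(sib_feats), " features")
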