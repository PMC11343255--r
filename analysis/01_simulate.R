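#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohorts.
#
# Builds the demonstration dataset every later stage consumes: a proband
# cohort with four latent phenotype classes over 60 mixed-type features
# (milestone ages, t-score scales, binary questionnaire items, 0-3
# categorical items), a sibling cohort observed only on the
# social/communication and developmental-delay instruments, a smaller
# replication cohort sharing a feature subset, a variant table with
# class-dependent de novo / rare-inherited rates, gene annotations
# (pLI, gene sets, devDEG memberships), and a polygenic-score table.

library(mixphen)

out <- "results/demo"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20240816

spec <- demo_spec(n_individuals = 2000, n_siblings = 1000, separation = 2,
                  seed = seed)
cohort <- generate_cohort(spec)
write_cohort_tsv(cohort, file.path(out, "cohort.tsv"))
message(sprintf("cohort: %d probands, %d siblings, %d features",
                sum(cohort$data$role == "proband"),
                sum(cohort$data$role == "sibling"), nrow(cohort$schema)))

# replication cohort: 40 of the 60 features, smaller n (mirrors an
# independent cohort sharing a questionnaire subset)
common <- spec$schema$name[c(1:14, 21:30, 31:42, 57:60)]
replication <- generate_replication_cohort(spec, common, n_individuals = 600,
                                           seed = seed + 1)
write_cohort_tsv(replication, file.path(out, "replication.tsv"))
message(sprintf("replication cohort: %d individuals, %d shared features",
                nrow(replication$data), nrow(replication$schema)))

# genetics: gene universe, annotations, class-dependent variant rates
gspec <- genetic_spec(n_genes = 400, n_classes = 4, seed = seed + 2)
variants <- generate_variant_table(cohort, gspec)
write_variants_tsv(variants, file.path(out, "variants.tsv"))
ann <- generate_gene_annotations(gspec)
write_annotations(ann, file.path(out, "annotations"))
message(sprintf("variants: %d records over %d genes (%.1f%% of offspring with zero de novo calls forced)",
                nrow(variants), length(gspec$genes), 100 * gspec$frac_zero_dnv))

# polygenic scores: one class shifted on an autism-like trait, one on an
# ADHD-like trait; siblings draw from the reference distribution
shifts <- matrix(0, 4, 3, dimnames = list(NULL, c("asd", "adhd", "edu")))
shifts[1, "asd"] <- 0.4    # moderate-challenges-like class: highest ASD PGS
shifts[3, "adhd"] <- 0.35  # social/behavioral-like class: highest ADHD PGS
shifts[c(2, 4), "edu"] <- -0.3  # DD classes: depleted educational attainment
pgs <- generate_pgs_table(cohort, traits = colnames(shifts),
                          class_shifts = shifts, n_pcs = 6, seed = seed + 3)
utils::write.table(pgs, file.path(out, "pgs.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("PGS table written for traits: ", paste(colnames(shifts), collapse = ", "))
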