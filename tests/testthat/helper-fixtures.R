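# Shared fixtures: tiny schemas, cohorts and variant tables built in code.

tiny_schema <- function(n_cont = 2, n_bin = 2, n_cat = 1, n_levels = 4) {
  feature_schema(
    name = c(sprintf("cont_%d", seq_len(n_cont)),
             sprintf("bin_%d", seq_len(n_bin)),
             sprintf("cat_%d", seq_len(n_cat))),
    type = rep(c("continuous", "binary", "categorical"), c(n_cont, n_bin, n_cat)),
    n_levels = c(rep(NA, n_cont + n_bin), rep(n_levels, n_cat)),
    category = rep(phenotype_categories()[seq_len(3)],
                   length.out = n_cont + n_bin + n_cat)
  )
}

tiny_spec <- function(n = 400, K = 2, separation = 3, seed = 1, n_siblings = 0,
                      schema = tiny_schema(), ...) {
  cohort_spec(n_individuals = n, n_classes = K, n_siblings = n_siblings,
              schema = schema, separation = separation, seed = seed, ...)
}

# Hand-buildable cohort from explicit feature columns (all probands).
manual_cohort <- function(feats, schema, sex = NULL, age = NULL, role = NULL) {
  n <- nrow(feats)
  dat <- data.frame(
    individual_id = sprintf("i%03d", seq_len(n)),
    family_id = sprintf("f%03d", seq_len(n)),
    role = if (is.null(role)) rep("proband", n) else role,
    sex = if (is.null(sex)) rep(0, n) else sex,
    age_years = if (is.null(age)) rep(10, n) else age,
    true_class = NA_integer_,
    stringsAsFactors = FALSE
  )
  phenotype_cohort(cbind(dat, feats), schema)
}

# Minimal variant record constructor.
vrec <- function(individual_id, gene = "G1", origin = "denovo",
                 consequence = "stop_gained", lof_confidence = "HC",
                 missense_class = NA_character_, allele_frequency = NA_real_,
                 family_id = paste0("f_", individual_id),
                 variant_key = paste0(gene, ":1")) {
  data.frame(individual_id = individual_id, family_id = family_id, gene = gene,
             origin = origin, consequence = consequence,
             lof_confidence = lof_confidence, missense_class = missense_class,
             allele_frequency = allele_frequency, variant_key = variant_key,
             stringsAsFactors = FALSE)
}
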