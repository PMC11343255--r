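# Synthetic-cohort generators: phenotype cohorts with known latent classes,
# replication cohorts on shared features, class-dependent variant tables,
# gene annotations, and polygenic-score tables.  Every generator is
# deterministic given its seed, so downstream stages can be tested against
# ground truth without any external data.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a synthetic phenotype cohort
#'
#' Defines the ground-truth generative model for a cohort: latent class
#' mixing proportions (or covariate-logit coefficients), a mixed-type feature
#' schema, per-class per-feature effects scaled by a global `separation`
#' knob, a covariate model (age in years, sex as 0/1), and a
#' missing-completely-at-random rate.  `separation = 0` makes all classes
#' identically distributed (the null used for type-I-error suites).
#'
#' Class-conditional families mirror the mixture model itself: Gaussian for
#' continuous features (mean shifted by `separation * effect`, in SD units),
#' Bernoulli for binary (logit shifted), multinomial for categorical
#' (log-linear tilt across levels).
#'
#' @param n_individuals number of probands.
#' @param n_classes number of latent classes K.
#' @param n_siblings number of non-autistic siblings (drawn from the
#'   reference, zero-effect distribution; only social/communication and
#'   developmental-delay features are observed for siblings).
#' @param mixing K class probabilities (summing to 1), ignored when
#'   `mixing_coef` is given.
#' @param mixing_coef optional 3 x K matrix of multinomial-logit coefficients
#'   on (intercept, sex, age) defining covariate-dependent class priors;
#'   column 1 is the reference class and is forced to zero.
#' @param schema a [feature_schema()]; may carry optional columns
#'   `base_mean`, `base_sd` (continuous; defaults 0/1) and `base_p`
#'   (binary; default 0.3).
#' @param class_effects K x n_features matrix of effects; default assigns
#'   each feature one "elevated" class in round-robin order (effect 1 there,
#'   0 elsewhere).
#' @param separation non-negative scale applied to all class effects.
#' @param age_mean,age_sd age model in years (defaults emulate a school-age
#'   cohort, mean 8.56, SD 3.15, truncated to 4-18).
#' @param sex_prob probability of sex = 1.
#' @param missingness scalar or per-feature vector of MCAR missing
#'   probabilities.
#' @param truncate_at_zero if `TRUE`, continuous features are truncated at 0
#'   (months-scale milestone emulation; a deliberate misspecification toggle,
#'   off by default).
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals, n_classes, n_siblings = 0,
                        mixing = NULL, mixing_coef = NULL,
                        schema, class_effects = NULL, separation = 1,
                        age_mean = 8.56, age_sd = 3.15, sex_prob = 0.774,
                        missingness = 0, truncate_at_zero = FALSE, seed = 1L) {
  stopifnot(n_individuals >= 1, n_classes >= 1, n_siblings >= 0)
  if (separation < 0) stop("value error: separation must be non-negative")
  validate_schema(schema)
  K <- as.integer(n_classes)
  d <- nrow(schema)
  if (is.null(mixing)) mixing <- rep(1 / K, K)
  if (length(mixing) != K) stop("value error: mixing must have length n_classes")
  if (abs(sum(mixing) - 1) > 1e-12) stop("value error: mixing must sum to 1")
  if (!is.null(mixing_coef)) {
    mixing_coef <- as.matrix(mixing_coef)
    stopifnot(nrow(mixing_coef) == 3, ncol(mixing_coef) == K)
    mixing_coef[, 1] <- 0
  }
  if (is.null(class_effects)) {
    class_effects <- matrix(0, K, d)
    if (K > 1) for (j in seq_len(d)) class_effects[((j - 1) %% K) + 1, j] <- 1
  }
  class_effects <- as.matrix(class_effects)
  stopifnot(nrow(class_effects) == K, ncol(class_effects) == d)
  if (length(missingness) == 1) missingness <- rep(missingness, d)
  stopifnot(length(missingness) == d, all(missingness >= 0 & missingness <= 1))
  structure(list(
    n_individuals = as.integer(n_individuals), n_siblings = as.integer(n_siblings),
    n_classes = K, mixing = mixing, mixing_coef = mixing_coef,
    schema = schema, class_effects = class_effects, separation = separation,
    age_mean = age_mean, age_sd = age_sd, sex_prob = sex_prob,
    missingness = missingness, truncate_at_zero = truncate_at_zero,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Ground-truth class-conditional parameters implied by a spec, per feature.
# Class index 0 means the sibling/reference (zero-effect) distribution.
spec_feature_params <- function(spec) {
  sch <- spec$schema
  d <- nrow(sch)
  K <- spec$n_classes
  base_mean <- if ("base_mean" %in% names(sch)) sch$base_mean else rep(0, d)
  base_sd <- if ("base_sd" %in% names(sch)) sch$base_sd else rep(1, d)
  base_p <- if ("base_p" %in% names(sch)) sch$base_p else rep(0.3, d)
  lapply(seq_len(d), function(j) {
    eff <- c(0, spec$class_effects[, j]) * spec$separation  # reference first
    switch(sch$type[j],
      continuous = list(mean = base_mean[j] + eff * base_sd[j],
                        sd = rep(base_sd[j], K + 1)),
      binary = list(p = stats::plogis(stats::qlogis(base_p[j]) + eff)),
      categorical = {
        L <- sch$n_levels[j]
        s <- (seq_len(L) - 1) / (L - 1) - 0.5
        probs <- t(vapply(eff, function(e) {
          w <- exp(2 * e * s); w / sum(w)
        }, numeric(L)))
        list(probs = probs)  # (K+1) x L
      })
  })
}

# Draw the feature block for given class labels (0 = reference/sibling).
draw_feature_block <- function(labels, schema, params, truncate_at_zero = FALSE) {
  n <- length(labels)
  idx <- labels + 1L
  out <- vector("list", nrow(schema))
  names(out) <- schema$name
  for (j in seq_len(nrow(schema))) {
    pj <- params[[j]]
    out[[j]] <- switch(schema$type[j],
      continuous = {
        x <- stats::rnorm(n, pj$mean[idx], pj$sd[idx])
        if (truncate_at_zero) x <- pmax(x, 0)
        x
      },
      binary = stats::rbinom(n, 1, pj$p[idx]),
      categorical = {
        L <- ncol(pj$probs)
        u <- stats::runif(n)
        cum <- t(apply(pj$probs, 1, cumsum))
        x <- integer(n)
        for (k in unique(idx)) {
          rows <- which(idx == k)
          x[rows] <- findInterval(u[rows], cum[k, ], left.open = TRUE) + 1L
        }
        pmin(x, L)
      })
  }
  as.data.frame(out, check.names = FALSE)
}

#' Generate a synthetic phenotype cohort
#'
#' Draws proband latent classes from the spec's mixing model, features from
#' the class-conditional distributions, and siblings from the reference
#' distribution.  Sibling features are restricted to the
#' social/communication and developmental-delay categories (all other
#' features are `NA` for siblings), emulating the limited questionnaire
#' coverage typical of sibling cohorts.  Identical spec and seed reproduce
#' bit-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed override (defaults to `spec$seed`).
#' @return A [phenotype_cohort()] with `true_class` set for probands.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- spec_feature_params(spec)
  with_seed(seed, {
    n <- spec$n_individuals
    ns <- spec$n_siblings
    K <- spec$n_classes
    age <- pmin(pmax(stats::rnorm(n + ns, spec$age_mean, spec$age_sd), 4), 18)
    sex <- stats::rbinom(n + ns, 1, spec$sex_prob)
    if (is.null(spec$mixing_coef)) {
      labels <- sample.int(K, n, replace = TRUE, prob = spec$mixing)
    } else {
      Z <- cbind(1, sex[seq_len(n)], age[seq_len(n)])
      eta <- Z %*% spec$mixing_coef
      pi_k <- exp(eta - apply(eta, 1, max))
      pi_k <- pi_k / rowSums(pi_k)
      labels <- vapply(seq_len(n), function(i) {
        sample.int(K, 1, prob = pi_k[i, ])
      }, integer(1))
    }
    feats <- draw_feature_block(labels, spec$schema, params, spec$truncate_at_zero)
    # MCAR missingness on proband features
    for (j in seq_len(nrow(spec$schema))) {
      mj <- spec$missingness[j]
      if (mj > 0) feats[[j]][stats::runif(n) < mj] <- NA
    }
    if (ns > 0) {
      sib_feats <- draw_feature_block(rep(0L, ns), spec$schema, params,
                                      spec$truncate_at_zero)
      observed <- spec$schema$category %in%
        c("limited social/communication", "developmental delay")
      if (any(!is.na(spec$schema$category))) {
        for (j in which(!observed)) sib_feats[[j]] <- sib_feats[[j]] * NA
      }
      feats <- rbind(feats, sib_feats)
    }
    fam <- sprintf("fam%05d", c(seq_len(n), seq_len(ns)))
    dat <- data.frame(
      individual_id = sprintf("ind%05d", seq_len(n + ns)),
      family_id = fam,
      role = rep(c("proband", "sibling"), c(n, ns)),
      sex = sex, age_years = age,
      true_class = c(labels, rep(NA_integer_, ns)),
      stringsAsFactors = FALSE
    )
    dat <- cbind(dat, feats)
    phenotype_cohort(dat, spec$schema)
  })
}

#' Generate a replication cohort on a shared feature subset
#'
#' Draws a new cohort from the *same* class-conditional distributions as
#' `spec`, restricted to `common_features` — emulating an independent cohort
#' that shares a subset of the training instruments.
#'
#' @param spec a [cohort_spec()] (the training-cohort ground truth).
#' @param common_features character vector of schema feature names.
#' @param n_individuals optional smaller sample size (default `spec`'s).
#' @param seed seed for the independent draw.
#' @return A [phenotype_cohort()] over exactly `common_features`.
#' @export
generate_replication_cohort <- function(spec, common_features,
                                        n_individuals = spec$n_individuals,
                                        seed = spec$seed + 1L) {
  miss <- setdiff(common_features, spec$schema$name)
  if (length(miss)) stop("schema error: unknown feature(s): ", paste(miss, collapse = ", "))
  keep <- spec$schema$name %in% common_features
  sub <- spec
  sub$schema <- spec$schema[keep, , drop = FALSE]
  sub$class_effects <- spec$class_effects[, keep, drop = FALSE]
  sub$missingness <- spec$missingness[keep]
  sub$n_individuals <- as.integer(n_individuals)
  sub$n_siblings <- 0L
  generate_cohort(sub, seed = seed)
}

#' A demonstration cohort spec emulating a broad-phenotype autism battery
#'
#' Sixty features spread over the seven phenotype categories: milestone-like
#' continuous features on a months scale, t-score-like continuous features,
#' binary questionnaire items, and 0-3 categorical items.  The four default
#' classes follow recognisable profiles: one moderately lower on everything,
#' one broadly elevated, one elevated on social/behavioral categories only,
#' and one elevated on developmental delay and repetitive behavior with
#' depleted social/communication items.
#'
#' @param n_individuals,n_siblings cohort sizes.
#' @param separation effect scale in SD units.
#' @param seed integer seed.
#' @return A [cohort_spec()] with K = 4.
#' @export
demo_spec <- function(n_individuals = 2000, n_siblings = 1000,
                      separation = 2, seed = 1L) {
  cats <- phenotype_categories()
  sch <- rbind(
    data.frame(name = sprintf("milestone_%02d", 1:8), type = "continuous",
               n_levels = NA, category = cats[6], base_mean = 14, base_sd = 6,
               base_p = NA),
    data.frame(name = sprintf("tscore_att_%02d", 1:6), type = "continuous",
               n_levels = NA, category = cats[3], base_mean = 60, base_sd = 10,
               base_p = NA),
    data.frame(name = sprintf("tscore_anx_%02d", 1:5), type = "continuous",
               n_levels = NA, category = cats[5], base_mean = 60, base_sd = 10,
               base_p = NA),
    data.frame(name = sprintf("tscore_dis_%02d", 1:5), type = "continuous",
               n_levels = NA, category = cats[4], base_mean = 60, base_sd = 10,
               base_p = NA),
    data.frame(name = sprintf("scq_%02d", 1:20), type = "binary",
               n_levels = NA, category = cats[1], base_mean = NA, base_sd = NA,
               base_p = 0.3),
    data.frame(name = sprintf("rbsr_%02d", 1:12), type = "categorical",
               n_levels = 4, category = cats[2], base_mean = NA, base_sd = NA,
               base_p = NA),
    data.frame(name = sprintf("selfinj_%02d", 1:4), type = "categorical",
               n_levels = 4, category = cats[7], base_mean = NA, base_sd = NA,
               base_p = NA)
  )
  class(sch) <- c("feature_schema", "data.frame")
  K <- 4
  eff <- matrix(0, K, nrow(sch))
  for (j in seq_len(nrow(sch))) {
    cat_j <- sch$category[j]
    eff[1, j] <- -0.5                      # moderate: lower on everything
    eff[2, j] <- 1                         # broad: elevated on everything
    eff[3, j] <- if (cat_j %in% cats[c(1, 3, 4, 5)]) 1 else 0   # social/behavioral
    eff[4, j] <- if (cat_j %in% cats[c(2, 6, 7)]) 1 else if (cat_j == cats[1]) -0.5 else 0
  }
  cohort_spec(n_individuals, n_classes = K, n_siblings = n_siblings,
              mixing = c(0.37, 0.10, 0.34, 0.19), schema = sch,
              class_effects = eff, separation = separation, seed = seed)
}

# ---------------------------------------------------------------------------
# Genetics generators

LOF_TERMS <- c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
               "splice_donor_variant", "start_lost", "stop_lost",
               "transcript_ablation")
MISSENSE_TERMS <- c("missense_variant", "inframe_deletion", "inframe_insertion",
                    "protein_altering_variant")
VARIANT_CHANNELS <- c("dnLoF", "dnMis", "dnSyn", "dnOther", "inhLoF", "inhMis")

#' Specify the synthetic genetic architecture
#'
#' Defines a gene universe with per-gene constraint (pLI), named gene sets,
#' developmental-expression (trend x cell type) memberships, and per-group
#' Poisson rates for each variant channel.  Rates are given as a long table
#' with one row per (group, channel, set): `set = "ALL"` rows are genome-wide
#' base rates (genes drawn uniformly from the universe); other rows add
#' set-restricted extra rates on top.  Groups are class indices `"1"..."K"`
#' and `"sibling"`.
#'
#' @param n_genes size of the gene universe.
#' @param genes optional explicit gene IDs.
#' @param pli optional per-gene pLI in `[0,1]` (default: seeded draw with a
#'   high-constraint tail).
#' @param gene_sets optional named list of gene vectors (default: seeded
#'   constraint/risk/FMRP-like sets).
#' @param devdeg optional named list keyed `"<trend>|<celltype>"` with trends
#'   Up, TransUp, Down, TransDown and cell types excitatory, MGE_IN, CGE_IN,
#'   glia (default: seeded random sets).
#' @param rates data.frame(group, channel, set, rate); default emulates a
#'   modest proband excess of damaging de novo variation over siblings.
#' @param n_classes number of proband classes the rate table covers.
#' @param frac_zero_dnv fraction of offspring forced to have zero de novo
#'   calls (default 0.045).
#' @param prop_rare_inherited probability an inherited variant is rare
#'   (allele frequency below 1%).
#' @param seed integer seed.
#' @return Object of class `genetic_spec`.
#' @export
genetic_spec <- function(n_genes = 500, genes = NULL, pli = NULL,
                         gene_sets = NULL, devdeg = NULL, rates = NULL,
                         n_classes = 4, frac_zero_dnv = 0.045,
                         prop_rare_inherited = 0.9, seed = 1L) {
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(n_genes))
  if (anyDuplicated(genes)) stop("integrity error: duplicate gene IDs")
  n_genes <- length(genes)
  if (is.null(pli)) {
    pli <- with_seed(seed * 7L + 11L, {
      p <- stats::rbeta(n_genes, 0.4, 0.8)
      hi <- sample.int(n_genes, max(1L, round(0.08 * n_genes)))
      p[hi] <- stats::runif(length(hi), 0.995, 1)
      mid <- sample(setdiff(seq_len(n_genes), hi), max(1L, round(0.15 * n_genes)))
      p[mid] <- stats::runif(length(mid), 0.5, 0.995)
      p
    })
  }
  stopifnot(length(pli) == n_genes, all(pli >= 0 & pli <= 1))
  names(pli) <- genes
  if (is.null(gene_sets)) {
    gene_sets <- with_seed(seed * 7L + 13L, list(
      all_protein_coding = genes,
      high_pli = genes[pli > 0.9],
      asd_risk = sample(genes, max(5L, round(0.08 * n_genes))),
      fmrp_targets = sample(genes, max(5L, round(0.12 * n_genes))),
      brain_expressed = sample(genes, max(5L, round(0.4 * n_genes)))
    ))
  }
  if (is.null(devdeg)) {
    trends <- c("Up", "TransUp", "Down", "TransDown")
    cells <- c("excitatory", "MGE_IN", "CGE_IN", "glia")
    devdeg <- with_seed(seed * 7L + 17L, {
      dd <- list()
      for (tr in trends) for (ce in cells)
        dd[[paste(tr, ce, sep = "|")]] <- sample(genes, max(5L, round(0.06 * n_genes)))
      dd
    })
  }
  for (s in c(gene_sets, devdeg)) {
    if (!all(s %in% genes)) stop("integrity error: gene set member outside the gene universe")
  }
  if (is.null(rates)) {
    groups <- as.character(seq_len(n_classes))
    base <- function(channel, sib, pro) {
      data.frame(group = c(groups, "sibling"), channel = channel, set = "ALL",
                 rate = c(pro, sib), stringsAsFactors = FALSE)
    }
    pro_lof <- rep(0.12, n_classes); pro_lof[min(2, n_classes)] <- 0.3
    rates <- rbind(
      base("dnLoF", 0.07, pro_lof),
      base("dnMis", 0.25, rep(0.35, n_classes)),
      base("dnSyn", 0.4, rep(0.4, n_classes)),
      base("dnOther", 1.9, rep(1.9, n_classes)),
      base("inhLoF", 2, rep(2.2, n_classes)),
      base("inhMis", 4, rep(4.3, n_classes))
    )
  }
  stopifnot(all(c("group", "channel", "set", "rate") %in% names(rates)))
  if (any(rates$rate < 0)) stop("value error: rates must be non-negative")
  bad <- setdiff(rates$channel, VARIANT_CHANNELS)
  if (length(bad)) stop("configuration error: unknown channel(s): ", paste(bad, collapse = ", "))
  structure(list(genes = genes, pli = pli, gene_sets = gene_sets,
                 devdeg = devdeg, rates = rates, n_classes = as.integer(n_classes),
                 frac_zero_dnv = frac_zero_dnv,
                 prop_rare_inherited = prop_rare_inherited, seed = as.integer(seed)),
            class = "genetic_spec")
}

channel_records <- function(ids, fams, n_var, genes_pool, channel, gspec) {
  total <- sum(n_var)
  if (total == 0) return(NULL)
  idx <- rep(seq_along(ids), n_var)
  origin <- if (startsWith(channel, "dn")) "denovo" else "inherited"
  consequence <- switch(channel,
    dnLoF = , inhLoF = sample(LOF_TERMS, total, replace = TRUE),
    dnMis = , inhMis = sample(MISSENSE_TERMS, total, replace = TRUE),
    dnSyn = rep("synonymous_variant", total),
    dnOther = rep("intron_variant", total))
  af <- if (origin == "inherited") {
    rare <- stats::runif(total) < gspec$prop_rare_inherited
    ifelse(rare, stats::runif(total, 0, 0.00999), stats::runif(total, 0.011, 0.5))
  } else rep(NA_real_, total)
  gene <- sample(genes_pool, total, replace = TRUE)
  data.frame(
    individual_id = ids[idx], family_id = fams[idx], gene = gene,
    origin = origin, consequence = consequence,
    lof_confidence = ifelse(consequence %in% LOF_TERMS, "HC", NA_character_),
    missense_class = ifelse(consequence %in% MISSENSE_TERMS, "likely_pathogenic",
                            NA_character_),
    allele_frequency = af,
    variant_key = paste0(gene, ":", sample.int(1000000L, total, replace = TRUE)),
    channel = channel, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic variant table
#'
#' Draws per-individual de novo and rare-inherited variant records with
#' class-specific Poisson rates per the genetic spec.  A configured fraction
#' of offspring receive zero de novo records (they appear only through the
#' roster when counts are later backfilled).
#'
#' @param cohort a [phenotype_cohort()] with `true_class` for probands.
#' @param gspec a [genetic_spec()] whose rate table covers every class
#'   present in the cohort plus `"sibling"`.
#' @param seed seed (default derived from `gspec`).
#' @return A `data.frame` of class `variant_table` with columns
#'   `individual_id`, `family_id`, `gene`, `origin`, `consequence`,
#'   `lof_confidence`, `missense_class`, `allele_frequency`, `variant_key`,
#'   and the generator's ground-truth `channel`.
#' @export
generate_variant_table <- function(cohort, gspec, seed = gspec$seed) {
  stopifnot(inherits(gspec, "genetic_spec"))
  dat <- cohort$data
  group <- ifelse(dat$role == "sibling", "sibling", as.character(dat$true_class))
  if (anyNA(group)) stop("cohort probands must carry true_class labels")
  need <- setdiff(unique(group), unique(gspec$rates$group))
  if (length(need)) {
    stop("configuration error: rate table missing group(s): ", paste(need, collapse = ", "))
  }
  with_seed(seed, {
    out <- list()
    for (r in seq_len(nrow(gspec$rates))) {
      row <- gspec$rates[r, ]
      if (row$rate == 0) next
      members <- which(group == row$group)
      if (!length(members)) next
      pool <- if (row$set == "ALL") gspec$genes else gspec$gene_sets[[row$set]]
      if (is.null(pool)) pool <- gspec$devdeg[[row$set]]
      if (is.null(pool)) stop("configuration error: unknown gene set in rates: ", row$set)
      n_var <- stats::rpois(length(members), row$rate)
      out[[length(out) + 1L]] <- channel_records(
        dat$individual_id[members], dat$family_id[members], n_var, pool,
        row$channel, gspec)
    }
    tab <- do.call(rbind, out)
    if (is.null(tab)) {
      tab <- data.frame(individual_id = character(), family_id = character(),
                        gene = character(), origin = character(),
                        consequence = character(), lof_confidence = character(),
                        missense_class = character(), allele_frequency = numeric(),
                        variant_key = character(), channel = character(),
                        stringsAsFactors = FALSE)
    }
    # zero-de-novo roster: strip all de novo records from a random fraction
    if (gspec$frac_zero_dnv > 0) {
      zeroed <- dat$individual_id[stats::runif(nrow(dat)) < gspec$frac_zero_dnv]
      tab <- tab[!(tab$origin == "denovo" & tab$individual_id %in% zeroed), ,
                 drop = FALSE]
      attr(tab, "zero_dnv_ids") <- zeroed
    } else {
      attr(tab, "zero_dnv_ids") <- character()
    }
    rownames(tab) <- NULL
    class(tab) <- c("variant_table", "data.frame")
    tab
  })
}

#' Materialise gene annotations from a genetic spec
#'
#' @param gspec a [genetic_spec()].
#' @return Object of class `gene_annotations`: list with `pli` (data.frame
#'   `gene`, `pli`), `gene_sets` (named list), `devdeg` (named list keyed
#'   `"<trend>|<celltype>"`).
#' @export
generate_gene_annotations <- function(gspec) {
  stopifnot(inherits(gspec, "genetic_spec"))
  structure(list(
    pli = data.frame(gene = gspec$genes, pli = unname(gspec$pli),
                     stringsAsFactors = FALSE),
    gene_sets = gspec$gene_sets,
    devdeg = gspec$devdeg
  ), class = "gene_annotations")
}

#' Generate a synthetic polygenic-score table
#'
#' Per individual and trait: `score = class_shift + sex effect + linear PC
#' effects + N(0,1) noise`; siblings draw from the zero-shift reference.
#'
#' @param cohort a [phenotype_cohort()].
#' @param traits character vector of trait names (non-empty).
#' @param class_shifts K x length(traits) matrix (or named list of per-class
#'   vectors) of score shifts in noise-SD units; default all zero.
#' @param n_pcs number of ancestry principal-component columns.
#' @param sex_effect,pc_effect_sd nuisance effect sizes.
#' @param seed integer seed.
#' @return data.frame with `individual_id`, `role`, `sex`, `PC1..PCn`, and
#'   one column per trait.
#' @export
generate_pgs_table <- function(cohort, traits, class_shifts = NULL, n_pcs = 6,
                               sex_effect = 0.2, pc_effect_sd = 0.15, seed = 1L) {
  if (length(traits) == 0) stop("value error: trait list is empty")
  stopifnot(n_pcs >= 0)
  dat <- cohort$data
  n <- nrow(dat)
  K <- max(dat$true_class, na.rm = TRUE)
  if (is.null(class_shifts)) class_shifts <- matrix(0, K, length(traits))
  class_shifts <- as.matrix(class_shifts)
  stopifnot(nrow(class_shifts) == K, ncol(class_shifts) == length(traits))
  with_seed(seed, {
    pcs <- if (n_pcs > 0) {
      m <- matrix(stats::rnorm(n * n_pcs), n, n_pcs)
      colnames(m) <- paste0("PC", seq_len(n_pcs)); m
    } else NULL
    out <- data.frame(individual_id = dat$individual_id, role = dat$role,
                      sex = dat$sex, stringsAsFactors = FALSE)
    if (!is.null(pcs)) out <- cbind(out, pcs)
    for (t in seq_along(traits)) {
      shift <- ifelse(dat$role == "sibling", 0, class_shifts[dat$true_class, t])
      score <- shift + sex_effect * dat$sex + stats::rnorm(n)
      if (!is.null(pcs)) {
        beta <- stats::rnorm(n_pcs, 0, pc_effect_sd)
        score <- score + drop(pcs %*% beta)
      }
      out[[traits[t]]] <- score
    }
    out
  })
}
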