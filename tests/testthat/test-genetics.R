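# Genetics: classification rules, QC filters, burden/OR arithmetic against
# hand and enumeration oracles, constraint bins, median test, hypergeometric
# enrichment, PGS normalisation properties.

test_that("variant classification follows the LoF/missense/synonymous rules", {
  v <- rbind(
    vrec("i1", consequence = "stop_gained", lof_confidence = "HC"),
    vrec("i2", consequence = "frameshift_variant", lof_confidence = "LC"),
    vrec("i3", consequence = "missense_variant", lof_confidence = NA,
         missense_class = "likely_pathogenic"),
    vrec("i4", consequence = "missense_variant", lof_confidence = NA,
         missense_class = "likely_benign"),
    vrec("i5", consequence = "synonymous_variant", lof_confidence = NA),
    vrec("i6", consequence = "intron_variant", lof_confidence = NA))
  cl <- classify_variants(v)$variant_class
  expect_identical(cl, c("LoF_HC", "other", "missense_damaging", "other",
                         "synonymous", "other"))
  expect_warning(classify_variants(vrec("i7", consequence = "made_up_term")),
                 "unknown consequence")
})

test_that("de novo filter: outliers, non-singletons, zero backfill, idempotence", {
  roster <- data.frame(individual_id = sprintf("i%d", 1:20))
  # i1 gets 40 variants (a >3SD outlier), i2..i10 get 1 each, i11..i20 none
  v <- do.call(rbind, c(
    lapply(1:40, function(j) vrec("i1", gene = sprintf("G%d", j),
                                  variant_key = sprintf("G%d:%d", j, j),
                                  family_id = "f1")),
    lapply(2:10, function(j) vrec(sprintf("i%d", j), gene = "G99",
                                  variant_key = sprintf("G99:%d", j),
                                  family_id = sprintf("f%d", j)))))
  counts0 <- c(40, rep(1, 9), rep(0, 10))
  expect_gt(40, mean(counts0) + 3 * sd(counts0))
  fd <- filter_de_novo(v, roster)
  expect_identical(fd$excluded, "i1")
  expect_equal(nrow(fd$counts), 19)
  expect_equal(sum(fd$counts$n_dnv == 0), 10)
  expect_equal(sum(fd$counts$n_dnv), nrow(fd$variants))  # count conservation
  # non-singleton removal: same key in two families
  v2 <- rbind(vrec("i2", variant_key = "G1:7", family_id = "fA"),
              vrec("i3", variant_key = "G1:7", family_id = "fB"),
              vrec("i4", variant_key = "G2:9", family_id = "fC"))
  fd2 <- filter_de_novo(v2, roster[2:4, , drop = FALSE])
  expect_equal(nrow(fd2$variants), 1)
  expect_identical(fd2$variants$individual_id, "i4")
  # idempotence
  fd3 <- filter_de_novo(fd2$variants, roster[2:4, , drop = FALSE])
  expect_identical(fd3$variants, fd2$variants)
  expect_error(filter_de_novo(v, roster[0, , drop = FALSE]), "value error")
})

test_that("rare-inherited filter keeps AF < 1% and flags missing AF", {
  v <- rbind(
    vrec("i1", origin = "inherited", allele_frequency = 0.005),
    vrec("i2", origin = "inherited", allele_frequency = 0.02),
    vrec("i3", origin = "inherited", allele_frequency = NA))
  out <- filter_rare_inherited(v)
  expect_setequal(out$individual_id, c("i1", "i3"))
  expect_equal(attr(out, "n_rare_by_absence"), 1)
  expect_true(out$rare_by_absence[out$individual_id == "i3"])
  # idempotent
  out2 <- filter_rare_inherited(out)
  expect_equal(out2$individual_id, out$individual_id)
  bad <- vrec("i4", origin = "inherited", allele_frequency = 1.5)
  expect_error(filter_rare_inherited(bad), "record rejected")
})

test_that("burden test matches hand arithmetic and t formula", {
  counts <- data.frame(count = c(3, 1, 2, 1, 0, 1),
                       group = rep(c("1", "sibling"), each = 3))
  bt <- burden_test(counts)
  r1 <- bt[bt$group == "1", ]
  expect_equal(r1$mean, 2)
  expect_equal(r1$fold_enrichment, 3.0, tolerance = 1e-12)
  expect_equal(r1$se, sd(c(3, 1, 2)) / sqrt(3), tolerance = 1e-12)
  # hand t: pooled sp2 = (2*1 + 2*1/3)/4 = 2/3; t = (2 - 2/3)/sqrt(2/3 * 2/3) = 2
  tt <- t.test(c(3, 1, 2), c(1, 0, 1), alternative = "greater", var.equal = TRUE)
  expect_equal(r1$p, tt$p.value, tolerance = 1e-12)
  expect_equal(unname(tt$statistic), 2, tolerance = 1e-12)
  # identical distributions -> FE 1, p ~ 0.5
  same <- data.frame(count = rep(c(1, 2, 3), 20),
                     group = rep(c("1", "sibling"), each = 30))
  bs <- burden_test(same)
  expect_equal(bs$fold_enrichment[bs$group == "1"], 1, tolerance = 1e-12)
  expect_equal(bs$p[bs$group == "1"], 0.5, tolerance = 0.05)
  # sibling mean zero -> FE flagged infinite but p still computed
  z <- data.frame(count = c(1, 2, 0, 0), group = c("1", "1", "sibling", "sibling"))
  bz <- burden_test(z)
  expect_true(is.infinite(bz$fold_enrichment[bz$group == "1"]))
  expect_true(is.finite(bz$p[bz$group == "1"]))
})

test_that("odds ratios match hand arithmetic and exact enumeration", {
  carrier <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 10), rep(FALSE, 90))
  group <- rep(c("1", "sibling"), each = 100)
  or <- odds_ratio_test(carrier, group)
  expect_equal(or$odds_ratio, (20 / 80) / (10 / 90), tolerance = 1e-12)
  expect_equal(or$odds_ratio, 2.25, tolerance = 1e-12)
  # equal rates -> OR 1
  c2 <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 10), rep(FALSE, 90))
  expect_equal(odds_ratio_test(c2, group)$odds_ratio, 1, tolerance = 1e-12)
  # zero cell -> Haldane-Anscombe correction
  c3 <- c(rep(TRUE, 5), rep(FALSE, 0), rep(TRUE, 2), rep(FALSE, 10))
  g3 <- c(rep("1", 5), rep("sibling", 12))
  or3 <- odds_ratio_test(c3, g3)
  expect_equal(or3$odds_ratio, ((5 + 0.5) / 0.5) / ((2 + 0.5) / (10 + 0.5)),
               tolerance = 1e-12)
  expect_error(odds_ratio_test(carrier, rep("1", 200)), "value error")
})

test_that("one-sided Fisher p equals direct hypergeometric enumeration", {
  # all 2x2 tables with margins <= 12: compare to a summation oracle
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + b; n <- c_ + d; k <- a + c_
    lo <- max(0, k - n); hi <- min(k, m)
    probs <- sapply(lo:hi, function(x) {
      choose(m, x) * choose(n, k - x) / choose(m + n, k)
    })
    sum(probs[(lo:hi) >= a])
  }
  set.seed(71)
  for (rep in 1:25) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                         alternative = "greater")$p.value
    expect_equal(p_pkg, fisher_oracle(a, b, c_, d), tolerance = 1e-10,
                 info = sprintf("table %d %d %d %d", a, b, c_, d))
  }
})

test_that("constraint bins honour the pLI cutoffs", {
  expect_identical(constraint_bin(c(0.997, 0.995, 0.7, 0.5, 0.3, 0.994)),
                   c("high", "high", "intermediate", "intermediate", "none",
                     "intermediate"))
  expect_error(constraint_bin(1.2), "value error")
})

test_that("hypergeometric enrichment matches direct tail summation", {
  bg <- sprintf("G%03d", 1:100)
  term <- bg[1:10]
  impacted <- bg[1:5]
  res <- hypergeom_enrichment(impacted, list(t1 = term), bg)
  expect_equal(res$fold_enrichment, (5 / 5) / (10 / 100), tolerance = 1e-12)
  expect_equal(res$fold_enrichment, 10)
  p_oracle <- sum(sapply(5:5, function(k) {
    choose(10, k) * choose(90, 5 - k) / choose(100, 5)
  }))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # disjoint -> FE 0, p 1; full background -> FE 1, p 1
  res2 <- hypergeom_enrichment(impacted, list(t = bg[50:60]), bg)
  expect_equal(res2$fold_enrichment, 0)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  res3 <- hypergeom_enrichment(impacted, list(t = bg), bg)
  expect_equal(res3$fold_enrichment, 1, tolerance = 1e-12)
  expect_equal(res3$p, 1, tolerance = 1e-12)
  expect_error(hypergeom_enrichment(character(), list(t = term), bg), "value error")
})

test_that("Mood's median test: exact small-table oracle and direction", {
  pli <- c(a1 = 0.1, a2 = 0.2, b1 = 0.8, b2 = 0.9)
  res <- pli_median_test(c("a1", "a2"), c("b1", "b2"), pli)
  # grand median 0.5 (ties none); table: B above = 2, A above = 0
  expect_equal(res$table["B", "above"], 2)
  expect_equal(res$table["A", "above"], 0)
  p_oracle <- fisher.test(matrix(c(2, 0, 0, 2), 2, byrow = TRUE),
                          alternative = "greater")$p.value
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  # strongly shifted groups reject; identical degenerate values give p = 1
  set.seed(73)
  pli2 <- c(stats::setNames(runif(40, 0, 0.3), sprintf("a%d", 1:40)),
            stats::setNames(runif(40, 0.7, 1), sprintf("b%d", 1:40)))
  r2 <- pli_median_test(sprintf("a%d", 1:40), sprintf("b%d", 1:40), pli2)
  expect_lt(r2$p, 0.01)
  pli3 <- c(x1 = 0.5, x2 = 0.5, y1 = 0.5)
  r3 <- pli_median_test(c("x1", "x2"), "y1", pli3)
  expect_true(r3$degenerate)
  expect_equal(r3$p, 1)
})

test_that("devDEG enrichment recovers an elevated cell and pools probands", {
  spec <- tiny_spec(n = 400, K = 2, seed = 75, n_siblings = 200)
  co <- generate_cohort(spec)
  gs <- genetic_spec(n_genes = 200, n_classes = 2, frac_zero_dnv = 0, seed = 77)
  # boost class 1 dnLoF in one devDEG set
  boost <- data.frame(group = "1", channel = "dnLoF", set = "Down|excitatory",
                      rate = 0.6)
  gs$rates <- rbind(gs$rates, boost)
  vt <- generate_variant_table(co, gs)
  v <- classify_variants(vt)
  grp <- ifelse(co$data$role == "sibling", "sibling",
                as.character(co$data$true_class))
  roster <- data.frame(individual_id = co$data$individual_id, group = grp)
  res <- devdeg_enrichment(v, roster, gs$devdeg)
  cell <- res[res$group == "1" & res$trend == "Down" & res$celltype == "excitatory", ]
  expect_gt(cell$fold_enrichment, 1.5)
  expect_lt(cell$q, 0.05)
  pooled <- res[res$group == "pooled", ]
  expect_equal(nrow(pooled), length(gs$devdeg))
  # pooled mean is the member-weighted mean of the class means
  one <- res[res$trend == "Down" & res$celltype == "excitatory", ]
  n1 <- one$n[one$group == "1"]; n2 <- one$n[one$group == "2"]
  m_pool <- (one$mean[one$group == "1"] * n1 + one$mean[one$group == "2"] * n2) /
    (n1 + n2)
  expect_equal(one$mean[one$group == "pooled"], m_pool, tolerance = 1e-12)
})

test_that("PGS normalisation: sibling moments, orthogonality, shift recovery", {
  spec <- tiny_spec(n = 500, K = 2, seed = 79, n_siblings = 500)
  co <- generate_cohort(spec)
  shifts <- matrix(c(0.5, 0), 2, 1)
  pgs <- generate_pgs_table(co, "asd", class_shifts = shifts, n_pcs = 6, seed = 81)
  lab <- ifelse(co$data$role == "proband", co$data$true_class, NA_integer_)
  res <- pgs_compare(pgs, lab, "asd")
  sib_row <- res[res$group == "sibling", ]
  expect_equal(sib_row$mean, 0, tolerance = 1e-10)
  # residual orthogonality to covariates
  pc_cols <- grep("^PC", names(pgs), value = TRUE)
  Zc <- as.matrix(cbind(1, pgs$sex, pgs[, pc_cols]))
  resid <- qr.resid(qr(Zc), pgs$asd)
  for (j in seq_len(ncol(Zc))) {
    expect_lt(abs(sum(resid * Zc[, j])),
              1e-8 * sqrt(sum(resid^2)) * sqrt(sum(Zc[, j]^2)))
  }
  # the 0.5-SD class shift is recovered
  c1 <- res[res$group == "class1" & res$trait == "asd", ]
  expect_lt(abs(c1$mean - 0.5), 0.15)
  expect_lt(c1$q, 0.01)
  # collinear covariate triggers an informative error
  pgs_bad <- pgs
  pgs_bad$PC6 <- pgs_bad$PC5
  expect_error(pgs_compare(pgs_bad, lab, "asd"), "collinear")
})

test_that("minimal VCF records map into the variant table", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "1\t100\t.\tA\tT\t50\tPASS\tGENE=G001;CSQ=stop_gained;LOF=HC;ORIGIN=denovo;IND=i1;FAM=f1",
           "2\t200\t.\tG\tC\t50\tPASS\tGENE=G002;CSQ=missense_variant;AM=likely_pathogenic;ORIGIN=inherited;AF=0.004;IND=i2;FAM=f2")
  path <- file.path(tempdir(), "mini.vcf")
  writeLines(vcf, path)
  v <- read_minimal_vcf(path)
  expect_equal(nrow(v), 2)
  expect_identical(v$gene, c("G001", "G002"))
  expect_identical(v$variant_key[1], "1:100:A:T")
  expect_equal(v$allele_frequency, c(NA, 0.004))
  cl <- classify_variants(v)
  expect_identical(cl$variant_class, c("LoF_HC", "missense_damaging"))
})

test_that("count conservation holds through counting and filters", {
  spec <- tiny_spec(n = 200, K = 2, seed = 83, n_siblings = 100)
  co <- generate_cohort(spec)
  gs <- genetic_spec(n_genes = 100, n_classes = 2, seed = 85)
  vt <- classify_variants(generate_variant_table(co, gs))
  roster <- data.frame(individual_id = co$data$individual_id)
  for (vc in c("LoF_HC", "missense_damaging", "synonymous")) {
    cnt <- count_variants(vt, roster, variant_class = vc, origin = "denovo")
    expect_equal(sum(cnt$count),
                 sum(vt$variant_class == vc & vt$origin == "denovo"))
  }
})
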