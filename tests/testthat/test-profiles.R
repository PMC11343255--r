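# Affinity engine: completeness filter, enrichment tests against exact
# oracles, exclusion rules, affinity arithmetic, external validation tests.

test_that("completeness filter drops sparse features then incomplete probands", {
  sch <- feature_schema(c("a", "b"), c("continuous", "continuous"))
  feats <- data.frame(a = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                      b = c(NA, NA, 3, 4, 5, 6, 7, 8, 9, 10))  # 80% complete
  co <- manual_cohort(feats, sch)
  out <- completeness_filter(co, 0.90)
  expect_equal(out$schema$name, "a")
  expect_equal(nrow(out$data), 10)
  expect_identical(attr(out, "dropped_features"), "b")
  # an individual missing a surviving feature is dropped
  feats2 <- feats
  feats2$b <- 1:10
  feats2$a[3] <- NA
  co2 <- manual_cohort(feats2, sch)
  out2 <- completeness_filter(co2, 0.90)
  expect_equal(nrow(out2$data), 9)
  expect_equal(attr(out2, "dropped_individuals"), 1)
  # fully complete cohorts pass through unchanged
  co3 <- manual_cohort(data.frame(a = 1:10, b = 1:10), sch)
  expect_equal(nrow(completeness_filter(co3)$data), 10)
  expect_equal(completeness_filter(co3)$schema$name, c("a", "b"))
})

test_that("binary enrichment matches a direct binomial-tail summation oracle", {
  # class: 30/100 successes; pooled others: 10/100 -> FE 3.0
  sch <- feature_schema("b", "binary", category = phenotype_categories()[1])
  feats <- data.frame(b = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90)))
  co <- manual_cohort(feats, sch)
  labels <- rep(c(1, 2), each = 100)
  enr <- feature_enrichment(co, labels)
  row1 <- enr[enr$class == 1, ]
  expect_equal(row1$fold_enrichment, 3.0, tolerance = 1e-12)
  # oracle: direct summation of the binomial upper tail at p0 = 0.1
  p0 <- 0.1
  p_up_oracle <- sum(sapply(30:100, function(k) choose(100, k) * p0^k * (1 - p0)^(100 - k)))
  expect_equal(row1$p_upper, p_up_oracle, tolerance = 1e-10)
  p_lo_oracle <- sum(sapply(0:30, function(k) choose(100, k) * p0^k * (1 - p0)^(100 - k)))
  expect_equal(row1$p_lower, p_lo_oracle, tolerance = 1e-10)
})

test_that("extreme binary separation gives p ~ 0 upper and 1 lower", {
  sch <- feature_schema("b", "binary")
  feats <- data.frame(b = rep(c(1, 0), each = 50))
  co <- manual_cohort(feats, sch)
  enr <- feature_enrichment(co, rep(c(1, 2), each = 50))
  expect_lt(enr$p_upper[enr$class == 1], 1e-20)
  expect_equal(enr$p_lower[enr$class == 1], 1, tolerance = 1e-12)
})

test_that("t-test enrichment agrees with stats::t.test in both directions", {
  sch <- feature_schema("x", "continuous")
  set.seed(37)
  x <- c(rnorm(60, 1), rnorm(140, 0))
  co <- manual_cohort(data.frame(x = x), sch)
  labels <- rep(c(1, 2), c(60, 140))
  enr <- feature_enrichment(co, labels)
  ref_up <- t.test(x[1:60], x[61:200], alternative = "greater",
                   var.equal = TRUE)$p.value
  ref_lo <- t.test(x[1:60], x[61:200], alternative = "less",
                   var.equal = TRUE)$p.value
  expect_equal(enr$p_upper[enr$class == 1], ref_up, tolerance = 1e-10)
  expect_equal(enr$p_lower[enr$class == 1], ref_lo, tolerance = 1e-10)
  d_ref <- (mean(x[1:60]) - mean(x[61:200])) /
    sqrt(((59 * var(x[1:60])) + 139 * var(x[61:200])) / 198)
  expect_equal(enr$cohens_d[enr$class == 1], d_ref, tolerance = 1e-10)
  # Welch toggle
  enr_w <- feature_enrichment(co, labels, welch = TRUE)
  ref_w <- t.test(x[1:60], x[61:200], alternative = "greater")$p.value
  expect_equal(enr_w$p_upper[enr_w$class == 1], ref_w, tolerance = 1e-10)
  # zero variance in both groups -> flagged NA
  co0 <- manual_cohort(data.frame(x = rep(1, 40)), sch)
  enr0 <- feature_enrichment(co0, rep(c(1, 2), each = 20))
  expect_true(all(is.na(enr0$p_upper)))
})

test_that("BH correction matches the reference step-up procedure", {
  set.seed(39)
  sch <- tiny_schema(n_cont = 6, n_bin = 0, n_cat = 0)
  spec <- tiny_spec(n = 200, K = 2, schema = sch, separation = 1, seed = 41)
  co <- generate_cohort(spec)
  enr <- feature_enrichment(mixphen:::cohort_probands(co), co$data$true_class)
  for (k in 1:2) {
    sel <- enr$class == k
    expect_equal(enr$q_upper[sel], p.adjust(enr$p_upper[sel], "BH"),
                 tolerance = 1e-12)
    # q >= p and monotone in p within the family
    expect_true(all(enr$q_upper[sel] >= enr$p_upper[sel] - 1e-12))
    o <- order(enr$p_upper[sel])
    expect_true(all(diff(enr$q_upper[sel][o]) >= -1e-12))
  }
})

test_that("the three exclusion criteria act as specified", {
  cats <- phenotype_categories()
  base <- data.frame(
    feature = c("f_small_d", "f_weak_fe", "f_never_sig", "f_good"),
    class = 1,
    p_upper = c(1e-6, 1e-6, 0.5, 1e-6), p_lower = c(1, 1, 0.6, 1),
    q_upper = c(1e-5, 1e-5, 0.9, 1e-5), q_lower = c(1, 1, 1, 1),
    cohens_d = c(0.1, NA, 0.5, 0.6), fold_enrichment = c(NA, 1.4, NA, NA),
    type = c("continuous", "binary", "continuous", "continuous"),
    category = cats[1], stringsAsFactors = FALSE)
  contrib <- feature_exclusion(base)
  expect_identical(contrib, "f_good")
})

test_that("affinity cells equal signed hand counts and stay within [-1, 1]", {
  cats <- phenotype_categories()
  # one category, 8 contributory features: 3 enriched, 1 depleted in class 1
  q_up <- c(0.01, 0.01, 0.01, 0.9, 0.9, 0.9, 0.9, 0.9)
  q_lo <- c(0.9, 0.9, 0.9, 0.01, 0.9, 0.9, 0.9, 0.9)
  enr <- data.frame(
    feature = sprintf("f%d", 1:8), class = 1,
    p_upper = q_up, p_lower = q_lo, q_upper = q_up, q_lower = q_lo,
    cohens_d = 0.5, fold_enrichment = NA_real_, type = "continuous",
    category = cats[2], stringsAsFactors = FALSE)
  A <- affinity_scores(enr, contributory = sprintf("f%d", 1:8))
  expect_equal(unname(A[1, cats[2]]), (3 - 1) / 8)
  # all enriched -> +1; all depleted -> -1
  enr_all_up <- transform(enr, q_upper = 0.01, q_lower = 0.9)
  expect_equal(unname(affinity_scores(enr_all_up, sprintf("f%d", 1:8))[1, cats[2]]), 1)
  enr_all_dn <- transform(enr, q_upper = 0.9, q_lower = 0.01)
  expect_equal(unname(affinity_scores(enr_all_dn, sprintf("f%d", 1:8))[1, cats[2]]), -1)
  # empty category -> NA cell
  expect_true(is.na(A[1, cats[1]]))
  expect_true(all(abs(A[!is.na(A)]) <= 1))
})

test_that("a feature is never both enriched and depleted in one class", {
  spec <- demo_spec(n_individuals = 600, n_siblings = 0, separation = 2, seed = 43)
  co <- generate_cohort(spec)
  enr <- feature_enrichment(co, co$data$true_class)
  both <- enr$q_upper < 0.05 & enr$q_lower < 0.05
  expect_false(any(both, na.rm = TRUE))
})

test_that("diagnosis enrichment reproduces exact binomial tails vs siblings", {
  lab <- c(rep(1, 200), rep(NA, 400))
  sib <- c(rep(FALSE, 200), rep(TRUE, 400))
  dx <- data.frame(adhd = c(rep(1, 20), rep(0, 180), rep(1, 20), rep(0, 380)))
  res <- diagnosis_enrichment(dx, lab, sib)
  expect_equal(res$fold_enrichment, (20 / 200) / (20 / 400), tolerance = 1e-12)
  p_oracle <- sum(sapply(20:200, function(k) {
    choose(200, k) * 0.05^k * 0.95^(200 - k)
  }))
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
  # equal prevalence -> FE 1
  dx2 <- data.frame(x = c(rep(c(1, 0), 100), rep(c(1, 0), 200)))
  res2 <- diagnosis_enrichment(dx2, lab, sib)
  expect_equal(res2$fold_enrichment, 1, tolerance = 1e-12)
  # zero sibling prevalence -> infinite FE, finite p
  dx3 <- data.frame(x = c(rep(1, 10), rep(0, 190), rep(0, 400)))
  res3 <- diagnosis_enrichment(dx3, lab, sib)
  expect_true(is.infinite(res3$fold_enrichment))
  expect_true(res3$p >= 0 && res3$p <= 1)
})

test_that("class-versus-sibling tests report means, CIs and one-sided p", {
  sch <- feature_schema("scq_total", "continuous",
                        category = phenotype_categories()[1])
  set.seed(45)
  feats <- data.frame(scq_total = c(rnorm(200, 22, 5), rnorm(200, 4, 3)))
  co <- manual_cohort(feats, sch, role = rep(c("proband", "sibling"), each = 200))
  res <- group_vs_sibling_tests(co, labels = rep(1, 200), "scq_total")
  cls <- res[res$group == "class1", ]
  expect_lt(cls$q, 0.01)
  expect_true(cls$ci_lower < cls$mean && cls$mean < cls$ci_upper)
  ref <- t.test(feats$scq_total[1:200], feats$scq_total[201:400],
                alternative = "greater", var.equal = TRUE)$p.value
  expect_equal(cls$p, ref, tolerance = 1e-12)
  # constant feature: zero-width CI at the constant
  co_const <- manual_cohort(data.frame(scq_total = rep(5, 40)), sch,
                            role = rep(c("proband", "sibling"), each = 20))
  rc <- group_vs_sibling_tests(co_const, rep(1, 20), "scq_total")
  expect_equal(rc$ci_lower[1], 5)
  expect_equal(rc$ci_upper[1], 5)
})

test_that("null cohorts keep the false-positive fraction near alpha", {
  # zero separation: q < 0.05 calls across features should be rare
  sch <- tiny_schema(n_cont = 10, n_bin = 6, n_cat = 4)
  n_sig <- 0; n_tot <- 0
  for (r in 1:5) {
    spec <- tiny_spec(n = 300, K = 2, schema = sch, separation = 0, seed = 50 + r)
    co <- generate_cohort(spec)
    enr <- feature_enrichment(co, co$data$true_class)
    n_sig <- n_sig + sum(enr$q_upper < 0.05, na.rm = TRUE) +
      sum(enr$q_lower < 0.05, na.rm = TRUE)
    n_tot <- n_tot + 2 * nrow(enr)
  }
  expect_lte(n_sig / n_tot, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tot))
})
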