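make_es <- function(mat, samples = sprintf("S%02d", seq_len(ncol(mat))),
                    sigs = sprintf("sig%02d", seq_len(nrow(mat)))) {
  dimnames(mat) <- list(sigs, samples)
  mat
}

test_that("compare_groups matches the closed-form two-sample t", {
  es <- make_es(rbind(c(0.5, 0.6, 0.7, 0.1, 0.2, 0.3)))
  labels <- c(rep("case", 3), rep("ctl", 3))
  res <- compare_groups(es, labels, "case", "ctl")
  expect_equal(res$delta, 0.4, tolerance = 1e-12)
  # pooled-variance formula by hand: sp = 0.1, se = 0.1*sqrt(2/3)
  expect_equal(res$t, 0.4 / (0.1 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(res$t, 4.899, tolerance = 1e-3)
  tt <- t.test(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.3), var.equal = TRUE)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, 4)
})

test_that("BH adjustment follows the step-up procedure", {
  es <- make_es(matrix(rnorm(24), 4, 6))
  labels <- rep(c("a", "b"), each = 3)
  res <- compare_groups(es, labels, "a", "b")
  # independent check against the hand rule on a known vector
  res$p_raw <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(res$p_raw, "BH"), rep(0.04, 4))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
})

test_that("swapping groups negates delta and t but keeps p", {
  es <- make_es(matrix(rnorm(50), 5, 10))
  labels <- rep(c("x", "y"), each = 5)
  r1 <- compare_groups(es, labels, "x", "y")
  r2 <- compare_groups(es, labels, "y", "x")
  expect_equal(r2$delta, -r1$delta, tolerance = 1e-12)
  expect_equal(r2$t, -r1$t, tolerance = 1e-12)
  expect_equal(r2$p_raw, r1$p_raw, tolerance = 1e-12)
})

test_that("paired comparison uses within-subject differences", {
  set.seed(5)
  es <- make_es(matrix(rnorm(40), 4, 10))
  labels <- rep(c("BL", "PT"), 5)
  subject <- rep(sprintf("subj%d", 1:5), each = 2)
  res <- compare_groups(es, labels, "PT", "BL", paired = TRUE,
                        subject = subject)
  for (i in 1:4) {
    tt <- t.test(es[i, labels == "PT"], es[i, labels == "BL"], paired = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("compare_groups validates labels and group sizes", {
  es <- make_es(matrix(rnorm(12), 2, 6))
  labels <- c("a", "a", "a", "a", "a", "b")
  expect_error(compare_groups(es, labels, "a", "b"), "at least 2")
  expect_error(compare_groups(es, labels, "a", "nope"), "unknown group")
  expect_error(compare_groups(es, c("a", "b"), "a", "b"), "named by sample")
})

test_that("select_enriched applies the inclusive dual threshold", {
  res <- data.frame(signature = c("at", "below", "sig", "neg"),
                    delta = c(0.20, 0.19, 0.5, -0.5),
                    p_raw = c(0.05, 1e-6, 0.01, 0.01),
                    p_adj = c(0.05, 1e-6, 0.04, 0.04))
  class(res) <- c("differential_result", class(res))
  crit <- selection_criteria(direction = "both")
  sel <- select_enriched(res, crit)
  expect_true("at" %in% sel)        # both boundaries inclusive
  expect_false("below" %in% sel)    # delta below 0.2, regardless of p
  expect_setequal(sel, c("at", "sig", "neg"))
  # direction filters on the sign of delta
  expect_setequal(select_enriched(res, selection_criteria(direction = "up")),
                  c("at", "sig"))
  expect_identical(
    as.character(select_enriched(res, selection_criteria(direction = "down"))),
    "neg")
  # raw-p mode is a config switch
  res$p_adj <- rep(1, 4)
  expect_length(select_enriched(res, crit), 0)
  expect_setequal(select_enriched(res, selection_criteria(
    direction = "both", use_adjusted = FALSE)), c("at", "sig", "neg"))
})

test_that("select_enriched is monotone in its thresholds", {
  set.seed(9)
  es <- make_es(matrix(rnorm(300, sd = 0.3), 30, 10))
  es[1:5, 1:5] <- es[1:5, 1:5] + 0.4
  labels <- rep(c("g1", "g2"), each = 5)
  res <- compare_groups(es, labels, "g1", "g2")
  sel_strict <- select_enriched(res, selection_criteria(0.3, 0.01,
                                                        direction = "both"))
  sel_mid <- select_enriched(res, selection_criteria(0.2, 0.05,
                                                     direction = "both"))
  sel_loose <- select_enriched(res, selection_criteria(0.0, 0.2,
                                                       direction = "both"))
  expect_true(all(sel_strict %in% sel_mid))
  expect_true(all(sel_mid %in% sel_loose))
})

test_that("planted signatures are recovered from a synthetic cohort", {
  co <- simulate_cohort(cohort_design(n_genes = 600, n_signatures = 30,
                                      n_true = 5, signature_size = 20,
                                      n_per_group = 8, diseases = "CD",
                                      timepoints = "BL", seed = 77L))
  es <- gsva_scores(co$expr, co$library)
  labels <- stats::setNames(
    ifelse(co$annotations$group == "NHV", "NHV", "CD_BL"),
    co$annotations$sample)
  res <- compare_groups(es, labels, "CD_BL", "NHV")
  sel <- select_enriched(res, selection_criteria())
  expect_setequal(sel, co$truth$true_ids)
})

test_that("venn_counts partitions id sets", {
  # counts mirroring the two disease-vs-healthy lists sharing 58 ids
  shared <- sprintf("s%02d", 1:58)
  a <- c(shared, "cd_only")
  b <- c(shared, sprintf("uc%02d", 1:9))
  v <- venn_counts(a, b)
  expect_identical(c(v$only_a, v$shared, v$only_b), c(1L, 58L, 9L))
  expect_identical(v$members_only_a, "cd_only")

  v2 <- venn_counts(a, a)
  expect_identical(c(v2$only_a, v2$shared, v2$only_b), c(0L, 59L, 0L))
  v3 <- venn_counts(c("x", "y"), c("p", "q", "r"))
  expect_identical(c(v3$only_a, v3$shared, v3$only_b), c(2L, 0L, 3L))
})
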