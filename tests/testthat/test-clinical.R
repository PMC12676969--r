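test_that("a deterministic threshold label makes its feature rank first", {
  withr::with_seed(2, {
    n <- 80
    clin <- data.frame(SampleID = paste0("S", 1:n),
                       driver = rnorm(n),
                       noise1 = rnorm(n), noise2 = rnorm(n),
                       noise3 = rnorm(n))
  })
  labels <- setNames(ifelse(clin$driver > 0, "C1", "C2"), clin$SampleID)
  rf <- fit_rf_predictor(clin, labels, n_trees = 300, seed = 4)
  expect_equal(rf$importance$feature[1], "driver")
  expect_equal(rf$importance$feature[rf$importance$rank_gini == 1], "driver")
  expect_true(setequal(rf$importance$rank_mda,
                       seq_len(nrow(rf$importance))))
  expect_gt(rf$oob_accuracy, 0.85)
})

test_that("pure-noise features give chance-level out-of-bag accuracy", {
  accs <- vapply(1:10, function(s) {
    clin <- withr::with_seed(s, data.frame(SampleID = paste0("S", 1:60),
                                           a = rnorm(60), b = rnorm(60)))
    labels <- setNames(rep(c("C1", "C2"), c(36, 24)), clin$SampleID)
    fit_rf_predictor(clin, labels, n_trees = 200, seed = s)$oob_accuracy
  }, numeric(1))
  # majority-class rate is 0.6
  expect_lt(abs(mean(accs) - 0.6), 0.1)
})

test_that("random-forest fits are reproducible and reject degenerate labels", {
  co <- simulate_cohort(small_config(3))
  pat <- co$npx$group == "AD"
  labels <- co$truth$cluster_label[co$npx$sample_ids[pat]]
  clin <- co$clinical[pat, ]
  a <- fit_rf_predictor(clin, labels, n_trees = 150, seed = 9)
  b <- fit_rf_predictor(clin, labels, n_trees = 150, seed = 9)
  expect_identical(a$importance, b$importance)
  expect_error(fit_rf_predictor(clin, setNames(rep("C1", sum(pat)),
                                               clin$SampleID)),
               "two classes")
})

test_that("threshold scan reports extrema, separability and split accuracy", {
  clin <- data.frame(SampleID = paste0("S", 1:6),
                     feat = c(1, 2, 3, 10, 11, 12))
  labels <- setNames(rep(c("A", "B"), each = 3), clin$SampleID)
  ts <- threshold_scan(clin, labels, "feat")
  expect_true(ts$separable)
  expect_equal(ts$threshold, 6.5)
  expect_equal(ts$split_accuracy, 1)
  expect_equal(ts$range["A", "max"], 3)
  # identical distributions: accuracy near the majority rate
  clin2 <- data.frame(SampleID = paste0("S", 1:40),
                      feat = rep(seq(0, 1, length.out = 20), 2))
  labels2 <- setNames(rep(c("A", "B"), each = 20), clin2$SampleID)
  ts2 <- threshold_scan(clin2, labels2, "feat")
  expect_false(ts2$separable)
  expect_lte(ts2$split_accuracy, 0.65)
  # single sample per cluster: extrema equal the values
  clin3 <- data.frame(SampleID = c("S1", "S2"), feat = c(2, 9))
  ts3 <- threshold_scan(clin3, setNames(c("A", "B"), clin3$SampleID), "feat")
  expect_equal(unname(ts3$range[, "min"]), c(2, 9))
  expect_error(threshold_scan(clin3, setNames(c("A", "B"), clin3$SampleID),
                              "nope"), "numeric")
})

test_that("group comparisons use the exact Wilcoxon where it applies", {
  clin <- data.frame(SampleID = paste0("S", 1:6), v = c(1, 2, 3, 4, 5, 6))
  labels <- setNames(rep(c("A", "B"), each = 3), clin$SampleID)
  cmp <- compare_groups(clin, labels)
  # most extreme rank split of 3 + 3: two-sided exact p = 2/choose(6,3)
  expect_equal(cmp$p[cmp$variable == "v"], 0.1, tolerance = 1e-12)
  expect_equal(cmp$test[cmp$variable == "v"], "wilcoxon")
  # identical groups sit at the null centre
  clin2 <- data.frame(SampleID = paste0("S", 1:8),
                      v = rep(c(1.5, 2.5, 3.5, 4.5), 2))
  labels2 <- setNames(rep(c("A", "B"), each = 4), clin2$SampleID)
  cmp2 <- compare_groups(clin2, labels2)
  expect_gt(cmp2$p, 0.9)
})

test_that("chi-squared statistics match the hand computation", {
  clin <- data.frame(SampleID = paste0("S", 1:20),
                     cat = rep(c("yes", "no"), each = 10))
  labels <- setNames(rep(c("A", "B"), each = 10), clin$SampleID)
  cmp <- compare_groups(clin, labels)          # perfect 10,0 / 0,10 table
  expect_equal(cmp$test, "chi-squared")
  expect_equal(unname(cmp$statistic), 20, tolerance = 1e-12)
  cmp_yates <- compare_groups(clin, labels, yates = TRUE)
  expect_lt(cmp_yates$statistic, 20)
})

test_that("exact and normal-approximation Wilcoxon p-values agree for larger n", {
  withr::with_seed(6, {
    x <- rnorm(25); y <- rnorm(25, 0.5)
  })
  p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
  clin <- data.frame(SampleID = paste0("S", 1:50), v = c(x, y))
  labels <- setNames(rep(c("A", "B"), each = 25), clin$SampleID)
  p_approx <- compare_groups(clin, labels)$p
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("degenerate variables are skipped with warnings", {
  clin <- data.frame(SampleID = paste0("S", 1:10),
                     ok = rnorm(10),
                     partial = c(rnorm(8), NA, NA))
  labels <- setNames(rep(c("A", "B"), c(8, 2)), clin$SampleID)
  expect_warning(cmp <- compare_groups(clin, labels), "skipped")
  expect_false("partial" %in% cmp$variable)
  expect_true("ok" %in% cmp$variable)
})
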