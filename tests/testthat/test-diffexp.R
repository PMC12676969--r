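test_that("two-group fits reduce to group-mean differences", {
  set.seed(2)
  Y <- matrix(rnorm(60, 6), 10, 6, dimnames = list(NULL, paste0("P", 1:6)))
  g <- rep(c("AD", "HC"), each = 5)
  design <- make_design(g, "AD")
  fits <- fit_linear_models(Y, design)
  expect_equal(unname(fits$coef),
               unname(colMeans(Y[1:5, ]) - colMeans(Y[6:10, ])),
               tolerance = 1e-12)
  # a covariate orthogonal to the group indicator leaves the contrast alone
  age <- rep(c(-1, 1, -1, 1, 0), 2)  # balanced within each group
  design2 <- make_design(g, "AD", age = age)
  fits2 <- fit_linear_models(Y, design2)
  expect_equal(fits$coef, fits2$coef, tolerance = 1e-10)
})

test_that("a noiseless planted shift is estimated exactly", {
  base <- matrix(rep(runif(8, 2, 10), each = 12), 12, 8,
                 dimnames = list(NULL, paste0("P", 1:8)))
  g <- rep(c("AD", "HC"), each = 6)
  base[g == "AD", 3] <- base[g == "AD", 3] + 1.7
  fits <- fit_linear_models(base, make_design(g, "AD"))
  expect_equal(unname(fits$coef[3]), 1.7, tolerance = 1e-12)
  expect_equal(unname(fits$coef[1]), 0, tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected", {
  g <- rep(c("AD", "HC"), each = 4)
  expect_error(make_design(g, "AD", age = as.integer(g == "AD")),
               "rank deficient")
  expect_error(make_design(rep("AD", 4), "AD"), "split")
})

test_that("d0 overrides reproduce the ordinary-t and fully-pooled limits", {
  co <- simulate_cohort(small_config(6))
  design <- make_design(co$npx$group, "AD", age = co$clinical$Age,
                        sex = co$clinical$Sex)
  fits <- fit_linear_models(co$npx, design)
  none <- ebayes_moderate(fits, d0_override = 0)
  t_ord <- fits$coef / (sqrt(fits$s2) * fits$stdev_unscaled)
  expect_equal(none$t_mod, unname(t_ord), tolerance = 1e-10)
  expect_equal(none$p_raw,
               unname(2 * pt(-abs(t_ord), fits$df_resid)), tolerance = 1e-10)
  full <- ebayes_moderate(fits, d0_override = Inf)
  expect_equal(length(unique(round(full$s2_post, 12))), 1L)
  expect_equal(full$s2_post[1], attr(full, "s0_sq"))
})

test_that("the moment estimator recovers the generating variance prior", {
  set.seed(7)
  G <- 2000; d0 <- 4; s0_sq <- 1; d <- 10
  sigma2 <- s0_sq * d0 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, d) / d
  fits <- structure(list(coef = rnorm(G), stdev_unscaled = rep(0.3, G),
                         s2 = s2, df_resid = rep(d, G), amean = rep(5, G),
                         protein = paste0("P", seq_len(G))),
                    class = "protein_fits")
  de <- ebayes_moderate(fits)
  expect_lt(abs(attr(de, "d0") - d0) / d0, 0.25)
  expect_lt(abs(attr(de, "s0_sq") - s0_sq) / s0_sq, 0.25)
})

test_that("moderation agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  co <- simulate_cohort(small_config(10))
  design <- make_design(co$npx$group, "AD", age = co$clinical$Age,
                        sex = co$clinical$Sex)
  fits <- fit_linear_models(co$npx, design)
  ours <- ebayes_moderate(fits)
  lf <- limma::lmFit(t(co$npx$values), design)
  le <- limma::eBayes(lf)
  expect_equal(attr(ours, "d0"), le$df.prior, tolerance = 0.05)
  expect_equal(attr(ours, "s0_sq"), le$s2.prior, tolerance = 0.05)
  expect_equal(ours$t_mod, unname(le$t[, "group"]), tolerance = 1e-6)
  expect_equal(ours$p_raw, unname(le$p.value[, "group"]), tolerance = 1e-6)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  p <- c(0.001, 0.02, 0.9, 0.04, 0.3)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("DE thresholds are strict on both axes", {
  de <- data.frame(protein = c("a", "b", "c", "d"),
                   coef = c(1.19, 2.0, 1.5, -1.5),
                   p_adj = c(0.001, 0.06, 0.01, 0.01))
  expect_setequal(threshold_de(de, 1.2, 0.05, "up"), "c")
  expect_setequal(threshold_de(de, 1.2, 0.05, "down"), "d")
  expect_setequal(threshold_de(de, 1.2, 0.05, "both"), c("c", "d"))
})

test_that("no downregulated proteins pass at the planted defaults", {
  co <- simulate_cohort(sim_config(seed = 3))
  de_ad <- de_contrast(co$npx, "ad_vs_hc", clinical = co$clinical)
  expect_length(threshold_de(de_ad, direction = "down"), 0)
  cl <- co$truth$cluster_label
  de_cc <- de_contrast(co$npx, "c1_vs_c2", clinical = co$clinical, cluster = cl)
  expect_length(threshold_de(de_cc, direction = "down"), 0)
})

test_that("the Venn trichotomy partitions the input sets", {
  g <- venn_trichotomy(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(g$stepwise, c("b", "c"))
  expect_setequal(g$unique, "d")
  expect_setequal(g$upregulated_ad, "a")
  same <- venn_trichotomy(c("a", "b"), c("a", "b"))
  expect_setequal(same$stepwise, c("a", "b"))
  expect_length(same$unique, 0)
  disjoint <- venn_trichotomy(c("a", "b"), c("x", "y"))
  expect_length(disjoint$stepwise, 0)
  expect_setequal(disjoint$unique, c("x", "y"))
  # partition property on random sets
  withr::with_seed(1, for (i in 1:20) {
    u <- sample(letters, 10)
    s1 <- sample(u, 6); s2 <- sample(u, 5)
    g <- venn_trichotomy(s1, s2)
    expect_setequal(c(g$upregulated_ad, g$stepwise, g$unique), union(s1, s2))
    expect_length(intersect(g$stepwise, g$unique), 0)
    expect_equal(length(g$stepwise) + length(g$unique), length(s2))
  })
})

test_that("volcano export clips zero p-values and preserves signs", {
  de <- data.frame(protein = c("a", "b", "c"),
                   coef = c(-2, 0.5, 3),
                   p_adj = c(0, 1, 0.01))
  v <- volcano_table(de)
  expect_true(is.finite(v$neg_log10_p_adj[1]))
  expect_equal(v$neg_log10_p_adj[2], 0)
  expect_identical(sign(v$coef), sign(de$coef))
  expect_identical(v$flag, c(TRUE, FALSE, TRUE))
})

test_that("the marginal type-I rate calibrates under the exchangeable structured null", {
  rates <- vapply(1:5, function(s) {
    co <- simulate_cohort(structured_null_config(s))
    de <- de_contrast(co$npx, "ad_vs_hc", clinical = co$clinical)
    mean(de$p_raw < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.025)
})
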