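test_that("GMT files round-trip", {
  sets <- list(alpha = c("P1", "P2", "P3"), beta = c("P2", "P9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, description = c("first", "second"))
  back <- read_gmt(path)
  expect_identical(back$alpha, sets$alpha)
  expect_identical(back$beta, sets$beta)
  expect_identical(attr(back, "description"), c("first", "second"))
})

test_that("ME-correlation ranking puts module members on top", {
  co <- simulate_cohort(small_config(17))
  Z <- zscale(co$npx)$values
  truth <- co$truth$module_label
  labels <- setNames(ifelse(truth == 0, "grey", paste0("mod", truth)),
                     names(truth))
  eig <- module_eigenproteins(Z, labels)
  ranked <- rank_by_me_correlation(co$npx, eig$me[, "mod1"])
  members <- names(labels)[labels == "mod1"]
  top_n <- ranked$protein[seq_along(members)]
  expect_gt(mean(members %in% top_n), 0.8)
  # exact self and anti profiles
  X <- cbind(self = eig$me[, "mod1"], anti = -eig$me[, "mod1"],
             noise = withr::with_seed(1, rnorm(nrow(Z))))
  r2 <- rank_by_me_correlation(X, eig$me[, "mod1"])
  expect_equal(r2$protein[1], "self")
  expect_equal(r2$score[1], 1, tolerance = 1e-12)
  expect_equal(r2$protein[nrow(r2)], "anti")
  expect_equal(r2$score[nrow(r2)], -1, tolerance = 1e-12)
})

test_that("the GSEA walk matches an explicit running sum on a toy list", {
  ranked <- data.frame(protein = paste0("P", 1:6),
                       score = c(0.9, 0.7, 0.4, -0.1, -0.5, -0.8))
  sets <- list(top = c("P1", "P3"))
  res <- gsea_preranked(ranked, sets, weight = 1, nperm = 100, seed = 1)
  # explicit walk: hits add |s|/sum(|s| in set), misses subtract 1/(N-K)
  hit_sum <- 0.9 + 0.4
  steps <- c(0.9 / hit_sum, -0.25, 0.4 / hit_sum, -0.25, -0.25, -0.25)
  walk <- cumsum(steps)
  expect_equal(res$ES, walk[which.max(abs(walk))], tolerance = 1e-12)
  expect_equal(res$K, 2)
})

test_that("extreme enrichment hits the permutation floor and the full set walks to zero", {
  co <- simulate_cohort(small_config(18))
  Z <- zscale(co$npx)$values
  truth <- co$truth$module_label
  labels <- setNames(ifelse(truth == 0, "grey", paste0("mod", truth)),
                     names(truth))
  eig <- module_eigenproteins(Z, labels)
  ranked <- rank_by_me_correlation(co$npx, eig$me[, "mod1"])
  sets <- list(top = ranked$protein[1:20],
               everything = ranked$protein)
  res <- gsea_preranked(ranked, sets, nperm = 200, seed = 2)
  # no null draw beats the planted set: p sits at the permutation floor
  expect_lt(res$p_raw[res$set == "top"], 0.02)
  expect_gt(res$ES[res$set == "top"], 0)
  # full-universe set: no misses exist, degenerate walk pinned at zero
  expect_equal(res$ES[res$set == "everything"], 0)
})

test_that("the enrichment score agrees with the reference implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(8, {
    scores <- sort(rnorm(50), decreasing = TRUE)
    names(scores) <- paste0("P", seq_len(50))
    set <- sample(names(scores), 10)
  })
  ranked <- data.frame(protein = names(scores), score = unname(scores))
  ours <- gsea_preranked(ranked, list(s = set), nperm = 100, seed = 1)
  ref <- suppressWarnings(
    fgsea::fgsea(list(s = set), scores, nperm = 100, gseaParam = 1))
  expect_equal(ours$ES, ref$ES, tolerance = 1e-6)
})

test_that("GSEA p-values are calibrated on shuffled scores", {
  base_scores <- seq(0.9, -0.9, length.out = 60)
  prots <- paste0("P", 1:60)
  pvals <- withr::with_seed(31, vapply(1:100, function(i) {
    ranked <- data.frame(protein = prots, score = sample(base_scores))
    ranked <- ranked[order(-ranked$score), ]
    set <- sample(prots, 12)
    gsea_preranked(ranked, list(s = set), nperm = 100, seed = i)$p_raw
  }, numeric(1)))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("hypergeometric p matches closed forms and exhaustive enumeration", {
  universe <- paste0("P", 1:10)
  sets <- list(s = universe[1:5])
  res <- hypergeometric_ora(universe[c(1, 2, 3, 4)], sets, universe)
  expect_equal(res$p_raw, choose(5, 4) * choose(5, 0) / choose(10, 4),
               tolerance = 1e-12)
  # brute force at N = 12: P(overlap >= k) over all selections of size n
  universe <- paste0("G", 1:12)
  setm <- universe[1:6]
  sel <- universe[c(1, 2, 3, 7, 8)]
  k_obs <- length(intersect(sel, setm))
  res <- hypergeometric_ora(sel, list(s = setm), universe)
  combos <- utils::combn(12, 5)
  overlap <- colSums(combos <= 6)
  expect_equal(res$p_raw, mean(overlap >= k_obs), tolerance = 1e-12)
})

test_that("ORA degenerate and monotonicity properties", {
  universe <- paste0("P", 1:30)
  sets <- list(s = universe[1:10])
  expect_equal(hypergeometric_ora(character(0), sets, universe)$p_raw, 1)
  # p is non-increasing in the overlap k at fixed K, n, N
  p_at_k <- vapply(0:5, function(k) {
    sel <- c(universe[seq_len(k)], universe[10 + seq_len(5 - k)])
    hypergeometric_ora(sel, sets, universe)$p_raw
  }, numeric(1))
  expect_true(all(diff(p_at_k) <= 1e-12))
  expect_error(hypergeometric_ora("missing", sets, universe), "subset")
})

test_that("results are invariant to gene-set ordering and to dropped empty sets", {
  co <- simulate_cohort(small_config(20))
  gmt <- make_module_gmt(co$truth$module_label, n_random = 3, seed = 5)
  sel <- co$truth$ad_up_set
  a <- hypergeometric_ora(sel, gmt, co$npx$protein_ids)
  b <- hypergeometric_ora(sel, rev(gmt), co$npx$protein_ids)
  expect_equal(a[order(a$set), c("k", "K", "p_raw", "p_adj")],
               b[order(b$set), c("k", "K", "p_raw", "p_adj")],
               ignore_attr = TRUE)
  gmt$ghost <- c("NOPE1", "NOPE2")
  expect_warning(c_res <- hypergeometric_ora(sel, gmt, co$npx$protein_ids),
                 "dropped")
  expect_false("ghost" %in% c_res$set)
})
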