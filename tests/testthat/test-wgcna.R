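test_that("signed adjacency matches its closed forms", {
  # build protein profiles with exact correlations 1, -1, 0
  x <- c(-1, 0, 1, 2)
  X <- cbind(a = x, b = 2 * x + 3, c = -x, d = c(1, -1, -1, 1))
  A <- signed_adjacency(X, power = 9)
  expect_equal(A["a", "b"], 1)
  expect_equal(A["a", "c"], 0)
  expect_equal(A["a", "d"], 0.5^9, tolerance = 1e-12)
  expect_equal(A["a", "d"], 0.001953125, tolerance = 1e-12)
  expect_true(isSymmetric(A))
  expect_true(all(A >= 0 & A <= 1))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  A2 <- signed_adjacency(X[, perm], power = 9)
  expect_equal(A2, A[perm, perm])
})

test_that("zero-variance proteins get zero correlation with a warning", {
  X <- cbind(a = rnorm(6), flat = rep(2, 6))
  expect_warning(A <- signed_adjacency(X, 6), "zero-variance")
  expect_equal(A["a", "flat"], 0.5^6)
})

test_that("TOM matches a brute-force triple-loop oracle", {
  withr::with_seed(11, {
    p <- 10
    C <- cor(matrix(rnorm(30 * p), 30, p))
    A <- ((1 + C) / 2)^4
    diag(A) <- 1
  })
  tom <- tom_similarity(A)
  oracle <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) if (i != j) {
    l <- sum(vapply(setdiff(seq_len(p), c(i, j)),
                    function(u) A[i, u] * A[u, j], numeric(1)))
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    oracle[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  expect_equal(tom, oracle, tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("TOM limit cases: complete graph and disconnected blocks", {
  ones <- matrix(1, 4, 4)
  expect_equal(tom_similarity(ones), ones)
  blocked <- matrix(0, 6, 6)
  blocked[1:3, 1:3] <- 0.8
  blocked[4:6, 4:6] <- 0.8
  diag(blocked) <- 1
  tom <- tom_similarity(blocked)
  expect_true(all(tom[1:3, 4:6] == 0))
})

test_that("scale-free structured data reaches the fit target, noise does not", {
  withr::with_seed(42, {
    n <- 100; p <- 400
    lam <- runif(p)^(-1 / 2.5); lam <- lam / max(lam)  # heavy-tailed hubs
    f <- rnorm(n)
    X_hub <- outer(f, lam) + matrix(rnorm(n * p, sd = 0.35), n, p)
    X_noise <- matrix(rnorm(200 * 120), 200, 120)
  })
  sp <- pick_soft_power(X_hub)
  expect_gte(max(sp$fit_table$r2, na.rm = TRUE), 0.9)
  expect_true(sp$fit_table$r2[sp$fit_table$power == sp$power] >= 0.9)
  expect_equal(nrow(sp$fit_table), 20)
  expect_warning(sp_noise <- pick_soft_power(X_noise), "default")
  expect_equal(sp_noise$power, 12)
})

test_that("perfectly correlated planted modules merge into one", {
  withr::with_seed(3, {
    n <- 40
    f <- rnorm(n)
    X <- cbind(matrix(rep(f, 25), n) + matrix(rnorm(n * 25, sd = 0.3), n),
               matrix(rep(f, 25), n) + matrix(rnorm(n * 25, sd = 0.3), n))
    colnames(X) <- paste0("P", 1:50)
  })
  A <- signed_adjacency(X, 6)
  mods <- detect_modules(tom_similarity(A), X, min_module_size = 10)
  expect_equal(length(mods$sizes), 1L)
})

test_that("a too-large minimum module size sends everything to grey", {
  co <- simulate_cohort(small_config(2))
  Z <- zscale(co$npx)$values
  A <- signed_adjacency(Z, 6)
  mods <- detect_modules(tom_similarity(A), Z, min_module_size = 150,
                         kme_rescue = 1.01)
  expect_true(all(mods$module == "grey"))
})

test_that("module detection recovers planted blocks on a compact cohort", {
  co <- simulate_cohort(small_config(12))
  Z <- zscale(co$npx)$values
  sp <- suppressWarnings(pick_soft_power(Z))
  A <- signed_adjacency(Z, sp$power)
  mods <- detect_modules(tom_similarity(A), Z, min_module_size = 15)
  truth <- co$truth$module_label
  nz <- truth != 0
  expect_gt(adjusted_rand_index(mods$module[nz], truth[nz]), 0.8)
  # order invariance up to labels
  perm <- withr::with_seed(4, sample(ncol(Z)))
  A2 <- signed_adjacency(Z[, perm], sp$power)
  mods2 <- detect_modules(tom_similarity(A2), Z[, perm], min_module_size = 15)
  expect_gt(adjusted_rand_index(mods$module[perm], mods2$module), 0.999)
})

test_that("eigenproteins summarise rank-1 modules exactly", {
  withr::with_seed(5, {
    n <- 30
    f <- rnorm(n)
    X <- cbind(matrix(rep(f, 12), n), matrix(rnorm(n * 12), n))
    colnames(X) <- paste0("P", 1:24)
  })
  labels <- setNames(rep(c("turquoise", "grey"), each = 12), colnames(X))
  eig <- module_eigenproteins(X, labels)
  # identical member profiles: ME reproduces the common profile, kME = 1
  expect_gt(abs(cor(eig$me[, "turquoise"], f)), 0.9999)
  expect_true(all(eig$kme[1:12, "turquoise"] > 0.9999))
  expect_gt(cor(eig$me[, "turquoise"], rowMeans(scale(X[, 1:12]))), 0)
  # PCA optimality: ME explains at least as much module variance as any member
  Z <- scale(X[, 1:12])
  best_member <- max(vapply(1:12, function(j)
    sum(cor(Z, Z[, j])^2), numeric(1)))
  me_var <- sum(cor(Z, eig$me[, "turquoise"])^2)
  expect_gte(me_var + 1e-8, best_member)
})

test_that("hubs are top-loading proteins of their planted blocks", {
  co <- simulate_cohort(small_config(13, noise_sd = 0.3,
                                     loading_range = c(0.3, 0.95)))
  Z <- zscale(co$npx)$values
  truth <- co$truth$module_label
  labels <- setNames(ifelse(truth == 0, "grey", paste0("mod", truth)),
                     names(truth))
  eig <- module_eigenproteins(Z, labels)
  for (m in c("mod1", "mod2")) {
    members <- names(labels)[labels == m]
    hub <- eig$hubs[[m]]
    lam <- co$truth$loadings[members]
    expect_gte(lam[hub], quantile(lam, 0.85))  # among the top-loading proteins
  }
})

test_that("module-trait correlations recognise self, coupling and nulls", {
  co <- simulate_cohort(sim_config(seed = 4))
  Z <- zscale(co$npx)$values
  truth <- co$truth$module_label
  labels <- setNames(ifelse(truth == 0, "grey", paste0("mod", truth)),
                     names(truth))
  eig <- module_eigenproteins(Z, labels)
  pat <- co$npx$group == "AD"
  eig_pat <- eig
  eig_pat$me <- eig$me[pat, , drop = FALSE]
  cl <- co$clinical[pat, ]
  cl$self_trait <- eig_pat$me[, "mod1"]
  cl$permuted <- withr::with_seed(9, sample(cl$EASI))
  mtc <- module_trait_correlation(eig_pat, cl)
  expect_equal(mtc$r["mod1", "self_trait"], 1, tolerance = 1e-10)
  expect_gt(mtc$r["mod1", "EASI"], 0.3)
  expect_lt(mtc$p_adj["mod1", "EASI"], 0.05)
  expect_lt(abs(mtc$r["mod1", "permuted"]), 0.3)
  expect_true(all(mtc$p_adj >= mtc$p_raw, na.rm = TRUE))
  expect_true(all(abs(mtc$r) <= 1, na.rm = TRUE))
})
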