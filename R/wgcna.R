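# conventional module colour sequence (largest module first)
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Signed soft-threshold adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^power` with Pearson correlation across
#' samples; anti-correlated proteins get near-zero adjacency (signed
#' network). Zero-variance proteins are assigned zero correlation with a
#' warning.
#'
#' @param X samples x proteins matrix (z-scaled NPX).
#' @param power soft-thresholding exponent (positive).
#' @return symmetric adjacency matrix with unit diagonal.
#' @export
signed_adjacency <- function(X, power) {
  stopifnot(power >= 1)
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  bad <- sds == 0 | is.na(sds)
  C <- suppressWarnings(cor(X))
  if (any(bad)) {
    warning(sum(bad), " zero-variance protein(s): correlations set to 0")
    C[bad, ] <- 0
    C[, bad] <- 0
  }
  C[is.na(C)] <- 0
  A <- ((1 + C) / 2)^power
  diag(A) <- 1
  A
}

# scale-free topology fit index: R^2 of log10 p(k) vs log10 k over
# equal-width connectivity bins, zeroed when the slope is non-negative
scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) < 3 || diff(range(k)) == 0) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  p_k <- as.numeric(table(bin)) / length(k)
  ok <- !is.na(mean_k) & p_k > 0 & mean_k > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- lm(log10(p_k[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  if (coef(fit)[2] >= 0) 0 else r2
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, the signed adjacency is computed, per-protein
#' connectivity `k_i = sum_j a_ij` is binned, and the scale-free fit R^2 is
#' taken from the log-log regression of the connectivity distribution.
#' Returns the lowest power reaching `r2_target`. When no candidate reaches
#' the target — typical for data whose correlation structure is modular
#' rather than scale-free — the conventional signed-network default power
#' (12, capped at the largest candidate) is used, with a warning.
#'
#' @param X samples x proteins matrix (z-scaled NPX).
#' @param powers candidate integer powers.
#' @param r2_target required scale-free fit.
#' @return list with `power` and `fit_table` (per power: R^2, mean and
#'   median connectivity).
#' @export
pick_soft_power <- function(X, powers = 1:20, r2_target = 0.9) {
  X <- as.matrix(X)
  if (ncol(X) < 30) stop("need at least 30 proteins for the scale-free fit")
  C <- suppressWarnings(cor(X))
  C[is.na(C)] <- 0
  base <- (1 + C) / 2
  diag(base) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(base^b)
    data.frame(power = b, r2 = scale_free_fit(k),
               mean_k = mean(k), median_k = median(k))
  })
  fit_table <- do.call(rbind, rows)
  reached <- which(!is.na(fit_table$r2) & fit_table$r2 >= r2_target)
  if (length(reached)) {
    power <- fit_table$power[reached[1]]
  } else {
    power <- min(12, max(powers))
    warning(sprintf(
      "no candidate power reached scale-free R^2 >= %.2f (max %.2f); using signed-network default %d",
      r2_target, max(fit_table$r2, na.rm = TRUE), power))
  }
  list(power = power, fit_table = fit_table)
}

#' Signed topological overlap matrix
#'
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_{u != i} a_iu`;
#' the shared-neighbourhood similarity used for module detection.
#'
#' @param adjacency symmetric adjacency matrix with unit diagonal.
#' @return symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  stopifnot(nrow(A) == ncol(A))
  diag(A) <- 1
  k <- rowSums(A) - 1
  L <- A %*% A - 2 * A      # removes the u = i and u = j terms (diag = 1)
  k_min <- outer(k, k, pmin)
  tom <- (L + A) / (k_min + 1 - A)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules on the TOM dendrogram
#'
#' Proteins are clustered hierarchically (Ward linkage on `1 - TOM`); the
#' tree is cut at the `cut_quantile` of merge heights; branches smaller than
#' `min_module_size` go to grey. Initial modules are then refined by
#' iterative kME reassignment (every protein moves to the module whose
#' eigenprotein it correlates with most, if that correlation reaches
#' `kme_rescue`) — the analogue of the assignment-refinement stage of hybrid
#' dynamic tree cut — and modules whose eigenproteins correlate above
#' `1 - merge_height` are merged. Final modules are named by the
#' conventional colour sequence in decreasing size order; unassigned
#' proteins are `"grey"`.
#'
#' @param tom TOM matrix from [tom_similarity].
#' @param X samples x proteins matrix used for eigenproteins (z-scaled NPX).
#' @param min_module_size smallest retained module.
#' @param cut_quantile quantile of dendrogram merge heights for the cut.
#' @param merge_height modules with ME correlation `> 1 - merge_height` merge.
#' @param kme_rescue minimum kME for (re)assignment to a module.
#' @param refine_iter kME-reassignment passes.
#' @return object of class `module_assignment`: per-protein `module` (colour
#'   labels), `sizes`, and the `merge_history`.
#' @export
detect_modules <- function(tom, X, min_module_size = 20, cut_quantile = 0.99,
                           merge_height = 0.25, kme_rescue = 0.3,
                           refine_iter = 2) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(nrow(tom) == p)
  if (p < min_module_size) {
    warning("fewer proteins than min_module_size; all grey")
    return(finish_modules(rep(0L, p), colnames(X), list()))
  }
  tree <- hclust(as.dist(1 - tom), method = "ward.D2")
  lab <- cutree(tree, h = quantile(tree$height, cut_quantile))
  lab <- drop_small(lab, min_module_size)
  # kME refinement
  for (i in seq_len(refine_iter)) {
    mods <- setdiff(unique(lab), 0L)
    if (!length(mods)) break
    ME <- vapply(mods, function(m) eigenprotein(X[, lab == m, drop = FALSE]),
                 numeric(nrow(X)))
    km <- suppressWarnings(cor(X, ME))
    km[is.na(km)] <- 0
    best <- max.col(km, ties.method = "first")
    best_val <- km[cbind(seq_len(p), best)]
    lab <- ifelse(best_val >= kme_rescue, mods[best], 0L)
    lab <- drop_small(lab, min_module_size)
  }
  # eigenprotein merge
  merge_history <- list()
  repeat {
    mods <- setdiff(unique(lab), 0L)
    if (length(mods) < 2) break
    ME <- vapply(mods, function(m) eigenprotein(X[, lab == m, drop = FALSE]),
                 numeric(nrow(X)))
    CM <- suppressWarnings(cor(ME))
    CM[is.na(CM)] <- 0
    diag(CM) <- 0
    if (max(CM) <= 1 - merge_height) break
    mx <- which(CM == max(CM), arr.ind = TRUE)[1, ]
    merge_history[[length(merge_history) + 1]] <-
      c(kept = mods[mx[1]], absorbed = mods[mx[2]], me_cor = max(CM))
    lab[lab == mods[mx[2]]] <- mods[mx[1]]
  }
  finish_modules(lab, colnames(X), merge_history)
}

drop_small <- function(lab, min_size) {
  sz <- table(lab[lab != 0])
  small <- as.integer(names(sz)[sz < min_size])
  lab[lab %in% small] <- 0L
  lab
}

finish_modules <- function(lab, protein_ids, merge_history) {
  mods <- setdiff(unique(lab), 0L)
  sz <- vapply(mods, function(m) sum(lab == m), integer(1))
  ord <- order(-sz)
  colors <- rep("grey", length(lab))
  for (i in seq_along(ord)) {
    name <- if (i <= length(module_colors)) module_colors[i] else paste0("module", i)
    colors[lab == mods[ord[i]]] <- name
  }
  names(colors) <- protein_ids
  sizes <- sort(table(colors[colors != "grey"]), decreasing = TRUE)
  structure(list(module = colors, sizes = sizes, merge_history = merge_history),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module assignment: %d modules (+%d grey)\n",
              length(x$sizes), sum(x$module == "grey")))
  print(x$sizes)
  invisible(x)
}

# first right-singular direction of a z-scaled submatrix, as per-sample
# scores; oriented to correlate positively with average expression
eigenprotein <- function(Xsub) {
  Z <- scale(Xsub)
  Z[is.na(Z)] <- 0
  s <- svd(Z, nu = 1, nv = 0)
  me <- s$u[, 1]
  avg <- rowMeans(Z)
  if (sum(me * avg) < 0) me <- -me
  me
}

#' Module eigenproteins, kME table and hub proteins
#'
#' The eigenprotein (ME) of a module is the first principal component of its
#' z-scaled sample x protein submatrix, oriented to correlate positively
#' with the module's average profile. kME is the Pearson correlation of
#' every protein (not only members) with every ME; the hub of a module is
#' its member with the highest own-module kME.
#'
#' @param X samples x proteins matrix (z-scaled NPX).
#' @param modules a `module_assignment` from [detect_modules] (or a named
#'   vector of module labels).
#' @return object of class `eigenprotein_set`: `me` (samples x modules),
#'   `kme` (proteins x modules), `hubs`, `var_explained`.
#' @export
module_eigenproteins <- function(X, modules) {
  X <- as.matrix(X)
  labels <- if (inherits(modules, "module_assignment")) modules$module else modules
  stopifnot(length(labels) == ncol(X))
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey modules")
  ME <- matrix(NA_real_, nrow(X), length(mods),
               dimnames = list(rownames(X), mods))
  var_exp <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    sub <- X[, labels == m, drop = FALSE]
    if (ncol(sub) < 2) { ME[, m] <- 0; next }
    Z <- scale(sub)
    Z[is.na(Z)] <- 0
    s <- svd(Z, nu = 1, nv = 0)
    me <- s$u[, 1]
    if (sum(me * rowMeans(Z)) < 0) me <- -me
    ME[, m] <- me
    var_exp[m] <- s$d[1]^2 / sum(Z^2)
  }
  kme <- suppressWarnings(cor(X, ME))
  kme[is.na(kme)] <- 0
  hubs <- vapply(mods, function(m) {
    members <- which(labels == m)
    members[which.max(kme[members, m])]
  }, integer(1))
  hubs <- setNames(colnames(X)[hubs], mods)
  structure(list(me = ME, kme = kme, hubs = hubs, var_explained = var_exp,
                 module = labels),
            class = "eigenprotein_set")
}

#' Module-trait correlation grid
#'
#' Pearson correlation of each module eigenprotein with each clinical trait
#' (pairwise-complete observations), two-sided p from the t transform, and
#' BH adjustment across the full module x trait grid. Binary traits are
#' coded 0/1; constant traits yield missing cells.
#'
#' @param eigen an `eigenprotein_set`.
#' @param clinical clinical data.frame (rows aligned by `SampleID` with the
#'   ME rows when present, otherwise by position).
#' @param traits optional subset of trait columns.
#' @return object of class `module_trait_corr` with matrices `r`, `p_raw`,
#'   `p_adj`, `n_obs`.
#' @export
module_trait_correlation <- function(eigen, clinical, traits = NULL) {
  ME <- eigen$me
  if (!is.null(clinical$SampleID) && !is.null(rownames(ME))) {
    clinical <- clinical[match(rownames(ME), clinical$SampleID), , drop = FALSE]
  }
  drop_cols <- c("SampleID", "Group")
  if (is.null(traits)) traits <- setdiff(names(clinical), drop_cols)
  tm <- sapply(traits, function(tr) {
    v <- clinical[[tr]]
    if (is.numeric(v)) return(as.numeric(v))
    f <- factor(v)
    if (nlevels(f) == 2) return(as.numeric(f) - 1)
    rep(NA_real_, length(v))
  })
  tm <- as.matrix(tm)
  mods <- colnames(ME)
  r <- p <- nobs <- matrix(NA_real_, length(mods), ncol(tm),
                           dimnames = list(mods, colnames(tm)))
  for (i in seq_along(mods)) {
    for (j in seq_len(ncol(tm))) {
      ok <- complete.cases(ME[, i], tm[, j])
      n <- sum(ok)
      nobs[i, j] <- n
      if (n < 3 || sd(tm[ok, j]) == 0 || sd(ME[ok, i]) == 0) next
      rv <- cor(ME[ok, i], tm[ok, j])
      r[i, j] <- rv
      tt <- rv * sqrt((n - 2) / max(1 - rv^2, .Machine$double.eps))
      p[i, j] <- 2 * pt(-abs(tt), df = n - 2)
    }
  }
  p_adj <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(r = r, p_raw = p, p_adj = p_adj, n_obs = nobs),
            class = "module_trait_corr")
}
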