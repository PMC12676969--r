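#' k-means endotype fit with k-means++ restarts
#'
#' Lloyd's algorithm seeded by k-means++ initialisation, keeping the best of
#' `restarts` runs by total within-cluster sum of squares. Cluster indices
#' are canonicalised by decreasing cluster size (ties broken by the smallest
#' member index) so labels are comparable across runs.
#'
#' @param X numeric matrix, samples in rows (typically z-scaled NPX).
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param restarts number of independent initialisations.
#' @param seed RNG seed; the fit is deterministic given it.
#' @return an object of class `cluster_model` with `assignments`,
#'   `centroids`, `wcss`, `k`, `seed`, `restarts`.
#' @export
kmeans_fit <- function(X, k, restarts = 25, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  best <- withr::with_seed(seed_stream(seed, "kmeans"), {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- NULL
      for (attempt in 1:5) {
        centers <- kmeanspp_init(X, k)
        fit <- tryCatch(
          suppressWarnings(kmeans(X, centers = centers, iter.max = 100,
                                  algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && !any(fit$size == 0)) break
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  if (is.null(best)) stop("k-means failed to produce a valid fit")
  relabelled <- canonical_labels(best$cluster)
  centroids <- best$centers[relabelled$order, , drop = FALSE]
  rownames(centroids) <- NULL
  structure(list(k = k, assignments = relabelled$labels, centroids = centroids,
                 wcss = best$tot.withinss, seed = seed, restarts = restarts),
            class = "cluster_model")
}

# k-means++ seeding: subsequent centres drawn with probability proportional
# to squared distance from the nearest chosen centre
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) i <- sample.int(n, 1)
      else i <- sample.int(n, 1, prob = d2)
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

canonical_labels <- function(labels) {
  sz <- table(labels)
  first <- tapply(seq_along(labels), labels, min)
  ord <- order(-as.vector(sz), as.vector(first))
  old <- as.integer(names(sz))[ord]
  new <- match(labels, old)
  list(labels = new, order = old)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means fit: k=%d, sizes %s, WCSS %.3f\n", x$k,
              paste(table(x$assignments), collapse = "/"), x$wcss))
  invisible(x)
}

#' Within-cluster sum of squares scree
#'
#' Best-of-restarts WCSS for `k = 1..k_max`, the elbow diagnostic used to
#' choose the number of endotypes.
#'
#' @inheritParams kmeans_fit
#' @param k_max largest number of clusters to evaluate.
#' @return data.frame with columns `k` and `wcss`.
#' @export
wcss_scree <- function(X, k_max = 10, restarts = 25, seed = 1) {
  X <- as.matrix(X)
  if (k_max > nrow(X)) stop("k_max cannot exceed the number of samples")
  wcss <- vapply(seq_len(k_max), function(k)
    kmeans_fit(X, k, restarts = restarts, seed = seed + k)$wcss, numeric(1))
  data.frame(k = seq_len(k_max), wcss = wcss)
}

#' Cluster stability under healthy-control perturbation
#'
#' Compares patient cluster assignments from a patients-only fit with those
#' from a fit on the combined patient + control data. The control-majority
#' cluster of the combined fit is identified, patient assignments are
#' cross-tabulated, labels are matched by maximum agreement, and patients
#' whose matched label disagrees — including patients landing in the
#' control-majority cluster — are reported as outliers.
#'
#' @param model_patients `cluster_model` fitted on patients only.
#' @param model_all `cluster_model` fitted on patients + controls.
#' @param patient_ids,all_ids sample identifiers aligned with the two models.
#' @param hc_ids identifiers of the control samples within `all_ids`.
#' @return an object of class `stability_report`: `confusion`, `mapping`,
#'   `agreement`, `outliers`, `hc_cluster`.
#' @export
stability_compare <- function(model_patients, model_all,
                              patient_ids, all_ids, hc_ids) {
  if (!all(patient_ids %in% all_ids))
    stop("patient samples must be a subset of the combined model's samples")
  if (!any(hc_ids %in% all_ids))
    stop("no control samples shared with the combined model")
  a_pat <- model_patients$assignments
  names(a_pat) <- patient_ids
  a_all <- model_all$assignments
  names(a_all) <- all_ids
  hc_tab <- table(a_all[intersect(hc_ids, all_ids)])
  hc_cluster <- as.integer(names(hc_tab)[which.max(hc_tab)])
  confusion <- table(patient = a_pat[patient_ids],
                     all = a_all[patient_ids])
  conf_m <- matrix(as.integer(confusion), nrow(confusion), ncol(confusion),
                   dimnames = dimnames(confusion))
  map <- match_labels(conf_m)
  all_levels <- as.integer(colnames(conf_m))
  pat_levels <- as.integer(rownames(conf_m))
  matched_all <- all_levels[map]
  agree <- vapply(seq_along(patient_ids), function(i) {
    pa <- a_pat[patient_ids[i]]
    isTRUE(matched_all[match(pa, pat_levels)] == a_all[patient_ids[i]])
  }, logical(1))
  outliers <- patient_ids[!agree]
  structure(list(confusion = conf_m,
                 mapping = data.frame(patient_cluster = pat_levels,
                                      matched_all_cluster = matched_all),
                 agreement = mean(agree),
                 outliers = outliers,
                 in_hc_cluster = patient_ids[a_all[patient_ids] == hc_cluster],
                 hc_cluster = hc_cluster),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("cluster stability: agreement %.3f, %d outlier(s)\n",
              x$agreement, length(x$outliers)))
  if (length(x$outliers)) cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Resampled cluster reproducibility with a random-forest prediction rule
#'
#' Repeats `iterations` times: split the samples at random, run k-means
#' independently on the training and testing parts, train a random forest to
#' predict the training part's cluster labels from the protein profile,
#' score its resubstitution accuracy on the training part, then predict the
#' testing samples and score agreement with the testing part's own k-means
#' labels, maximised over cluster-label permutations (two independent
#' k-means runs have no shared label space).
#'
#' @inheritParams kmeans_fit
#' @param iterations number of random splits.
#' @param split_fraction proportion of samples in the training part.
#' @param n_trees random-forest size per iteration.
#' @return class `reproducibility_report`: per-iteration accuracies (in
#'   percent), their medians, and the number of skipped iterations.
#' @export
reproducibility <- function(X, k = 2, iterations = 100, split_fraction = 0.7,
                            seed = 1, restarts = 10, n_trees = 500) {
  X <- as.matrix(X)
  n <- nrow(X)
  n_train <- floor(split_fraction * n)
  if (n_train < k || (n - n_train) < k)
    stop("both split parts must contain at least k samples")
  train_acc <- test_acc <- rep(NA_real_, iterations)
  for (it in seq_len(iterations)) {
    it_seed <- seed_stream(seed, paste0("repro-", it))
    idx <- withr::with_seed(it_seed, sample.int(n, n_train))
    tr <- X[idx, , drop = FALSE]
    te <- X[-idx, , drop = FALSE]
    ok <- tryCatch({
      lab_tr <- kmeans_fit(tr, k, restarts = restarts, seed = it_seed + 1)$assignments
      lab_te <- kmeans_fit(te, k, restarts = restarts, seed = it_seed + 2)$assignments
      if (length(unique(lab_tr)) < k || length(unique(lab_te)) < k)
        stop("degenerate split")
      rf <- withr::with_seed(it_seed + 3,
        randomForest::randomForest(x = tr, y = factor(lab_tr), ntree = n_trees))
      pred_tr <- predict(rf, newdata = tr)
      train_acc[it] <- 100 * mean(pred_tr == factor(lab_tr))
      pred_te <- as.integer(as.character(predict(rf, newdata = te)))
      test_acc[it] <- 100 * best_permuted_agreement(pred_te, lab_te, k)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
  }
  skipped <- sum(is.na(train_acc))
  if (skipped > 0.1 * iterations)
    stop("more than 10% of reproducibility iterations were degenerate")
  structure(list(train_accuracy = train_acc, test_accuracy = test_acc,
                 median_train = median(train_acc, na.rm = TRUE),
                 median_test = median(test_acc, na.rm = TRUE),
                 iterations = iterations, split_fraction = split_fraction,
                 skipped = skipped),
            class = "reproducibility_report")
}

best_permuted_agreement <- function(pred, truth, k) {
  perms <- permutations_of(k)
  max(vapply(perms, function(p) mean(p[pred] == truth), numeric(1)))
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf(
    "reproducibility over %d iterations (split %.0f/%.0f): median train %.1f%%, median test %.1f%%\n",
    x$iterations, 100 * x$split_fraction, 100 * (1 - x$split_fraction),
    x$median_train, x$median_test))
  invisible(x)
}
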