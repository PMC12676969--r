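#' Random-forest prediction of endotype membership from clinical data
#'
#' Bagged decision trees predicting proteomics-derived cluster labels from
#' clinical/laboratory variables. Missing values are imputed by the median
#' (numeric) or mode (categorical) before fitting. Reports out-of-bag
#' accuracy and ranks predictors by permutation importance (mean decrease in
#' accuracy) and Gini impurity decrease.
#'
#' @param clinical clinical data.frame (feature columns only are used;
#'   `SampleID`/`Group` are dropped).
#' @param labels per-sample cluster label (aligned by `SampleID` when
#'   present, else by position). Samples with missing labels are dropped.
#' @param n_trees forest size.
#' @param seed RNG seed.
#' @return list of class `rf_predictor`: `model`, `importance` (data.frame
#'   with both measures and their ranks), `oob_accuracy`.
#' @export
fit_rf_predictor <- function(clinical, labels, n_trees = 500, seed = 1) {
  if (!is.null(clinical$SampleID) && !is.null(names(labels)))
    labels <- labels[clinical$SampleID]
  keep <- !is.na(labels)
  y <- factor(labels[keep])
  if (nlevels(y) < 2) stop("need at least two classes")
  feats <- clinical[keep, setdiff(names(clinical), c("SampleID", "Group")),
                    drop = FALSE]
  for (j in names(feats)) {
    v <- feats[[j]]
    if (is.numeric(v)) {
      v[is.na(v)] <- median(v, na.rm = TRUE)
    } else {
      v <- factor(v)
      if (any(is.na(v))) {
        mode_lvl <- names(which.max(table(v)))
        v[is.na(v)] <- mode_lvl
      }
    }
    feats[[j]] <- v
  }
  rf <- withr::with_seed(seed_stream(seed, "rf-clinical"),
    randomForest::randomForest(x = feats, y = y, ntree = n_trees,
                               importance = TRUE))
  imp <- randomForest::importance(rf)
  importance <- data.frame(
    feature = rownames(imp),
    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
    gini_decrease = imp[, "MeanDecreaseGini"],
    row.names = NULL)
  importance$rank_mda <- rank(-importance$mean_decrease_accuracy,
                              ties.method = "first")
  importance$rank_gini <- rank(-importance$gini_decrease, ties.method = "first")
  importance <- importance[order(importance$rank_mda), ]
  oob <- 1 - rf$err.rate[n_trees, "OOB"]
  structure(list(model = rf, importance = importance,
                 oob_accuracy = as.numeric(oob)),
            class = "rf_predictor")
}

#' @export
print.rf_predictor <- function(x, ...) {
  cat(sprintf("random-forest endotype predictor: OOB accuracy %.1f%%\n",
              100 * x$oob_accuracy))
  print(head(x$importance, 5))
  invisible(x)
}

#' Scan a clinical feature for a cluster-separating threshold
#'
#' Reports per-cluster extrema and, when one cluster's maximum lies below
#' the other's minimum, the clean separating value (their midpoint);
#' otherwise the threshold maximising single-split accuracy.
#'
#' @param clinical clinical data.frame.
#' @param labels per-sample cluster labels (two clusters).
#' @param feature numeric feature column name.
#' @return list: `range` (per-cluster min/max), `threshold`, `separable`,
#'   `split_accuracy`.
#' @export
threshold_scan <- function(clinical, labels, feature) {
  if (!is.null(clinical$SampleID) && !is.null(names(labels)))
    labels <- labels[clinical$SampleID]
  v <- clinical[[feature]]
  if (!is.numeric(v)) stop("feature must be numeric")
  ok <- !is.na(v) & !is.na(labels)
  if (!any(ok)) stop("feature has no observed values")
  v <- v[ok]; lab <- factor(labels[ok])
  if (nlevels(lab) != 2) stop("threshold_scan expects exactly two clusters")
  lv <- levels(lab)
  rng <- t(vapply(lv, function(g) range(v[lab == g]), numeric(2)))
  colnames(rng) <- c("min", "max")
  separable <- rng[1, "max"] < rng[2, "min"] || rng[2, "max"] < rng[1, "min"]
  if (separable) {
    if (rng[1, "max"] < rng[2, "min"])
      threshold <- mean(c(rng[1, "max"], rng[2, "min"]))
    else threshold <- mean(c(rng[2, "max"], rng[1, "min"]))
    acc <- 1
  } else {
    cuts <- sort(unique(v))
    accs <- vapply(cuts, function(t) {
      pred <- v <= t
      max(mean(pred == (lab == lv[1])), mean(pred == (lab == lv[2])))
    }, numeric(1))
    threshold <- cuts[which.max(accs)]
    acc <- max(accs)
  }
  list(range = rng, threshold = threshold, separable = separable,
       split_accuracy = acc)
}

#' Per-cluster descriptive comparisons
#'
#' Two-sided Wilcoxon rank-sum tests for numeric variables (exact when both
#' groups have at most `exact_max` observations and no ties, otherwise the
#' tie-corrected normal approximation with continuity correction) and
#' Pearson chi-squared tests for categorical variables (Yates correction
#' off by default). Returns group summaries and a significance flag.
#'
#' @param clinical clinical data.frame.
#' @param labels per-sample cluster labels (two clusters).
#' @param yates apply the continuity correction to chi-squared tests.
#' @param exact_max largest per-group n for the exact Wilcoxon path.
#' @param alpha significance flag threshold.
#' @return data.frame of class `comparison_table`.
#' @export
compare_groups <- function(clinical, labels, yates = FALSE, exact_max = 10,
                           alpha = 0.05) {
  if (!is.null(clinical$SampleID) && !is.null(names(labels)))
    labels <- labels[clinical$SampleID]
  lab <- factor(labels)
  if (nlevels(lab) != 2) stop("compare_groups expects exactly two clusters")
  lv <- levels(lab)
  vars <- setdiff(names(clinical), c("SampleID", "Group"))
  rows <- lapply(vars, function(vn) {
    v <- clinical[[vn]]
    ok <- !is.na(v) & !is.na(lab)
    if (sum(ok & lab == lv[1]) < 2 || sum(ok & lab == lv[2]) < 2) {
      warning("variable skipped (too few observations per group): ", vn)
      return(NULL)
    }
    binaryish <- !is.numeric(v) || length(unique(v[ok])) == 2
    if (is.numeric(v) && !binaryish) {
      x1 <- v[ok & lab == lv[1]]; x2 <- v[ok & lab == lv[2]]
      exact <- length(x1) <= exact_max && length(x2) <= exact_max &&
        !any(duplicated(c(x1, x2)))
      wt <- suppressWarnings(wilcox.test(x1, x2, exact = exact, correct = TRUE))
      data.frame(variable = vn, test = "wilcoxon",
                 mean_1 = mean(x1), sd_1 = sd(x1),
                 mean_2 = mean(x2), sd_2 = sd(x2),
                 statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      tab <- table(factor(v[ok]), lab[ok])
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) || nrow(tab) < 2) {
        warning("variable skipped (degenerate contingency): ", vn)
        return(NULL)
      }
      ct <- suppressWarnings(chisq.test(tab, correct = yates))
      m1 <- if (is.numeric(v)) mean(v[ok & lab == lv[1]]) else NA_real_
      m2 <- if (is.numeric(v)) mean(v[ok & lab == lv[2]]) else NA_real_
      data.frame(variable = vn, test = "chi-squared",
                 mean_1 = m1, sd_1 = NA_real_,
                 mean_2 = m2, sd_2 = NA_real_,
                 statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  attr(out, "groups") <- lv
  class(out) <- c("comparison_table", "data.frame")
  out
}
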