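#' Build a design matrix for a two-group contrast with covariates
#'
#' Intercept + group indicator + centred age + 0/1 sex, the standard
#' adjustment for serum proteomic comparisons. The returned matrix carries
#' the contrast column name in `attr(, "coef")`.
#'
#' @param group factor-like vector; `contrast_level` is coded 1.
#' @param contrast_level the level of interest (coded 1).
#' @param age,sex optional covariate vectors aligned with `group`.
#' @return design matrix with attribute `coef`.
#' @export
make_design <- function(group, contrast_level, age = NULL, sex = NULL) {
  g <- as.integer(group == contrast_level)
  if (all(g == 0) || all(g == 1)) stop("contrast level must split the samples")
  X <- cbind(intercept = 1, group = g)
  if (!is.null(age)) X <- cbind(X, age = as.numeric(age) - mean(as.numeric(age)))
  if (!is.null(sex)) {
    s <- if (is.numeric(sex)) sex else as.integer(factor(sex)) - 1L
    if (length(unique(s)) > 1) X <- cbind(X, sex = s)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  attr(X, "coef") <- "group"
  X
}

#' Per-protein ordinary least squares fits
#'
#' Fits the same linear model to every protein column and extracts the
#' contrast coefficient, its unscaled standard error (the design-dependent
#' factor, so `se = sqrt(s2) * unscaled`), the residual variance and the
#' residual degrees of freedom.
#'
#' @param npx an [npx_matrix] or numeric matrix (samples x proteins).
#' @param design design matrix from [make_design].
#' @return a list of class `protein_fits` with per-protein vectors `coef`,
#'   `stdev_unscaled`, `s2`, `df_resid` and the mean expression `amean`.
#' @export
fit_linear_models <- function(npx, design) {
  Y <- if (inherits(npx, "npx_matrix")) npx$values else as.matrix(npx)
  stopifnot(nrow(Y) == nrow(design))
  coef_name <- attr(design, "coef")
  if (is.null(coef_name)) coef_name <- colnames(design)[2]
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  df_resid <- nrow(design) - qrX$rank
  if (df_resid < 1) stop("no residual degrees of freedom")
  XtXinv <- solve(crossprod(design))
  dimnames(XtXinv) <- list(colnames(design), colnames(design))
  B <- qr.coef(qrX, Y)
  R <- Y - design %*% B
  s2 <- colSums(R^2) / df_resid
  unscaled <- sqrt(XtXinv[coef_name, coef_name])
  structure(list(coef = B[coef_name, ],
                 stdev_unscaled = rep(unscaled, ncol(Y)),
                 s2 = s2,
                 df_resid = rep(df_resid, ncol(Y)),
                 amean = colMeans(Y),
                 protein = colnames(Y)),
            class = "protein_fits")
}

# Newton inversion of the trigamma function (solve trigamma(y) = x)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (!is.finite(y) || y <= 0) return(Inf)
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-protein residual variances towards a pooled prior estimated
#' by the log-variance moment method: with `z_g = log(s2_g)` and
#' `e_g = z_g - digamma(d_g/2) + log(d_g/2)`, the prior degrees of freedom
#' solve `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` and the prior
#' variance follows from the mean of `e`. The moderated statistic uses the
#' posterior variance `(d0 s0^2 + d_g s2_g) / (d0 + d_g)` and a t reference
#' with `d0 + d_g` degrees of freedom. When the moment equation has no
#' positive solution the prior is treated as infinitely informative
#' (`d0 = Inf`, all variances pooled), with a message.
#'
#' @param fits result of [fit_linear_models].
#' @param d0_override force the prior degrees of freedom: `0` recovers the
#'   ordinary t statistic, `Inf` fully pools the variances.
#' @return a data.frame of class `de_result` with per-protein `coef`, `se`,
#'   `s2`, `df_resid`, `s2_post`, `t_mod`, `p_raw`, `p_adj`; the prior
#'   `(d0, s0_sq)` is attached as attributes.
#' @export
ebayes_moderate <- function(fits, d0_override = NULL) {
  s2 <- fits$s2
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("need at least two proteins with positive residual variance")
  dg <- fits$df_resid
  z <- log(s2[ok])
  e <- z - digamma(dg[ok] / 2) + log(dg[ok] / 2)
  G <- sum(ok)
  evar <- sum((e - mean(e))^2) / (G - 1)
  target <- evar - mean(trigamma(dg[ok] / 2))
  if (!is.null(d0_override)) {
    d0 <- d0_override
    # prior variance from the moment mean under the chosen d0
    s0_sq <- if (is.infinite(d0) || d0 <= 0) exp(mean(e))
    else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else if (target <= 0) {
    message("log-variance moment equation has no positive solution; using d0 = Inf")
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
  else if (d0 == 0) s2
  else (d0 * s0_sq + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post) * fits$stdev_unscaled
  t_mod <- fits$coef / se
  df_total <- dg + d0
  p_raw <- 2 * pt(-abs(t_mod), df = df_total)
  out <- data.frame(protein = fits$protein,
                    coef = fits$coef,
                    se = se,
                    s2 = s2,
                    df_resid = dg,
                    s2_post = s2_post,
                    t_mod = t_mod,
                    p_raw = p_raw,
                    p_adj = bh_adjust(p_raw),
                    amean = fits$amean,
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, capped at 1 and monotone in the p-value ranking.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Threshold a moderated-t result into a DE protein set
#'
#' Strict thresholds: `coef > lfc` (up) or `coef < -lfc` (down), and
#' `p_adj < alpha`.
#'
#' @param de a `de_result` from [ebayes_moderate].
#' @param lfc log2 fold-change threshold (NPX difference).
#' @param alpha adjusted p-value threshold.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of protein identifiers.
#' @export
threshold_de <- function(de, lfc = 1.2, alpha = 0.05,
                         direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(lfc > 0, alpha > 0)
  up <- de$coef > lfc
  down <- de$coef < -lfc
  passing <- switch(direction, up = up, down = down, both = up | down)
  de$protein[passing & de$p_adj < alpha]
}

#' Three-way Venn grouping of DE proteins
#'
#' Partitions the union of the two upregulated sets into `stepwise`
#' (up in both the all-patients-vs-controls and the endotype contrast),
#' `unique` (endotype contrast only) and `upregulated_ad` (cohort contrast
#' only).
#'
#' @param up_all_vs_hc proteins upregulated in all patients vs controls.
#' @param up_c1_vs_c2 proteins upregulated in endotype 1 vs endotype 2.
#' @return list of class `de_groups` with the three disjoint sets.
#' @export
venn_trichotomy <- function(up_all_vs_hc, up_c1_vs_c2) {
  stepwise <- intersect(up_all_vs_hc, up_c1_vs_c2)
  structure(list(upregulated_ad = setdiff(up_all_vs_hc, stepwise),
                 stepwise = stepwise,
                 unique = setdiff(up_c1_vs_c2, up_all_vs_hc)),
            class = "de_groups")
}

#' @export
print.de_groups <- function(x, ...) {
  cat(sprintf("DE groups: %d upregulated-AD, %d stepwise, %d unique\n",
              length(x$upregulated_ad), length(x$stepwise), length(x$unique)))
  invisible(x)
}

#' Volcano-plot export table
#'
#' Per-protein effect size and `-log10` adjusted p-value, with a flag for
#' proteins passing both thresholds. Zero p-values are clipped to the
#' smallest positive double before the log.
#'
#' @inheritParams threshold_de
#' @return data.frame with `protein`, `coef`, `neg_log10_p_adj`, `flag`.
#' @export
volcano_table <- function(de, lfc = 1.2, alpha = 0.05) {
  p <- pmax(de$p_adj, .Machine$double.xmin)
  data.frame(protein = de$protein,
             coef = de$coef,
             neg_log10_p_adj = -log10(p),
             flag = abs(de$coef) > lfc & de$p_adj < alpha,
             row.names = NULL)
}

#' Mean-variance diagnostic table
#'
#' Mean NPX versus log residual variance per protein, exported for visual
#' assessment of the constant-variance assumption.
#'
#' @param fits result of [fit_linear_models].
#' @return data.frame with `protein`, `amean`, `log_s2`.
#' @export
mean_variance_table <- function(fits) {
  data.frame(protein = fits$protein, amean = fits$amean,
             log_s2 = log(fits$s2), row.names = NULL)
}

#' Run one moderated differential-expression contrast
#'
#' Convenience wrapper: builds the design for the requested contrast,
#' fits per-protein models with age/sex adjustment and applies the
#' empirical-Bayes moderation.
#'
#' @param npx an [npx_matrix].
#' @param contrast `"ad_vs_hc"` (all patients vs controls) or `"c1_vs_c2"`
#'   (endotype 1 vs endotype 2; requires `cluster`).
#' @param clinical optional clinical table supplying `Age`/`Sex` covariates.
#' @param cluster per-sample endotype labels (needed for `"c1_vs_c2"`).
#' @return a `de_result`.
#' @export
de_contrast <- function(npx, contrast = c("ad_vs_hc", "c1_vs_c2"),
                        clinical = NULL, cluster = NULL) {
  contrast <- match.arg(contrast)
  if (contrast == "ad_vs_hc") {
    keep <- seq_along(npx$sample_ids)
    grp <- npx$group
    level <- "AD"
  } else {
    if (is.null(cluster)) stop("c1_vs_c2 contrast requires cluster labels")
    cl <- cluster[npx$sample_ids]
    keep <- which(cl %in% c("C1", "C2", "1", "2"))
    grp <- ifelse(cl[keep] %in% c("C1", "1"), "C1", "C2")
    level <- "C1"
  }
  age <- sex <- NULL
  if (!is.null(clinical)) {
    ci <- clinical[match(npx$sample_ids[keep], clinical$SampleID), ]
    if ("Age" %in% names(ci)) age <- ci$Age
    if ("Sex" %in% names(ci)) sex <- ci$Sex
  }
  sub <- npx_subset(npx, samples = keep)
  design <- make_design(grp, level, age = age, sex = sex)
  ebayes_moderate(fit_linear_models(sub, design))
}
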