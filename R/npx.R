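#' NPX expression matrix container
#'
#' Bundles a samples x proteins matrix of log2-scale NPX values with sample
#' and assay identifiers, per-sample group labels (`"AD"` or `"HC"`) and an
#' optional per-protein subpanel annotation.
#'
#' @param values numeric matrix, samples in rows, proteins in columns.
#' @param sample_ids,protein_ids unique identifiers matching the dimensions.
#' @param group character vector of `"AD"`/`"HC"` per sample.
#' @param panel optional per-protein panel label.
#' @return an object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, sample_ids, protein_ids, group, panel = NULL) {
  values <- as.matrix(values)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(protein_ids)) stop("duplicate protein identifiers")
  if (nrow(values) != length(sample_ids) || ncol(values) != length(protein_ids))
    stop("matrix dimensions do not match identifier lengths")
  if (length(group) != length(sample_ids))
    stop("group must have one label per sample")
  if (!all(group %in% c("AD", "HC")))
    stop("group labels must be 'AD' or 'HC'")
  if (!is.null(panel) && length(panel) != length(protein_ids))
    stop("panel must have one label per protein")
  dimnames(values) <- list(sample_ids, protein_ids)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         protein_ids = as.character(protein_ids),
         group = as.character(group), panel = panel),
    class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  cat(sprintf("npx_matrix: %d samples x %d proteins (%d AD, %d HC)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "AD"), sum(x$group == "HC")))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

# subset an npx_matrix by sample and/or protein index
npx_subset <- function(npx, samples = NULL, proteins = NULL) {
  si <- if (is.null(samples)) seq_along(npx$sample_ids) else samples
  pi <- if (is.null(proteins)) seq_along(npx$protein_ids) else proteins
  npx_matrix(npx$values[si, pi, drop = FALSE],
             npx$sample_ids[si], npx$protein_ids[pi],
             npx$group[si],
             if (is.null(npx$panel)) NULL else npx$panel[pi])
}

#' Read an NPX matrix from CSV
#'
#' Wide layout: first column `SampleID`, second `Group`, remaining columns one
#' assay each. Long layout: columns `SampleID`, `Assay`, `NPX`, optional
#' `Panel`, plus `Group`. Row order (wide) or first-appearance order (long)
#' is preserved.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @return an [npx_matrix].
#' @export
read_npx <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    need <- c("SampleID", "Group")
    if (!all(need %in% names(df)[1:2]))
      stop("wide layout requires leading columns SampleID, Group")
    assays <- setdiff(names(df), need)
    if (anyDuplicated(df$SampleID)) stop("duplicate (sample, assay) pairs")
    vals <- as.matrix(df[, assays, drop = FALSE])
    storage.mode(vals) <- "double"
    npx_matrix(vals, df$SampleID, assays, df$Group)
  } else {
    need <- c("SampleID", "Assay", "NPX", "Group")
    if (!all(need %in% names(df)))
      stop("long layout requires columns SampleID, Assay, NPX, Group")
    if (anyDuplicated(df[, c("SampleID", "Assay")]))
      stop("duplicate (sample, assay) pairs")
    sids <- unique(df$SampleID)
    pids <- unique(df$Assay)
    vals <- matrix(NA_real_, length(sids), length(pids),
                   dimnames = list(sids, pids))
    vals[cbind(match(df$SampleID, sids), match(df$Assay, pids))] <- df$NPX
    grp <- df$Group[match(sids, df$SampleID)]
    panel <- if ("Panel" %in% names(df)) df$Panel[match(pids, df$Assay)] else NULL
    npx_matrix(vals, sids, pids, grp, panel)
  }
}

#' Write an NPX matrix to wide CSV
#'
#' Inverse of [read_npx] with `layout = "wide"`; round-trips values at full
#' precision.
#'
#' @param npx an [npx_matrix].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_npx <- function(npx, path) {
  df <- data.frame(SampleID = npx$sample_ids, Group = npx$group,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(npx$values, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical/laboratory table
#'
#' A CSV with one row per sample; first column `SampleID`. All other columns
#' are kept as-is (numeric or categorical).
#'
#' @param path CSV file path.
#' @param npx optional [npx_matrix]; in strict mode every NPX sample must be
#'   present in the table.
#' @param strict fail if `npx` samples are missing from the table.
#' @return a data.frame with rownames set to `SampleID`.
#' @export
read_clinical <- function(path, npx = NULL, strict = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"SampleID" %in% names(df)) stop("clinical table requires a SampleID column")
  if (anyDuplicated(df$SampleID)) stop("duplicate sample identifiers in clinical table")
  rownames(df) <- df$SampleID
  if (!is.null(npx)) {
    missing <- setdiff(npx$sample_ids, df$SampleID)
    if (length(missing) && strict)
      stop("clinical table lacks samples: ", paste(missing, collapse = ", "))
  }
  df
}

#' Coefficient-of-variation marker filter
#'
#' Per protein, CoV% = 100 * sd / mean, computed on linearised values
#' `2^NPX` by default (CoV on a log scale is not scale-invariant) or on NPX
#' directly with `scale = "log"`. Markers with CoV above the threshold are
#' retained (a variability filter: markers that do not vary across sera carry
#' no endotype signal); `mode = "keep-below"` inverts the rule.
#'
#' Proteins with more than `max_missing` missing entries are dropped;
#' remaining missing values are imputed by the per-protein median.
#'
#' @param npx an [npx_matrix].
#' @param threshold CoV threshold in percent (strict `>` / `<` comparison).
#' @param scale compute CoV on `"linear"` (2^NPX) or `"log"` (NPX) values.
#' @param mode `"keep-above"` (default) retains CoV > threshold.
#' @param max_missing maximum tolerated fraction of missing values per protein.
#' @return a list with elements `npx` (filtered matrix) and `report`
#'   (class `qc_report`: per-protein CoV, pass flag, counts).
#' @export
cov_filter <- function(npx, threshold = 20, scale = c("linear", "log"),
                       mode = c("keep-above", "keep-below"),
                       max_missing = 0.25) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, nrow(npx$values) >= 2)
  vals <- npx$values
  miss_frac <- colMeans(is.na(vals))
  drop_missing <- miss_frac > max_missing
  n_imputed <- 0L
  if (any(is.na(vals[, !drop_missing, drop = FALSE]))) {
    for (j in which(!drop_missing & miss_frac > 0)) {
      med <- median(vals[, j], na.rm = TRUE)
      n_imputed <- n_imputed + sum(is.na(vals[, j]))
      vals[is.na(vals[, j]), j] <- med
    }
  }
  base <- if (scale == "linear") 2^vals else vals
  mu <- colMeans(base)
  sdev <- apply(base, 2, sd)
  cov_pct <- ifelse(mu == 0, NA_real_, 100 * sdev / abs(mu))
  undefined <- is.na(cov_pct) & !drop_missing
  if (any(undefined))
    warning(sum(undefined), " protein(s) with zero mean on the ", scale,
            " scale dropped (CoV undefined)")
  pass <- !drop_missing & !is.na(cov_pct) &
    if (mode == "keep-above") cov_pct > threshold else cov_pct < threshold
  report <- structure(
    list(table = data.frame(protein = npx$protein_ids,
                            cov_pct = cov_pct,
                            pass = pass,
                            row.names = NULL),
         n_before = ncol(vals), n_after = sum(pass),
         threshold = threshold, scale = scale, mode = mode,
         n_dropped_missing = sum(drop_missing), n_imputed = n_imputed),
    class = "qc_report")
  filtered <- npx
  filtered$values <- vals
  filtered <- npx_subset(filtered, proteins = which(pass))
  list(npx = filtered, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("CoV QC (%s scale, %s %g%%): %d -> %d proteins\n",
              x$scale, x$mode, x$threshold, x$n_before, x$n_after))
  invisible(x)
}

#' Standardise proteins to zero mean and unit variance
#'
#' Each protein column is centred and scaled (sd with n-1 denominator) across
#' samples. Constant columns are mapped to zero with a warning.
#'
#' @param npx an [npx_matrix] (or a plain matrix).
#' @return object of the same type with scaled values.
#' @export
zscale <- function(npx) {
  vals <- if (inherits(npx, "npx_matrix")) npx$values else as.matrix(npx)
  stopifnot(nrow(vals) >= 2)
  mu <- colMeans(vals)
  sdev <- apply(vals, 2, sd)
  degenerate <- sdev == 0 | is.na(sdev)
  if (any(degenerate)) {
    warning(sum(degenerate), " constant protein(s) set to zero after scaling")
    sdev[degenerate] <- 1
  }
  out <- sweep(sweep(vals, 2, mu), 2, sdev, "/")
  out[, degenerate] <- 0
  if (inherits(npx, "npx_matrix")) {
    npx$values <- out
    npx
  } else out
}
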