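#' Build a pipeline configuration
#'
#' Exactly one of `npx_path` (+ optional `clinical_path`, `gmt_path`) or
#' `simulate` (a [sim_config] or list of overrides) must be given. Stage
#' parameter lists override documented defaults; `stages` toggles whole
#' stages off.
#'
#' @param npx_path,clinical_path,gmt_path input files (wide NPX CSV,
#'   clinical CSV, GMT).
#' @param simulate a [sim_config] (or list of overrides) to generate the
#'   cohort instead of reading files.
#' @param seed master seed; all stage randomness derives from it.
#' @param out_dir optional output directory for report files.
#' @param qc,cluster,diffexp,wgcna,network,enrichment,clinical_model named
#'   lists of stage-parameter overrides.
#' @param stages character vector of stages to run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(npx_path = NULL, clinical_path = NULL,
                            gmt_path = NULL, simulate = NULL, seed = 1,
                            out_dir = NULL,
                            qc = list(), cluster = list(), diffexp = list(),
                            wgcna = list(), network = list(),
                            enrichment = list(), clinical_model = list(),
                            stages = c("qc", "cluster", "diffexp", "wgcna",
                                       "network", "enrichment",
                                       "clinical_model")) {
  if (is.null(npx_path) == is.null(simulate))
    stop("exactly one of npx_path or simulate must be provided")
  cfg <- list(npx_path = npx_path, clinical_path = clinical_path,
              gmt_path = gmt_path, simulate = simulate, seed = seed,
              out_dir = out_dir, qc = qc, cluster = cluster,
              diffexp = diffexp, wgcna = wgcna, network = network,
              enrichment = enrichment, clinical_model = clinical_model,
              stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config] arguments
#'   (a `simulate:` mapping holds [sim_config] overrides).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

pget <- function(lst, name, default) if (is.null(lst[[name]])) default else lst[[name]]

#' Run the full endotyping pipeline
#'
#' QC -> k-means endotype discovery (scree, stability, reproducibility,
#' embedding) -> moderated differential expression with the three-way Venn
#' grouping -> signed co-expression network analysis with module-trait
#' correlation -> hub networks -> pathway enrichment -> clinical prediction.
#' Identical config + seed yields an identical bundle; a stage error aborts
#' with the stage name attached and the completed stages preserved.
#'
#' @param config a `pipeline_config`.
#' @return list of class `report_bundle` holding every stage output (or
#'   `"skipped"`) plus provenance (seed, config hash, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  bundle <- list()
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sim <- if (inherits(config$simulate, "sim_config")) config$simulate
      else do.call(sim_config, config$simulate)
      cohort <- simulate_cohort(sim)
      npx <- cohort$npx
      clinical <- cohort$clinical
      bundle$truth <- cohort$truth
    } else {
      npx <- read_npx(config$npx_path, layout = "wide")
      clinical <- if (!is.null(config$clinical_path))
        read_clinical(config$clinical_path, npx) else NULL
    }

    run <- function(s) s %in% config$stages

    stage <- "qc"
    if (run("qc")) {
      qc <- cov_filter(npx,
                       threshold = pget(config$qc, "threshold", 20),
                       scale = pget(config$qc, "scale", "linear"),
                       mode = pget(config$qc, "mode", "keep-above"))
      npx <- qc$npx
      bundle$qc <- qc$report
    } else bundle$qc <- "skipped"

    Z_all <- zscale(npx)$values
    pat_idx <- which(npx$group == "AD")
    Z_pat <- zscale(npx_subset(npx, samples = pat_idx))$values
    cluster_labels <- NULL

    stage <- "cluster"
    if (run("cluster")) {
      k <- pget(config$cluster, "k", 2)
      restarts <- pget(config$cluster, "restarts", 25)
      scree <- wcss_scree(Z_pat, k_max = pget(config$cluster, "k_max", 10),
                          restarts = restarts,
                          seed = seed_stream(seed, "scree"))
      model_pat <- kmeans_fit(Z_pat, k, restarts = restarts,
                              seed = seed_stream(seed, "kmeans-pat"))
      model_all <- kmeans_fit(Z_all, k + 1, restarts = restarts,
                              seed = seed_stream(seed, "kmeans-all"))
      stability <- stability_compare(model_pat, model_all,
                                     patient_ids = npx$sample_ids[pat_idx],
                                     all_ids = npx$sample_ids,
                                     hc_ids = npx$sample_ids[npx$group == "HC"])
      repro <- reproducibility(Z_pat, k = k,
                               iterations = pget(config$cluster, "iterations", 100),
                               split_fraction = pget(config$cluster, "split_fraction", 0.7),
                               seed = seed_stream(seed, "repro"))
      cluster_labels <- setNames(rep(NA_character_, length(npx$sample_ids)),
                                 npx$sample_ids)
      # orient endotype indices by overall expression level: C1 is the
      # high-inflammatory cluster (highest mean z-scaled profile), matching
      # the convention that endotype 1 carries the elevated signature
      lvl <- tapply(rowMeans(Z_pat), model_pat$assignments, mean)
      ord <- order(-lvl)
      cluster_labels[pat_idx] <- paste0("C", match(model_pat$assignments,
                                                   as.integer(names(lvl))[ord]))
      cluster_labels[npx$group == "HC"] <- "HC"
      embedding <- embed_2d(Z_all, seed = seed_stream(seed, "tsne"),
                            clusters = cluster_labels)
      bundle$scree <- scree
      bundle$cluster_model <- model_pat
      bundle$cluster_model_all <- model_all
      bundle$stability <- stability
      bundle$reproducibility <- repro
      bundle$embedding <- embedding
      bundle$cluster_labels <- cluster_labels
    } else {
      bundle$cluster_model <- "skipped"
    }

    stage <- "diffexp"
    if (run("diffexp")) {
      de_ad <- de_contrast(npx, "ad_vs_hc", clinical = clinical)
      lfc <- pget(config$diffexp, "lfc", 1.2)
      alpha <- pget(config$diffexp, "alpha", 0.05)
      up_ad <- threshold_de(de_ad, lfc, alpha, "up")
      groups <- NULL
      de_c1c2 <- NULL
      if (!is.null(cluster_labels)) {
        de_c1c2 <- de_contrast(npx, "c1_vs_c2", clinical = clinical,
                               cluster = cluster_labels)
        up_c1c2 <- threshold_de(de_c1c2, lfc, alpha, "up")
        groups <- venn_trichotomy(up_ad, up_c1c2)
      }
      bundle$de_ad_vs_hc <- de_ad
      bundle$de_c1_vs_c2 <- de_c1c2
      bundle$de_groups <- groups
      bundle$volcano_ad_vs_hc <- volcano_table(de_ad, lfc, alpha)
    } else bundle$de_groups <- "skipped"

    stage <- "wgcna"
    eigen <- NULL
    assignment <- NULL
    A <- NULL
    if (run("wgcna")) {
      sp <- pick_soft_power(Z_all,
                            powers = pget(config$wgcna, "powers", 1:20),
                            r2_target = pget(config$wgcna, "r2_target", 0.9))
      A <- signed_adjacency(Z_all, sp$power)
      dimnames(A) <- list(npx$protein_ids, npx$protein_ids)
      tom <- tom_similarity(A)
      assignment <- detect_modules(
        tom, Z_all,
        min_module_size = pget(config$wgcna, "min_module_size", 20),
        cut_quantile = pget(config$wgcna, "cut_quantile", 0.99),
        merge_height = pget(config$wgcna, "merge_height", 0.25),
        kme_rescue = pget(config$wgcna, "kme_rescue", 0.3))
      eigen <- module_eigenproteins(Z_all, assignment)
      mtc <- NULL
      if (!is.null(clinical)) {
        samples_mode <- pget(config$wgcna, "samples", "ad")
        cl_trait <- clinical
        if (!is.null(cluster_labels))
          cl_trait$Endotype1 <- as.integer(cluster_labels[cl_trait$SampleID] == "C1")
        if (samples_mode == "ad") {
          keep <- cl_trait$SampleID %in% npx$sample_ids[pat_idx]
          eig_sub <- eigen
          eig_sub$me <- eigen$me[npx$sample_ids %in% cl_trait$SampleID[keep] &
                                   npx$group == "AD", , drop = FALSE]
          mtc <- module_trait_correlation(eig_sub, cl_trait[keep, , drop = FALSE])
        } else {
          mtc <- module_trait_correlation(eigen, cl_trait)
        }
      }
      bundle$soft_power <- sp
      bundle$modules <- assignment
      bundle$eigenproteins <- eigen
      bundle$module_trait <- mtc
    } else bundle$modules <- "skipped"

    stage <- "network"
    if (run("network") && !is.null(assignment)) {
      top_mods <- names(assignment$sizes)[seq_len(min(3, length(assignment$sizes)))]
      de_groups <- if (is.list(bundle$de_groups)) bundle$de_groups else NULL
      bundle$hub_networks <- lapply(setNames(top_mods, top_mods), function(m)
        hub_network(m, assignment, eigen, A, de_groups,
                    top_k = pget(config$network, "top_k", 30),
                    edge_floor_quantile = pget(config$network, "edge_floor_quantile", 0)))
    } else bundle$hub_networks <- "skipped"

    stage <- "enrichment"
    if (run("enrichment") && !is.null(assignment)) {
      sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
      else make_module_gmt(assignment$module,
                           seed = seed_stream(seed, "gmt-fixture"))
      top_mods <- names(assignment$sizes)[seq_len(min(3, length(assignment$sizes)))]
      enr <- lapply(setNames(top_mods, top_mods), function(m) {
        ranked <- rank_by_me_correlation(npx, eigen$me[, m])
        members <- names(assignment$module)[assignment$module == m]
        list(gsea = gsea_preranked(ranked, sets,
                                   nperm = pget(config$enrichment, "nperm", 1000),
                                   seed = seed_stream(seed, paste0("gsea-", m))),
             ora = hypergeometric_ora(members, sets, npx$protein_ids))
      })
      bundle$enrichment <- enr
    } else bundle$enrichment <- "skipped"

    stage <- "clinical_model"
    if (run("clinical_model") && !is.null(clinical) && !is.null(cluster_labels)) {
      pat_labels <- cluster_labels[cluster_labels %in% c("C1", "C2")]
      cl_pat <- clinical[clinical$SampleID %in% names(pat_labels), , drop = FALSE]
      rf <- fit_rf_predictor(cl_pat, pat_labels,
                             n_trees = pget(config$clinical_model, "n_trees", 500),
                             seed = seed_stream(seed, "rf"))
      comparisons <- compare_groups(cl_pat, pat_labels,
                                    yates = pget(config$clinical_model, "yates", FALSE))
      top_feat <- rf$importance$feature[1]
      scan <- if (is.numeric(cl_pat[[top_feat]]))
        threshold_scan(cl_pat, pat_labels, top_feat) else NULL
      bundle$clinical_rf <- rf
      bundle$comparisons <- comparisons
      bundle$threshold_scan <- scan
    } else bundle$clinical_rf <- "skipped"

    stage <- "report"
    bundle$provenance <- list(
      package_version = as.character(utils::packageVersion("endoprot")),
      seed = seed,
      config_hash = fnv1a_hash(paste(deparse(config[setdiff(names(config), "out_dir")]),
                                     collapse = "")),
      timestamp_free = TRUE)
    class(bundle) <- "report_bundle"
    if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
    bundle
  }, error = function(e) {
    e$message <- sprintf("pipeline stage '%s' failed: %s", stage, e$message)
    e$partial_bundle <- bundle
    stop(e)
  })
  result
}

# write the machine-readable report files
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "tables"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "graphs"), showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, "tables", name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (is.list(bundle$qc)) wt(bundle$qc$table, "qc_report.tsv")
  if (!is.null(bundle$scree)) wt(bundle$scree, "wcss_scree.tsv")
  if (is.list(bundle$cluster_model))
    wt(data.frame(SampleID = names(bundle$cluster_labels),
                  cluster = bundle$cluster_labels),
       "cluster_assignments.tsv")
  if (!is.null(bundle$de_ad_vs_hc)) wt(bundle$de_ad_vs_hc, "de_ad_vs_hc.tsv")
  if (!is.null(bundle$de_c1_vs_c2)) wt(bundle$de_c1_vs_c2, "de_c1_vs_c2.tsv")
  if (is.list(bundle$modules))
    wt(data.frame(protein = names(bundle$modules$module),
                  module = bundle$modules$module),
       "module_assignment.tsv")
  if (is.list(bundle$hub_networks))
    for (m in names(bundle$hub_networks))
      export_graph(bundle$hub_networks[[m]],
                   file.path(dir, "graphs", paste0("hub_", m, ".graphml")))
  report <- list(
    provenance = bundle$provenance,
    qc = if (is.list(bundle$qc))
      list(n_before = bundle$qc$n_before, n_after = bundle$qc$n_after),
    cluster_sizes = if (is.list(bundle$cluster_model))
      as.list(table(bundle$cluster_model$assignments)),
    stability_agreement = if (is.list(bundle$stability)) bundle$stability$agreement,
    reproducibility = if (is.list(bundle$reproducibility))
      list(median_train = bundle$reproducibility$median_train,
           median_test = bundle$reproducibility$median_test),
    de_group_sizes = if (is.list(bundle$de_groups))
      lapply(bundle$de_groups, length),
    soft_power = if (is.list(bundle$soft_power)) bundle$soft_power$power,
    module_sizes = if (is.list(bundle$modules))
      as.list(bundle$modules$sizes),
    clinical_oob = if (is.list(bundle$clinical_rf)) bundle$clinical_rf$oob_accuracy,
    skipped = names(bundle)[vapply(bundle, identical, logical(1), "skipped")])
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  done <- names(x)[!vapply(x, identical, logical(1), "skipped")]
  cat("pipeline report bundle with stages:", paste(done, collapse = ", "), "\n")
  invisible(x)
}
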