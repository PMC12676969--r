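# shared fixture builders; everything is generated in code at test time

# compact structured cohort for fast unit tests (non-default shapes use the
# generic DE-set placement)
small_config <- function(seed = 1, ...) {
  sim_config(n_hc = 8, n_cluster1 = 12, n_cluster2 = 16, n_proteins = 200,
             module_sizes = c(60L, 45L, 30L, 24L),
             endotype_contrast = c(3, 2.5, 1, 1),
             ad_elevation = c(0.3, 0.3, 0.3, 0.3),
             n_ad_up = 30, n_stepwise = 10, n_unique = 6,
             seed = seed, ...)
}

# exchangeable structured null: modules present, no group structure at all
structured_null_config <- function(seed = 1) {
  sim_config(delta_ad = 0, delta_step = 0, delta_unique = 0,
             endotype_contrast = rep(0, 10), ad_elevation = rep(0, 10),
             hc_factor_sd = 1, seed = seed)
}

# structureless Gaussian null: independent noise panel, no group effect
flat_null_config <- function(seed = 1) {
  sim_config(module_sizes = integer(0), endotype_contrast = numeric(0),
             ad_elevation = numeric(0), delta_ad = 0, delta_step = 0,
             delta_unique = 0, hc_factor_sd = 1, seed = seed)
}

# two planted clusters over independent noise (well separated at this p)
flat_two_cluster_config <- function(seed = 1, n1 = 20, n2 = 20, p = 100,
                                    shift = 2, n_markers = 40) {
  sim_config(n_hc = 0, n_cluster1 = n1, n_cluster2 = n2, n_proteins = p,
             module_sizes = integer(0), endotype_contrast = numeric(0),
             ad_elevation = numeric(0),
             n_ad_up = n_markers, n_stepwise = n_markers, n_unique = 0,
             delta_ad = 0, delta_step = shift, delta_unique = 0,
             hc_factor_sd = 1, seed = seed)
}

# the reproducibility benchmark cohort: study-structured patients with the
# 40 stepwise markers as the informative set, their total between-cluster
# shift calibrated to 2 within-cluster standard deviations
benchmark_cohort_config <- function(seed = 1) {
  defaults <- default_config()
  lam_bar <- mean(defaults$loading_range)
  dstep <- 2 * sqrt(lam_bar^2 + 1) - lam_bar * defaults$endotype_contrast[1]
  sim_config(n_hc = 0, delta_step = dstep, n_unique = 0, delta_unique = 0,
             seed = seed)
}

patient_z <- function(cohort) {
  zscale(cohort$npx$values[cohort$npx$group == "AD", , drop = FALSE])
}

# tiny deterministic npx matrix for I/O tests
tiny_npx <- function() {
  set.seed(99)
  vals <- matrix(round(rnorm(24, 6, 1), 4), 4, 6,
                 dimnames = list(NULL, paste0("IL", 1:6)))
  npx_matrix(vals, paste0("S", 1:4), paste0("IL", 1:6),
             c("AD", "AD", "AD", "HC"))
}
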