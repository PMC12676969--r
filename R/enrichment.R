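#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member identifiers.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "description") <- vapply(fields, `[`, character(1), 2)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (defaults to the name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a module-aligned synthetic gene-set collection
#'
#' Builds sets that overlap the planted (or detected) modules at a given
#' purity, plus unrelated random sets — a controlled fixture for enrichment
#' tests.
#'
#' @param module_label named vector of module labels per protein (0 or
#'   "grey" = background).
#' @param n_random number of unrelated random sets.
#' @param purity fraction of each module-aligned set drawn from the module.
#' @param set_size size of each random set.
#' @param seed RNG seed.
#' @return named list of protein-id sets.
#' @export
make_module_gmt <- function(module_label, n_random = 5, purity = 0.8,
                            set_size = 40, seed = 1) {
  universe <- names(module_label)
  mods <- setdiff(unique(module_label), c(0, "0", "grey"))
  withr::with_seed(seed_stream(seed, "gmt"), {
    sets <- lapply(mods, function(m) {
      members <- universe[module_label == m]
      n_in <- max(2, round(purity * min(set_size, length(members))))
      n_out <- max(0, round(n_in * (1 - purity) / purity))
      unique(c(sample(members, min(n_in, length(members))),
               sample(setdiff(universe, members), n_out)))
    })
    names(sets) <- paste0("module_", mods, "_set")
    rand <- lapply(seq_len(n_random), function(i)
      sample(universe, min(set_size, length(universe))))
    names(rand) <- paste0("random_set_", seq_len(n_random))
    c(sets, rand)
  })
}

#' Rank proteins by correlation with a module eigenprotein
#'
#' The preranked-GSEA score: Pearson correlation of each protein's NPX
#' profile with the ME, sorted in decreasing order (ties broken by protein
#' id for determinism).
#'
#' @param npx an [npx_matrix] or samples x proteins matrix.
#' @param me per-sample eigenprotein scores.
#' @return data.frame with `protein` and `score`, sorted.
#' @export
rank_by_me_correlation <- function(npx, me) {
  X <- if (inherits(npx, "npx_matrix")) npx$values else as.matrix(npx)
  stopifnot(nrow(X) >= 3, nrow(X) == length(me))
  sds <- apply(X, 2, sd)
  score <- suppressWarnings(as.vector(cor(X, me)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant protein(s) assigned score 0")
    score[sds == 0] <- 0
  }
  ord <- order(-score, colnames(X))
  data.frame(protein = colnames(X)[ord], score = score[ord], row.names = NULL)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(scores, is_hit, weight = 1) {
  w <- abs(scores)^weight
  hit_sum <- sum(w[is_hit])
  n_miss <- sum(!is_hit)
  if (hit_sum == 0 || n_miss == 0) return(0)
  step <- ifelse(is_hit, w / hit_sum, -1 / n_miss)
  walk <- cumsum(step)
  walk[which.max(abs(walk))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum statistic on a ranked score list: hits add
#' `|score|^weight` (normalised by the in-set score sum), misses subtract
#' `1/(N-K)`; ES is the maximum-magnitude excursion. The null is built by
#' drawing `nperm` random same-size sets from the universe; the p-value
#' compares `|ES|` with the null scores of the matching sign side,
#' `(1 + #{|ES_null| >= |ES|, same side}) / (1 + #{null on that side})`, so
#' null p-values are uniform; NES divides ES by the mean `|ES_null|` of that
#' side. BH across sets.
#'
#' @param ranked data.frame from [rank_by_me_correlation].
#' @param sets named list of protein sets.
#' @param weight score-weight exponent.
#' @param nperm permutation count (>= 100).
#' @param seed RNG seed.
#' @return data.frame of class `enrichment_result`.
#' @export
gsea_preranked <- function(ranked, sets, weight = 1, nperm = 1000, seed = 1) {
  stopifnot(nperm >= 100)
  universe <- ranked$protein
  scores <- ranked$score
  N <- length(universe)
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0, logical(1))
  if (!all(keep)) warning(sum(!keep), " set(s) with empty universe overlap dropped")
  sets <- sets[keep]
  rows <- withr::with_seed(seed_stream(seed, "gsea"), {
    lapply(names(sets), function(nm) {
      members <- intersect(sets[[nm]], universe)
      K <- length(members)
      is_hit <- universe %in% members
      es <- gsea_es(scores, is_hit, weight)
      null_es <- vapply(seq_len(nperm), function(i) {
        idx <- sample.int(N, K)
        hit <- rep(FALSE, N)
        hit[idx] <- TRUE
        gsea_es(scores, hit, weight)
      }, numeric(1))
      side <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      p <- (1 + sum(abs(side) >= abs(es))) / (1 + length(side))
      nes <- if (length(side) && mean(abs(side)) > 0) es / mean(abs(side)) else NA_real_
      data.frame(set = nm, method = "gsea", ES = es, NES = nes,
                 K = K, N = N, p_raw = p)
    })
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Hypergeometric overrepresentation analysis
#'
#' For each set S: `K = |S ∩ universe|`, `k = |S ∩ selection|`,
#' `n = |selection|`, `N = |universe|`; the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution. BH across sets.
#'
#' @param selection protein set of interest (must lie within the universe).
#' @param sets named list of protein sets.
#' @param universe all assayed proteins.
#' @return data.frame of class `enrichment_result` with `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_adj`.
#' @export
hypergeometric_ora <- function(selection, sets, universe) {
  if (!all(selection %in% universe)) stop("selection must be a subset of the universe")
  N <- length(unique(universe))
  n <- length(unique(selection))
  keep <- vapply(sets, function(s) length(intersect(s, universe)) > 0, logical(1))
  if (!all(keep)) warning(sum(!keep), " set(s) with empty universe overlap dropped")
  sets <- sets[keep]
  rows <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], selection))
    p <- if (n == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, method = "ora", k = k, K = K, n = n, N = N, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
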