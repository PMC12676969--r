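#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic stages of the pipeline draw their randomness from named
#' substreams of one master seed, so that adding a stage (or a trait to the
#' simulator) does not perturb the draws of another.
#'
#' @param seed master seed (integer).
#' @param name character scalar naming the consumer.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
seed_stream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) + h * 10007) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# exact maximum-agreement label matching between two clusterings from their
# contingency table; enumerates permutations for small k (assignment problem)
match_labels <- function(confusion) {
  ka <- nrow(confusion)
  kb <- ncol(confusion)
  k <- max(ka, kb)
  pad <- matrix(0, k, k)
  pad[seq_len(ka), seq_len(kb)] <- confusion
  if (k <= 8) {
    perms <- permutations_of(k)
    scores <- vapply(perms, function(p) sum(pad[cbind(seq_len(k), p)]), numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    # greedy fallback for unusually large k
    best <- integer(k)
    remaining <- seq_len(k)
    for (i in order(-apply(pad, 1, max))) {
      j <- remaining[which.max(pad[i, remaining])]
      best[i] <- j
      remaining <- setdiff(remaining, j)
    }
  }
  map <- best[seq_len(ka)]
  map[map > kb] <- NA_integer_
  map
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[idx]] <- append(p, k, after = pos)
      idx <- idx + 1
    }
  }
  out
}

# FNV-1a hash of a character scalar, for run provenance
fnv1a_hash <- function(x) {
  h <- 2166136261
  for (ch in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
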