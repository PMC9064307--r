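# Post-ordination disparity: sum of variances (SoV) per group / time bin,
# with bootstrap percentile intervals and rarefaction.

#' Sum of variances of ordination scores
#'
#' Sum over retained axes of the sample variance (n-1 denominator).
#'
#' @param scores points x axes matrix.
#' @return non-negative scalar.
#' @export
sum_of_variances <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 points for a variance")
  sum(apply(scores, 2, stats::var))
}

#' Bootstrapped sum of variances
#'
#' Resamples rows with replacement and returns the observed SoV with
#' 2.5/97.5 percentile bounds of the bootstrap distribution.
#'
#' @param scores points x axes matrix (>= 2 rows).
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer RNG seed.
#' @param probs percentile bounds (default `c(0.025, 0.975)`).
#' @return list with `point`, `lo`, `hi`.
#' @export
bootstrap_sov <- function(scores, reps = 500L, seed = 1L,
                          probs = c(0.025, 0.975)) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need at least 2 points")
  if (reps < 100) stop("reps must be >= 100")
  set.seed(seed)
  n <- nrow(scores)
  boots <- vapply(seq_len(reps), function(i)
    sum_of_variances(scores[sample.int(n, n, replace = TRUE), , drop = FALSE]),
    0)
  q <- stats::quantile(boots, probs, names = FALSE)
  list(point = sum_of_variances(scores), lo = q[1], hi = q[2])
}

#' Rarefied sum of variances
#'
#' Mean SoV over subsamples of `target_n` rows drawn without replacement.
#'
#' @param scores points x axes matrix.
#' @param target_n rarefaction size, `2 <= target_n <= nrow(scores)`.
#' @param reps subsample count.
#' @param seed integer RNG seed.
#' @return scalar mean SoV.
#' @export
rarefy_sov <- function(scores, target_n, reps = 500L, seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (target_n < 2 || target_n > n) stop("target_n must be in [2, n]")
  set.seed(seed)
  mean(vapply(seq_len(reps), function(i)
    sum_of_variances(scores[sample.int(n, target_n), , drop = FALSE]), 0))
}

#' Disparity through time
#'
#' Per-bin sum of variances with bootstrap interval and rarefied value at the
#' smallest bin size with at least 2 taxa (the global rarefaction target,
#' reported in the `rarefaction_n` attribute). Bins with fewer than 2 taxa in
#' the ordination are returned with `NA` disparity.
#'
#' @param ord a `pco_ord`.
#' @param membership per-bin taxon lists from [taxa_in_bins()].
#' @param reps bootstrap/rarefaction replicates (default 500).
#' @param seed integer RNG seed.
#' @return data frame `bin`, `n`, `sov`, `lo`, `hi`, `rarefied_sov`, `reps`.
#' @export
disparity_through_time <- function(ord, membership, reps = 500L, seed = 1L) {
  counts <- vapply(membership, function(tx)
    length(intersect(tx, ord$taxa)), 0L)
  target <- suppressWarnings(min(counts[counts >= 2]))
  if (!is.finite(target)) stop("no bin holds >= 2 ordinated taxa")
  out <- data.frame(bin = names(membership), n = counts, sov = NA_real_,
                    lo = NA_real_, hi = NA_real_, rarefied_sov = NA_real_,
                    reps = as.integer(reps), row.names = NULL)
  for (i in seq_along(membership)) {
    tx <- intersect(membership[[i]], ord$taxa)
    if (length(tx) < 2) next
    sc <- ord$scores[tx, , drop = FALSE]
    bs <- bootstrap_sov(sc, reps = reps, seed = seed + i)
    out$sov[i] <- bs$point; out$lo[i] <- bs$lo; out$hi[i] <- bs$hi
    out$rarefied_sov[i] <- rarefy_sov(sc, target, reps = reps,
                                      seed = seed + i)
  }
  attr(out, "rarefaction_n") <- target
  out
}
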