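# Morphospace cluster structure and character-axis association.

#' PAM clustering with silhouette-selected k
#'
#' Runs partitioning-around-medoids for each candidate k and returns the
#' solution maximising the average silhouette width.
#'
#' @param x points x axes score matrix, or a distance matrix/`dist`.
#' @param k_range candidate cluster counts (subset of `2:(n-1)`).
#' @param seed integer RNG seed (PAM itself is deterministic; the seed guards
#'   any tie handling).
#' @return object of class `cluster_solution`: list with `k`, `medoids`
#'   (labels), `assignment` (named integer vector), `avg_silhouette`, and
#'   `silhouettes` (named by k).
#' @export
select_k_medoids <- function(x, k_range = 2:6, seed = 1L) {
  isdist <- inherits(x, "dist") ||
    (is.matrix(x) && nrow(x) == ncol(x) && isSymmetric(unname(x)) &&
       all(diag(x) == 0))
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
  if (n < 3) stop("need at least 3 observations")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("empty k range")
  set.seed(seed)
  fits <- lapply(k_range, function(k)
    cluster::pam(if (isdist) stats::as.dist(x) else x, k,
                 diss = isdist, keep.diss = FALSE, keep.data = FALSE))
  sil <- vapply(fits, function(f) f$silinfo$avg.width, 0)
  best <- which.max(sil)
  f <- fits[[best]]
  labels <- if (inherits(x, "dist")) attr(x, "Labels") else rownames(x)
  medoids <- if (is.character(f$medoids)) f$medoids
             else if (!is.null(labels)) labels[f$id.med] else f$id.med
  structure(list(k = k_range[best],
                 medoids = medoids,
                 assignment = f$clustering,
                 avg_silhouette = sil[best],
                 silhouettes = stats::setNames(sil, k_range)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("PAM solution: k = ", x$k, ", average silhouette width ",
      round(x$avg_silhouette, 3), "\n", sep = "")
  invisible(x)
}

#' Cramer's V for a contingency table
#'
#' \eqn{V = \sqrt{\chi^2 / (N (\min(r, c) - 1))}} with the uncorrected
#' chi-squared statistic.
#'
#' @param tab non-negative contingency table (matrix) with at least 2 rows
#'   and 2 columns and positive total.
#' @return scalar in \[0, 1\].
#' @export
cramer_v <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate table: need >= 2 rows and columns")
  if (any(tab < 0) || sum(tab) <= 0) stop("table must be non-negative with positive total")
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
  min(v, 1)
}

#' Character-to-axis Cramer coefficient profile
#'
#' Discretises one ordination axis into quantile bins and, per character,
#' computes Cramer's V between character state and axis bin over the taxa
#' scored with a single state for that character (polymorphic cells are
#' excluded). Characters scored for fewer than 5 taxa, or with no state or
#' axis-bin variation, get `NA`.
#'
#' @param m a `character_matrix`.
#' @param ord a `pco_ord` on (a subset of) the same taxa.
#' @param axis axis index (default 1).
#' @param n_axis_bins number of quantile bins (default 4).
#' @return data frame: `character`, `axis`, `V`, `n`.
#' @export
character_axis_cramer <- function(m, ord, axis = 1, n_axis_bins = 4) {
  if (axis > ncol(ord$scores)) stop("axis ", axis, " not in the ordination")
  if (n_axis_bins < 2) stop("n_axis_bins must be >= 2")
  taxa <- intersect(m$taxa, ord$taxa)
  sc <- ord$scores[taxa, axis]
  br <- unique(stats::quantile(sc, probs = seq(0, 1, length.out = n_axis_bins + 1)))
  axis_bin <- cut(sc, breaks = br, include.lowest = TRUE)
  out <- data.frame(character = m$characters$index, axis = axis,
                    V = NA_real_, n = 0L)
  cells <- m$cells[taxa, , drop = FALSE]
  for (j in seq_len(n_characters(m))) {
    col <- cells[, j]
    ok <- !is.na(col) & col != "" & !grepl("/", col, fixed = TRUE)
    out$n[j] <- sum(ok)
    if (sum(ok) < 5) next
    tab <- table(col[ok], axis_bin[ok])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    out$V[j] <- cramer_v(tab)
  }
  out
}
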