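# Principal coordinates morphospace and time-binned occupation.

#' Principal coordinates analysis of a MORD distance matrix
#'
#' Double-centres \eqn{-\tfrac12 D^2}, eigendecomposes, and scales
#' eigenvectors by the square root of their eigenvalues. Only
#' positive-eigenvalue axes are retained; with the Cailliez correction a
#' constant is added to the off-diagonal distances first (via
#' [stats::cmdscale()]). MORD matrices are typically non-Euclidean, so
#' `variance_explained` is reported relative to the positive eigenvalue sum
#' (recorded in `$correction`). The sign of each axis is fixed by making its
#' first nonzero loading positive.
#'
#' @param d an `mord_dist` with no undefined entries (see
#'   [trim_incalculable()]), or a plain symmetric distance matrix.
#' @param correction `"none"` or `"cailliez"`.
#' @return object of class `pco_ord`: list with `taxa`, `scores`
#'   (taxa x axes), `eigenvalues` (descending, positive), and
#'   `variance_explained`.
#' @export
pco <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  D <- if (inherits(d, "mord_dist")) d$D else as.matrix(d)
  if (anyNA(D)) stop("distance matrix has undefined entries; trim first")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa for ordination")
  taxa <- rownames(D)
  tol <- 1e-9

  if (correction == "cailliez") {
    fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1,
                                            eig = TRUE, add = TRUE))
    ev <- fit$eig
    keep <- which(ev > max(ev) * tol)
    scores <- fit$points[, keep, drop = FALSE]
    ev <- ev[keep]
  } else {
    B <- -0.5 * D^2
    B <- sweep(B, 1, rowMeans(B))
    B <- sweep(B, 2, colMeans(B))
    eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
    keep <- which(eig$values > max(eig$values) * tol)
    ev <- eig$values[keep]
    scores <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev), length(ev))
  }
  # reproducible sign convention
  for (j in seq_len(ncol(scores))) {
    nz <- which(abs(scores[, j]) > 1e-12)
    if (length(nz) && scores[nz[1], j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(taxa, paste0("PCO", seq_len(ncol(scores))))
  structure(list(taxa = taxa, scores = scores, eigenvalues = ev,
                 variance_explained = ev / sum(ev),
                 correction = correction),
            class = "pco_ord")
}

#' @export
print.pco_ord <- function(x, ...) {
  cat("PCO ordination: ", length(x$taxa), " taxa, ", length(x$eigenvalues),
      " positive axes (correction: ", x$correction, ")\n",
      "  variance explained PCO1-3: ",
      paste(round(100 * utils::head(x$variance_explained, 3), 1),
            collapse = ", "), " %\n", sep = "")
  invisible(x)
}

#' Taxon membership of time bins
#'
#' Under the default `"range"` rule a taxon belongs to every bin its
#' \[fad, lad\] range intersects; under `"point"` it belongs to the single
#' bin containing its sampled point age. Extant taxa fall in the youngest
#' bin under both rules.
#'
#' @param ranges a `fossil_ranges` data frame.
#' @param bins a `time_bins` data frame.
#' @param rule `"range"` or `"point"`.
#' @param point_ages named point ages (required for `"point"`), e.g. from
#'   [sample_tip_ages()].
#' @return named list (one element per bin) of taxon label vectors.
#' @export
taxa_in_bins <- function(ranges, bins, rule = c("range", "point"),
                         point_ages = NULL) {
  rule <- match.arg(rule)
  youngest <- bins$younger == min(bins$younger)
  out <- vector("list", nrow(bins))
  names(out) <- bins$name
  for (i in seq_len(nrow(bins))) {
    if (rule == "range") {
      # [fad, lad] meets (younger, older]; the all-zero (extant-only) range
      # falls in the youngest bin, whose younger bound is closed
      hit <- (ranges$fad > bins$younger[i] & ranges$lad <= bins$older[i]) |
        (youngest[i] & ranges$fad == 0)
    } else {
      if (is.null(point_ages)) stop("point rule needs 'point_ages'")
      a <- as.numeric(point_ages[ranges$taxon])
      hit <- age_in_bin(a, bins$older[i], bins$younger[i], youngest[i])
    }
    out[[i]] <- ranges$taxon[hit]
  }
  out
}

#' Convex hull area of a 2-D point set
#'
#' Shoelace area of the convex hull; degenerate (collinear or < 3 distinct
#' points) sets have area 0.
#'
#' @param scores two-column matrix of coordinates.
#' @return non-negative scalar.
#' @export
hull_area <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stop("hull_area needs a 2-column matrix")
  pts <- unique(scores)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Brownian ancestral coordinates for a phylomorphospace
#'
#' Per-axis maximum-likelihood Brownian-motion ancestral estimates on a dated
#' tree (equivalent to weighted squared-change parsimony), for placing
#' internal nodes in morphospace (phylo- and chronophylomorphospace).
#'
#' @param dt a `dated_tree` whose tips all appear in `scores`.
#' @param scores taxa x axes matrix of ordination scores (row names are
#'   taxon labels).
#' @return matrix of internal-node coordinates (rows named by node id).
#' @export
ancestral_coordinates <- function(dt, scores) {
  tree <- dt$tree
  miss <- setdiff(tree$tip.label, rownames(scores))
  if (length(miss)) stop("tips missing from scores: ",
                         paste(miss, collapse = ", "))
  x <- scores[tree$tip.label, , drop = FALSE]
  anc <- apply(x, 2, function(v)
    as.numeric(phytools::fastAnc(tree, stats::setNames(v, tree$tip.label))))
  anc <- matrix(anc, nrow = tree$Nnode,
                dimnames = list(ape::Ntip(tree) + seq_len(tree$Nnode),
                                colnames(scores)))
  anc
}

#' Per-bin morphospace hull areas
#'
#' @param ord a `pco_ord`.
#' @param membership per-bin taxon lists from [taxa_in_bins()].
#' @param axes two axis indices (default 1:2).
#' @return data frame `bin`, `n`, `hull_area`.
#' @export
bin_hull_areas <- function(ord, membership, axes = 1:2) {
  out <- data.frame(bin = names(membership),
                    n = vapply(membership, length, 0L),
                    hull_area = NA_real_)
  for (i in seq_along(membership)) {
    tx <- intersect(membership[[i]], ord$taxa)
    out$n[i] <- length(tx)
    if (length(tx) >= 1)
      out$hull_area[i] <- hull_area(ord$scores[tx, axes, drop = FALSE])
  }
  out
}
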