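# Inter-taxon morphological distances from discrete characters.
#
# MORD (maximum observable rescaled distance): per pair of taxa, the summed
# per-character raw distance over comparable characters divided by the summed
# maximum attainable distance over those same characters. Missing and
# inapplicable cells are both non-comparable. Polymorphism distance is the
# minimum over cross-pairs of the two state sets. For ordered characters the
# maximum attainable distance is the observed state range of that character
# across the whole matrix.

#' Distance between two cells of one character
#'
#' @param a,b encoded cells (see [character_matrix()]).
#' @param ordering `"unordered"` or `"ordered"`.
#' @param observed_states integer states observed for the character anywhere
#'   in the matrix (sets the ordered maximum range).
#' @param weight character weight; multiplies both raw and maximum distance.
#' @return list with `raw`, `max` and logical `comparable`.
#' @export
character_distance <- function(a, b, ordering = "unordered",
                               observed_states = NULL, weight = 1) {
  sa <- decode_cell(a); sb <- decode_cell(b)
  if (length(sa) == 0L || length(sb) == 0L)
    return(list(raw = NA_real_, max = NA_real_, comparable = FALSE))
  if (ordering == "ordered") {
    if (is.null(observed_states)) observed_states <- sort(unique(c(sa, sb)))
    raw <- min(abs(outer(sa, sb, "-")))
    mx <- diff(range(observed_states))
  } else {
    raw <- if (length(intersect(sa, sb))) 0 else 1
    mx <- 1
  }
  list(raw = raw * weight, max = mx * weight, comparable = TRUE)
}

#' Maximum observable rescaled distances (MORD)
#'
#' Computes the symmetric MORD matrix between all taxon pairs of a discrete
#' character matrix, together with the per-pair comparable-character weight
#' sums and maximum attainable raw distances. Pairs sharing no comparable
#' character (or only characters of zero attainable distance) are undefined
#' (`NA`), not an error.
#'
#' @param m a `character_matrix` with at least 2 taxa.
#' @return object of class `mord_dist`: list with `taxa`, `D` (MORD, `NA`
#'   where undefined, 0 diagonal), `C` (comparable-character weight sums) and
#'   `M` (summed maximum raw distances).
#' @export
mord <- function(m) {
  n <- n_taxa(m)
  if (n < 2) stop("need at least 2 taxa")
  num <- matrix(0, n, n); den <- matrix(0, n, n); cw <- matrix(0, n, n)
  for (j in seq_len(n_characters(m))) {
    col <- m$cells[, j]
    scored <- !is.na(col) & col != ""
    if (sum(scored) < 2) next
    w <- m$characters$weight[j]
    ord <- m$characters$ordering[j] == "ordered"
    obs <- m$characters$observed_states[[j]]
    idx <- which(scored)
    poly <- grepl("/", col[idx], fixed = TRUE)
    lo <- hi <- rep(NA_real_, length(idx))
    single_val <- suppressWarnings(as.numeric(col[idx]))
    lo[!poly] <- hi[!poly] <- single_val[!poly]
    if (any(poly)) {
      sets <- lapply(col[idx[poly]], decode_cell)
      lo[poly] <- vapply(sets, min, 0)
      hi[poly] <- vapply(sets, max, 0)
    }
    if (ord) {
      if (any(obs != round(obs))) stop("ordered character ", j,
                                       " has non-integer states")
      # interval gap; exact for single states, refined below for sparse
      # polymorphic sets
      raw <- pmax(outer(lo, hi, "-"), t(outer(lo, hi, "-")), 0)
      if (any(poly)) {
        pi_ <- which(poly)
        for (a in pi_) for (b in seq_along(idx)) if (a != b) {
          sa <- decode_cell(col[idx[a]]); sb <- decode_cell(col[idx[b]])
          raw[a, b] <- raw[b, a] <- min(abs(outer(sa, sb, "-")))
        }
      }
      mx <- diff(range(obs))
    } else {
      # sets intersect iff (for single/poly cells) any shared state
      if (any(poly)) {
        sets <- lapply(col[idx], decode_cell)
        share <- outer(seq_along(sets), seq_along(sets), Vectorize(function(a, b)
          length(intersect(sets[[a]], sets[[b]])) > 0))
      } else {
        share <- outer(single_val, single_val, "==")
      }
      raw <- 1 - share
      mx <- 1
    }
    num[idx, idx] <- num[idx, idx] + w * raw
    den[idx, idx] <- den[idx, idx] + w * mx
    cw[idx, idx] <- cw[idx, idx] + w
  }
  D <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), NA_real_)
  diag(D) <- 0  # self-distance defined even with no scorable characters
  diag(cw) <- 0; diag(den) <- 0  # C and M are pair quantities
  dimnames(D) <- dimnames(cw) <- dimnames(den) <- list(m$taxa, m$taxa)
  structure(list(taxa = m$taxa, D = D, C = cw, M = den), class = "mord_dist")
}

#' @export
print.mord_dist <- function(x, ...) {
  off <- x$D[upper.tri(x$D)]
  cat("MORD distances: ", length(x$taxa), " taxa; ",
      sum(is.na(off)), " undefined pair(s); mean defined distance ",
      round(mean(off, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Remove taxa until all pairwise distances are defined
#'
#' Iteratively drops the taxon participating in the largest number of
#' undefined entries (ties broken alphabetically) until the distance matrix is
#' fully defined.
#'
#' @param d an `mord_dist`.
#' @return list with `distances` (trimmed `mord_dist`) and `removed`
#'   (character vector, in removal order).
#' @export
trim_incalculable <- function(d) {
  D <- d$D; C <- d$C; M <- d$M
  removed <- character(0)
  repeat {
    und <- is.na(D)
    if (!any(und)) break
    counts <- rowSums(und)
    worst <- which(counts == max(counts))
    drop <- sort(rownames(D)[worst])[1]
    removed <- c(removed, drop)
    keep <- rownames(D) != drop
    D <- D[keep, keep, drop = FALSE]
    C <- C[keep, keep, drop = FALSE]
    M <- M[keep, keep, drop = FALSE]
  }
  list(distances = structure(list(taxa = rownames(D), D = D, C = C, M = M),
                             class = "mord_dist"),
       removed = removed)
}

#' Weighted mean pairwise distance (WMPD)
#'
#' Mean pairwise MORD distance over a taxon subset, weighting each pair by its
#' comparable-character weight sum.
#'
#' @param d an `mord_dist`.
#' @param taxa taxon subset (default all).
#' @return non-negative scalar.
#' @export
wmpd <- function(d, taxa = d$taxa) {
  unknown <- setdiff(taxa, d$taxa)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2) stop("need at least 2 taxa")
  D <- d$D[taxa, taxa]; C <- d$C[taxa, taxa]
  ut <- upper.tri(D)
  ok <- ut & !is.na(D)
  if (!any(ok)) stop("all pairwise distances undefined for this subset")
  sum(C[ok] * D[ok]) / sum(C[ok])
}

#' Export a distance matrix as square CSV
#'
#' Taxon labels as header row and first column; undefined entries written as
#' empty fields.
#'
#' @param d an `mord_dist`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(d$D, path, na = "")
  invisible(path)
}
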