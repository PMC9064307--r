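# A-posteriori time-calibration of cladograms from tip stratigraphic ranges.
#
# Ages are in Ma before present. A dated tree stores an age for every node
# (tips included); branch lengths are durations in Myr and every duration is
# strictly positive after dating. Time bins are half-open [older, younger):
# an age on a bin boundary belongs to the younger bin.

#' Fossil stratigraphic ranges
#'
#' @param taxon taxon labels.
#' @param fad first appearance dates, Ma (older bound).
#' @param lad last appearance dates, Ma (younger bound).
#' @return data frame of class `fossil_ranges` with columns `taxon`, `fad`,
#'   `lad`, `is_extant` (`lad == 0`).
#' @export
fossil_ranges <- function(taxon, fad, lad) {
  fad <- as.numeric(fad); lad <- as.numeric(lad)
  if (any(fad < lad)) stop("fad must be >= lad")
  if (any(lad < 0)) stop("ages must be >= 0")
  if (anyDuplicated(taxon)) stop("duplicate taxa in ranges")
  structure(data.frame(taxon = as.character(taxon), fad = fad, lad = lad,
                       is_extant = lad == 0),
            class = c("fossil_ranges", "data.frame"))
}

#' Read a tip-age table (`taxon,fad,lad` CSV)
#' @param path CSV file.
#' @return a `fossil_ranges` data frame.
#' @export
read_ranges <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "fad", "lad") %in% names(x)))
  fossil_ranges(x$taxon, x$fad, x$lad)
}

#' Draw point tip ages from stratigraphic ranges
#'
#' Each fossil tip age is drawn uniformly on \[lad, fad\]; extant tips
#' (`lad == 0`) are fixed at 0.
#'
#' @param ranges a `fossil_ranges` data frame.
#' @param seed integer RNG seed.
#' @return named numeric vector of tip ages (Ma).
#' @export
sample_tip_ages <- function(ranges, seed = 1L) {
  set.seed(seed)
  ages <- stats::runif(nrow(ranges), min = ranges$lad, max = ranges$fad)
  ages[ranges$is_extant] <- 0
  stats::setNames(ages, ranges$taxon)
}

# ---- phylo helpers ----------------------------------------------------------

# match a named tip-age vector to tree tip order; error on missing taxa
match_tip_ages <- function(tree, tip_ages) {
  miss <- setdiff(tree$tip.label, names(tip_ages))
  if (length(miss)) stop("no age for tip(s): ", paste(miss, collapse = ", "))
  as.numeric(tip_ages[tree$tip.label])
}

node_children <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_all)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

node_parents <- function(tree) {
  par <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# oldest descendant tip age for every node (postorder max)
init_node_ages <- function(tree, tip_ages) {
  n <- ape::Ntip(tree)
  ages <- c(tip_ages, rep(NA_real_, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; c_ <- po[e, 2]
    ages[p] <- max(ages[p], ages[c_], na.rm = TRUE)
  }
  ages
}

# build a dated_tree object from a phylo + full age vector
as_dated_tree <- function(tree, ages, method, seed = NA_integer_) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(tree$edge.length <= 0))
    stop("internal error: non-positive branch duration after dating")
  structure(list(tree = tree, ages = ages,
                 tip_ages = stats::setNames(ages[seq_len(ape::Ntip(tree))],
                                            tree$tip.label),
                 method = method, seed = seed),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat("Dated tree (", x$method, "): ", ape::Ntip(x$tree), " tips, root age ",
      round(max(x$ages), 2), " Ma\n", sep = "")
  invisible(x)
}

#' Node ages of a dated tree
#' @param dt a `dated_tree`.
#' @return numeric vector of ages (Ma) indexed by node id (tips first).
#' @export
node_ages <- function(dt) dt$ages

# ---- 'equal' dating ---------------------------------------------------------

#' Date a cladogram with the 'equal' method
#'
#' Node ages are initialised to the age of their oldest descendant tip; the
#' root is pushed back by `root_extension`; every run of zero-duration edges
#' is then removed by sharing the duration of the closest ancestral
#' positive-length branch equally among itself and the consecutive
#' zero-length edges along the path.
#'
#' @param tree rooted `phylo` (polytomies allowed).
#' @param tip_ages named tip ages (Ma), or `NULL` when `node_ages` given.
#' @param root_extension Myr added above the oldest tip (default 10).
#' @param node_ages optional full initial age vector (tips then internal
#'   nodes); when supplied it is used instead of the first-appearance
#'   initialisation and no root extension is added, so a tree whose ages
#'   already give positive durations is returned unchanged.
#' @return a `dated_tree`.
#' @export
date_equal <- function(tree, tip_ages = NULL, root_extension = 10,
                       node_ages = NULL) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  if (is.null(node_ages)) {
    ta <- match_tip_ages(tree, tip_ages)
    ages <- init_node_ages(tree, ta)
    if (root_extension <= 0)
      stop("root_extension must be > 0: the root age would equal its oldest tip")
    ages[root] <- ages[root] + root_extension
  } else {
    ages <- node_ages
  }
  par <- node_parents(tree)
  kids <- node_children(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge  # preorder edges

  repeat {
    zero <- which(ages[pre[, 1]] - ages[pre[, 2]] <= 0)
    if (!length(zero)) break
    p <- pre[zero[1], 1]; c_ <- pre[zero[1], 2]
    x <- ages[c_]
    # up-walk: topmost node of the equal-age chain
    top <- p
    while (top != root && ages[par[top]] <= x) top <- par[top]
    a <- par[top]
    A <- ages[a]
    if (is.na(A) || A <= x)
      stop("cannot resolve zero-length branches at the root; ",
           "increase root_extension")
    # down-walk: extend the chain through consecutive equal-age descendants
    chain <- top
    cur <- c_
    while (cur > n) {  # internal
      chain <- c(chain, cur)
      nxt <- kids[[cur]][ages[kids[[cur]]] >= x]
      if (!length(nxt)) break
      cur <- nxt[1]
    }
    if (cur <= n) {
      # chain ends at a tip with fixed age x
      moved <- chain
      k <- length(moved) + 1L            # edges sharing A - x
    } else {
      moved <- chain
      k <- length(moved) + 1L
    }
    ages[moved] <- A - seq_along(moved) * (A - x) / k
  }
  as_dated_tree(tree, ages, "equal")
}

# ---- minimum branch length dating -------------------------------------------

#' Date a cladogram with the minimum-branch-length method
#'
#' Tips-to-root pass setting each node age to
#' `max(oldest descendant tip age, oldest child age + mbl)`, so every branch
#' duration is at least `mbl`.
#'
#' @param tree rooted `phylo`.
#' @param tip_ages named tip ages (Ma).
#' @param mbl minimum branch duration, Myr (> 0; default 1).
#' @return a `dated_tree`.
#' @export
date_mbl <- function(tree, tip_ages, mbl = 1) {
  if (mbl <= 0) stop("mbl must be > 0")
  ta <- match_tip_ages(tree, tip_ages)
  n <- ape::Ntip(tree)
  ages <- c(ta, rep(-Inf, tree$Nnode))
  fad_below <- init_node_ages(tree, ta)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; c_ <- po[e, 2]
    ages[p] <- max(ages[p], fad_below[p], ages[c_] + mbl)
  }
  as_dated_tree(tree, ages, "mbl")
}

# ---- Hedman successive-outgroup Bayesian dating -----------------------------

#' Date a cladogram with the whole-tree Hedman method
#'
#' Bayesian node-age estimation from successive outgroup first appearances.
#' Time is discretised into `resolution` grid cells on (0, `t0`). The root
#' posterior is built by the recursive uniform-prior integration over the
#' supplied outgroup ages (oldest first); each remaining node, visited
#' root-to-tips, takes its parent's posterior as the distribution of its
#' older bound and a uniform prior between its own oldest descendant tip age
#' and that bound. Point estimates are posterior means and strictly decrease
#' root-to-tips.
#'
#' @param tree rooted `phylo`.
#' @param tip_ages named tip ages (Ma).
#' @param outgroup_ages first-appearance ages of successive outgroups,
#'   oldest first (may be empty).
#' @param t0 hard older bound on all ages (Ma); must exceed every input age.
#' @param resolution number of grid cells (>= 100).
#' @param seed stored for provenance; the quadrature is deterministic.
#' @return a `dated_tree` with an extra element `posteriors` (matrix, one row
#'   per internal node, of posterior masses on the grid `grid_ages`).
#' @export
date_hedman <- function(tree, tip_ages, outgroup_ages = numeric(0), t0,
                        resolution = 1000L, seed = NA_integer_) {
  if (resolution < 100) stop("resolution must be >= 100")
  ta <- match_tip_ages(tree, tip_ages)
  if (t0 <= max(c(ta, outgroup_ages)))
    stop("t0 must exceed all tip and outgroup ages")
  if (is.unsorted(rev(outgroup_ages)))
    stop("outgroup_ages must be in descending order (oldest first)")
  n <- ape::Ntip(tree)
  root <- n + 1L
  fad_below <- init_node_ages(tree, ta)

  h <- t0 / resolution
  grid <- seq(h / 2, t0 - h / 2, length.out = resolution)  # cell midpoints

  # successive-outgroup recursion for the root
  f <- as.numeric(grid > if (length(outgroup_ages)) outgroup_ages[1] else 0)
  if (sum(f) == 0) stop("no grid support above the oldest outgroup age")
  f <- f / sum(f)
  for (t_i in outgroup_ages[-1]) f <- hedman_step(f, grid, t_i)
  f <- hedman_truncate(f, grid, fad_below[root])

  n_all <- n + tree$Nnode
  post <- matrix(NA_real_, tree$Nnode, resolution)
  post[root - n, ] <- f
  ages <- c(ta, rep(NA_real_, tree$Nnode))
  ages[root] <- sum(grid * f)

  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; c_ <- pre[e, 2]
    if (c_ <= n) next
    fc <- hedman_step(post[p - n, ], grid, fad_below[c_])
    post[c_ - n, ] <- fc
    ages[c_] <- sum(grid * fc)
    if (ages[c_] >= ages[p]) ages[c_] <- ages[p] - h / 10  # numeric guard
  }
  dt <- as_dated_tree(tree, ages, "hedman", seed)
  dt$posteriors <- post
  dt$grid_ages <- grid
  dt
}

# one Hedman propagation step: given the older-bound distribution f (mass on
# grid), the age x is uniform on (lower, y) given bound y:
#   g(x) propto 1{x > lower} * sum_{y > x} f(y) / (y - lower)
hedman_step <- function(f, grid, lower) {
  w <- ifelse(grid > lower, f / (grid - lower), 0)
  g <- rev(cumsum(rev(w))) - w        # strictly older grid cells
  g[grid <= lower] <- 0
  if (sum(g) <= 0) {
    # degenerate: bound mass sits at/below 'lower'; fall back to the bound
    g <- as.numeric(grid > lower) * f
    if (sum(g) <= 0) g <- as.numeric(seq_along(grid) == which.max(f))
  }
  g / sum(g)
}

hedman_truncate <- function(f, grid, lower) {
  f[grid <= lower] <- 0
  if (sum(f) <= 0) stop("posterior support empty above age ", lower)
  f / sum(f)
}

# ---- time bins --------------------------------------------------------------

#' Construct time bins
#'
#' Either the bundled ICS geological-stage chart intersected with a time
#' span, or equal-width bins.
#'
#' @param kind `"stages"` or `"equal"`.
#' @param span `c(older, younger)` ages in Ma.
#' @param width bin width in Myr (equal bins only).
#' @return data frame of class `time_bins` with columns `name`, `older`,
#'   `younger`, ordered oldest first; bins are half-open \[older, younger).
#' @export
make_time_bins <- function(kind = c("equal", "stages"), span, width = 10) {
  kind <- match.arg(kind)
  old <- span[1]; young <- span[2]
  if (old <= young) stop("empty span")
  if (kind == "equal") {
    if (width <= 0) stop("width must be > 0")
    edges <- seq(young, old, by = width)
    if (edges[length(edges)] < old) edges <- c(edges, old)
    older <- rev(edges[-1]); younger <- rev(edges[-length(edges)])
    bins <- data.frame(name = sprintf("%g-%g", older, younger),
                       older = older, younger = younger)
  } else {
    chart <- utils::read.csv(system.file("extdata", "ics_stages.csv",
                                         package = "morphoevo"),
                             stringsAsFactors = FALSE)
    keep <- chart$older > young & chart$younger < old
    bins <- chart[keep, ]
    bins$older <- pmin(bins$older, old)
    bins$younger <- pmax(bins$younger, young)
    names(bins)[1] <- "name"
  }
  rownames(bins) <- NULL
  structure(bins, class = c("time_bins", "data.frame"))
}

# does age a fall in bin i (half-open [older, younger); the youngest bin is
# closed at its younger bound so that age 0 belongs to it)
age_in_bin <- function(a, older, younger, youngest = younger == min(younger)) {
  in_open <- a <= older & a > younger
  in_open | (youngest & a == younger)
}
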