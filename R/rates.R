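# Per-branch and per-bin rates of discrete character evolution.
#
# Changes are counted between modal ancestral states (ties toward the lower
# state code) and observed tip states; a branch is scorable for a character
# when both ends carry information (the tip is scored, resp. the internal
# node has at least one scored descendant tip). Character weights multiply
# change counts. The Poisson exposure of a branch is its duration multiplied
# by the (weight-)fraction of scorable characters, and rate heterogeneity is
# tested by likelihood-ratio tests of a two-rate against a one-rate Poisson
# model, compared to chi-squared with 1 df.

#' Per-branch change counts and exposures
#'
#' @param anc an `mk_ancestral` from [ancestral_states_mk()].
#' @param m the `character_matrix` used for the reconstruction.
#' @param dt the `dated_tree` used for the reconstruction.
#' @param bins optional `time_bins`; when given, each branch's duration and
#'   changes are allocated to bins proportionally to temporal overlap.
#' @return object of class `branch_changes`: list with `summaries` (data
#'   frame: `branch`, `parent`, `child`, `duration`, `weighted_duration`,
#'   `changes`), and, with bins, matrices `bin_duration` and `bin_changes`
#'   (branches x bins) whose rows sum to the branch totals.
#' @export
branch_changes <- function(anc, m, dt, bins = NULL) {
  tree <- dt$tree
  n <- ape::Ntip(tree)
  ages <- dt$ages
  cells <- m$cells[tree$tip.label, , drop = FALSE]
  w <- m$characters$weight
  nch <- n_characters(m)
  edge <- tree$edge

  scored <- !is.na(cells) & cells != ""          # tips x chars
  # does each internal node have a scored descendant tip, per character
  has_desc <- matrix(FALSE, n + tree$Nnode, nch)
  has_desc[seq_len(n), ] <- scored
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po)))
    has_desc[po[e, 1], ] <- has_desc[po[e, 1], ] | has_desc[po[e, 2], ]

  nodestate <- function(nd) anc$states[as.character(nd), ]
  nb <- nrow(edge)
  changes <- numeric(nb); wdur <- numeric(nb); dur <- numeric(nb)
  for (e in seq_len(nb)) {
    p <- edge[e, 1]; c_ <- edge[e, 2]
    dur[e] <- ages[p] - ages[c_]
    sp <- nodestate(p)
    if (c_ <= n) {
      scor <- scored[c_, ] & has_desc[p, ] & !is.na(sp)
      diff <- rep(FALSE, nch)
      for (j in which(scor))
        diff[j] <- !(sp[j] %in% decode_cell(cells[c_, j]))
    } else {
      sc <- nodestate(c_)
      scor <- has_desc[c_, ] & has_desc[p, ] & !is.na(sp) & !is.na(sc)
      diff <- scor & (sp != sc)
      diff[is.na(diff)] <- FALSE
    }
    changes[e] <- sum(w[diff])
    wdur[e] <- dur[e] * (sum(w[scor]) / sum(w))
  }
  out <- list(summaries = data.frame(branch = seq_len(nb),
                                     parent = edge[, 1], child = edge[, 2],
                                     duration = dur,
                                     weighted_duration = wdur,
                                     changes = changes))
  if (!is.null(bins)) {
    nb_bins <- nrow(bins)
    bd <- matrix(0, nb, nb_bins, dimnames = list(NULL, bins$name))
    for (i in seq_len(nb_bins)) {
      top <- pmin(ages[edge[, 1]], bins$older[i])
      bot <- pmax(ages[edge[, 2]], bins$younger[i])
      bd[, i] <- pmax(top - bot, 0)
    }
    share <- bd / dur
    out$bin_duration <- share * wdur
    out$bin_changes <- share * changes
  }
  structure(out, class = "branch_changes")
}

# Poisson log-likelihood up to a constant: sum x log r - r d
pois_lnl <- function(x, d, r) {
  sum(ifelse(x > 0, x * log(r), 0)) - r * sum(d)
}

lrt_one_unit <- function(x_focal, d_focal, x_rest, d_rest) {
  X <- x_focal + x_rest; D <- d_focal + d_rest
  r_hat <- X / D
  if (d_rest <= 0) {
    # degenerate partition (single unit): the focal rate is the global rate
    lnl <- pois_lnl(x_focal, d_focal, r_hat)
    return(data.frame(rate = r_hat, global_rate = r_hat, lnl_1rate = lnl,
                      lnl_2rate = lnl, lrt_stat = 0, p_value = 1,
                      direction = "none"))
  }
  lnl1 <- pois_lnl(c(x_focal, x_rest), c(d_focal, d_rest), r_hat)
  r1 <- x_focal / d_focal
  r2 <- x_rest / d_rest
  lnl2 <- (if (x_focal > 0) x_focal * log(r1) else 0) - r1 * d_focal +
    (if (x_rest > 0) x_rest * log(r2) else 0) - r2 * d_rest
  lrt <- max(2 * (lnl2 - lnl1), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  dir_ <- if (isTRUE(all.equal(r1, r_hat)) || lrt < 1e-12) "none"
          else if (r1 > r_hat) "high" else "low"
  data.frame(rate = r1, global_rate = r_hat, lnl_1rate = lnl1,
             lnl_2rate = lnl2, lrt_stat = lrt, p_value = p,
             direction = dir_)
}

#' Likelihood-ratio test for one branch's rate
#'
#' Tests a two-rate Poisson model (focal branch vs the rest of the tree)
#' against a single shared rate; the statistic is compared to
#' \eqn{\chi^2_1}.
#'
#' @param bc a `branch_changes`.
#' @param branch focal branch id (row of `bc$summaries`).
#' @return one-row data frame: `unit`, `changes`, `weighted_duration`,
#'   `rate`, `global_rate`, `lnl_1rate`, `lnl_2rate`, `lrt_stat`, `p_value`,
#'   `direction`.
#' @export
branch_rate_test <- function(bc, branch) {
  s <- bc$summaries
  if (s$weighted_duration[branch] <= 0)
    stop("focal branch has zero weighted duration")
  res <- lrt_one_unit(s$changes[branch], s$weighted_duration[branch],
                      sum(s$changes[-branch]),
                      sum(s$weighted_duration[-branch]))
  cbind(data.frame(unit = as.character(branch),
                   changes = s$changes[branch],
                   weighted_duration = s$weighted_duration[branch]), res)
}

#' Likelihood-ratio tests for all branches
#' @param bc a `branch_changes`.
#' @return data frame, one row per branch with positive weighted duration.
#' @export
all_branch_rate_tests <- function(bc) {
  ok <- which(bc$summaries$weighted_duration > 0)
  do.call(rbind, lapply(ok, function(b) branch_rate_test(bc, b)))
}

#' Likelihood-ratio tests for per-bin rates
#'
#' Aggregates each branch's change and exposure shares into time bins and
#' tests each bin against the remainder with the same two-rate Poisson LRT.
#' Bins with zero aggregated exposure are excluded (and listed in the
#' `excluded_bins` attribute).
#'
#' @param bc a `branch_changes` computed with `bins`.
#' @return data frame: `unit` (bin name), `changes`, `weighted_duration`,
#'   `rate`, `global_rate`, `lnl_1rate`, `lnl_2rate`, `lrt_stat`, `p_value`,
#'   `direction`.
#' @export
bin_rate_test <- function(bc) {
  if (is.null(bc$bin_duration)) stop("branch_changes was built without bins")
  x <- colSums(bc$bin_changes)
  d <- colSums(bc$bin_duration)
  keep <- d > 0
  if (!any(keep)) stop("no bin has positive weighted duration")
  res <- do.call(rbind, lapply(which(keep), function(i)
    lrt_one_unit(x[i], d[i], sum(x[keep][-match(i, which(keep))]),
                 sum(d[keep][-match(i, which(keep))]))))
  out <- cbind(data.frame(unit = names(x)[keep], changes = x[keep],
                          weighted_duration = d[keep]), res)
  rownames(out) <- NULL
  attr(out, "excluded_bins") <- names(x)[!keep]
  out
}

#' Multiple-testing correction for rate tests
#'
#' Adjusts the `p_value` column and adds `p_adjusted` and
#' `significant_after_correction`.
#'
#' @param results data frame from [bin_rate_test()],
#'   [all_branch_rate_tests()] or [branch_rate_test()].
#' @param method `"benjamini-hochberg"` (default) or `"bonferroni"`.
#' @param alpha significance level (default 0.05).
#' @return `results` with the two extra columns.
#' @export
adjust_rate_tests <- function(results, method = c("benjamini-hochberg",
                                                  "bonferroni"),
                              alpha = 0.05) {
  method <- match.arg(method)
  results$p_adjusted <- stats::p.adjust(results$p_value,
                                        method = if (method == "bonferroni")
                                          "bonferroni" else "BH")
  results$significant_after_correction <- results$p_adjusted <= alpha
  results
}

#' Random tree subset
#' @param trees a `multiPhylo` or list of `phylo`.
#' @param n subset size.
#' @param seed integer RNG seed.
#' @return list of `phylo`, drawn uniformly without replacement.
#' @export
select_trees <- function(trees, n, seed = 1L) {
  if (length(trees) == 0) stop("empty tree set")
  if (n > length(trees)) stop("n exceeds the number of trees")
  set.seed(seed)
  unclass(trees)[sample.int(length(trees), n)]
}

#' Replicated per-bin rate curves across trees and datings
#'
#' Emulates a replicated study design: `n_trees` trees are drawn at random
#' from the supplied set and each is dated `n_datings` times per dating
#' method (tip ages redrawn from the stratigraphic ranges each time); per-bin
#' rates and LRTs are computed for every iteration, giving
#' `n_trees * n_datings` "spaghetti" curves per method plus their pointwise
#' mean.
#'
#' @param m a `character_matrix`.
#' @param trees `multiPhylo`/list of undated cladograms.
#' @param ranges a `fossil_ranges` for all tips.
#' @param bins a `time_bins`.
#' @param methods subset of `c("equal", "mbl", "hedman")`.
#' @param n_trees,n_datings replication design (default 5 x 5 = 25
#'   iterations per method).
#' @param seed integer master seed; each iteration uses a derived child seed.
#' @param rate_grid passed to [ancestral_states_mk()].
#' @param dating_args named list of extra arguments for the dating functions
#'   (e.g. `root_extension`, `mbl`, `outgroup_ages`, `t0`, `resolution`).
#' @param alpha,correction multiple-testing control for per-iteration flags.
#' @return list with `curves` (long data frame: `iteration`, `tree_id`,
#'   `dating_id`, `method`, `bin`, `rate`, `p_value`, `significant`,
#'   `direction`) and `mean_curve` (`method`, `bin`, `mean_rate`).
#' @export
rates_replicated <- function(m, trees, ranges, bins,
                             methods = "equal", n_trees = 5L, n_datings = 5L,
                             seed = 1L, rate_grid = NULL,
                             dating_args = list(), alpha = 0.05,
                             correction = "benjamini-hochberg") {
  chosen <- select_trees(trees, n_trees, seed = child_seed(seed, 1))
  rows <- list()
  counter <- 1L
  for (method in methods) {
    it <- 0L
    for (ti in seq_along(chosen)) {
      for (di in seq_len(n_datings)) {
        it <- it + 1L; counter <- counter + 1L
        tree <- chosen[[ti]]
        tips <- sample_tip_ages(ranges[match(tree$tip.label, ranges$taxon), ],
                                seed = child_seed(seed, counter))
        dt <- switch(method,
          equal = do.call(date_equal, c(list(tree, tips),
            dating_args[intersect(names(dating_args), "root_extension")])),
          mbl = do.call(date_mbl, c(list(tree, tips),
            dating_args[intersect(names(dating_args), "mbl")])),
          hedman = do.call(date_hedman, c(list(tree, tips),
            dating_args[intersect(names(dating_args),
              c("outgroup_ages", "t0", "resolution"))])),
          stop("unknown dating method: ", method))
        anc <- ancestral_states_mk(m, dt, rate_grid = rate_grid)
        bc <- branch_changes(anc, m, dt, bins = bins)
        bt <- adjust_rate_tests(bin_rate_test(bc), method = correction,
                                alpha = alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          iteration = it, tree_id = ti, dating_id = di, method = method,
          bin = bt$unit, rate = bt$rate, p_value = bt$p_value,
          significant = bt$significant_after_correction,
          direction = bt$direction)
      }
    }
  }
  curves <- do.call(rbind, rows)
  agg <- stats::aggregate(rate ~ method + bin, data = curves, FUN = mean)
  names(agg)[names(agg) == "rate"] <- "mean_rate"
  # keep bins in chart order
  agg <- agg[order(match(agg$method, methods), match(agg$bin, bins$name)), ]
  rownames(agg) <- NULL
  list(curves = curves, mean_curve = agg)
}

# documented child-seed scheme: one master seed fans out to per-stage seeds
child_seed <- function(seed, counter) {
  (as.integer(seed) %% 1000003L) * 2011L + counter
}
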