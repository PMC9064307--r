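# Synthetic data: birth-death trees with fossil sampling and stratigraphic
# ranges, plus Mk-evolved character matrices with bin-specific rate
# multipliers. The generator emits the same formats the analysis consumes,
# so every stage of the pipeline can be verified against known truth.

#' Simulation configuration
#'
#' @param seed integer master seed.
#' @param n_tips target sampled tip count (`NULL` = no acceptance window).
#' @param birth,death speciation/extinction rates (events per lineage-Myr).
#' @param root_age root age, Ma.
#' @param extant_fraction sampling probability of an extant tip.
#' @param fossil_rate fossil sampling rate per lineage-Myr on extinct
#'   terminal branches.
#' @param range_halfwidth half-width (Myr) of the stratigraphic range placed
#'   symmetrically around a fossil tip's true age (clipped at 0).
#' @param n_characters number of characters.
#' @param state_probs probabilities of 2, 3, 4 states per character.
#' @param fraction_ordered fraction of ordered characters.
#' @param base_rate Mk rate, changes per character per Myr.
#' @param bins a `time_bins` over which rate multipliers apply.
#' @param multipliers per-bin rate multipliers (> 0), recycled; times older
#'   than the oldest bin use multiplier 1.
#' @param min_span_fraction minimum fraction of `root_age` the oldest sampled
#'   tip must reach (the generator emulates a fossil record spanning the
#'   study interval; simulations with only young samples are redrawn).
#' @param expansion_boundary optional age (Ma): before this time a character
#'   partition is frozen (rate 0) and only evolves afterwards, planting a
#'   morphospace expansion at the boundary. `NULL` disables it.
#' @param expansion_fraction fraction of characters in the gated partition.
#' @param missing_fraction,inapplicable_fraction i.i.d. masking fractions.
#' @param retry_cap resimulation attempts before giving up.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_tips = 40L, birth = 0.08,
                              death = 0.07, root_age = 250,
                              extant_fraction = 0.5, fossil_rate = 0.05,
                              range_halfwidth = 5, n_characters = 200L,
                              state_probs = c(0.6, 0.3, 0.1),
                              fraction_ordered = 0.25, base_rate = 0.001,
                              bins = make_time_bins("equal", span = c(250, 0),
                                                    width = 50),
                              multipliers = 1,
                              min_span_fraction = 0.6,
                              expansion_boundary = NULL,
                              expansion_fraction = 0.5,
                              missing_fraction = 0.25,
                              inapplicable_fraction = 0.05,
                              retry_cap = 200L) {
  cfg <- list(seed = as.integer(seed), n_tips = n_tips, birth = birth,
              death = death, root_age = root_age,
              extant_fraction = extant_fraction, fossil_rate = fossil_rate,
              range_halfwidth = range_halfwidth,
              n_characters = as.integer(n_characters),
              state_probs = state_probs / sum(state_probs),
              fraction_ordered = fraction_ordered, base_rate = base_rate,
              bins = bins,
              multipliers = rep_len(multipliers, nrow(bins)),
              min_span_fraction = min_span_fraction,
              expansion_boundary = expansion_boundary,
              expansion_fraction = expansion_fraction,
              missing_fraction = missing_fraction,
              inapplicable_fraction = inapplicable_fraction,
              retry_cap = as.integer(retry_cap))
  stopifnot(cfg$birth > 0, cfg$death >= 0, cfg$fossil_rate >= 0,
            cfg$extant_fraction >= 0, cfg$extant_fraction <= 1,
            cfg$missing_fraction >= 0, cfg$missing_fraction <= 1,
            cfg$inapplicable_fraction >= 0,
            cfg$missing_fraction + cfg$inapplicable_fraction <= 1,
            all(cfg$multipliers > 0), cfg$base_rate >= 0)
  class(cfg) <- "simulation_config"
  cfg
}

#' Built-in simulation scenarios
#'
#' `"null"`: homogeneous rates (all bin multipliers 1). `"burst"`: a single
#' mid-series elevated-rate bin (multiplier 3 in the 150-100 Ma bin),
#' emulating a localized burst of morphological evolution. `"expansion"`:
#' homogeneous rates, but half the characters are frozen until 150 Ma and
#' only evolve afterwards, planting a morphospace expansion at that bin
#' boundary.
#'
#' @param name `"null"`, `"burst"` or `"expansion"`.
#' @param seed master seed stored in the config.
#' @return a `simulation_config`.
#' @export
make_scenario <- function(name = c("null", "burst", "expansion"), seed = 1L) {
  name <- match.arg(name)
  mult <- rep(1, 5)
  if (name == "burst") mult[3] <- 3   # bin "150-100"
  simulation_config(seed = seed, multipliers = mult,
                    expansion_boundary = if (name == "expansion") 150)
}

#' Which bin is the planted burst bin of a config
#' @param cfg a `simulation_config`.
#' @return bin name(s) with multiplier > 1 (empty for null scenarios).
#' @export
burst_bins <- function(cfg) cfg$bins$name[cfg$multipliers > 1]

#' Simulate a dated tree with fossil sampling
#'
#' Simulates a birth-death tree from the root age, samples extant tips with
#' probability `extant_fraction` and extinct tips with probability
#' `1 - exp(-fossil_rate * terminal branch duration)`, and builds
#' stratigraphic ranges of half-width `range_halfwidth` around true tip ages.
#' Resimulates (up to `retry_cap` times) when everything dies unsampled or
#' the sampled tip count misses the `n_tips` acceptance window
#' (\[0.5, 1.6\] x target).
#'
#' @param cfg a `simulation_config`.
#' @return list with `true_tree` (a `dated_tree` on the true time scale),
#'   `ranges` (`fossil_ranges`), and `cladogram` (the same topology with
#'   branch lengths stripped).
#' @export
simulate_tree <- function(cfg) {
  tol <- 1e-8
  for (attempt in seq_len(cfg$retry_cap)) {
    set.seed(child_seed(cfg$seed, attempt))
    full <- ape::rlineage(cfg$birth, cfg$death, Tmax = cfg$root_age)
    if (is.null(full) || ape::Ntip(full) < 3) next
    depth <- ape::node.depth.edgelength(full)
    ntip <- ape::Ntip(full)
    tip_depth <- depth[seq_len(ntip)]
    tip_age <- cfg$root_age - tip_depth
    extant <- tip_age < tol
    term_edge <- full$edge.length[match(seq_len(ntip), full$edge[, 2])]
    p_fossil <- 1 - exp(-cfg$fossil_rate * term_edge)
    u <- stats::runif(ntip)
    keep <- (extant & u < cfg$extant_fraction) |
      (!extant & u < p_fossil)
    if (sum(keep) < 3) next
    if (!is.null(cfg$n_tips) &&
        (sum(keep) < 0.5 * cfg$n_tips || sum(keep) > 1.6 * cfg$n_tips)) next
    if (cfg$fossil_rate > 0 &&
        max(tip_age[keep]) < cfg$min_span_fraction * cfg$root_age) next

    tree <- ape::keep.tip(full, which(keep))
    # absolute ages: anchor the pruned depths on one kept tip's true age
    d2 <- ape::node.depth.edgelength(tree)
    anchor <- match(tree$tip.label[1], full$tip.label)
    root_age2 <- tip_age[anchor] + d2[1]
    ages <- root_age2 - d2
    ages[abs(ages) < tol] <- 0
    true_age <- ages[seq_len(ape::Ntip(tree))]
    is_ext <- true_age < tol
    fad <- ifelse(is_ext, 0, true_age + cfg$range_halfwidth)
    lad <- ifelse(is_ext, 0, pmax(true_age - cfg$range_halfwidth, 0))
    ranges <- fossil_ranges(tree$tip.label, fad, lad)
    clado <- tree
    clado$edge.length <- NULL
    return(list(true_tree = as_dated_tree(tree, ages, "true", cfg$seed),
                ranges = ranges, cladogram = clado))
  }
  stop("simulation failed after ", cfg$retry_cap,
       " attempts (all lineages died unsampled or tip-count window missed)")
}

# multiplier at an age (Ma); ages older than the oldest bin get 1
rate_multiplier_at <- function(age, bins, multipliers) {
  youngest <- bins$younger == min(bins$younger)
  for (i in seq_len(nrow(bins)))
    if (age_in_bin(age, bins$older[i], bins$younger[i], youngest[i]))
      return(multipliers[i])
  1
}

# split [age_from, age_to] (decreasing) at bin boundaries; returns a matrix
# with columns from, to, rate (= base * multiplier of the bin)
edge_segments <- function(age_from, age_to, base_rate, bins, multipliers) {
  cuts <- sort(unique(c(bins$older, bins$younger)), decreasing = TRUE)
  cuts <- cuts[cuts < age_from & cuts > age_to]
  from <- c(age_from, cuts); to <- c(cuts, age_to)
  rate <- base_rate * vapply(seq_along(from), function(s)
    rate_multiplier_at((from[s] + to[s]) / 2, bins, multipliers), 0)
  cbind(from = from, to = to, rate = rate)
}

# as evolve_state, but also counts the substitution events (used to verify
# the Poisson change-count mean)
evolve_state_count <- function(state, k, ordered, seg) {
  count <- 0L
  for (s in seq_len(nrow(seg))) {
    rate <- seg[s, 3]
    if (rate <= 0) next
    t_now <- seg[s, 1]
    repeat {
      leave <- if (!ordered) rate else
        rate / 2 * ((state > 0) + (state < k - 1))
      if (leave <= 0) break
      t_now <- t_now - stats::rexp(1, leave)
      if (t_now <= seg[s, 2]) break
      count <- count + 1L
      if (!ordered) {
        state <- sample(setdiff(0:(k - 1), state), 1)
      } else {
        moves <- c(if (state > 0) state - 1, if (state < k - 1) state + 1)
        state <- if (length(moves) == 1) moves else sample(moves, 1)
      }
    }
  }
  list(state = state, count = count)
}

# evolve one character state across precomputed segments with exact
# exponential waiting times (Gillespie); returns the state at the end
evolve_state <- function(state, k, ordered, seg) {
  for (s in seq_len(nrow(seg))) {
    rate <- seg[s, 3]
    if (rate <= 0) next
    t_now <- seg[s, 1]
    repeat {
      leave <- if (!ordered) rate else
        rate / 2 * ((state > 0) + (state < k - 1))
      if (leave <= 0) break
      t_now <- t_now - stats::rexp(1, leave)
      if (t_now <= seg[s, 2]) break
      if (!ordered) {
        state <- sample(setdiff(0:(k - 1), state), 1)
      } else {
        moves <- c(if (state > 0) state - 1, if (state < k - 1) state + 1)
        state <- if (length(moves) == 1) moves else sample(moves, 1)
      }
    }
  }
  state
}

#' Simulate a character matrix on a dated tree
#'
#' Per character: the number of states and ordering are drawn from the
#' config, the root state is uniform, and the state evolves root-to-tips
#' under an Mk process whose instantaneous rate at time t is
#' `base_rate * multiplier(bin(t))`, using exact exponential waiting times.
#' Ordered characters evolve by the stepwise chain (neighbour rate
#' `base_rate/2`). Missing and inapplicable masks are applied i.i.d.
#'
#' @param cfg a `simulation_config`.
#' @param dt a `dated_tree` (normally the true tree from [simulate_tree()]).
#' @return a `character_matrix` over the tree's tips.
#' @export
simulate_characters <- function(cfg, dt) {
  set.seed(child_seed(cfg$seed, 9999L))
  tree <- dt$tree
  ages <- dt$ages
  n <- ape::Ntip(tree)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  root <- n + 1L

  nch <- cfg$n_characters
  kvec <- sample(2:4, nch, replace = TRUE, prob = cfg$state_probs)
  ordered <- stats::runif(nch) < cfg$fraction_ordered
  gated <- rep(FALSE, nch)
  if (!is.null(cfg$expansion_boundary))
    gated <- seq_len(nch) <= round(cfg$expansion_fraction * nch)
  segs <- lapply(seq_len(nrow(pre)), function(e)
    edge_segments(ages[pre[e, 1]], ages[pre[e, 2]], cfg$base_rate,
                  cfg$bins, cfg$multipliers))
  segs_gated <- segs
  if (!is.null(cfg$expansion_boundary)) {
    segs_gated <- lapply(segs, function(sg) {
      sg[, 3] <- sg[, 3] * ((sg[, 1] + sg[, 2]) / 2 < cfg$expansion_boundary)
      sg
    })
  }
  cells <- matrix(NA_character_, n, nch, dimnames = list(tree$tip.label, NULL))
  for (j in seq_len(nch)) {
    st <- integer(n + tree$Nnode)
    st[root] <- sample.int(kvec[j], 1) - 1L
    sg <- if (gated[j]) segs_gated else segs
    for (e in seq_len(nrow(pre)))
      st[pre[e, 2]] <- evolve_state(st[pre[e, 1]], kvec[j], ordered[j],
                                    sg[[e]])
    cells[, j] <- as.character(st[seq_len(n)])
  }
  u <- matrix(stats::runif(n * nch), n, nch)
  cells[u < cfg$missing_fraction] <- NA_character_
  cells[u >= cfg$missing_fraction &
          u < cfg$missing_fraction + cfg$inapplicable_fraction] <- ""
  character_matrix(cells,
                   ordering = ifelse(ordered, "ordered", "unordered"))
}

#' Topology variants of a cladogram
#'
#' Generates a set of cladograms differing by small local rearrangements
#' (random collapse of internal edges followed by random re-resolution),
#' emulating a sample of equally parsimonious topologies.
#'
#' @param clado rooted `phylo` without branch lengths.
#' @param n number of trees (the first is the input topology).
#' @param n_collapse internal edges collapsed per variant (default 2).
#' @param seed integer RNG seed.
#' @return list of `phylo`.
#' @export
make_cladogram_set <- function(clado, n, n_collapse = 2L, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  out[[1]] <- clado
  if (n == 1) return(out)
  for (i in seq_len(n - 1)) {
    t2 <- ape::compute.brlen(clado, 1)
    internal <- which(t2$edge[, 2] > ape::Ntip(t2))
    pick <- sample(internal, min(n_collapse, length(internal)))
    t2$edge.length[pick] <- 0
    t2 <- ape::di2multi(t2, tol = 1e-9)
    t2 <- ape::multi2di(t2, random = TRUE)
    t2$edge.length <- NULL
    out[[i + 1]] <- t2
  }
  out
}

#' Write a simulated scenario to pipeline input files
#'
#' Emits `matrix.nex`, `cladograms.nwk` (a tree set), `ranges.csv` and
#' `truth.json` (true node ages and per-bin rates) into a directory.
#'
#' @param cfg a `simulation_config`.
#' @param dir output directory (created if needed).
#' @param n_cladograms size of the emitted topology set (default 5).
#' @return invisibly, a list with the simulated objects and file paths.
#' @export
simulate_scenario_files <- function(cfg, dir, n_cladograms = 5L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_tree(cfg)
  m <- simulate_characters(cfg, sim$true_tree)
  trees <- make_cladogram_set(sim$cladogram, n_cladograms,
                              seed = child_seed(cfg$seed, 555L))
  paths <- list(matrix = file.path(dir, "matrix.nex"),
                trees = file.path(dir, "cladograms.nwk"),
                ranges = file.path(dir, "ranges.csv"),
                truth = file.path(dir, "truth.json"))
  write_nexus(m, paths$matrix)
  ape::write.tree(do.call(c, lapply(trees, identity)), paths$trees)
  utils::write.csv(sim$ranges[, c("taxon", "fad", "lad")], paths$ranges,
                   row.names = FALSE)
  truth <- list(
    node_ages = as.list(stats::setNames(sim$true_tree$ages,
                                        seq_along(sim$true_tree$ages))),
    bin = as.list(stats::setNames(cfg$base_rate * cfg$multipliers,
                                  cfg$bins$name)),
    burst_bins = burst_bins(cfg))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(matrix = m, tree = sim$true_tree, ranges = sim$ranges,
                 cladograms = trees, paths = paths))
}

#' Serialize / restore a simulation config
#'
#' @param cfg a `simulation_config`.
#' @param path YAML file.
#' @return [write_simulation_config()] returns `path` invisibly;
#'   [read_simulation_config()] returns the restored `simulation_config`.
#' @export
write_simulation_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$bins <- list(name = cfg$bins$name, older = cfg$bins$older,
                 younger = cfg$bins$younger)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  bins <- structure(data.frame(name = x$bins$name, older = x$bins$older,
                               younger = x$bins$younger),
                    class = c("time_bins", "data.frame"))
  simulation_config(seed = x$seed, n_tips = x$n_tips, birth = x$birth,
                    death = x$death, root_age = x$root_age,
                    extant_fraction = x$extant_fraction,
                    fossil_rate = x$fossil_rate,
                    range_halfwidth = x$range_halfwidth,
                    n_characters = x$n_characters,
                    state_probs = unlist(x$state_probs),
                    fraction_ordered = x$fraction_ordered,
                    base_rate = x$base_rate, bins = bins,
                    multipliers = unlist(x$multipliers),
                    min_span_fraction = x$min_span_fraction,
                    expansion_boundary = x$expansion_boundary,
                    expansion_fraction = x$expansion_fraction,
                    missing_fraction = x$missing_fraction,
                    inapplicable_fraction = x$inapplicable_fraction,
                    retry_cap = x$retry_cap)
}
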