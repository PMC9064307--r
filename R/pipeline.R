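# Config-driven orchestration: matrix -> distances -> ordination -> binned
# morphospace, disparity, rates, clusters and Cramer profiles, with all
# results exported as flat tables plus a run manifest. The tables are the
# contract; plots are rendered from them only.

#' Pipeline configuration
#'
#' Builds and validates a pipeline configuration. `matrix`, `trees` and
#' `ranges` are input file paths (NEXUS matrix, newick tree set, and a
#' `taxon,fad,lad` CSV).
#'
#' @param matrix,trees,ranges input file paths.
#' @param char_meta optional character-metadata CSV (`index,ordering,weight`).
#' @param bins a `time_bins`, or a list `list(kind=, span=, width=)`.
#' @param dating_methods subset of `c("equal", "mbl", "hedman")`.
#' @param dating_args named list of dating parameters (`root_extension`,
#'   `mbl`, `outgroup_ages`, `t0`, `resolution`); `t0` is required when
#'   `"hedman"` is requested.
#' @param n_trees,n_datings replication design (default 5 x 5).
#' @param bootstrap_reps bootstrap/rarefaction replicates.
#' @param alpha significance level; `correction` the multiple-test method.
#' @param seed master seed; all stages derive child seeds from it.
#' @param groups optional named list of taxon subsets (must nest within the
#'   matrix taxa) given per-group disparity.
#' @param cluster_k_range candidate k for PAM clustering.
#' @param cramer_axes ordination axes profiled with Cramer coefficients.
#' @param outdir output directory.
#' @param make_plots render PNG figures from the exported tables.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, trees, ranges, char_meta = NULL,
                            bins = list(kind = "equal", span = c(250, 0),
                                        width = 50),
                            dating_methods = "equal",
                            dating_args = list(),
                            n_trees = 5L, n_datings = 5L,
                            bootstrap_reps = 500L, alpha = 0.05,
                            correction = "benjamini-hochberg", seed = 1L,
                            groups = NULL, cluster_k_range = 2:6,
                            cramer_axes = 1:2, outdir = "morphoevo-out",
                            make_plots = TRUE) {
  cfg <- list(matrix = matrix, trees = trees, ranges = ranges,
              char_meta = char_meta, bins = bins,
              dating_methods = dating_methods, dating_args = dating_args,
              n_trees = as.integer(n_trees), n_datings = as.integer(n_datings),
              bootstrap_reps = as.integer(bootstrap_reps), alpha = alpha,
              correction = correction, seed = as.integer(seed),
              groups = groups, cluster_k_range = cluster_k_range,
              cramer_axes = cramer_axes, outdir = outdir,
              make_plots = isTRUE(make_plots))
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  for (f in c("matrix", "trees")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config error: input file '", f, "' missing or not found: ",
           cfg[[f]])
  }
  if (length(cfg$dating_methods)) {
    if (is.null(cfg$ranges) || !file.exists(cfg$ranges))
      stop("config error: dating methods requested but the tip-age file ",
           "('ranges') is missing")
    bad <- setdiff(cfg$dating_methods, c("equal", "mbl", "hedman"))
    if (length(bad)) stop("config error: unknown dating method: ", bad[1])
    if ("hedman" %in% cfg$dating_methods &&
        is.null(cfg$dating_args$t0))
      stop("config error: the hedman method needs dating_args$t0")
  }
  if (cfg$n_trees < 1 || cfg$n_datings < 1)
    stop("config error: replication must be >= 1")
  if (!inherits(cfg$bins, "time_bins"))
    cfg$bins <- do.call(make_time_bins, cfg$bins)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()]; relative
#'   input paths are resolved against the file's directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("matrix", "trees", "ranges", "char_meta"))
    if (!is.null(x[[f]]) && !startsWith(x[[f]], "/"))
      x[[f]] <- file.path(base, x[[f]])
  if (!is.null(x$bins)) x$bins$span <- unlist(x$bins$span)
  do.call(pipeline_config, x)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs; MORD distances (exported as square CSV); taxon
#' trimming; PCO ordination; per-bin occupancy and convex-hull areas;
#' bootstrapped/rarefied disparity through time; per-group disparity;
#' replicated per-bin rate curves across trees/datings plus one
#' representative per-branch rate table; PAM clusters; character-axis Cramer
#' profiles; completeness summaries; and a run manifest. Deterministic given
#' the config seed. Any stage failure aborts with the stage name.
#'
#' @param config a `pipeline_config`, or the path of a YAML config file.
#' @return invisibly, a list with the main in-memory results and `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  log_stage <- function(s) message("[morphoevo] stage: ", s)
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  m <- stage("read_matrix", read_nexus(cfg$matrix, meta_csv = cfg$char_meta))
  trees <- stage("read_trees", {
    tr <- ape::read.tree(cfg$trees)
    if (inherits(tr, "phylo")) list(tr) else unclass(tr)
  })
  ranges <- stage("read_ranges", read_ranges(cfg$ranges))
  bins <- cfg$bins

  if (!is.null(cfg$groups)) {
    for (g in names(cfg$groups)) {
      extra <- setdiff(cfg$groups[[g]], m$taxa)
      if (length(extra))
        stop("pipeline stage 'groups' failed: group '", g,
             "' has taxa outside the matrix: ",
             paste(extra, collapse = ", "), call. = FALSE)
    }
  }

  d <- stage("distances", mord(m))
  write_distance_csv(d, out("distances.csv"))
  tr_res <- stage("trim", trim_incalculable(d))
  writeLines(tr_res$removed, out("removed_taxa.txt"))
  ord <- stage("ordination", pco(tr_res$distances))
  write_tsv(data.frame(taxon = ord$taxa, ord$scores, check.names = FALSE),
            out("ordination.tsv"))
  write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                       eigenvalue = ord$eigenvalues,
                       variance_explained = ord$variance_explained),
            out("eigenvalues.tsv"))

  comp <- completeness(m)
  write_tsv(data.frame(taxon = m$taxa, completeness = comp$taxon),
            out("completeness_taxa.tsv"))

  membership <- stage("bin_membership",
                      taxa_in_bins(ranges[ranges$taxon %in% ord$taxa, ], bins))
  write_tsv(data.frame(
    bin = rep(names(membership), vapply(membership, length, 0L)),
    taxon = unlist(membership)), out("bin_membership.tsv"))
  hulls <- stage("hull_areas", bin_hull_areas(ord, membership))
  write_tsv(hulls, out("hull_areas.tsv"))

  disp <- stage("disparity",
                disparity_through_time(ord, membership,
                                       reps = cfg$bootstrap_reps,
                                       seed = child_seed(cfg$seed, 101L)))
  write_tsv(disp, out("disparity.tsv"))

  groups_tab <- NULL
  if (!is.null(cfg$groups)) {
    groups_tab <- stage("groups", do.call(rbind, lapply(names(cfg$groups),
      function(g) {
        tx <- intersect(cfg$groups[[g]], ord$taxa)
        data.frame(group = g, n = length(tx),
                   sov = if (length(tx) >= 2)
                     sum_of_variances(ord$scores[tx, , drop = FALSE])
                   else NA_real_,
                   wmpd = tryCatch(wmpd(d, intersect(cfg$groups[[g]], d$taxa)),
                                   error = function(e) NA_real_))
      })))
    write_tsv(groups_tab, out("groups.tsv"))
  }

  rates <- NULL
  if (length(cfg$dating_methods)) {
    rates <- stage("rates", rates_replicated(
      m, trees, ranges, bins, methods = cfg$dating_methods,
      n_trees = min(cfg$n_trees, length(trees)), n_datings = cfg$n_datings,
      seed = child_seed(cfg$seed, 202L), dating_args = cfg$dating_args,
      alpha = cfg$alpha, correction = cfg$correction))
    write_tsv(rates$curves, out("rates_iterations.tsv"))
    write_tsv(rates$mean_curve, out("rates_mean.tsv"))

    branch_tab <- stage("branch_rates", {
      tips <- sample_tip_ages(ranges, seed = child_seed(cfg$seed, 303L))
      meth <- cfg$dating_methods[1]
      dt <- switch(meth,
        equal = do.call(date_equal, c(list(trees[[1]], tips),
          cfg$dating_args[intersect(names(cfg$dating_args),
                                    "root_extension")])),
        mbl = do.call(date_mbl, c(list(trees[[1]], tips),
          cfg$dating_args[intersect(names(cfg$dating_args), "mbl")])),
        hedman = do.call(date_hedman, c(list(trees[[1]], tips),
          cfg$dating_args[intersect(names(cfg$dating_args),
                                    c("outgroup_ages", "t0", "resolution"))])))
      anc <- ancestral_states_mk(m, dt)
      bc <- branch_changes(anc, m, dt, bins = bins)
      list(branch = adjust_rate_tests(all_branch_rate_tests(bc),
                                      method = cfg$correction,
                                      alpha = cfg$alpha),
           bin = adjust_rate_tests(bin_rate_test(bc),
                                   method = cfg$correction,
                                   alpha = cfg$alpha))
    })
    write_tsv(branch_tab$branch, out("branch_rates.tsv"))
    write_tsv(branch_tab$bin, out("bin_rates.tsv"))
  }

  clus <- stage("clusters",
                select_k_medoids(ord$scores[, 1:2, drop = FALSE],
                                 k_range = cfg$cluster_k_range,
                                 seed = child_seed(cfg$seed, 404L)))
  write_tsv(data.frame(taxon = ord$taxa, cluster = clus$assignment),
            out("clusters.tsv"))

  cram <- stage("cramer", do.call(rbind, lapply(
    cfg$cramer_axes[cfg$cramer_axes <= ncol(ord$scores)],
    function(ax) character_axis_cramer(m, ord, axis = ax))))
  write_tsv(cram, out("cramer.tsv"))

  manifest <- stage("manifest", {
    cfg_file <- out("config.yaml")
    cfg_y <- cfg
    cfg_y$bins <- list(name = bins$name, older = bins$older,
                       younger = bins$younger)
    yaml::write_yaml(cfg_y[setdiff(names(cfg_y), "outdir")], cfg_file)
    man <- list(package = "morphoevo",
                version = as.character(utils::packageVersion("morphoevo")),
                seed = cfg$seed,
                config_md5 = unname(tools::md5sum(cfg_file)),
                n_taxa = n_taxa(m), n_characters = n_characters(m),
                n_trees_available = length(trees),
                removed_taxa = tr_res$removed,
                rarefaction_n = attr(disp, "rarefaction_n"))
    jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    man
  })

  if (cfg$make_plots) stage("plots", render_pipeline_plots(cfg$outdir))

  invisible(list(matrix = m, distances = d, ordination = ord,
                 membership = membership, disparity = disp, rates = rates,
                 clusters = clus, cramer = cram, groups = groups_tab,
                 manifest = manifest, outdir = cfg$outdir))
}

# figures drawn from the exported tables only (no hidden state)
render_pipeline_plots <- function(outdir) {
  disp <- utils::read.delim(file.path(outdir, "disparity.tsv"))
  grDevices::png(file.path(outdir, "disparity.png"), width = 800,
                 height = 500)
  mid <- seq_len(nrow(disp))
  graphics::plot(mid, disp$sov, type = "b", pch = 16, xaxt = "n",
                 xlab = "time bin", ylab = "sum of variances",
                 main = "Disparity through time",
                 ylim = range(c(disp$lo, disp$hi, disp$sov), na.rm = TRUE))
  graphics::axis(1, at = mid, labels = disp$bin, las = 2, cex.axis = 0.8)
  graphics::arrows(mid, disp$lo, mid, disp$hi, angle = 90, code = 3,
                   length = 0.04)
  graphics::lines(mid, disp$rarefied_sov, lty = 2)
  grDevices::dev.off()

  rate_file <- file.path(outdir, "rates_iterations.tsv")
  if (file.exists(rate_file)) {
    cur <- utils::read.delim(rate_file)
    avg <- utils::read.delim(file.path(outdir, "rates_mean.tsv"))
    grDevices::png(file.path(outdir, "rates.png"), width = 800, height = 500)
    bins_u <- unique(avg$bin)
    mid <- seq_along(bins_u)
    graphics::plot(NULL, xlim = range(mid), ylim = range(cur$rate),
                   xaxt = "n", xlab = "time bin",
                   ylab = "rate (changes / char-weighted Myr)",
                   main = "Evolutionary rates through time")
    graphics::axis(1, at = mid, labels = bins_u, las = 2, cex.axis = 0.8)
    for (it in unique(interaction(cur$method, cur$iteration))) {
      sub <- cur[interaction(cur$method, cur$iteration) == it, ]
      graphics::lines(match(sub$bin, bins_u), sub$rate,
                      col = grDevices::grey(0.8))
    }
    for (meth in unique(avg$method)) {
      sub <- avg[avg$method == meth, ]
      graphics::lines(match(sub$bin, bins_u), sub$mean_rate, lwd = 2)
    }
    grDevices::dev.off()
  }

  ord <- utils::read.delim(file.path(outdir, "ordination.tsv"))
  clus <- utils::read.delim(file.path(outdir, "clusters.tsv"))
  grDevices::png(file.path(outdir, "morphospace.png"), width = 600,
                 height = 600)
  graphics::plot(ord$PCO1, ord$PCO2, pch = 16,
                 col = clus$cluster[match(ord$taxon, clus$taxon)],
                 xlab = "PCO1", ylab = "PCO2", main = "Morphospace")
  grDevices::dev.off()
  invisible(NULL)
}
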