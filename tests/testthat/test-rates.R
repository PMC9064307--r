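make_bc <- function(changes, durations) {
  structure(list(summaries = data.frame(
    branch = seq_along(changes), parent = NA, child = NA,
    duration = durations, weighted_duration = durations,
    changes = changes)), class = "branch_changes")
}

test_that("branch changes count state flips and allocate to bins", {
  tr <- ape::read.tree(text = "((A,B),C);")
  dt <- date_equal(tr, c(A = 150, B = 160, C = 160), root_extension = 10)
  # one character, single flip on the branch to A
  m <- character_matrix(rbind(A = "1", B = "0", C = "0"))
  anc <- ancestral_states_mk(m, dt, rate = 0.001)
  bc <- branch_changes(anc, m, dt)
  s <- bc$summaries
  expect_equal(sum(s$changes), 1)
  expect_equal(s$changes[s$child == 1], 1)

  # parent = child everywhere: zero changes
  m0 <- character_matrix(rbind(A = "0", B = "0", C = "0"))
  bc0 <- branch_changes(ancestral_states_mk(m0, dt, rate = 0.001), m0, dt)
  expect_equal(sum(bc0$summaries$changes), 0)

  # proportional allocation: branch spanning two bins 60/40 with 5 changes
  bins <- make_time_bins("equal", span = c(170, 140), width = 10)
  cells <- do.call(rbind, lapply(1:3, function(i)
    c(A = "1", B = "0", C = "0")[i]))
  m5 <- character_matrix(matrix(rep(c("1", "0", "0"), 5), 3, 5,
                                dimnames = list(c("A", "B", "C"), NULL)))
  bc5 <- branch_changes(ancestral_states_mk(m5, dt, rate = 0.001), m5, dt,
                        bins = bins)
  br <- which(bc5$summaries$child == 1)   # A's branch spans 165..150
  expect_equal(bc5$summaries$changes[br], 5)
  expect_equal(unname(bc5$bin_changes[br, ]),
               5 * c(5, 10, 0) / 15, tolerance = 1e-9)
  # bin duration shares sum to the branch exposure
  expect_equal(rowSums(bc5$bin_duration), bc5$summaries$weighted_duration,
               tolerance = 1e-9)

  # a missing tip makes its terminal branch unscorable for that character
  mna <- character_matrix(rbind(A = NA, B = "0", C = "0"))
  bcna <- branch_changes(ancestral_states_mk(mna, dt, rate = 0.001), mna, dt)
  expect_equal(bcna$summaries$weighted_duration[bcna$summaries$child == 1], 0)
})

test_that("branch LRT matches the closed-form Poisson oracle", {
  bc <- make_bc(changes = c(8, 2), durations = c(10, 10))
  r <- branch_rate_test(bc, 1)
  lnl2 <- 8 * log(0.8) - 8 + 2 * log(0.2) - 2
  lnl1 <- 10 * log(0.5) - 10
  expect_equal(r$lrt_stat, 2 * (lnl2 - lnl1), tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(2 * (lnl2 - lnl1), 1, lower.tail = FALSE))
  expect_identical(r$direction, "high")
  expect_equal(r$rate, 0.8)
  expect_equal(r$global_rate, 0.5)

  # identical rates everywhere: LRT ~ 0, p ~ 1, no direction
  bc2 <- make_bc(changes = c(5, 5, 5), durations = c(10, 10, 10))
  r2 <- branch_rate_test(bc2, 2)
  expect_lt(r2$lrt_stat, 1e-10)
  expect_gt(r2$p_value, 0.999)
  expect_identical(r2$direction, "none")

  # invariance under relabeling of non-focal branches
  bc3 <- make_bc(changes = c(7, 1, 4, 2), durations = c(5, 8, 6, 9))
  bc3p <- make_bc(changes = c(7, 4, 2, 1), durations = c(5, 6, 9, 8))
  expect_equal(branch_rate_test(bc3, 1)$lrt_stat,
               branch_rate_test(bc3p, 1)$lrt_stat)

  bc4 <- make_bc(changes = c(1, 1), durations = c(0, 10))
  expect_error(branch_rate_test(bc4, 1), "zero weighted duration")
})

test_that("global rate is conserved across partitions", {
  set.seed(12)
  x <- rpois(20, 5); d <- runif(20, 2, 10)
  bc <- make_bc(x, d)
  for (b in c(1, 7, 20))
    expect_equal(branch_rate_test(bc, b)$global_rate, sum(x) / sum(d))
})

test_that("bin tests aggregate shares and handle degenerate partitions", {
  tr <- ape::read.tree(text = "((A,B),C);")
  dt <- date_equal(tr, c(A = 150, B = 160, C = 160), root_extension = 10)
  m <- character_matrix(rbind(A = c("1", "0"), B = c("0", "0"),
                              C = c("0", "1")))
  anc <- ancestral_states_mk(m, dt, rate = 0.001)

  # single covering bin: rate equals the global rate, LRT 0
  one <- make_time_bins("equal", span = c(170, 140), width = 30)
  bt1 <- bin_rate_test(branch_changes(anc, m, dt, bins = one))
  expect_equal(bt1$rate, bt1$global_rate)
  expect_equal(bt1$p_value, 1)

  # bins with zero exposure are excluded and logged
  wide <- make_time_bins("equal", span = c(250, 0), width = 50)
  btw <- bin_rate_test(branch_changes(anc, m, dt, bins = wide))
  expect_true(all(btw$weighted_duration > 0))
  expect_true("50-0" %in% attr(btw, "excluded_bins"))
  expect_error(bin_rate_test(branch_changes(anc, m, dt)), "without bins")
})

test_that("multiple-test correction matches hand-applied BH", {
  res <- data.frame(unit = letters[1:5],
                    p_value = c(0.010, 0.020, 0.030, 0.040, 0.200))
  adj <- adjust_rate_tests(res, method = "benjamini-hochberg", alpha = 0.05)
  # hand BH: p * 5 / rank, cumulative minimum from the largest rank
  expect_equal(adj$p_adjusted, c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_equal(adj$significant_after_correction, c(rep(TRUE, 4), FALSE))

  bon <- adjust_rate_tests(res, method = "bonferroni", alpha = 0.05)
  expect_equal(bon$p_adjusted, pmin(res$p_value * 5, 1))
  expect_equal(sum(bon$significant_after_correction), 1)

  one <- adjust_rate_tests(data.frame(unit = "x", p_value = 0.04))
  expect_true(one$significant_after_correction)
  all1 <- adjust_rate_tests(data.frame(unit = letters[1:4],
                                       p_value = rep(1, 4)))
  expect_false(any(all1$significant_after_correction))
})

test_that("planted multipliers are recovered within 30% at fixture scale", {
  ratio_for <- function(scenario) {
    mean(vapply(1:6, function(s) {
      cfg <- make_scenario(scenario, seed = s)
      sim <- simulate_tree(cfg)
      m <- simulate_characters(cfg, sim$true_tree)
      anc <- ancestral_states_mk(m, sim$true_tree)
      bt <- bin_rate_test(branch_changes(anc, m, sim$true_tree,
                                         bins = cfg$bins))
      focal <- bt$rate[bt$unit == "150-100"]
      # baseline: bins not adjacent to the focal bin (adjacent bins receive
      # smeared changes from branches spanning the boundary)
      focal / mean(bt$rate[bt$unit %in% c("250-200", "50-0")])
    }, 0))
  }
  expect_equal(ratio_for("burst"), 3, tolerance = 0.3)
  expect_equal(ratio_for("null"), 1, tolerance = 0.3)
})

test_that("tree selection is uniform, seeded and validated", {
  trees <- lapply(1:4, function(i) ape::rtree(5))
  expect_identical(select_trees(trees, 4, seed = 1)[[1]]$tip.label,
                   select_trees(trees, 4, seed = 1)[[1]]$tip.label)
  expect_length(select_trees(trees, 4, seed = 2), 4)
  counts <- table(vapply(1:4000, function(i)
    which(vapply(trees, identical, TRUE,
                 select_trees(trees, 1, seed = i)[[1]]))[1], 0L))
  expect_true(all(abs(counts / 4000 - 0.25) < 0.03))
  expect_error(select_trees(trees, 5, seed = 1), "exceeds")
  expect_error(select_trees(list(), 1, seed = 1), "empty")
})

test_that("replicated rate curves reproduce and average correctly", {
  cfg <- simulation_config(seed = 3, n_tips = 15L, n_characters = 40L,
                           root_age = 120,
                           bins = make_time_bins("equal", span = c(120, 0),
                                                 width = 40))
  sim <- simulate_tree(cfg)
  m <- simulate_characters(cfg, sim$true_tree)

  one <- rates_replicated(m, list(sim$cladogram), sim$ranges, cfg$bins,
                          methods = "equal", n_trees = 1, n_datings = 1,
                          seed = 5)
  # single iteration: mean curve equals the curve itself
  merged <- merge(one$curves, one$mean_curve, by = c("method", "bin"))
  expect_equal(merged$rate, merged$mean_rate)

  two <- rates_replicated(m, list(sim$cladogram), sim$ranges, cfg$bins,
                          methods = "equal", n_trees = 1, n_datings = 2,
                          seed = 5)
  expect_equal(sort(unique(two$curves$iteration)), 1:2)
  agg <- aggregate(rate ~ bin, data = two$curves, FUN = mean)
  expect_equal(two$mean_curve$mean_rate[match(agg$bin, two$mean_curve$bin)],
               agg$rate)
  # full reproducibility under the same seed
  two_b <- rates_replicated(m, list(sim$cladogram), sim$ranges, cfg$bins,
                            methods = "equal", n_trees = 1, n_datings = 2,
                            seed = 5)
  expect_identical(two, two_b)
})
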