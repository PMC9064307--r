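test_that("tree simulation respects its contracts", {
  # death = 0, fossil rate = 0: all tips extant at age 0
  cfg <- simulation_config(seed = 5, n_tips = NULL, birth = 0.03, death = 0,
                           fossil_rate = 0, root_age = 100,
                           extant_fraction = 1)
  sim <- simulate_tree(cfg)
  expect_true(all(sim$ranges$is_extant))
  expect_true(all(abs(sim$true_tree$tip_ages) < 1e-8))

  # seeded reproducibility and valid dated-tree invariants
  cfg2 <- make_scenario("burst", seed = 11)
  s1 <- simulate_tree(cfg2)
  s2 <- simulate_tree(cfg2)
  expect_identical(ape::write.tree(s1$true_tree$tree),
                   ape::write.tree(s2$true_tree$tree))
  expect_identical(s1$ranges, s2$ranges)
  expect_true(all(s1$true_tree$tree$edge.length > 0))
  expect_null(s1$cladogram$edge.length)

  # stratigraphic ranges bracket the true tip ages
  fossil <- !s1$ranges$is_extant
  expect_true(all(s1$ranges$fad[fossil] >=
                    s1$true_tree$tip_ages[fossil] - 1e-9))
  expect_true(all(s1$ranges$lad[fossil] <=
                    s1$true_tree$tip_ages[fossil] + 1e-9))
  # the record spans deep time (acceptance condition of the generator)
  expect_gte(max(s1$ranges$fad), 0.6 * cfg2$root_age)
})

test_that("pure-birth tip counts match the closed-form expectation", {
  counts <- vapply(1:400, function(s) {
    cfg <- simulation_config(seed = s, n_tips = NULL, birth = 0.04,
                             death = 0, fossil_rate = 0, root_age = 50,
                             extant_fraction = 1, retry_cap = 50)
    nrow(simulate_tree(cfg)$ranges)
  }, 0)
  # two founder lineages diverge at the root age: E[N] = 2 exp(bT) = 14.8;
  # the >= 3 tip acceptance affects < 2% of draws at these settings
  expected <- 2 * exp(0.04 * 50)
  expect_true(all(counts >= 3))
  expect_equal(mean(counts), expected, tolerance = 0.12)
})

test_that("the Mk branch process has the right moments", {
  bins <- make_time_bins("equal", span = c(100, 0), width = 50)
  seg <- morphoevo:::edge_segments(60, 40, 0.1, bins, c(1, 1))
  # zero rate: state never moves
  seg0 <- seg; seg0[, 3] <- 0
  expect_equal(morphoevo:::evolve_state(1, 3, FALSE, seg0), 1)

  # unordered leave rate is state-independent, so the change count is
  # exactly Poisson(rate x duration x multiplier)
  set.seed(21)
  n1 <- vapply(1:4000, function(i)
    morphoevo:::evolve_state_count(0, 3, FALSE, seg)$count, 0L)
  expect_equal(mean(n1), 0.1 * 20, tolerance = 0.05)

  # an edge lying inside the x3 bin sees a tripled Poisson mean
  segm <- morphoevo:::edge_segments(90, 70, 0.1, bins, c(3, 1))
  set.seed(22)
  n3 <- vapply(1:4000, function(i)
    morphoevo:::evolve_state_count(0, 3, FALSE, segm)$count, 0L)
  expect_equal(mean(n3), 0.1 * 20 * 3, tolerance = 0.05)
  # an edge straddling the boundary sees the mixed mean
  segx <- morphoevo:::edge_segments(60, 40, 0.1, bins, c(3, 1))
  set.seed(24)
  nx <- vapply(1:4000, function(i)
    morphoevo:::evolve_state_count(0, 3, FALSE, segx)$count, 0L)
  expect_equal(mean(nx), 0.1 * 10 * 3 + 0.1 * 10, tolerance = 0.06)

  # high-rate two-state character reaches the uniform stationary frequency
  seghot <- morphoevo:::edge_segments(100, 0, 1, bins, c(1, 1))
  set.seed(23)
  ends <- vapply(1:2000, function(i)
    morphoevo:::evolve_state(0, 2, FALSE, seghot), 0)
  expect_equal(mean(ends), 0.5, tolerance = 0.06)

  # base rate 0: every tip equals the root state
  cfg <- simulation_config(seed = 2, n_tips = 10L, n_characters = 12L,
                           base_rate = 0, missing_fraction = 0,
                           inapplicable_fraction = 0)
  sim <- simulate_tree(cfg)
  m <- simulate_characters(cfg, sim$true_tree)
  expect_true(all(apply(m$cells, 2, function(x) length(unique(x)) == 1)))
})

test_that("character simulation is seeded and masked as configured", {
  cfg <- make_scenario("null", seed = 31)
  sim <- simulate_tree(cfg)
  m1 <- simulate_characters(cfg, sim$true_tree)
  m2 <- simulate_characters(cfg, sim$true_tree)
  expect_identical(m1$cells, m2$cells)
  expect_equal(mean(is.na(m1$cells)), cfg$missing_fraction,
               tolerance = 0.05)
  masked <- is.na(m1$cells) | m1$cells == ""
  expect_equal(mean(masked),
               cfg$missing_fraction + cfg$inapplicable_fraction,
               tolerance = 0.05)
  expect_equal(mean(m1$characters$ordering == "ordered"), 0.25,
               tolerance = 0.12)
})

test_that("a planted expansion raises post-boundary disparity", {
  hits <- vapply(1:12, function(s) {
    cfg <- make_scenario("expansion", seed = s)
    sim <- simulate_tree(cfg)
    m <- simulate_characters(cfg, sim$true_tree)
    o <- pco(trim_incalculable(mord(m))$distances)
    rg <- sim$ranges[sim$ranges$taxon %in% o$taxa, ]
    pre <- rg$taxon[rg$fad > cfg$expansion_boundary]
    post <- rg$taxon[rg$lad <= cfg$expansion_boundary]
    sum_of_variances(o$scores[post, , drop = FALSE]) >
      sum_of_variances(o$scores[pre, , drop = FALSE])
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("scenario configs serialize losslessly and validate", {
  for (name in c("null", "burst", "expansion")) {
    cfg <- make_scenario(name, seed = 17)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_simulation_config(cfg, path)
    cfg2 <- read_simulation_config(path)
    expect_equal(unclass(cfg)[setdiff(names(cfg), "bins")],
                 unclass(cfg2)[setdiff(names(cfg2), "bins")])
    expect_equal(as.data.frame(cfg$bins), as.data.frame(cfg2$bins))
  }
  expect_error(make_scenario("upswing"), "arg")
  expect_error(simulation_config(birth = 0), "birth")
  expect_error(simulation_config(multipliers = c(1, -1)), "multipliers")
})

test_that("scenario files round trip through the pipeline readers", {
  cfg <- make_scenario("burst", seed = 23)
  dir <- withr::local_tempdir()
  files <- simulate_scenario_files(cfg, dir, n_cladograms = 3)
  m <- read_nexus(files$paths$matrix)
  expect_identical(unname(m$cells), unname(files$matrix$cells))
  trees <- ape::read.tree(files$paths$trees)
  expect_length(trees, 3)
  expect_setequal(trees[[1]]$tip.label, files$ranges$taxon)
  expect_setequal(trees[[2]]$tip.label, trees[[1]]$tip.label)
  rg <- read_ranges(files$paths$ranges)
  expect_equal(rg$fad, files$ranges$fad)
  truth <- jsonlite::read_json(files$paths$truth)
  expect_identical(unlist(truth$burst_bins), "150-100")
  expect_equal(truth$bin[["150-100"]], cfg$base_rate * 3)
})
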