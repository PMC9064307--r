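test_that("tip ages are drawn uniformly within stratigraphic ranges", {
  rg <- fossil_ranges(c("a", "b", "e"), fad = c(160, 120, 0),
                      lad = c(150, 120, 0))
  a1 <- sample_tip_ages(rg, seed = 4)
  expect_equal(unname(a1["b"]), 120)   # fad == lad is deterministic
  expect_equal(unname(a1["e"]), 0)     # extant fixed at 0
  expect_identical(a1, sample_tip_ages(rg, seed = 4))

  rg2 <- fossil_ranges("x", 160, 150)
  draws <- vapply(1:5000, function(i)
    sample_tip_ages(rg2, seed = i)[["x"]], 0)
  expect_equal(mean(draws), 155, tolerance = 0.002)  # analytic mean 155
  expect_true(all(draws >= 150 & draws <= 160))

  expect_error(fossil_ranges("a", 10, 20), "fad")
})

test_that("'equal' dating matches hand-worked fixtures", {
  # cherry with outgroup: zero-length cherry edge shares the 10 Myr root edge
  tr <- ape::read.tree(text = "((A,B),C);")
  dt <- date_equal(tr, c(A = 150, B = 160, C = 160), root_extension = 10)
  expect_equal(unname(node_ages(dt)[4:5]), c(170, 165))
  expect_true(all(dt$tree$edge.length > 0))

  # all tips at the same age: internal nodes evenly spaced along the extension
  tr2 <- ape::read.tree(text = "((A,B),(C,D));")
  dt2 <- date_equal(tr2, c(A = 100, B = 100, C = 100, D = 100),
                    root_extension = 12)
  expect_equal(unname(node_ages(dt2)[5:7]), c(112, 106, 106))
  tr3 <- ape::read.tree(text = "(((A,B),C),D);")
  dt3 <- date_equal(tr3, c(A = 100, B = 100, C = 100, D = 100),
                    root_extension = 12)
  expect_equal(unname(node_ages(dt3)[5:7]), c(112, 108, 104))

  # a tree whose supplied node ages already give positive durations is kept
  ages <- c(0, 0, 0, 0, 30, 20, 10)
  dt4 <- date_equal(tr3, node_ages = ages)
  expect_equal(node_ages(dt4), ages)

  expect_error(date_equal(tr, c(A = 150, B = 160, C = 160),
                          root_extension = 0), "root_extension")
})

test_that("minimum-branch-length dating enforces the floor", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  dt <- date_mbl(tr, c(A = 100, B = 100, C = 100, D = 100), mbl = 1)
  expect_equal(unname(node_ages(dt)[5:7]), c(103, 102, 101))

  # random trees: every duration >= mbl
  for (seed in 1:5) {
    set.seed(seed)
    rt <- ape::rtree(12)
    ages <- stats::setNames(runif(12, 0, 80), rt$tip.label)
    dtr <- date_mbl(rt, ages, mbl = 2)
    expect_true(all(dtr$tree$edge.length >= 2 - 1e-9))
    expect_true(all(node_ages(dtr) >=
                      morphoevo:::init_node_ages(rt, ages[rt$tip.label]) - 1e-9))
  }

  # tiny mbl reproduces the first-appearance initialisation where it already
  # gives positive durations (independent recursive max oracle)
  set.seed(42)
  rt <- ape::rtree(10)
  ages <- stats::setNames(sort(runif(10, 0, 100), decreasing = TRUE) +
                            10 * (10:1), rt$tip.label)
  dtr <- date_mbl(rt, ages, mbl = 1e-9)
  oracle <- morphoevo:::init_node_ages(rt, unname(ages[rt$tip.label]))
  n <- ape::Ntip(rt)
  expect_equal(node_ages(dtr)[-(1:n)], unname(oracle[-(1:n)]),
               tolerance = 1e-6)

  expect_error(date_mbl(rt, ages, mbl = 0), "mbl")
})

test_that("Hedman node ages match a direct quadrature oracle", {
  # one outgroup at 170, ingroup cherry with oldest tip 160
  tr <- ape::read.tree(text = "(OG,(A,B));")
  tips <- c(OG = 170, A = 160, B = 150)
  t0 <- 250
  dt <- date_hedman(tr, tips, outgroup_ages = 170, t0 = t0,
                    resolution = 2000)
  # root prior: uniform(170, t0)
  expect_equal(unname(node_ages(dt)[4]), (170 + t0) / 2, tolerance = 1e-3)
  # ingroup node: p(x) propto int_{max(x,170)}^{t0} 1/(t0-170) / (y-160) dy
  f <- function(x) vapply(x, function(xi)
    stats::integrate(function(y) 1 / (y - 160), max(xi, 170), t0)$value, 0)
  xs <- seq(160, t0, length.out = 4000)
  px <- f(xs)
  oracle_mean <- sum(xs * px) / sum(px)
  expect_equal(unname(node_ages(dt)[5]), oracle_mean,
               tolerance = 0.01 * oracle_mean)

  # bound property and monotone decrease root-to-tip
  expect_true(all(dt$tree$edge.length > 0))
  expect_true(all(node_ages(dt) < t0))
  expect_true(node_ages(dt)[5] > 160)

  # doubling the resolution moves posterior means by < 0.5%
  lo <- date_hedman(tr, tips, outgroup_ages = 170, t0 = t0, resolution = 500)
  hi <- date_hedman(tr, tips, outgroup_ages = 170, t0 = t0, resolution = 1000)
  rel <- abs(node_ages(lo)[4:5] - node_ages(hi)[4:5]) / node_ages(hi)[4:5]
  expect_true(all(rel < 0.005))

  expect_error(date_hedman(tr, tips, outgroup_ages = 170, t0 = 165,
                           resolution = 500), "t0")
  expect_error(date_hedman(tr, tips, t0 = 250, resolution = 50),
               "resolution")
})

test_that("successive outgroup constraints propagate through the recursion", {
  tr <- ape::read.tree(text = "(OG,(A,B));")
  tips <- c(OG = 170, A = 160, B = 150)
  # chain with two outgroups: x1 ~ U(200, 250), root | x1 ~ U(170, x1),
  # so E[root] = (170 + E[x1]) / 2 = 197.5
  two <- date_hedman(tr, tips, outgroup_ages = c(200, 170), t0 = 250,
                     resolution = 1500)
  expect_equal(unname(node_ages(two)[4]), 197.5, tolerance = 0.005)
  expect_true(all(two$tree$edge.length > 0))
})

test_that("time bins are contiguous, ordered and correctly classify ages", {
  b <- make_time_bins("equal", span = c(100, 0), width = 10)
  expect_equal(nrow(b), 10)
  expect_equal(b$older[1], 100)
  expect_true(all(b$younger[-nrow(b)] == b$older[-1]))

  s <- make_time_bins("stages", span = c(252, 0))
  expect_identical(s$name[1], "Induan")
  expect_true(all(diff(s$older) < 0))
  expect_true(all(abs(s$younger[-nrow(s)] - s$older[-1]) < 1e-9))
  expect_equal(s$younger[nrow(s)], 0)

  # truncation of the oldest bin for non-multiple spans
  b2 <- make_time_bins("equal", span = c(95, 0), width = 10)
  expect_equal(b2$older[1], 95)
  expect_equal(nrow(b2), 10)

  # boundary age belongs to the younger bin (point rule)
  rg <- fossil_ranges(c("edge", "ext"), fad = c(90, 0), lad = c(90, 0))
  mb <- taxa_in_bins(rg, b, rule = "point",
                     point_ages = c(edge = 90, ext = 0))
  expect_true("edge" %in% mb[["90-80"]])
  expect_false("edge" %in% mb[["100-90"]])
  expect_true("ext" %in% mb[["10-0"]])

  expect_error(make_time_bins("equal", span = c(0, 0), width = 10), "span")
})
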