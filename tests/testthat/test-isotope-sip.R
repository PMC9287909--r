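test_that("atom percent follows the VPDB map and is strictly increasing", {
  expect_equal(atom_percent(0), 100 * 0.0111802 / 1.0111802, tolerance = 1e-12)
  expect_equal(atom_percent(0), 1.10566, tolerance = 1e-5)
  expect_error(atom_percent(-1000), "-1000")
  deltas <- seq(-900, 5000, length.out = 50)
  expect_true(all(diff(atom_percent(deltas)) > 0))
  # symbolic re-derivation oracle at random points
  set.seed(14)
  d <- runif(20, -500, 2000)
  R <- 0.0111802 * (d / 1000 + 1)
  expect_equal(atom_percent(d), 100 * R / (1 + R), tolerance = 1e-12)
})

test_that("13C excess matches hand arithmetic, is linear in mass, and flags negatives", {
  atom_to_delta <- function(a) (a / (100 - a) / 0.0111802 - 1) * 1000
  dl <- atom_to_delta(1.30)
  dc <- atom_to_delta(1.08)
  ex <- c13_excess(10, 0.45, dl, dc)
  expect_equal(ex, (1.30 - 1.08) / 100 * 4.5, tolerance = 1e-9)
  expect_equal(ex, 0.0099, tolerance = 1e-6)
  expect_equal(c13_excess(20, 0.45, dl, dc), 2 * ex, tolerance = 1e-12)
  expect_equal(c13_excess(10, 0.45, dc, dc), 0)
  expect_warning(c13_excess(10, 0.45, dc, dl), "negative")
  expect_error(c13_excess(10, 0.45, dl, NA), "control")
})

test_that("allocation fractions sum to 100 and are scale invariant", {
  af <- allocation_fractions(c(shoot = 1, root = 1, soil = 2))
  expect_equal(unname(af), c(25, 25, 50))
  expect_equal(unname(allocation_fractions(c(a = 0, b = 3))), c(0, 100))
  set.seed(15)
  for (k in 1:5) {
    ex <- runif(3, 0.01, 2)
    expect_equal(sum(allocation_fractions(ex)), 100, tolerance = 1e-9)
    expect_equal(allocation_fractions(ex), allocation_fractions(ex * 7.3),
                 tolerance = 1e-12)
  }
  expect_error(allocation_fractions(c(a = 0, b = 0)), "undefined|not positive")
  expect_error(allocation_fractions(c(a = 1)), "2 compartments")
})

test_that("identical labeled and control SIP profiles yield no heavy window", {
  dens <- seq(1.66, 1.78, length.out = 15)
  prof <- data.frame(fraction = 1:15, density = dens,
                     copies = exp(-(dens - 1.7)^2 / (2 * 0.02^2)) * 1e6)
  hw <- heavy_fractions(prof, prof)
  expect_length(hw, 0)
})

test_that("ratio_min = 0 selects every fraction at or above the density floor", {
  dens <- seq(1.66, 1.78, length.out = 15)
  ctrl <- data.frame(fraction = 1:15, density = dens,
                     copies = exp(-(dens - 1.7)^2 / (2 * 0.02^2)) * 1e6)
  lab <- ctrl
  hw <- heavy_fractions(lab, ctrl, density_min = 1.72, ratio_min = 0)
  expect_equal(hw, which(dens >= 1.72), ignore_attr = TRUE)
})

test_that("heavy windows shrink as ratio_min grows", {
  gs <- gen_sip(shift = 0.03, seed = 19)
  rmins <- c(1.1, 1.5, 2.5, 5)
  wins <- lapply(rmins, function(r) {
    as.integer(heavy_fractions(gs$labeled, gs$control, ratio_min = r))
  })
  for (i in seq_len(length(wins) - 1)) {
    expect_true(all(wins[[i + 1]] %in% wins[[i]]))
  }
})

test_that("non-monotone density profiles are rejected", {
  bad <- data.frame(fraction = 1:3, density = c(1.7, 1.69, 1.71),
                    copies = c(1, 2, 3))
  good <- data.frame(fraction = 1:3, density = c(1.68, 1.70, 1.72),
                     copies = c(1, 2, 3))
  expect_error(heavy_fractions(bad, good), "monotone")
})

test_that("planted heavy windows are recovered exactly from shifted synthetic profiles", {
  for (s in 1:10) {
    gs <- gen_sip(shift = 0.03, seed = 700 + s)
    hw <- heavy_fractions(gs$labeled, gs$control)
    expect_equal(as.integer(hw), gs$truth_window)
    expect_gt(length(gs$truth_window), 0)
  }
})

test_that("isotope generator recovers planted allocations within tolerance", {
  gi <- gen_isotope(seed = 23)
  for (tr in unique(gi$pools$treatment)) {
    af <- allocation_fractions(gi$pools[gi$pools$treatment == tr, ])
    planted <- gi$truth[[tr]][gi$pools$compartment[gi$pools$treatment == tr]]
    expect_true(all(abs(unname(af) - unname(planted)) <= 5))
  }
  # zero enrichment with no noise leaves allocation undefined
  gi0 <- gen_isotope(allocations = list(P1 = c(shoot = 1 / 3, root = 1 / 3,
                                               soil = 1 / 3)),
                     total_excess = 0, noise_sd = 0, seed = 2)
  expect_error(suppressWarnings(allocation_fractions(gi0$pools)),
               "undefined|not positive")
})
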