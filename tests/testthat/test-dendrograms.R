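char_frame <- function(m) {
  # minimal characteristics table from raw element counts
  f <- molecular_characteristics(m)
  f$formula <- formula_id(f)
  f
}

test_that("UPGMA cophenetic heights match the brute-force agglomeration oracle", {
  for (s in 1:5) {
    set.seed(300 + s)
    x <- matrix(rnorm(12), 6)
    rownames(x) <- paste0("f", 1:6)
    tr <- upgma(dist(x))
    co <- cophenetic_distances(tr)
    oracle <- brute_upgma_cophenetic(dist(x))
    expect_equal(co[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-9)
  }
})

test_that("UPGMA trees are ultrametric with non-negative branch lengths", {
  set.seed(17)
  x <- matrix(rnorm(40), 20)
  rownames(x) <- paste0("f", 1:20)
  tr <- upgma(dist(x))
  expect_true(all(tr$edge.length >= -1e-12))
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  co <- cophenetic_distances(tr)
  # ultrametric three-point condition
  for (k in 1:30) {
    ijk <- sample(rownames(co), 3)
    expect_lte(co[ijk[1], ijk[3]],
               max(co[ijk[1], ijk[2]], co[ijk[2], ijk[3]]) + 1e-9)
  }
})

test_that("MCD standardizes characteristics, merges identical formulas at height zero, and ignores row order", {
  f <- char_frame(data.frame(C = c(6, 6, 20), H = c(12, 12, 40),
                             O = c(6, 6, 2)))
  f$formula <- c("fa", "fb", "fc")
  mcd <- suppressMessages(build_mcd(f))
  co <- cophenetic_distances(mcd)
  expect_equal(co["fa", "fb"], 0, tolerance = 1e-12)
  expect_gt(co["fa", "fc"], 0)

  f2 <- char_frame(data.frame(C = c(6, 10, 20, 8, 15),
                              H = c(12, 16, 40, 10, 24),
                              O = c(6, 4, 2, 7, 3)))
  mcd_a <- suppressMessages(build_mcd(f2))
  perm <- c(3, 1, 5, 2, 4)
  mcd_b <- suppressMessages(build_mcd(f2[perm, ]))
  ca <- cophenetic_distances(mcd_a)
  cb <- cophenetic_distances(mcd_b)[rownames(ca), colnames(ca)]
  expect_equal(ca, cb, tolerance = 1e-9)
})

test_that("MCD refuses fewer than three formulas", {
  f <- char_frame(data.frame(C = c(6, 7), H = c(12, 14), O = c(6, 6)))
  expect_error(suppressMessages(build_mcd(f)), "3 formulas")
})

test_that("TD uses shortest-path distances and drops non-largest components", {
  # path graph a-b-c plus an isolated pair d-e
  edges <- data.frame(from = c("a", "b", "d"), to = c("b", "c", "e"),
                      name = "H2O", observed_delta = 18.01,
                      error_da = 1e-5, stringsAsFactors = FALSE)
  net <- structure(list(nodes = c("a", "b", "c", "d", "e"), edges = edges),
                   class = "transformation_network")
  td <- suppressMessages(build_td(net))
  expect_setequal(td$tree$tip.label, c("a", "b", "c"))
  expect_setequal(td$record$dropped, c("d", "e"))
  co <- cophenetic_distances(td)
  # a,b and b,c merge at path length 1; a,c at the 1.5 average height
  expect_equal(co["a", "c"], max(co))
  # UPGMA on path lengths: d(a,c)=2 so a-c cophenetic > a-b
  expect_gt(co["a", "c"], min(co["a", "b"], co["b", "c"]))
})

test_that("TD on a complete graph handles tied merges deterministically", {
  nodes <- c("a", "b", "c", "d")
  pairs <- t(combn(nodes, 2))
  edges <- data.frame(from = pairs[, 1], to = pairs[, 2], name = "CH2",
                      observed_delta = 14.0157, error_da = 0,
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "transformation_network")
  td1 <- build_td(net)
  td2 <- build_td(net)
  expect_equal(ape::write.tree(td1$tree), ape::write.tree(td2$tree))
  co <- cophenetic_distances(td1)
  expect_equal(max(co), 1, tolerance = 1e-9)  # all pairwise path lengths 1
})

test_that("TD errors when the largest component is too small", {
  edges <- data.frame(from = "a", to = "b", name = "H2O",
                      observed_delta = 18.01, error_da = 0,
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = c("a", "b", "x"), edges = edges),
                   class = "transformation_network")
  expect_error(suppressMessages(build_td(net)), "fewer than 3")
})

test_that("TWCD with an all-constant profile reduces to the MCD topology", {
  f <- char_frame(data.frame(C = c(6, 10, 20, 8), H = c(12, 16, 40, 10),
                             O = c(6, 4, 2, 7)))
  prof <- matrix(0L, 4, 2, dimnames = list(f$formula, c("H2O", "CH2")))
  mcd <- suppressMessages(build_mcd(f))
  twcd <- suppressMessages(build_twcd(f, prof))
  expect_equal(cophenetic_distances(twcd)[f$formula, f$formula],
               cophenetic_distances(mcd)[f$formula, f$formula],
               tolerance = 1e-9)
})

test_that("TWCD separates identical chemistry with different transformation profiles", {
  f <- char_frame(data.frame(C = c(6, 6, 20, 8), H = c(12, 12, 40, 10),
                             O = c(6, 6, 2, 7)))
  f$formula <- c("fa", "fb", "fc", "fd")
  prof <- matrix(c(5L, 0L, 1L, 1L), 4, 1, dimnames = list(f$formula, "H2O"))
  twcd <- suppressMessages(build_twcd(f, prof))
  expect_gt(cophenetic_distances(twcd)["fa", "fb"], 0)
  expect_error(suppressMessages(
    build_twcd(f, matrix(0, 2, 1, dimnames = list(c("zz", "zy"), "H2O")))),
    "shared|intersection|no formulas")
})
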