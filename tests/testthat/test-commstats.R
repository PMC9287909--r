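test_that("diversity indices match closed forms", {
  comm <- cbind(S1 = c(1, 1, 1, 1), S2 = c(10, 0, 0, 0), S3 = c(3, 1, 0, 0))
  rownames(comm) <- paste0("f", 1:4)
  di <- diversity_indices(comm)
  expect_equal(di$shannon[di$sample == "S1"], log(4), tolerance = 1e-12)
  expect_equal(di$richness[di$sample == "S1"], 4)
  expect_equal(di$shannon[di$sample == "S2"], 0)
  expect_equal(di$richness[di$sample == "S2"], 1)
  expect_equal(di$shannon[di$sample == "S3"],
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(di$shannon[di$sample == "S3"], 0.5623, tolerance = 1e-4)
  expect_error(diversity_indices(cbind(S1 = c(0, 0))), "zero total")
})

test_that("Bray-Curtis matches hand values and vegan", {
  comm <- cbind(A = c(2, 2), B = c(2, 2), C = c(4, 0), D = c(0, 4),
                E = c(6, 2), F = c(2, 2))
  rownames(comm) <- c("f1", "f2")
  d <- as.matrix(bray_curtis(comm))
  expect_equal(d["A", "B"], 0)
  expect_equal(d["C", "D"], 1)
  expect_equal(d["E", "F"], 1 / 3, tolerance = 1e-12)
  skip_if_not_installed("vegan")
  set.seed(21)
  comm2 <- matrix(rpois(60, 4), 10, 6,
                  dimnames = list(paste0("f", 1:10), paste0("S", 1:6)))
  comm2[, colSums(comm2) == 0] <- 1
  ours <- as.matrix(bray_curtis(comm2))
  theirs <- as.matrix(vegan::vegdist(t(comm2), method = "bray"))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA of Euclidean distances reconstructs the configuration exactly", {
  set.seed(33)
  x <- matrix(rnorm(24), 8, 3)
  rownames(x) <- paste0("S", 1:8)
  d <- dist(x)
  pc <- pcoa(d)
  drec <- dist(pc$coordinates)
  expect_equal(as.numeric(drec), as.numeric(d), tolerance = 1e-8)
  # collinear 1-D points: one meaningful positive eigenvalue
  y <- matrix(c(0, 1, 3), 3, 1, dimnames = list(paste0("P", 1:3), NULL))
  pcy <- pcoa(dist(y))
  expect_equal(sum(pcy$eigenvalues > 1e-8), 1)
  expect_equal(as.numeric(dist(pcy$coordinates[, 1])), c(1, 3, 2),
               tolerance = 1e-8)
  # regular simplex: n-1 equal positive eigenvalues (centering of d^2/2)
  ds <- matrix(1, 5, 5); diag(ds) <- 0
  dimnames(ds) <- list(paste0("V", 1:5), paste0("V", 1:5))
  pcs <- pcoa(ds)
  ev <- pcs$eigenvalues[pcs$eigenvalues > 1e-10]
  expect_length(ev, 4)
  expect_equal(max(ev) - min(ev), 0, tolerance = 1e-10)
  # deterministic axis orientation: largest-magnitude loading positive
  expect_true(all(apply(pc$coordinates, 2,
                        function(a) a[which.max(abs(a))] > 0)))
})

test_that("one-way PERMANOVA reduces to the classical distance decomposition", {
  for (s in 1:4) {
    set.seed(500 + s)
    n <- 8
    groups <- rep(c("g1", "g2"), each = n / 2)
    x <- matrix(rnorm(n * 2), n)
    x[groups == "g2", ] <- x[groups == "g2", ] + 1
    D <- as.matrix(dist(x))
    dimnames(D) <- list(paste0("S", 1:n), paste0("S", 1:n))
    pv <- permanova_two_way(D, A = groups, n_perm = 99, seed = 7)
    expect_equal(pv$pseudo_F[1], brute_permanova_oneway_F(D, groups),
                 tolerance = 1e-10)
  }
})

test_that("two-way sequential PERMANOVA agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(61)
  n <- 12
  A <- rep(c("W6", "W10"), each = 6)
  B <- rep(rep(c("P1", "P5", "P10"), each = 2), 2)
  x <- matrix(rnorm(n * 3), n)
  x[B == "P1", ] <- x[B == "P1", ] + 0.8
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("S", 1:n), paste0("S", 1:n))
  pv <- permanova_two_way(D, A = A, B = B, n_perm = 99, seed = 5)
  ad <- vegan::adonis2(as.dist(D) ~ A + B,
                       data = data.frame(A = A, B = B), by = "terms",
                       permutations = 99)
  expect_equal(pv$ss[1:2], ad$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(pv$pseudo_F[1:2], ad$F[1:2], tolerance = 1e-10)
  expect_equal(pv$df[1:3], ad$Df[1:3])
})

test_that("duplicating every sample doubles all sums of squares in a balanced design", {
  set.seed(71)
  n <- 6
  a <- 2
  groups <- rep(c("a", "b"), each = 3)
  x <- matrix(rnorm(n * 2), n)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("S", 1:n), paste0("S", 1:n))
  pv1 <- permanova_two_way(D, A = groups, n_perm = 9, seed = 1)
  idx <- rep(seq_len(n), 2)
  D2 <- D[idx, idx]
  dimnames(D2) <- list(paste0("T", 1:(2 * n)), paste0("T", 1:(2 * n)))
  pv2 <- permanova_two_way(D2, A = rep(groups, 2), n_perm = 9, seed = 1)
  # each pairwise-squared-distance sum quadruples while n doubles, so
  # every SS term doubles and the SS ratio is exactly invariant
  expect_equal(pv2$ss, 2 * pv1$ss, tolerance = 1e-10)
  expect_equal(pv2$ss[1] / pv2$ss[2], pv1$ss[1] / pv1$ss[2],
               tolerance = 1e-10)
  # the pseudo-F changes only through the residual df
  expect_equal(pv2$pseudo_F[1],
               pv1$pseudo_F[1] * (2 * n - a) / (n - a), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the aliased factor named", {
  D <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(D) <- list(paste0("S", 1:6), paste0("S", 1:6))
  A <- rep(c("x", "y"), each = 3)
  expect_error(permanova_two_way(D, A = A, B = A, n_perm = 9, seed = 1),
               "aliased|cell")
})

test_that("Mantel statistic agrees with vegan and honours the add-one rule", {
  skip_if_not_installed("vegan")
  set.seed(81)
  x <- matrix(rnorm(30), 10)
  y <- x + matrix(rnorm(30, sd = 0.5), 10)
  d1 <- as.matrix(dist(x)); d2 <- as.matrix(dist(y))
  dimnames(d1) <- dimnames(d2) <- list(paste0("S", 1:10), paste0("S", 1:10))
  mt <- mantel(d1, d2, n_perm = 199, seed = 4)
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 199)
  expect_equal(mt$statistic, unname(vg$statistic), tolerance = 1e-12)
  expect_gt(mt$p_value, 0)
  expect_lte(mt$p_value, 1)
  # p can never be zero by construction
  self <- mantel(d1, d1, n_perm = 99, seed = 2)
  expect_gte(self$p_value, 1 / 100)
  # spearman option
  ms <- mantel(d1, d2, n_perm = 99, seed = 4, method = "spearman")
  vs <- vegan::mantel(as.dist(d1), as.dist(d2), method = "spearman",
                      permutations = 99)
  expect_equal(ms$statistic, unname(vs$statistic), tolerance = 1e-12)
  expect_error(mantel(d1[1:3, 1:3], d2[1:3, 1:3], n_perm = 99, seed = 1),
               "at least 4")
})

test_that("Mantel excludes NaN pairs listwise", {
  set.seed(91)
  z1 <- matrix(rnorm(64), 8); z1 <- z1 + t(z1); diag(z1) <- NaN
  z2 <- z1 + matrix(rnorm(64, sd = 0.1), 8)
  z2 <- (z2 + t(z2)) / 2; diag(z2) <- NaN
  z1[1, 2] <- z1[2, 1] <- NaN
  mt <- mantel(z1, z2, n_perm = 99, seed = 1)
  expect_equal(mt$n_pairs_used, choose(8, 2) - 1)
  expect_gt(mt$statistic, 0.9)
})

test_that("exact Wilcoxon enrichment reproduces enumeration and base R", {
  comm <- rbind(f1 = c(1, 2, 3, 4, 5, 6, 7, 8),
                f2 = c(5, 6, 7, 8, 1, 2, 3, 4),
                f3 = c(2, 2, 2, 2, 2, 2, 2, 2))
  colnames(comm) <- paste0("S", 1:8)
  groups <- rep(c("P1", "P5"), each = 4)
  res <- wilcoxon_enrichment(comm, groups, alpha = 0.25)
  expect_equal(res$p_raw[res$feature == "f1"], 2 / 70, tolerance = 1e-12)
  expect_equal(res$p_raw[res$feature == "f1"], 0.0286, tolerance = 1e-3)
  expect_equal(res$p_raw[res$feature == "f3"], 1)
  # agrees with base wilcox.test exact two-sided p in the no-tie case
  wb <- wilcox.test(comm["f1", 1:4], comm["f1", 5:8], exact = TRUE)$p.value
  expect_equal(res$p_raw[res$feature == "f1"], wb, tolerance = 1e-12)
  # enrichment labels point at the larger-mean group
  expect_equal(res$enriched_in[res$feature == "f1"], "P5")
  expect_equal(res$enriched_in[res$feature == "f2"], "P1")
})

test_that("BH adjustment is monotone, bounded and matches the hand step-up", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  comm <- matrix(rpois(80, 3) + 1, 10, 8,
                 dimnames = list(paste0("f", 1:10), paste0("S", 1:8)))
  res <- wilcoxon_enrichment(comm, rep(c("a", "b"), each = 4))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-12))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("all-zero features are dropped and group sizes validated", {
  comm <- rbind(f1 = c(1, 2, 3, 4, 3, 2), f2 = rep(0, 6))
  colnames(comm) <- paste0("S", 1:6)
  expect_message(res <- wilcoxon_enrichment(comm, rep(c("a", "b"), each = 3)),
                 "dropped")
  expect_equal(res$feature, "f1")
  expect_error(wilcoxon_enrichment(comm[, 1:4, drop = FALSE],
                                   rep(c("a", "b"), each = 2)),
               "at least 3")
})
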