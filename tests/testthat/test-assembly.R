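test_that("bMNTD matches hand evaluation on a 4-tip balanced tree", {
  tree <- ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
  d <- ape::cophenetic.phylo(tree)
  comm <- matrix(c(1, 1, 0, 0,
                   0, 0, 1, 1), 4, 2,
                 dimnames = list(paste0("t", 1:4), c("A", "B")))
  b <- bmntd(comm, d, mode = "presence")
  # every cross nearest-taxon distance is the root-spanning 4
  expect_equal(b["A", "B"], 4)
  expect_equal(b["A", "A"], 0)
  # identical single-feature communities
  comm2 <- matrix(c(1, 1), 1, 2, dimnames = list("t1", c("X", "Y")))
  expect_equal(bmntd(comm2, d)["X", "Y"], 0)
  # abundance mode with all mass on one taxon reduces to that patristic distance
  comm3 <- matrix(c(9, 0, 0, 0,
                    0, 0, 0, 5), 4, 2,
                  dimnames = list(paste0("t", 1:4), c("A", "B")))
  expect_equal(bmntd(comm3, d, mode = "abundance")["A", "B"], d["t1", "t4"])
})

test_that("bMNTD agrees with the brute-force definition on random instances", {
  for (s in 1:6) {
    set.seed(400 + s)
    nf <- sample(5:20, 1)
    ns <- sample(3:6, 1)
    tree <- ape::rphylo(nf, 1, 0)
    d <- ape::cophenetic.phylo(tree)
    comm <- matrix(rpois(nf * ns, 2), nf, ns,
                   dimnames = list(tree$tip.label, paste0("S", 1:ns)))
    comm[, colSums(comm) == 0] <- 1
    for (mode in c("abundance", "presence")) {
      expect_equal(bmntd(comm, d, mode = mode), brute_bmntd(comm, d, mode),
                   tolerance = 1e-12)
    }
  }
})

test_that("abundance-weighted bMNTD agrees with picante::comdistnt", {
  skip_if_not_installed("picante")
  set.seed(88)
  tree <- ape::rphylo(15, 1, 0)
  d <- ape::cophenetic.phylo(tree)
  comm <- matrix(rpois(15 * 4, 3), 15, 4,
                 dimnames = list(tree$tip.label, paste0("S", 1:4)))
  comm[, colSums(comm) == 0] <- 1
  ours <- bmntd(comm, d, mode = "abundance")
  theirs <- as.matrix(picante::comdistnt(t(comm), d, abundance.weighted = TRUE))
  expect_equal(ours[rownames(theirs), colnames(theirs)], theirs,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a star tree gives a degenerate null flagged as NaN", {
  tree <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1,t5:1);")
  comm <- matrix(c(1, 1, 0, 0, 0,
                   0, 0, 1, 1, 0,
                   1, 0, 0, 1, 1), 5, 3,
                 dimnames = list(paste0("t", 1:5), c("A", "B", "C")))
  expect_warning(bn <- beta_nti(comm, tree, n_null = 99, seed = 1,
                                mode = "presence"),
                 "degenerate")
  expect_true(all(is.nan(bn$z[upper.tri(bn$z)])))
})

test_that("betaNTI is invariant to consistent feature relabeling", {
  gc_ <- gen_community(n_tips = 30, treatments = rep("M", 5), mode = "drift",
                       depth = 500, seed = 6)
  bn1 <- beta_nti(gc_$counts, gc_$tree, n_null = 99, seed = 42)
  relabel <- setNames(paste0("x", seq_len(30)), gc_$tree$tip.label)
  counts2 <- gc_$counts
  rownames(counts2) <- relabel[rownames(counts2)]
  tree2 <- gc_$tree
  tree2$tip.label <- relabel[tree2$tip.label]
  bn2 <- beta_nti(counts2, tree2, n_null = 99, seed = 42)
  expect_equal(bn1$z, bn2$z, tolerance = 1e-12)
})

test_that("seed and n_null are mandatory and validated", {
  gc_ <- gen_community(n_tips = 25, treatments = rep("M", 4), mode = "drift",
                       depth = 200, seed = 2)
  expect_error(beta_nti(gc_$counts, gc_$tree, n_null = 99), "seed")
  expect_error(beta_nti(gc_$counts, gc_$tree, n_null = 50, seed = 1),
               "at least 99")
})

test_that("assembly classification splits pairs at the two-sigma threshold", {
  z <- matrix(NaN, 3, 3)
  z[1, 2] <- z[2, 1] <- 3.1
  z[1, 3] <- z[3, 1] <- -2.6
  z[2, 3] <- z[3, 2] <- 0.4
  cl <- classify_assembly(z)
  expect_equal(unname(cl$fractions),
               c(1 / 3, 1 / 3, 1 / 3))
  z0 <- matrix(0, 3, 3); diag(z0) <- NaN
  expect_equal(unname(classify_assembly(z0)$fractions["stochastic"] -
                        classify_assembly(z0)$fractions["stochastic"]), 0)
  expect_equal(unname(classify_assembly(z0)$fractions[["stochastic"]]), 1)
  # threshold 0: only exact zeros count as stochastic
  cl0 <- classify_assembly(z, threshold = 0)
  expect_equal(unname(cl0$counts[["stochastic"]]), 0)
  cl00 <- classify_assembly(z0, threshold = 0)
  expect_equal(unname(cl00$fractions[["stochastic"]]), 1)
})

test_that("betaNTI coupling recovers perfect and inverted correlation", {
  set.seed(9)
  z <- matrix(rnorm(36), 6); z <- z + t(z); diag(z) <- NaN
  dimnames(z) <- list(paste0("S", 1:6), paste0("S", 1:6))
  mt <- betanti_coupling(z, z, n_perm = 99, seed = 3)
  expect_equal(mt$statistic, 1, tolerance = 1e-12)
  expect_lte(mt$p_value, 0.2)
  mt2 <- betanti_coupling(z, -z, n_perm = 99, seed = 3)
  expect_equal(mt2$statistic, -1, tolerance = 1e-12)
  zbad <- z[1:5, 1:5]
  expect_error(betanti_coupling(z, zbad, n_perm = 99, seed = 1),
               "labels|dimension")
})

test_that("raising the null count shrinks the Monte-Carlo spread of a betaNTI cell", {
  gc_ <- gen_community(n_tips = 30, treatments = rep(c("A", "B"), c(3, 3)),
                       mode = "selection", depth = 500, seed = 10)
  cell <- function(n_null, seed) {
    beta_nti(gc_$counts, gc_$tree, n_null = n_null, seed = seed)$z[1, 2]
  }
  z99 <- vapply(1:8, function(s) cell(99, 1000 + s), numeric(1))
  z999 <- vapply(1:8, function(s) cell(999, 2000 + s), numeric(1))
  expect_lt(sd(z999), sd(z99))
})
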