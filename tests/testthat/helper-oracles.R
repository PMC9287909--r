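# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. These deliberately share no code
# with the implementations they verify.

# Sorensen distance from explicit set operations
brute_sorensen <- function(inc) {
  n <- nrow(inc)
  d <- matrix(0, n, n, dimnames = list(rownames(inc), rownames(inc)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A <- which(inc[i, ] > 0)
      B <- which(inc[j, ] > 0)
      d[i, j] <- 1 - 2 * length(intersect(A, B)) / (length(A) + length(B))
    }
  }
  d
}

# bMNTD by direct evaluation of the definition
brute_bmntd <- function(comm, d, mode = "abundance") {
  S <- ncol(comm)
  out <- matrix(0, S, S, dimnames = list(colnames(comm), colnames(comm)))
  for (k in seq_len(S)) {
    for (l in seq_len(S)) {
      ik <- which(comm[, k] > 0)
      il <- which(comm[, l] > 0)
      fk <- if (mode == "abundance") comm[ik, k] / sum(comm[, k]) else
        rep(1 / length(ik), length(ik))
      fl <- if (mode == "abundance") comm[il, l] / sum(comm[, l]) else
        rep(1 / length(il), length(il))
      t1 <- sum(fk * vapply(ik, function(i) min(d[i, il]), numeric(1)))
      t2 <- sum(fl * vapply(il, function(j) min(d[j, ik]), numeric(1)))
      out[k, l] <- 0.5 * (t1 + t2)
    }
  }
  out
}

# UPGMA cophenetic heights by direct pairwise-average agglomeration
# (valid because UPGMA inter-cluster distance equals the unweighted
# mean of the original cross-pair distances)
brute_upgma_cophenetic <- function(d) {
  m <- as.matrix(d)
  labs <- rownames(m)
  clusters <- as.list(seq_len(nrow(m)))
  coph <- matrix(0, nrow(m), nrow(m), dimnames = list(labs, labs))
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        avg <- mean(m[clusters[[a]], clusters[[b]]])
        if (avg < bestd) { bestd <- avg; best <- c(a, b) }
      }
    }
    for (i in clusters[[best[1]]]) for (j in clusters[[best[2]]]) {
      coph[i, j] <- coph[j, i] <- bestd
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# one-way PERMANOVA pseudo-F from the pairwise-distance SS identity
brute_permanova_oneway_F <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- factor(groups)
  ss_from <- function(idx) {
    sub <- D[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_total <- ss_from(seq_len(n))
  ss_within <- sum(vapply(levels(groups), function(g) {
    ss_from(which(groups == g))
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  a <- nlevels(groups)
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# transformation matching by exhaustive pair x reference scan
brute_transformations <- function(masses, reference, tolerance) {
  n <- length(masses)
  hits <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dm <- abs(masses[i] - masses[j])
      for (r in seq_len(nrow(reference))) {
        if (abs(dm - reference$delta_mass[r]) <= tolerance) hits <- hits + 1
      }
    }
  }
  hits
}

# small random incidence matrix with guaranteed non-empty rows
random_incidence <- function(n_samples, n_features, p = 0.4, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_samples * n_features, 1, p), n_samples)
    if (all(rowSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("S", seq_len(n_samples)),
                      paste0("f", seq_len(n_features)))
  m
}
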