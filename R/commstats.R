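# Community-level statistics implemented from first principles:
# diversity indices, Bray-Curtis, PCoA, two-way PERMANOVA, Mantel, and
# exact two-tailed Wilcoxon enrichment with BH correction. Established
# implementations (vegan, base wilcox.test) serve only as independent
# cross-checks in the test suite.

#' Alpha diversity: Shannon index and richness
#'
#' Richness = number of features with count > 0; Shannon =
#' -sum p_i ln p_i over present features (natural log).
#'
#' @param community features x samples matrix of non-negative counts.
#' @param sample optional sample id(s); default all.
#' @return data frame with columns sample, shannon, richness.
#' @export
diversity_indices <- function(community, sample = NULL) {
  comm <- as.matrix(community)
  if (any(comm < 0)) stop("counts must be non-negative")
  if (is.null(sample)) sample <- colnames(comm)
  if (!all(sample %in% colnames(comm))) {
    stop("unknown sample(s): ",
         paste(setdiff(sample, colnames(comm)), collapse = ", "))
  }
  res <- lapply(sample, function(s) {
    x <- comm[, s]
    if (sum(x) == 0) stop("sample ", s, " has zero total count")
    p <- x[x > 0] / sum(x)
    data.frame(sample = s, shannon = -sum(p * log(p)),
               richness = sum(x > 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(k,l) = sum |x_ik - x_il| / sum (x_ik + x_il) over features.
#'
#' @param community features x samples matrix of non-negative counts.
#' @return \code{dist} object over samples.
#' @export
bray_curtis <- function(community) {
  comm <- as.matrix(community)
  if (ncol(comm) < 2) stop("need at least 2 samples")
  if (any(comm < 0)) stop("counts must be non-negative")
  if (any(colSums(comm) == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(comm)[colSums(comm) == 0], collapse = ", "))
  }
  S <- ncol(comm)
  d <- matrix(0, S, S, dimnames = list(colnames(comm), colnames(comm)))
  for (k in seq_len(S - 1)) {
    for (l in (k + 1):S) {
      d[k, l] <- d[l, k] <-
        sum(abs(comm[, k] - comm[, l])) / sum(comm[, k] + comm[, l])
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering G = -1/2 J D^2 J followed by an
#' eigendecomposition; coordinates are eigenvectors scaled by the
#' square root of their (positive) eigenvalues. Axes with negative
#' eigenvalues are omitted but the eigenvalues are reported. Each
#' axis's sign is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param d \code{dist} or square symmetric matrix.
#' @return list with \code{coordinates} (samples x positive axes),
#'   \code{eigenvalues} (all), \code{prop_explained} (over positive
#'   eigenvalues).
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D * D) %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  for (a in seq_len(ncol(coords))) {
    imax <- which.max(abs(coords[, a]))
    if (coords[imax, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = e$values,
       prop_explained = e$values[pos] / sum(e$values[pos]))
}

gower_center <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D * D) %*% J
  (G + t(G)) / 2
}

hat_matrix <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) stop("rank-deficient design")
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

permanova_ss <- function(G, HA, HAB, H1) {
  n <- nrow(G)
  c(ss_a = sum(diag((HA - H1) %*% G)),
    ss_b = sum(diag((HAB - HA) %*% G)),
    ss_res = sum(diag((diag(n) - HAB) %*% G)),
    ss_total = sum(diag((diag(n) - H1) %*% G)))
}

#' Two-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA with two crossed factors and
#' sequential (Type-I-like) sums of squares, factor A fitted before B,
#' no interaction term. Sums of squares come from the Gower-centered
#' inner-product matrix with projection (hat) matrices; pseudo-F uses
#' residual df N - a - b + 1. p-values are obtained by free permutation
#' of the rows/columns of the distance matrix, with the add-one rule.
#' With \code{B = NULL} this reduces to one-way PERMANOVA
#' (residual df N - a).
#'
#' @param d \code{dist} or labelled square matrix.
#' @param A,B factors over the samples, in the order of \code{d}'s
#'   labels. \code{B} may be NULL.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed (mandatory).
#' @return data frame of class \code{permanova} with one row per
#'   factor: df, ss, pseudo_F, p_value, plus residual/total rows;
#'   attributes n_perm and seed.
#' @export
permanova_two_way <- function(d, A, B = NULL, n_perm = 999, seed) {
  if (missing(seed)) stop("seed is mandatory for the permutation test")
  D <- as.matrix(d)
  n <- nrow(D)
  A <- factor(A)
  if (length(A) != n) stop("factor A length must match samples")
  one_way <- is.null(B)
  if (!one_way) {
    B <- factor(B)
    if (length(B) != n) stop("factor B length must match samples")
    tab <- table(A, B)
    if (any(tab == 0)) stop("every (A,B) cell needs at least one sample")
  }
  H1 <- matrix(1 / n, n, n)
  XA <- stats::model.matrix(~A)
  HA <- tryCatch(hat_matrix(XA),
                 error = function(e) stop("factor A is aliased (rank-deficient design)"))
  if (one_way) {
    HAB <- HA
    df <- c(a = nlevels(A) - 1)
    df_res <- n - nlevels(A)
  } else {
    XAB <- stats::model.matrix(~ A + B)
    HAB <- tryCatch(hat_matrix(XAB),
                    error = function(e) stop("factor B is aliased (rank-deficient design)"))
    df <- c(a = nlevels(A) - 1, b = nlevels(B) - 1)
    df_res <- n - nlevels(A) - nlevels(B) + 1
  }
  if (df_res <= 0) stop("no residual degrees of freedom")
  fstats <- function(D) {
    ss <- permanova_ss(gower_center(D), HA, HAB, H1)
    ms_res <- ss[["ss_res"]] / df_res
    f <- c((ss[["ss_a"]] / df[["a"]]) / ms_res)
    if (!one_way) f <- c(f, (ss[["ss_b"]] / df[["b"]]) / ms_res)
    list(f = f, ss = ss)
  }
  obs <- fstats(D)
  set.seed(seed)
  exceed <- numeric(length(obs$f))
  for (r in seq_len(n_perm)) {
    p <- sample.int(n)
    fp <- fstats(D[p, p])$f
    exceed <- exceed + (fp >= obs$f)
  }
  pvals <- (exceed + 1) / (n_perm + 1)
  labs <- if (one_way) "A" else c("A", "B")
  out <- data.frame(
    term = c(labs, "residual", "total"),
    df = c(unname(df), df_res, n - 1),
    ss = c(obs$ss[["ss_a"]],
           if (!one_way) obs$ss[["ss_b"]],
           obs$ss[["ss_res"]], obs$ss[["ss_total"]]),
    pseudo_F = c(obs$f, NA, NA),
    p_value = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova", class(out))
  out
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance (or betaNTI)
#' matrices over the same samples; entries that are NA/NaN in either
#' matrix are excluded listwise. Significance by simultaneous
#' row/column permutation of the second matrix; one-sided
#' p = (# permuted r >= observed + 1) / (n_perm + 1).
#'
#' @param d1,d2 \code{dist} objects or square matrices with matching
#'   labels and order.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed (mandatory).
#' @param method pearson (default) or spearman.
#' @return list of class \code{mantel_test}: statistic (r), p_value,
#'   n_perm, seed, method, n_pairs_used.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed,
                   method = c("pearson", "spearman")) {
  if (missing(seed)) stop("seed is mandatory for the permutation test")
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have the same dimension")
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 samples for a meaningful permutation test")
  ut <- upper.tri(m1)
  corfun <- function(a, b) {
    ok <- !is.na(a) & !is.nan(a) & !is.na(b) & !is.nan(b)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs")
    if (method == "spearman") {
      a <- rank(a[ok]); b <- rank(b[ok])
    } else {
      a <- a[ok]; b <- b[ok]
    }
    stats::cor(a, b)
  }
  r_obs <- corfun(m1[ut], m2[ut])
  set.seed(seed)
  exceed <- 0
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    exceed <- exceed + (corfun(m1[ut], m2[p, p][ut]) >= r_obs)
  }
  structure(list(statistic = r_obs, p_value = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, method = method,
                 n_pairs_used = sum(!is.na(m1[ut]) & !is.nan(m1[ut]) &
                                      !is.na(m2[ut]) & !is.nan(m2[ut]))),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel r =", round(x$statistic, 4), ", p =", x$p_value,
      "(", x$method, ",", x$n_perm, "permutations, seed", x$seed, ")\n")
  invisible(x)
}

# exact two-sided rank-sum p by full enumeration of group-1 positions
rank_sum_exact_p <- function(r, n1) {
  n <- length(r)
  w_obs <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# tie-corrected normal approximation, two-sided
rank_sum_normal_p <- function(r, n1) {
  n <- length(r)
  n2 <- n - n1
  w <- sum(r[seq_len(n1)])
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - n1 * (n + 1) / 2) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' Two-tailed Wilcoxon rank-sum enrichment with FDR
#'
#' Feature-wise two-tailed Wilcoxon (Mann-Whitney) rank-sum tests
#' between two sample groups. The p-value is exact (full enumeration of
#' rank-assignments, valid under ties) when both groups have <= 10
#' samples, otherwise a tie-corrected normal approximation. Raw
#' p-values are Benjamini-Hochberg adjusted across tested features;
#' each significant feature is labelled with the group of greater mean
#' relative abundance. Features that are all-zero across both groups
#' are dropped (with a message).
#'
#' @param community features x samples matrix (counts or relative
#'   abundances; KO tables work the same way).
#' @param groups factor/character of length n samples with exactly two
#'   levels, each with >= 3 samples.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data frame: feature, mean_1, mean_2 (group mean relative
#'   abundances), w_statistic, p_raw, p_adjusted, enriched_in (NA where
#'   p_adjusted > alpha).
#' @export
wilcoxon_enrichment <- function(community, groups, alpha = 0.05) {
  comm <- as.matrix(community)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (length(groups) != ncol(comm)) stop("groups length must match samples")
  if (any(table(groups) < 3)) stop("both groups need at least 3 samples")
  keep <- rowSums(comm) > 0
  if (any(!keep)) {
    message(sum(!keep), " all-zero feature(s) dropped")
    comm <- comm[keep, , drop = FALSE]
  }
  rel <- sweep(comm, 2, colSums(comm), "/")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  i1 <- which(groups == g1); i2 <- which(groups == g2)
  exact <- length(i1) <= 10 && length(i2) <= 10
  res <- lapply(seq_len(nrow(comm)), function(f) {
    x <- comm[f, c(i1, i2)]
    r <- rank(x)
    p <- if (exact) rank_sum_exact_p(r, length(i1)) else
      rank_sum_normal_p(r, length(i1))
    data.frame(feature = rownames(comm)[f],
               mean_1 = mean(rel[f, i1]), mean_2 = mean(rel[f, i2]),
               w_statistic = sum(r[seq_along(i1)]),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$enriched_in <- ifelse(out$p_adjusted <= alpha,
                            ifelse(out$mean_1 > out$mean_2, g1, g2),
                            NA_character_)
  names(out)[2:3] <- c(paste0("mean_", g1), paste0("mean_", g2))
  out
}

#' Convenience wrappers: Spearman correlation and two-way ANOVA
#'
#' Thin wrappers with no bespoke logic, provided for the routine scalar
#' analyses (correlations between diversity measures, two-way ANOVA on
#' chemodiversity or allocation).
#'
#' @param x,y numeric vectors.
#' @return \code{spearman_cor}: list with estimate and p.value from
#'   [stats::cor.test()].
#' @export
spearman_cor <- function(x, y) {
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}

#' @rdname spearman_cor
#' @param response numeric response vector.
#' @param A,B factors.
#' @return \code{two_way_anova}: the [stats::anova()] table of
#'   \code{aov(response ~ A + B)}.
#' @export
two_way_anova <- function(response, A, B) {
  stats::anova(stats::aov(response ~ factor(A) + factor(B)))
}
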