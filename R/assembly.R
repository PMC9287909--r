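# Phylogeny- / dendrogram-informed null-model inference of community
# assembly. The same machinery serves microbial communities on a 16S
# phylogeny (abundance-weighted) and metabolite incidence matrices on
# the MCD/TD/TWCD relational dendrograms (presence-weighted): betaMNTD
# turnover, the betaNTI z-score against a taxa-shuffle null, process
# classification, and Mantel coupling of metabolite and microbial
# betaNTI matrices.

# fast per-column minima
col_mins <- function(m) {
  m[cbind(max.col(-t(m), ties.method = "first"), seq_len(ncol(m)))]
}

community_weights <- function(comm, mode) {
  totals <- colSums(comm)
  if (any(totals == 0)) {
    stop("sample(s) with zero features: ",
         paste(colnames(comm)[totals == 0], collapse = ", "))
  }
  if (mode == "presence") {
    pres <- (comm > 0) * 1
    sweep(pres, 2, colSums(pres), "/")
  } else {
    sweep(comm, 2, totals, "/")
  }
}

# all-pairs bMNTD given weights (features x samples) and tip distances
bmntd_all <- function(W, d) {
  S <- ncol(W)
  M <- matrix(0, nrow(W), S)
  for (l in seq_len(S)) {
    idx <- which(W[, l] > 0)
    M[, l] <- col_mins(d[idx, , drop = FALSE])
  }
  B <- crossprod(W, M)          # B[k, l] = sum_i f_ik * min_j d_ij
  0.5 * (B + t(B))
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' For a pair of communities k and l,
#' \deqn{bMNTD(k,l) = 0.5 [ \sum_{i \in k} f_{ik} \min_{j \in l} d_{ij}
#'   + \sum_{j \in l} f_{jl} \min_{i \in k} d_{ij} ]}
#' where d are cophenetic/patristic tip distances and f are relative
#' abundances (\code{mode = "abundance"}) or 1/richness for present
#' features (\code{mode = "presence"}).
#'
#' @param community features x samples matrix (counts or 0/1).
#' @param tip_distances labelled square matrix of tip distances
#'   covering all community features (e.g. [cophenetic_distances()]).
#' @param mode weighting mode.
#' @return \code{dist}-like square matrix of bMNTD values over samples.
#' @export
bmntd <- function(community, tip_distances,
                  mode = c("abundance", "presence")) {
  mode <- match.arg(mode)
  comm <- reconcile_community(community, tip_distances)
  d <- tip_distances[rownames(comm), rownames(comm), drop = FALSE]
  W <- community_weights(comm, mode)
  b <- bmntd_all(W, d)
  dimnames(b) <- list(colnames(comm), colnames(comm))
  b
}

reconcile_community <- function(community, tip_distances) {
  comm <- as.matrix(community)
  if (is.null(rownames(comm))) stop("community needs feature row names")
  miss <- setdiff(rownames(comm), rownames(tip_distances))
  if (length(miss)) {
    stop("feature(s) missing from tip distances: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  if (any(comm < 0)) stop("negative values in community matrix")
  comm
}

#' betaNTI: z-score of bMNTD against the taxa-shuffle null
#'
#' For every sample pair, betaNTI = (bMNTD_obs - mean(bMNTD_null)) /
#' sd(bMNTD_null), where each null replicate shuffles the tip labels of
#' the distance matrix uniformly at random (the standard "taxa
#' shuffle", preserving per-sample richness and abundances) and
#' recomputes bMNTD. sd is the sample standard deviation over
#' replicates; a degenerate null (sd = 0) yields NaN with a warning.
#'
#' |betaNTI| > 2 is conventionally read as deterministic selection
#' (positive: variable selection, negative: homogeneous selection),
#' |betaNTI| <= 2 as stochastic assembly.
#'
#' @param community features x samples matrix; a \code{metabolome}
#'   object may be passed instead (transposed to formulas x samples and
#'   forced to presence mode).
#' @param tree ape \code{phylo}, \code{relational_dendrogram}, or a
#'   labelled square tip-distance matrix.
#' @param n_null null replicates (>= 99; default 999).
#' @param seed RNG seed (mandatory).
#' @param mode abundance (default, microbial) or presence (metabolite)
#'   weighting.
#' @return object of class \code{betanti}: list with \code{z} (samples
#'   x samples, NaN diagonal), \code{obs}, \code{null_mean},
#'   \code{null_sd}, \code{n_null}, \code{seed}, \code{tree_kind},
#'   \code{mode}.
#' @export
beta_nti <- function(community, tree, n_null = 999, seed,
                     mode = c("abundance", "presence")) {
  if (missing(seed)) stop("seed is mandatory for the null model")
  if (n_null < 99) stop("n_null must be at least 99")
  tree_kind <- "phylogeny"
  if (inherits(community, "metabolome")) {
    community <- t(community$incidence)
    mode <- "presence"
  } else {
    mode <- match.arg(mode)
  }
  if (inherits(tree, "relational_dendrogram")) {
    tree_kind <- tree$kind
    d <- cophenetic_distances(tree)
  } else if (inherits(tree, "phylo")) {
    d <- ape::cophenetic.phylo(tree)
  } else {
    d <- as.matrix(tree)
    tree_kind <- "distance matrix"
  }
  comm <- as.matrix(community)
  # restrict to features present in the tree distance table; samples
  # left with no feature (e.g. none of their formulas sit in the TD
  # dendrogram's connected component) are excluded, not an error
  keep <- rownames(comm) %in% rownames(d)
  if (!all(keep)) {
    warning(sum(!keep), " feature(s) not in the tree were dropped")
    comm <- comm[keep, , drop = FALSE]
  }
  empty <- colSums(comm) == 0
  if (any(empty)) {
    warning(sum(empty), " sample(s) with no features on the tree were dropped")
    comm <- comm[, !empty, drop = FALSE]
  }
  comm <- reconcile_community(comm, d)
  if (ncol(comm) < 2) stop("need at least 2 samples")
  d <- d[rownames(comm), rownames(comm), drop = FALSE]
  W <- community_weights(comm, mode)
  obs <- bmntd_all(W, d)

  nf <- nrow(comm)
  set.seed(seed)
  S <- ncol(comm)
  sum1 <- matrix(0, S, S)
  sum2 <- matrix(0, S, S)
  for (r in seq_len(n_null)) {
    p <- sample.int(nf)
    b <- bmntd_all(W, d[p, p])
    sum1 <- sum1 + b
    sum2 <- sum2 + b * b
  }
  mu <- sum1 / n_null
  varr <- (sum2 - n_null * mu * mu) / (n_null - 1)
  varr[varr < 0] <- 0
  sdv <- sqrt(varr)
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NaN
  diag(z) <- NaN
  if (any(is.nan(z[upper.tri(z)]))) {
    warning(sum(is.nan(z[upper.tri(z)])),
            " pair(s) had a degenerate null (sd = 0); set to NaN")
  }
  dimnames(z) <- dimnames(obs) <- dimnames(mu) <- dimnames(sdv) <-
    list(colnames(comm), colnames(comm))
  structure(list(z = z, obs = obs, null_mean = mu, null_sd = sdv,
                 n_null = n_null, seed = seed, tree_kind = tree_kind,
                 mode = mode),
            class = "betanti")
}

#' @export
print.betanti <- function(x, ...) {
  v <- x$z[upper.tri(x$z)]
  cat("betaNTI matrix over", ncol(x$z), "samples (", x$tree_kind, ",",
      x$mode, "mode,", x$n_null, "nulls, seed", x$seed, ")\n")
  cat("  median betaNTI:", stats::median(v, na.rm = TRUE), "\n")
  invisible(x)
}

#' Classify assembly processes from a betaNTI matrix
#'
#' betaNTI > +threshold: variable selection; < -threshold: homogeneous
#' selection; |betaNTI| <= threshold: stochastic. NaN cells are
#' excluded and counted.
#'
#' @param bnti \code{betanti} object or z matrix.
#' @param threshold classification threshold (default 2, the two-sigma
#'   convention).
#' @return list with \code{fractions} (named, sums to 1),
#'   \code{counts}, \code{n_excluded}, \code{threshold}.
#' @export
classify_assembly <- function(bnti, threshold = 2) {
  z <- if (inherits(bnti, "betanti")) bnti$z else as.matrix(bnti)
  v <- z[upper.tri(z)]
  n_na <- sum(is.nan(v) | is.na(v))
  v <- v[!is.nan(v) & !is.na(v)]
  if (length(v) == 0) stop("no classifiable pairs")
  counts <- c(variable_selection = sum(v > threshold),
              homogeneous_selection = sum(v < -threshold),
              stochastic = sum(abs(v) <= threshold))
  list(fractions = counts / length(v), counts = counts,
       n_excluded = n_na, threshold = threshold)
}

#' Mantel coupling of metabolite and microbial betaNTI matrices
#'
#' Correlates two betaNTI matrices over the same samples with a Mantel
#' permutation test (Pearson on upper-triangle entries, NaN pairs
#' excluded listwise; one-sided p with the add-one rule).
#'
#' @param bnti1,bnti2 \code{betanti} objects or square matrices with
#'   identical sample labels/order.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed (mandatory).
#' @return [mantel()] result.
#' @export
betanti_coupling <- function(bnti1, bnti2, n_perm = 999, seed) {
  z1 <- if (inherits(bnti1, "betanti")) bnti1$z else as.matrix(bnti1)
  z2 <- if (inherits(bnti2, "betanti")) bnti2$z else as.matrix(bnti2)
  if (!identical(dimnames(z1), dimnames(z2))) {
    stop("betaNTI matrices must share sample labels and order")
  }
  mantel(z1, z2, n_perm = n_perm, seed = seed, method = "pearson")
}
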