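# The three relational dendrograms of metabolites. Each plays the role
# of a phylogeny for the metabolite null models: MCD clusters formulas
# by molecular characteristics, TD by shortest-path distance in the
# pooled transformation network, TWCD by characteristics concatenated
# with per-peak transformation profiles. All three use standardized
# columns, Euclidean distance and UPGMA (average-linkage) agglomeration
# with a deterministic lexicographic tie-break, so they are
# reproducible bit-for-bit.

#' UPGMA agglomeration with lexicographic tie-break
#'
#' Average-linkage hierarchical clustering. Among merge candidates at
#' equal (within 1e-12) minimal distance, the pair whose clusters have
#' the lexicographically smallest representative labels is merged, so
#' the result is invariant to input order.
#'
#' @param d \code{dist} object or square symmetric matrix with labels.
#' @return ultrametric \code{phylo} tree (ape); tip-to-tip cophenetic
#'   distances reproduce the UPGMA merge heights.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  n <- nrow(m)
  if (n < 2) stop("need at least 2 tips")
  # active cluster bookkeeping
  size <- rep(1L, n)
  rep_lab <- labels            # lexicographic representative per cluster
  id <- -seq_len(n)            # hclust-style: negative singleton, positive merge
  active <- seq_len(n)
  D <- m
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    sub <- D[active, active, drop = FALSE]
    diag(sub) <- Inf
    dmin <- min(sub)
    cand <- which(sub <= dmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest (sorted) representative pair
    r1 <- rep_lab[active[cand[, 1]]]; r2 <- rep_lab[active[cand[, 2]]]
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    pick <- order(lo, hi)[1]
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- D[i, j]
    # average-linkage update into slot i
    others <- setdiff(active, c(i, j))
    D[i, others] <- D[others, i] <-
      (size[i] * D[i, others] + size[j] * D[j, others]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    id[i] <- step
    active <- setdiff(active, j)
  }
  hc <- list(merge = merge, height = height,
             order = hclust_order(merge), labels = labels,
             method = "average", call = match.call(),
             dist.method = "euclidean")
  class(hc) <- "hclust"
  ape::as.phylo(hc)
}

# leaf ordering for a valid hclust object
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

standardize_columns <- function(x, label = "matrix") {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  keep <- !is.na(sds) & sds > 0
  if (any(!keep)) {
    message("dropping ", sum(!keep), " constant column(s) from ", label, ": ",
            paste(colnames(x)[!keep], collapse = ", "))
  }
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) stop("no non-constant columns left in ", label)
  scale(x)
}

char_matrix <- function(characteristics) {
  ch <- as.data.frame(characteristics)
  cols <- c("C", "H", "O", "N", "S", "P", "mass", "oc", "hc",
            "dbe", "ai_mod", "nosc")
  miss <- setdiff(cols, names(ch))
  if (length(miss)) stop("characteristics missing column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(ch[cols])
  rownames(m) <- if (!is.null(ch$formula)) ch$formula else rownames(ch)
  m
}

new_dendrogram <- function(tree, kind, record) {
  structure(list(tree = tree, kind = kind, record = record),
            class = "relational_dendrogram")
}

#' @export
print.relational_dendrogram <- function(x, ...) {
  cat(x$kind, "relational dendrogram:", length(x$tree$tip.label), "tips;",
      length(x$record$dropped), "tip(s) dropped\n")
  invisible(x)
}

#' Molecular-characteristics dendrogram (MCD)
#'
#' Standardizes the molecular-characteristics matrix (element counts,
#' mass, O/C, H/C, DBE, AImod, NOSC) to zero mean and unit variance
#' (constant columns dropped), computes Euclidean distances, and
#' agglomerates by UPGMA.
#'
#' @param characteristics data frame as returned by
#'   [molecular_characteristics()], with a \code{formula} id column.
#' @return \code{relational_dendrogram} of kind "MCD".
#' @export
build_mcd <- function(characteristics) {
  m <- char_matrix(characteristics)
  if (nrow(m) < 3) stop("need at least 3 formulas")
  z <- standardize_columns(m, "characteristics")
  tree <- upgma(stats::dist(z))
  new_dendrogram(tree, "MCD",
                 list(distance = "euclidean on standardized characteristics",
                      linkage = "UPGMA", dropped = character()))
}

#' Transformation-network dendrogram (TD)
#'
#' Distances between formulas are unweighted shortest-path lengths in
#' the pooled (all-sample) transformation network; formulas outside the
#' largest connected component are dropped (recorded). UPGMA on the
#' path-length matrix.
#'
#' @param network pooled \code{transformation_network}.
#' @return \code{relational_dendrogram} of kind "TD".
#' @export
build_td <- function(network) {
  stopifnot(inherits(network, "transformation_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = network$nodes))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  keep <- names(comp$membership)[comp$membership == main]
  dropped <- setdiff(network$nodes, keep)
  if (length(keep) < 3) stop("largest connected component has fewer than 3 nodes")
  if (length(dropped)) {
    message(length(dropped),
            " formula(s) outside the largest component dropped from TD")
  }
  sub <- igraph::induced_subgraph(g, keep)
  pd <- igraph::distances(sub, weights = NA)   # unweighted path lengths
  pd <- pd[order(rownames(pd)), order(colnames(pd))]
  tree <- upgma(pd)
  new_dendrogram(tree, "TD",
                 list(distance = "unweighted shortest-path length",
                      linkage = "UPGMA", dropped = dropped))
}

#' Transformation-weighted characteristics dendrogram (TWCD)
#'
#' Concatenates the standardized molecular characteristics with the
#' standardized per-peak transformation-count profile (intersection of
#' the two formula sets), then Euclidean + UPGMA as in the MCD. With an
#' all-constant profile the TWCD degenerates to the MCD.
#'
#' @param characteristics as for [build_mcd()].
#' @param profile node x transformation-name count matrix from
#'   [peak_transformation_profile()].
#' @return \code{relational_dendrogram} of kind "TWCD".
#' @export
build_twcd <- function(characteristics, profile) {
  m <- char_matrix(characteristics)
  common <- intersect(rownames(m), rownames(profile))
  if (length(common) == 0) stop("no formulas shared between characteristics and profile")
  if (length(common) < 3) stop("need at least 3 shared formulas")
  dropped <- setdiff(union(rownames(m), rownames(profile)), common)
  if (length(dropped)) {
    message(length(dropped), " formula(s) outside the intersection dropped from TWCD")
  }
  common <- sort(common)
  z1 <- standardize_columns(m[common, , drop = FALSE], "characteristics")
  prof <- profile[common, , drop = FALSE]
  sds <- apply(prof, 2, stats::sd)
  blocks <- z1
  if (any(!is.na(sds) & sds > 0)) {
    z2 <- standardize_columns(prof, "transformation profile")
    blocks <- cbind(z1, z2)
  } else if (ncol(prof) > 0) {
    message("transformation profile is constant; TWCD reduces to MCD columns")
  }
  tree <- upgma(stats::dist(blocks))
  new_dendrogram(tree, "TWCD",
                 list(distance = "euclidean on standardized characteristics + profile",
                      linkage = "UPGMA", dropped = dropped))
}

#' Cophenetic tip-to-tip distances of a dendrogram or tree
#'
#' @param x \code{relational_dendrogram} or ape \code{phylo}.
#' @return labelled square matrix of cophenetic (patristic) distances.
#' @export
cophenetic_distances <- function(x) {
  tree <- if (inherits(x, "relational_dendrogram")) x$tree else x
  ape::cophenetic.phylo(tree)
}

#' Write a dendrogram to newick
#'
#' @param x \code{relational_dendrogram} or \code{phylo}.
#' @param path output file.
#' @export
write_dendrogram <- function(x, path) {
  tree <- if (inherits(x, "relational_dendrogram")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}
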