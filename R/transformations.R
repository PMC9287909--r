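# Putative biochemical transformations between rhizodeposit peaks,
# detected as pairwise mass differences matching a reference list of
# common biochemical deltas (functional-group gains/losses and the
# amino-acid residue set).

#' Default transformation reference list
#'
#' A bundled, user-replaceable table of common biochemical mass
#' deltas (H2, CH2, H2O, CO2, ..., glucose unit, amino-acid residues)
#' given as element-count deltas; delta masses are computed from the
#' counts with the package's monoisotopic constants.
#'
#' @param path optional replacement table (same columns: name,
#'   C,H,O,N,S,P and optionally delta_mass to cross-check).
#' @return data frame with columns name, C,H,O,N,S,P, delta_mass.
#' @export
transformation_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "transformation_reference.csv",
                        package = "chemassembly")
  }
  tb <- read_table_auto(path)
  if (anyDuplicated(tb$name)) stop("transformation names must be unique")
  supplied <- tb$delta_mass
  tb$delta_mass <- formula_mass(tb)
  if (!is.null(supplied)) {
    bad <- abs(supplied - tb$delta_mass) > 1e-5
    if (any(bad)) stop("supplied delta_mass disagrees with computed mass for: ",
                       paste(tb$name[bad], collapse = ", "))
  }
  if (any(tb$delta_mass <= 0)) stop("delta masses must be positive")
  tb
}

#' Detect putative transformations within one sample
#'
#' Builds the undirected transformation network over a sample's peak
#' masses: an edge links every unordered pair of peaks whose absolute
#' mass difference matches a reference delta within \code{tolerance}.
#' A pair matching k reference entries yields k parallel edges.
#'
#' @param masses numeric vector of peak masses (Da); names, if present,
#'   become node ids.
#' @param reference transformation reference table (see
#'   [transformation_reference()]).
#' @param tolerance matching tolerance; in Da by default, in ppm of the
#'   larger mass when \code{ppm = TRUE}.
#' @param ppm interpret \code{tolerance} as parts-per-million.
#' @return object of class \code{transformation_network}: list with
#'   \code{nodes} (ids) and \code{edges} (data frame from, to, name,
#'   observed_delta, error_da).
#' @export
detect_transformations <- function(masses, reference = transformation_reference(),
                                   tolerance = 0.001, ppm = FALSE) {
  if (is.null(reference) || nrow(reference) == 0) {
    stop("empty transformation reference")
  }
  if (tolerance <= 0) stop("tolerance must be positive")
  nodes <- names(masses)
  if (is.null(nodes)) nodes <- as.character(seq_along(masses))
  # canonical order so the result is invariant to input order
  ord <- order(masses, nodes)
  masses <- masses[ord]; nodes <- nodes[ord]
  n <- length(masses)
  edges <- list()
  if (n >= 2) {
    ref_mass <- reference$delta_mass
    ref_name <- reference$name
    for (i in seq_len(n - 1)) {
      dm <- masses[(i + 1):n] - masses[i]   # >= 0 by sort
      for (r in seq_along(ref_mass)) {
        tol <- if (ppm) tolerance * 1e-6 * pmax(masses[(i + 1):n], masses[i]) else tolerance
        hit <- which(abs(dm - ref_mass[r]) <= tol)
        if (length(hit)) {
          edges[[length(edges) + 1]] <- data.frame(
            from = nodes[i], to = nodes[i + hit],
            name = ref_name[r], observed_delta = dm[hit],
            error_da = abs(dm[hit] - ref_mass[r]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), name = character(),
               observed_delta = numeric(), error_da = numeric(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, edges$name), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes[order(nodes)], edges = edges),
            class = "transformation_network")
}

#' @export
print.transformation_network <- function(x, ...) {
  cat("Transformation network:", length(x$nodes), "peaks,",
      nrow(x$edges), "transformation edge(s)\n")
  invisible(x)
}

#' Number of transformations in a network
#'
#' Total edge count of a sample's transformation network (parallel
#' edges for distinct transformation names counted separately).
#'
#' @param network \code{transformation_network}.
#' @return integer edge count.
#' @export
transformation_count <- function(network) {
  stopifnot(inherits(network, "transformation_network"))
  nrow(network$edges)
}

#' Per-peak transformation profile
#'
#' Node-by-transformation-name count matrix: entry (i, t) is the number
#' of edges of transformation t incident to peak i. Row sums equal node
#' degrees; the grand total is twice the edge count.
#'
#' @param network \code{transformation_network}.
#' @return integer matrix nodes x transformation names.
#' @export
peak_transformation_profile <- function(network) {
  stopifnot(inherits(network, "transformation_network"))
  nodes <- network$nodes
  nm <- sort(unique(network$edges$name))
  prof <- matrix(0L, length(nodes), length(nm),
                 dimnames = list(nodes, nm))
  e <- network$edges
  for (k in seq_len(nrow(e))) {
    prof[e$from[k], e$name[k]] <- prof[e$from[k], e$name[k]] + 1L
    prof[e$to[k], e$name[k]] <- prof[e$to[k], e$name[k]] + 1L
  }
  prof
}

#' Per-sample transformation networks and counts
#'
#' Convenience wrapper running [detect_transformations()] on every
#' sample of a metabolome (using the formula monoisotopic masses of the
#' peaks present in that sample), plus optionally the pooled network
#' over all formulas (used by the TD dendrogram).
#'
#' @param metabolome \code{metabolome} object.
#' @inheritParams detect_transformations
#' @param pooled also build the all-sample pooled network.
#' @return list with \code{per_sample} (named list of networks),
#'   \code{counts} (named integer vector) and, if requested,
#'   \code{pooled}.
#' @export
sample_transformations <- function(metabolome, reference = transformation_reference(),
                                   tolerance = 0.001, pooled = TRUE) {
  inc <- metabolome$incidence
  masses <- metabolome$formulas$mass
  names(masses) <- metabolome$formulas$formula
  per <- lapply(rownames(inc), function(s) {
    present <- masses[inc[s, ] == 1]
    detect_transformations(present, reference, tolerance)
  })
  names(per) <- rownames(inc)
  out <- list(per_sample = per,
              counts = vapply(per, transformation_count, integer(1)))
  if (pooled) out$pooled <- detect_transformations(masses, reference, tolerance)
  out
}
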