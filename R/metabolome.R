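# Presence/absence community ecology of rhizodeposit molecular formulas.
# Peak intensities are deliberately never used in any statistic: all
# downstream ecology is on binary incidence.

#' Build a samples-by-formula incidence matrix from a peak table
#'
#' Deduplicates formulas by exact element counts, collapses repeated
#' detections within a sample to a single presence, and returns a
#' binary incidence matrix (samples x unique formulas) together with
#' the formula table. Intensities are retained in the peak table but
#' excluded from the matrix.
#'
#' @param peaks a \code{peak_table} (or data frame with sample_id and
#'   element-count columns).
#' @return list of class \code{metabolome}: \code{incidence}
#'   (samples x formulas 0/1 matrix, columns named by [formula_id()]),
#'   \code{formulas} (one row per unique formula with characteristics).
#' @export
metabolome_matrix <- function(peaks) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) {
    return(structure(list(incidence = matrix(0, 0, 0),
                          formulas = data.frame()),
                     class = "metabolome"))
  }
  ids <- formula_id(peaks)
  uniq <- !duplicated(ids)
  formulas <- peaks[uniq, intersect(ELEMENTS, names(peaks)), drop = FALSE]
  rownames(formulas) <- NULL
  formulas <- molecular_characteristics(formulas)
  formulas$formula <- ids[uniq]
  samples <- sort(unique(peaks$sample_id))
  inc <- matrix(0L, length(samples), nrow(formulas),
                dimnames = list(samples, formulas$formula))
  inc[cbind(match(peaks$sample_id, samples), match(ids, formulas$formula))] <- 1L
  if (any(rowSums(inc) == 0)) {
    stop("sample(s) with zero present formulas: ",
         paste(samples[rowSums(inc) == 0], collapse = ", "))
  }
  structure(list(incidence = inc, formulas = formulas),
            class = "metabolome")
}

#' @export
print.metabolome <- function(x, ...) {
  cat("Metabolome incidence matrix:", nrow(x$incidence), "samples x",
      ncol(x$incidence), "unique formulas\n")
  invisible(x)
}

inc_matrix <- function(matrix) {
  m <- if (inherits(matrix, "metabolome")) matrix$incidence else as.matrix(matrix)
  if (any(!m %in% c(0, 1))) stop("incidence matrix entries must be 0/1")
  m
}

#' Chemodiversity: effective peak count per sample
#'
#' The chemodiversity of a sample is the number of distinct molecular
#' formulas (effective peaks) detected in it, i.e. the row sum of the
#' binary incidence matrix.
#'
#' @param matrix a \code{metabolome} object or 0/1 matrix (samples x
#'   formulas).
#' @param sample optional sample id(s); default all samples.
#' @return named integer vector of formula counts.
#' @export
chemodiversity <- function(matrix, sample = NULL) {
  m <- inc_matrix(matrix)
  cd <- rowSums(m)
  if (!is.null(sample)) {
    if (!all(sample %in% rownames(m))) {
      stop("unknown sample(s): ",
           paste(setdiff(sample, rownames(m)), collapse = ", "))
    }
    cd <- cd[sample]
  }
  cd
}

#' Sorensen distance matrix on presence/absence data
#'
#' Pairwise Sorensen dissimilarity d(A,B) = 1 - 2|A&B| / (|A|+|B|) on
#' the presence sets of each pair of samples.
#'
#' @param matrix \code{metabolome} object or 0/1 matrix.
#' @return \code{dist} object over samples.
#' @export
sorensen_matrix <- function(matrix) {
  m <- inc_matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 samples")
  sizes <- rowSums(m)
  if (any(sizes == 0)) {
    stop("Sorensen distance undefined for zero-peak sample(s): ",
         paste(rownames(m)[sizes == 0], collapse = ", "))
  }
  shared <- m %*% t(m)                      # |A & B|
  d <- 1 - 2 * shared / outer(sizes, sizes, `+`)
  stats::as.dist(d)
}

#' Per-sample compound-class relative abundance
#'
#' Fractions of the formulas present in each sample that fall in each
#' van Krevelen compound class; rows sum to 1.
#'
#' @param matrix \code{metabolome} object, or 0/1 matrix if
#'   \code{classes} is supplied.
#' @param classes optional character vector of class names per formula
#'   (matrix columns); computed with [classify_compound()] for
#'   \code{metabolome} input.
#' @param class_table boundary table for classification.
#' @return matrix samples x classes of fractions.
#' @export
class_relative_abundance <- function(matrix, classes = NULL,
                                     class_table = default_class_table()) {
  m <- inc_matrix(matrix)
  if (is.null(classes)) {
    if (!inherits(matrix, "metabolome")) {
      stop("supply classes= when not passing a metabolome object")
    }
    classes <- classify_compound(matrix$formulas, class_table)
  }
  if (length(classes) != ncol(m)) {
    stop("classes length must match number of formulas")
  }
  lev <- unique(c(class_table$class, "unclassified"))
  lev <- c(lev[lev %in% classes], setdiff(unique(classes), lev))
  counts <- sapply(lev, function(cl) rowSums(m[, classes == cl, drop = FALSE]))
  counts <- matrix(counts, nrow = nrow(m),
                   dimnames = list(rownames(m), lev))
  counts / rowSums(m)
}
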