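#' Molecular characteristics of assigned formulas
#'
#' Computes, for each molecular formula given as element counts, the
#' monoisotopic mass and the standard FTICR-MS derived indices: O/C and
#' H/C elemental ratios (the van Krevelen axes), double-bond equivalents
#' (DBE), the modified aromaticity index (AImod) and the nominal
#' oxidation state of carbon (NOSC).
#'
#' DBE uses the ring-plus-double-bond formula with trivalent N and P
#' (divalent O and S do not contribute):
#' \deqn{DBE = 1 + (2C - H + N + P)/2}
#' A half-integer DBE indicates a radical-inconsistent formula; such
#' rows are flagged (\code{dbe_radical}), not dropped.
#'
#' AImod treats half of the oxygen as carbonyl-like:
#' \deqn{AImod = (1 + C - 0.5 O - S - 0.5 H) / (C - 0.5 O - N - S - P)}
#' and is set to 0 when the denominator is <= 0. Negative values
#' (highly saturated, oxygen-rich formulas) are kept as computed.
#'
#' NOSC follows the usual electron-bookkeeping form:
#' \deqn{NOSC = 4 - (4C + H - 3N - 2O + 5P - 2S)/C}
#'
#' @param formulas data frame with integer columns C, H, O, N, S, P
#'   (missing element columns are treated as 0). One row per formula.
#' @return The input with columns \code{mass}, \code{oc}, \code{hc},
#'   \code{dbe}, \code{ai_mod}, \code{nosc}, \code{dbe_radical} appended.
#' @examples
#' molecular_characteristics(data.frame(C = 6, H = 12, O = 6))
#' @export
molecular_characteristics <- function(formulas) {
  formulas <- as.data.frame(formulas)
  for (el in ELEMENTS) {
    if (is.null(formulas[[el]])) formulas[[el]] <- 0L
    if (any(is.na(formulas[[el]])) || any(formulas[[el]] < 0) ||
        any(formulas[[el]] != round(formulas[[el]]))) {
      stop("element counts for ", el, " must be non-negative integers")
    }
  }
  if (any(formulas$C < 1)) {
    stop("derived characteristics are undefined for formulas with C = 0")
  }
  C <- formulas$C; H <- formulas$H; O <- formulas$O
  N <- formulas$N; S <- formulas$S; P <- formulas$P

  formulas$mass <- formula_mass(formulas)
  formulas$oc <- O / C
  formulas$hc <- H / C
  formulas$dbe <- 1 + (2 * C - H + N + P) / 2
  denom <- C - 0.5 * O - N - S - P
  ai <- (1 + C - 0.5 * O - S - 0.5 * H) / denom
  ai[denom <= 0] <- 0
  formulas$ai_mod <- ai
  formulas$nosc <- 4 - (4 * C + H - 3 * N - 2 * O + 5 * P - 2 * S) / C
  formulas$dbe_radical <- formulas$dbe != round(formulas$dbe)
  formulas
}

#' Monoisotopic mass of formulas
#'
#' @param formulas data frame with element-count columns (any subset of
#'   C, H, O, N, S, P; missing columns count as zero).
#' @return numeric vector of monoisotopic masses in Da.
#' @export
formula_mass <- function(formulas) {
  formulas <- as.data.frame(formulas)
  mass <- numeric(nrow(formulas))
  for (el in ELEMENTS) {
    cnt <- formulas[[el]]
    if (!is.null(cnt)) mass <- mass + cnt * ATOMIC_MASS[[el]]
  }
  mass
}

#' Canonical formula identifiers
#'
#' Keys a set of formulas by exact element counts, e.g. "C6H12O6".
#' Elements with zero count are omitted; element order is C, H, O, N,
#' S, P. Used to deduplicate formulas and to label dendrogram tips.
#'
#' @param formulas data frame with element-count columns.
#' @return character vector of ids.
#' @export
formula_id <- function(formulas) {
  formulas <- as.data.frame(formulas)
  ids <- rep("", nrow(formulas))
  for (el in ELEMENTS) {
    cnt <- formulas[[el]]
    if (is.null(cnt)) next
    part <- ifelse(cnt > 0, paste0(el, cnt), "")
    ids <- paste0(ids, part)
  }
  ids
}

#' Default van Krevelen compound-class boundaries
#'
#' The widely used rectangular O/C x H/C windows assigning FTICR-MS
#' formulas to seven biochemical compound classes. Intervals are
#' half-open on the sides indicated by \code{oc_max_open} /
#' \code{hc_max_open} so the classes are disjoint; a formula falling in
#' no rectangle is "unclassified". The table is ordered by precedence
#' and can be replaced by any user table with the same columns.
#'
#' @return data frame with columns class, oc_min, oc_max, hc_min,
#'   hc_max, oc_max_open, hc_max_open, precedence.
#' @export
default_class_table <- function() {
  tb <- read.csv(system.file("extdata", "vk_classes.csv",
                             package = "chemassembly"),
                 stringsAsFactors = FALSE)
  validate_class_table(tb)
  tb
}

validate_class_table <- function(tb) {
  need <- c("class", "oc_min", "oc_max", "hc_min", "hc_max",
            "oc_max_open", "hc_max_open", "precedence")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("class table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tb$precedence)) stop("precedence ranks must be unique")
  invisible(tb)
}

#' Classify formulas into van Krevelen compound classes
#'
#' Assigns each formula to the first class (by precedence) whose
#' O/C-H/C rectangle contains its point, or "unclassified". This is a
#' total, deterministic function of the boundary table.
#'
#' @param characteristics data frame with \code{oc} and \code{hc}
#'   columns (as returned by [molecular_characteristics()]).
#' @param class_table boundary table; defaults to
#'   [default_class_table()].
#' @return character vector of class names, one per formula.
#' @examples
#' ch <- molecular_characteristics(data.frame(C = 6, H = 12, O = 6))
#' classify_compound(ch)  # "carbohydrates"
#' @export
classify_compound <- function(characteristics, class_table = default_class_table()) {
  validate_class_table(class_table)
  class_table <- class_table[order(class_table$precedence), , drop = FALSE]
  oc <- characteristics$oc
  hc <- characteristics$hc
  if (is.null(oc) || is.null(hc)) stop("characteristics must have oc and hc")
  out <- rep("unclassified", length(oc))
  unset <- rep(TRUE, length(oc))
  for (r in seq_len(nrow(class_table))) {
    row <- class_table[r, ]
    in_oc <- oc >= row$oc_min &
      (if (isTRUE(as.logical(row$oc_max_open))) oc < row$oc_max else oc <= row$oc_max)
    in_hc <- hc >= row$hc_min &
      (if (isTRUE(as.logical(row$hc_max_open))) hc < row$hc_max else hc <= row$hc_max)
    hit <- unset & in_oc & in_hc
    out[hit] <- row$class
    unset[hit] <- FALSE
  }
  out
}
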