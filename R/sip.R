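# DNA stable-isotope probing: identification of 13C-labeled "heavy"
# buoyant-density fractions from density-resolved qPCR profiles. DNA of
# organisms that assimilated the 13C-labeled rhizodeposits is denser
# than unlabeled DNA, so labeled profiles show excess 16S copies at
# high buoyant density relative to the unlabeled control gradient.

#' Read a SIP fraction table
#'
#' Delimited text with columns sample_id, fraction (1..k), density
#' (g/mL), copies (16S gene copies), label ("labeled" or "control").
#' Densities must be strictly monotone across fractions within each
#' sample.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_sip_table <- function(path) {
  tb <- read_table_auto(path)
  need <- c("sample_id", "fraction", "density", "copies", "label")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("SIP table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tb$copies < 0)) stop("copies must be non-negative")
  for (s in unique(tb$sample_id)) {
    sub <- tb[tb$sample_id == s, ]
    sub <- sub[order(sub$fraction), ]
    if (any(diff(sub$density) <= 0) && any(diff(sub$density) >= 0) &&
        !(all(diff(sub$density) > 0) || all(diff(sub$density) < 0))) {
      stop("densities not strictly monotone for sample ", s)
    }
  }
  tb
}

check_profile <- function(profile) {
  need <- c("density", "copies")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("profile missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- diff(profile$density)
  if (!(all(d > 0) || all(d < 0))) {
    stop("profile densities must be strictly monotone")
  }
  if (any(profile$copies < 0)) stop("copies must be non-negative")
  profile[order(profile$density), , drop = FALSE]
}

#' Identify heavy (13C-labeled) density fractions
#'
#' Copies are normalized to proportion-of-total within each profile;
#' control proportions are linearly interpolated onto the labeled
#' profile's densities. A fraction is heavy-eligible when its density
#' is at least \code{density_min} and its labeled/control proportion
#' ratio is at least \code{ratio_min}; the heavy window is the maximal
#' contiguous run of eligible fractions (ties broken toward the denser
#' run). An empty result means no detectable labeling.
#'
#' @param labeled,control data frames with columns \code{density}
#'   (g/mL, strictly monotone) and \code{copies}; \code{fraction}
#'   column optional (defaults to the density order).
#' @param density_min minimal buoyant density of a heavy fraction
#'   (default 1.72 g/mL).
#' @param ratio_min minimal labeled/control proportion ratio (default
#'   1.5).
#' @return integer vector of heavy fraction indices (possibly empty),
#'   with attribute \code{ratio} carrying the per-fraction enrichment
#'   ratios.
#' @export
heavy_fractions <- function(labeled, control, density_min = 1.72,
                            ratio_min = 1.5) {
  labeled <- check_profile(labeled)
  control <- check_profile(control)
  if (max(labeled$density) < min(control$density) ||
      max(control$density) < min(labeled$density)) {
    stop("labeled and control profiles do not overlap in density")
  }
  lp <- labeled$copies / sum(labeled$copies)
  cp <- control$copies / sum(control$copies)
  cp_at <- stats::approx(control$density, cp, xout = labeled$density,
                         rule = 2)$y
  ratio <- ifelse(cp_at > 0, lp / cp_at, ifelse(lp > 0, Inf, 1))
  frac_idx <- if (!is.null(labeled$fraction)) labeled$fraction else
    seq_len(nrow(labeled))
  eligible <- labeled$density >= density_min & ratio >= ratio_min
  runs <- rle(eligible)
  out <- integer(0)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    cand <- which(runs$values)
    lens <- runs$lengths[cand]
    best <- cand[lens == max(lens)]
    best <- best[length(best)]            # densest run on ties
    out <- frac_idx[starts[best]:ends[best]]
  }
  attr(out, "ratio") <- stats::setNames(ratio, frac_idx)
  out
}
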