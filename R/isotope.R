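# 13C pulse-label accounting: converting delta-13C values to atom
# percent 13C against the VPDB standard, excess 13C per compartment
# (shoot, root, soil), and the allocation of photosynthesized carbon
# among compartments.

#' Convert delta-13C to atom percent 13C
#'
#' R = R_VPDB (delta/1000 + 1), atom% = 100 R / (1 + R), with
#' R_VPDB = 0.0111802 (13C/12C of Vienna Pee Dee Belemnite).
#'
#' @param delta13C delta-13C in permil vs VPDB; must be > -1000.
#' @return atom percent 13C.
#' @examples
#' atom_percent(0)     # 1.10566
#' @export
atom_percent <- function(delta13C) {
  if (any(delta13C <= -1000)) {
    stop("delta-13C must be greater than -1000 permil")
  }
  R <- R_VPDB * (delta13C / 1000 + 1)
  100 * R / (1 + R)
}

#' Excess 13C in a compartment
#'
#' excess (g 13C) = (atom%_labeled - atom%_control)/100 x (dry mass x C
#' concentration). Negative excess (control above labeled) is kept and
#' flagged with a warning, never clamped.
#'
#' @param mass dry mass (g).
#' @param c_conc carbon concentration (g C per g dry mass).
#' @param delta_labeled,delta_control delta-13C (permil) of the labeled
#'   and control samples.
#' @return excess 13C in g.
#' @export
c13_excess <- function(mass, c_conc, delta_labeled, delta_control) {
  if (any(is.na(delta_control))) stop("control delta-13C is required")
  if (any(mass <= 0) || any(c_conc <= 0)) {
    stop("mass and C concentration must be positive")
  }
  excess <- (atom_percent(delta_labeled) - atom_percent(delta_control)) / 100 *
    (mass * c_conc)
  if (any(excess < 0)) {
    warning(sum(excess < 0), " compartment(s) with negative 13C excess ",
            "(control exceeds labeled)")
  }
  excess
}

#' Allocation of photosynthesized carbon among compartments
#'
#' Percent of total recovered excess 13C in each compartment:
#' fraction_c = 100 excess_c / sum(excess). Fractions sum to 100 and
#' are invariant to rescaling all pools by a constant.
#'
#' @param pools data frame with columns compartment, mass, c_conc,
#'   delta_labeled, delta_control; or a named numeric vector of
#'   precomputed excesses.
#' @return named numeric vector of allocation percentages.
#' @export
allocation_fractions <- function(pools) {
  if (is.data.frame(pools)) {
    excess <- c13_excess(pools$mass, pools$c_conc,
                         pools$delta_labeled, pools$delta_control)
    names(excess) <- pools$compartment
  } else {
    excess <- pools
  }
  if (length(excess) < 2) stop("need at least 2 compartments")
  total <- sum(excess)
  if (total <= 0) stop("total 13C excess is not positive; allocation undefined")
  100 * excess / total
}

#' Read an isotope pool table
#'
#' Delimited text with columns sample_id (or treatment), compartment,
#' mass, c_conc, delta_labeled, delta_control.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_isotope_table <- function(path) {
  tb <- read_table_auto(path)
  need <- c("compartment", "mass", "c_conc", "delta_labeled", "delta_control")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("isotope table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tb$mass <= 0) || any(tb$c_conc <= 0)) {
    stop("masses and C concentrations must be positive")
  }
  if (any(tb$delta_labeled <= -1000) || any(tb$delta_control <= -1000)) {
    stop("delta-13C values must exceed -1000 permil")
  }
  tb
}
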