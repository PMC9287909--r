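#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of the elements handled by the package,
#' fixed to 7 decimal places. Used for every mass computation
#' (formula masses, transformation deltas, mass-consistency checks).
#'
#' @format Named numeric vector with elements C, H, O, N, S, P.
#' @export
ATOMIC_MASS <- c(
  C = 12.0000000,
  H = 1.0078250,
  O = 15.9949146,
  N = 14.0030740,
  S = 31.9720707,
  P = 30.9737615
)

#' VPDB carbon isotope ratio
#'
#' The 13C/12C ratio of the Vienna Pee Dee Belemnite standard, the
#' reference for delta-13C values.
#'
#' @export
R_VPDB <- 0.0111802

# canonical element order used everywhere a formula is keyed or printed
ELEMENTS <- c("C", "H", "O", "N", "S", "P")
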