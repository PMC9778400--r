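# Element data for the organic subset handled by the SMILES machinery.
# Masses: IUPAC 2021 standard atomic weights. Radii: Bondi van der Waals
# radii (Angstrom); boron from Mantina et al. (2009).

.elements <- local({
  df <- data.frame(
    symbol  = c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
    mass    = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
                30.974, 32.06, 35.45, 79.904, 126.904),
    rvdw    = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
    zv      = c(1L, 3L, 4L, 5L, 6L, 7L, 5L, 6L, 7L, 7L, 7L),  # valence electrons
    period  = c(1L, 2L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 5L),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$symbol
  df
})

# Default valence lists (Daylight conventions) used to fill implicit hydrogens.
.default_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

.elem_prop <- function(symbol, prop) {
  i <- match(symbol, .elements$symbol)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .elements[[prop]][i]
}

#' Van der Waals volume of an element
#'
#' Computed from the Bondi radius as a sphere volume, the weighting used by
#' the `ats()` autocorrelation with `weight = "vdw_volume"`.
#'
#' @param symbol character vector of element symbols.
#' @return numeric vector of volumes in cubic Angstrom.
#' @keywords internal
vdw_volume <- function(symbol) {
  4 / 3 * pi * .elem_prop(symbol, "rvdw")^3
}
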