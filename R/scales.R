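# Embedded per-residue property tables.
#
# Sign convention throughout the package: NEGATIVE free energies mark
# bilayer-preferring (hydrophobic) residues, so that positional hydropathy
# profiles dip below zero inside the membrane. The GES table is published
# with the opposite sign (favourable transfer to the bilayer positive) and is
# stored here negated; the Wimley-White octanol and Biological (translocon)
# tables are published in the convention used here and are stored verbatim.

# Goldman-Engelman-Steitz transfer free energies (kcal/mol), Engelman,
# Steitz & Goldman (1986) Annu Rev Biophys, sign-flipped (hydrophobic < 0).
GES_VALUES <- c(
  A = -1.6, C = -2.0, D =  9.2, E =  8.2, F = -3.7,
  G = -1.0, H =  3.0, I = -3.1, K =  8.8, L = -2.8,
  M = -3.4, N =  4.8, P =  0.2, Q =  4.1, R = 12.3,
  S = -0.6, T = -1.2, V = -2.6, W = -1.9, Y =  0.7
)

# Wimley-White whole-residue water->n-octanol transfer free energies
# (kcal/mol), Wimley & White (1996) Nat Struct Biol; neutral His.
WW_VALUES <- c(
  A =  0.50, C = -0.02, D =  3.64, E =  3.63, F = -1.71,
  G =  1.15, H =  0.11, I = -1.12, K =  2.80, L = -1.25,
  M = -0.67, N =  0.85, P =  0.14, Q =  0.77, R =  1.81,
  S =  0.46, T =  0.25, V = -0.46, W = -2.09, Y = -0.71
)

# "Biological" translocon-mediated insertion scale: apparent free energies
# of membrane insertion (kcal/mol), Hessa et al. (2005) Nature.
BIO_VALUES <- c(
  A =  0.11, C = -0.13, D =  3.49, E =  2.68, F = -0.32,
  G =  0.74, H =  2.06, I = -0.60, K =  2.71, L = -0.55,
  M = -0.10, N =  2.05, P =  2.23, Q =  2.36, R =  2.58,
  S =  0.84, T =  0.52, V = -0.31, W =  0.30, Y =  0.68
)

# Mean residue volumes in solution (cubic Angstrom), Zamyatnin (1972)
# Prog Biophys Mol Biol 24:107-123. Glycine is the smallest.
RESIDUE_VOLUMES <- c(
  A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
  G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
  M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
  S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6
)

#' Hydrophobicity scales for TMD edge scanning
#'
#' Returns one of the three per-residue free-energy scales used to delineate
#' hydrophobic cores, together with the scanning thresholds associated with
#' it. Values are in kcal/mol with hydrophobic (bilayer-preferring) residues
#' negative. The window threshold is the largest (most hydrophilic) 5-residue
#' window mean still counted as core; the residue threshold is the individual
#' value above which a single residue terminates the core outright (on the
#' GES scale this catches exactly D, E, K and R).
#'
#' @param name `"ges"` (Goldman-Engelman-Steitz, the default scale for all
#'   analyses), `"ww"` (Wimley-White whole-residue octanol) or `"bio"`
#'   (Biological/translocon apparent insertion free energies).
#' @return An object of class `hydro_scale`: a list with elements `name`,
#'   `values` (named numeric, 20 residues), `window_threshold`,
#'   `residue_threshold`, `window` (5) and `indent` (4).
#' @examples
#' ges <- hydrophobicity_scale("ges")
#' ges$values[["L"]]
#' @export
hydrophobicity_scale <- function(name = c("ges", "ww", "bio")) {
  name <- match.arg(tolower(name[1]), c("ges", "ww", "bio"))
  params <- switch(name,
    ges = list(values = GES_VALUES, window_threshold = -0.94, residue_threshold = 8.0),
    ww  = list(values = WW_VALUES,  window_threshold = -0.50, residue_threshold = 3.60),
    bio = list(values = BIO_VALUES, window_threshold =  0.20, residue_threshold = 2.70)
  )
  structure(
    list(name = name, values = params$values[AA_ALPHABET],
         window_threshold = params$window_threshold,
         residue_threshold = params$residue_threshold,
         window = 5L, indent = 4L),
    class = "hydro_scale"
  )
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat(sprintf("<hydro_scale: %s>  window %d, indent %d, thresholds: window %.2f / residue %.2f kcal/mol\n",
              x$name, x$window, x$indent, x$window_threshold, x$residue_threshold))
  print(round(x$values, 2))
  invisible(x)
}

#' Residue volume table
#'
#' Mean amino-acid residue volumes in solution (cubic Angstrom), used for
#' positional volume profiles, leaflet-preference interpretation and the
#' helical size moment. A different published table can be swapped in by
#' passing any complete named vector wherever a volume table is accepted.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @examples
#' residue_volumes()[["G"]]  # glycine, the smallest
#' @export
residue_volumes <- function() {
  RESIDUE_VOLUMES[AA_ALPHABET]
}

# resolve a property argument: a hydro_scale, a scale name, or a named vector
resolve_property <- function(property) {
  if (inherits(property, "hydro_scale")) {
    return(property$values)
  }
  if (is.character(property) && length(property) == 1) {
    if (tolower(property) %in% c("ges", "ww", "bio")) {
      return(hydrophobicity_scale(property)$values)
    }
    if (tolower(property) == "volume") {
      return(residue_volumes())
    }
    abort(sprintf("unknown property '%s'", property))
  }
  if (is.numeric(property) && !is.null(names(property))) {
    missing <- setdiff(AA_ALPHABET, names(property))
    if (length(missing) > 0) {
      abort(paste0("property table is missing residues: ",
                   paste(missing, collapse = ", ")))
    }
    return(property[AA_ALPHABET])
  }
  abort("property must be a hydro_scale, a scale name, \"volume\", or a named numeric vector")
}
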