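# Physical constants and residue property tables.
# Monoisotopic masses in Da; values frozen from standard atomic composition.

PROTON_MASS <- 1.00727646677
WATER_MASS <- 18.0105646837

RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Monoisotopic residue mass table
#'
#' Named vector of monoisotopic masses (Da) for the 20 canonical amino acid
#' residues (residue masses, i.e. the mass added per residue in a peptide
#' chain; the peptide neutral mass is the sum of residue masses plus one
#' water). The same table ships as a plain-text resource under
#' \code{inst/extdata/monoisotopic_masses.tsv}.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function() {
  c(A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
    F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
    K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
    P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
    T = 101.047678, V = 99.068414, W = 186.079313, Y = 163.063329)
}

# Named modification registry: maps common monoisotopic deltas to a
# modification class used during tokenization. Deltas outside the registry
# fall into the catch-all "other" class (they still shift fragment masses by
# their exact value; only the token class is coarse).
MOD_REGISTRY <- c(
  oxidation         = 15.9949,
  carbamidomethyl   = 57.02146,
  xl_stub_alkene    = 54.01057,   # DSSO remnant after cleavage
  xl_hydrolyzed     = 176.01433   # hydrolyzed mono-linked DSSO
)
MOD_CLASS_TOL <- 0.01  # Da window for matching a delta to the registry

#' Default cross-linker mass
#'
#' Intact DSSO linker mass (Da) carried by fragments that contain the
#' cross-linked residue.
#' @return Numeric scalar.
#' @export
dsso_linker_mass <- function() 158.00376

mod_class_of <- function(delta_mass) {
  hit <- which(abs(MOD_REGISTRY - delta_mass) <= MOD_CLASS_TOL)
  if (length(hit) >= 1L) names(MOD_REGISTRY)[hit[1L]] else "other"
}

#' Residue physicochemical scale table
#'
#' Monoisotopic residue mass and Zimmerman bulkiness for each of the 20
#' canonical residues, used to correlate per-residue attributions with
#' physical properties. User-replaceable: any data frame with columns
#' \code{residue}, \code{mass}, \code{bulkiness} works in
#' \code{\link{scale_correlation}}.
#'
#' @return data.frame with columns residue, mass, bulkiness.
#' @export
residue_scales <- function() {
  bulk <- c(A = 11.50, C = 13.46, D = 11.68, E = 13.57, F = 19.80,
            G = 3.40, H = 13.69, I = 21.40, K = 15.71, L = 21.40,
            M = 16.25, N = 12.82, P = 17.43, Q = 14.45, R = 14.28,
            S = 9.47, T = 15.77, V = 21.57, W = 21.67, Y = 18.03)
  data.frame(residue = RESIDUES,
             mass = unname(residue_masses()[RESIDUES]),
             bulkiness = unname(bulk[RESIDUES]),
             stringsAsFactors = FALSE)
}
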