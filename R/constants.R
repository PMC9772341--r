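#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in alphabetical order. This
#' ordering fixes the column order of every composition feature produced by
#' the package.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ambiguity codes tolerated on input; excluded from composition denominators.
AMBIGUOUS_CODES <- c("B", "Z", "X", "U", "O")

#' Residue class membership tables
#'
#' Named residue sets used by the physicochemical features. Sets fixed by
#' convention in the thermostability literature (EFMR, tiny, small, IVYWREL,
#' positive, negative) are hard-wired; the remaining sets (acidic, basic,
#' polarity, ring structure, aliphatic) follow standard textbook definitions
#' and can be overridden by passing a modified copy of this list to the
#' feature functions.
#'
#' Note that [msa_residue_classes()] uses a different, five-class partition
#' for positional association tests; the two tables are deliberately
#' independent.
#'
#' @return Named list of character vectors, each a subset of [amino_acids()].
#' @export
residue_classes <- function() {
  acidic <- c("D", "E")
  basic <- c("K", "R", "H")
  polar <- c("S", "T", "N", "Q", "Y", "C", "H", "D", "E", "K", "R")
  cyclic <- c("F", "W", "Y", "H", "P")
  list(
    acidic = acidic,
    basic = basic,
    non_polar = setdiff(amino_acids(), polar),
    polar = polar,
    acyclic = setdiff(amino_acids(), cyclic),
    cyclic = cyclic,
    aliphatic = c("A", "G", "V", "L", "I"),
    aromatic = c("F", "W", "Y", "H"),
    charged = c("D", "E", "K", "R"),
    EFMR = c("E", "F", "M", "R"),
    tiny = c("A", "G", "P", "S"),
    small = c("T", "D"),
    IVYWREL = c("I", "V", "Y", "W", "R", "E", "L"),
    positive = c("R", "K"),
    negative = c("D", "E")
  )
}

#' Five-class residue grouping for positional tests
#'
#' The coarse residue-type partition used by the alignment-column
#' association tests: aliphatic (A, G, V, L, I, M, C, P), aromatic
#' (F, W, Y, H), positive (R, K), negative (D, E) and polar (N, Q, S, T).
#' The five classes partition the 20 canonical residues exactly; this is
#' verified every time the table is constructed.
#'
#' @return Named character vector mapping each residue to its class name.
#' @export
msa_residue_classes <- function() {
  m <- c(
    A = "aliphatic", G = "aliphatic", V = "aliphatic", L = "aliphatic",
    I = "aliphatic", M = "aliphatic", C = "aliphatic", P = "aliphatic",
    F = "aromatic", W = "aromatic", Y = "aromatic", H = "aromatic",
    R = "positive", K = "positive",
    D = "negative", E = "negative",
    N = "polar", Q = "polar", S = "polar", T = "polar"
  )
  stopifnot(setequal(names(m), amino_acids()), !anyDuplicated(names(m)))
  m
}

#' Per-residue physical constant tables
#'
#' Constants used by the physicochemical features:
#' \describe{
#'   \item{max_asa}{theoretical maximum solvent-accessible surface area per
#'     residue, in square Angstroms (Tien et al. theoretical scale).}
#'   \item{heat_capacity}{partial molar heat capacity per residue,
#'     cal mol^-1 K^-1 (Hutchens-type scale).}
#'   \item{mass}{average residue mass in Da (monomer mass minus water).}
#'   \item{water_mass}{mass of one water molecule, added once per chain.}
#'   \item{pka}{dissociation constants of the ionizable groups used by the
#'     isoelectric-point calculation: both termini plus D, E, C, Y, H, K, R
#'     side chains (EMBOSS-style values).}
#' }
#'
#' All tables are plain R objects; users may supply modified copies to the
#' feature functions. The absolute scale of max_asa and heat_capacity does
#' not affect classification after feature standardization.
#'
#' @return Named list with elements `max_asa`, `heat_capacity`, `mass`,
#'   `water_mass`, `pka`.
#' @export
feature_constants <- function() {
  list(
    max_asa = c(
      A = 129, C = 167, D = 193, E = 223, F = 240, G = 104, H = 224,
      I = 197, K = 236, L = 201, M = 224, N = 195, P = 159, Q = 225,
      R = 274, S = 155, T = 172, V = 174, W = 285, Y = 263
    ),
    heat_capacity = c(
      A = 29.22, C = 50.70, D = 37.09, E = 41.84, F = 48.52, G = 23.71,
      H = 59.64, I = 45.00, K = 57.10, L = 48.03, M = 69.32, N = 38.30,
      P = 36.13, Q = 44.02, R = 26.37, S = 32.40, T = 35.20, V = 40.35,
      W = 56.92, Y = 51.73
    ),
    mass = c(
      A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
      G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
      M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
      S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
    ),
    water_mass = 18.0153,
    pka = c(
      Nterm = 8.6, Cterm = 3.6,
      D = 3.9, E = 4.1, C = 8.5, Y = 10.1, H = 6.5, K = 10.8, R = 12.5
    )
  )
}

#' Background amino-acid frequencies
#'
#' SwissProt-like background residue frequencies used as the default by the
#' synthetic-sequence generator and by the profile-HMM background model when
#' a non-uniform null is requested.
#'
#' @return Named numeric vector over the 20 canonical residues, summing to 1.
#' @export
background_frequencies <- function() {
  f <- c(
    A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
    G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
    M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
    S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292
  )
  f / sum(f)
}
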