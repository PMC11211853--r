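# Monoisotopic residue masses (Da), water and proton. The residue table is the
# standard 20-letter monoisotopic set; modification deltas supplied in search
# configurations are added on top of these.
AA_MASS <- c(
  G = 57.02146372, A = 71.03711381, S = 87.03202841, P = 97.05276385,
  V = 99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

MASS_WATER  <- 18.0105646863
MASS_PROTON <- 1.00727646688
MASS_CO     <- 27.99491462
MASS_NH3    <- 17.02654910
MASS_H2O    <- 18.01056468

AMBIGUOUS_RESIDUES <- c("B", "Z", "X", "U", "O")

#' Tokenize a modified peptide string
#'
#' Peptides are represented throughout the package as modified sequence
#' strings: residue letters with bracketed mass deltas, e.g.
#' \code{"AC[+57.02146]M[+15.994915]K"}, optionally prefixed by an N-terminal
#' modification token written \code{"[+42.010565]-"}. Each modified residue is
#' a distinct token, as in an autoregressive sequence model's vocabulary; an
#' N-terminal modification is its own prefix token.
#'
#' @param peptide a modified peptide string.
#' @return a list with \code{tokens} (character vector) and \code{masses}
#'   (numeric vector, one monoisotopic mass per token; the N-terminal token's
#'   mass is its delta alone).
#' @export
tokenize_peptide <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  tokens <- character(0)
  masses <- numeric(0)
  rest <- peptide
  m <- regmatches(rest, regexec("^\\[([+-][0-9.]+)\\]-", rest))[[1]]
  if (length(m)) {
    tokens <- m[1]
    masses <- as.numeric(m[2])
    rest <- substring(rest, nchar(m[1]) + 1L)
  }
  pat <- "([A-Z])(\\[[+-][0-9.]+\\])?"
  pos <- gregexpr(pat, rest)[[1]]
  parts <- regmatches(rest, gregexpr(pat, rest))[[1]]
  if (sum(nchar(parts)) != nchar(rest)) {
    stop("cannot tokenize peptide string: ", peptide)
  }
  for (p in parts) {
    res <- substring(p, 1L, 1L)
    if (!res %in% names(AA_MASS)) stop("unknown residue '", res, "' in ", peptide)
    delta <- 0
    if (nchar(p) > 1L) {
      delta <- as.numeric(sub("^[A-Z]\\[([+-][0-9.]+)\\]$", "\\1", p))
    }
    tokens <- c(tokens, p)
    masses <- c(masses, unname(AA_MASS[res]) + delta)
  }
  list(tokens = tokens, masses = masses)
}

#' Strip modifications from a modified peptide string
#'
#' @param peptide modified peptide string(s).
#' @return the plain residue sequence(s).
#' @export
strip_mods <- function(peptide) {
  gsub("\\[[+-][0-9.]+\\]-?", "", peptide)
}

#' Neutral monoisotopic peptide mass
#'
#' Mass is the sum of residue monoisotopic masses, all modification deltas,
#' and one water.
#'
#' @param peptide a modified peptide string (see [tokenize_peptide()]).
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")   # 75.0320 Da
#' @export
peptide_mass <- function(peptide) {
  vapply(peptide, function(p) sum(tokenize_peptide(p)$masses) + MASS_WATER,
         numeric(1), USE.NAMES = FALSE)
}

#' Neutral-mass window for a precursor
#'
#' Converts an observed precursor m/z and charge to a neutral-mass interval of
#' the given relative half-width: M = z (mz - m_proton), window
#' [M (1 - tol 1e-6), M (1 + tol 1e-6)].
#'
#' @param precursor_mz observed precursor m/z.
#' @param charge precursor charge (>= 1).
#' @param tol_ppm relative tolerance in parts per million (> 0).
#' @return numeric length-2 vector \code{c(lo, hi)} in Da.
#' @export
precursor_window <- function(precursor_mz, charge, tol_ppm) {
  stopifnot(charge >= 1, tol_ppm > 0)
  m <- charge * (precursor_mz - MASS_PROTON)
  if (m <= 0) stop("non-positive neutral mass from precursor_mz=", precursor_mz)
  c(m * (1 - tol_ppm * 1e-6), m * (1 + tol_ppm * 1e-6))
}
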