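# Physicochemical parameters of protein sequences: average molecular weight
# and theoretical isoelectric point. Mass and pKa tables are overridable so
# alternative conventions (e.g. different software vendors) can be emulated.

# Expasy average residue masses (Da); a peptide adds one water (18.0153 Da).
AA_AVERAGE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# EMBOSS pKa set: termini plus ionizable side chains.
EMBOSS_PKA <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

check_alphabet <- function(sequence, alphabet = names(AA_AVERAGE_MASS)) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a single non-empty amino-acid string")
  }
  residues <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(residues %in% alphabet))
  if (length(bad) > 0) {
    stop("non-standard residue(s) '",
         paste(unique(residues[bad]), collapse = "', '"),
         "' at position(s) ", paste(bad, collapse = ", "))
  }
  residues
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water, in kDa.
#'
#' @param sequence Amino-acid string (standard 20-letter alphabet).
#' @param mass_table Named vector of average residue masses (Da); defaults to
#'   the Expasy table.
#' @param water Mass of water (Da) added once per chain.
#' @return Molecular weight in kDa.
#' @examples
#' compute_mw("G")   # 0.0750672 kDa
#' @export
compute_mw <- function(sequence, mass_table = AA_AVERAGE_MASS,
                       water = WATER_MASS) {
  residues <- check_alphabet(sequence, names(mass_table))
  (sum(mass_table[residues]) + water) / 1000
}

net_charge <- function(residues, ph, pka) {
  counts <- table(factor(residues, levels = c("C", "D", "E", "H", "K", "R", "Y")))
  positive <- 1 / (1 + 10^(ph - pka[["Nterm"]]))
  for (aa in c("H", "K", "R")) {
    positive <- positive + counts[[aa]] / (1 + 10^(ph - pka[[aa]]))
  }
  negative <- 1 / (1 + 10^(pka[["Cterm"]] - ph))
  for (aa in c("C", "D", "E", "Y")) {
    negative <- negative + counts[[aa]] / (1 + 10^(pka[[aa]] - ph))
  }
  positive - negative
}

#' Theoretical isoelectric point of a protein sequence
#'
#' pH at which the Henderson-Hasselbalch net charge over the two termini and
#' the D, E, C, Y, H, K, R side chains is zero, located by bisection on
#' `[0, 14]`.
#'
#' @param sequence Amino-acid string.
#' @param pka Named pKa vector with entries `Nterm`, `Cterm`, `C`, `D`, `E`,
#'   `H`, `K`, `R`, `Y`; defaults to the EMBOSS set.
#' @param tol Bisection tolerance in pH units.
#' @return Isoelectric point (pH units).
#' @examples
#' compute_pi("GG")  # midpoint of the terminal pKa values (6.1 under EMBOSS)
#' @export
compute_pi <- function(sequence, pka = EMBOSS_PKA, tol = 1e-4) {
  residues <- check_alphabet(sequence)
  lo <- 0; hi <- 14
  # charge is strictly decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(residues, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
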