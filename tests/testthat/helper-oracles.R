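# Independent oracles and small constructors shared across tests.

# Exhaustive enumeration of all global alignments with affine gap costs
# (gap of length L costs open + (L-1)*extend). Plain recursion over the
# three move types, tracking only the previous move; no dynamic programming,
# so it is independent of the implementation under test. Feasible for
# sequences up to ~6 residues.
brute_force_align_score <- function(a, b, scoring) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sub <- scoring$matrix
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {
      best <- max(best, -(if (state == "X") ge else go) + rec(i + 1, j, "X"))
    }
    if (j <= length(bv)) {
      best <- max(best, -(if (state == "Y") ge else go) + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# Fixed-point solver for the hemithioacetal equilibrium, iterating
# x <- mg*gsh / (mg + gsh + kdiss - x) from zero; converges to the smaller
# quadratic root. Independent of the closed-form route under test.
fixed_point_ha <- function(mg, gsh, kdiss, tol = 1e-12, maxit = 10000) {
  C <- mg + gsh + kdiss
  x <- 0
  for (it in seq_len(maxit)) {
    x_new <- mg * gsh / (C - x)
    if (abs(x_new - x) < tol) return(x_new)
    x <- x_new
  }
  x
}

# Single-domain protein record spanning the whole sequence.
full_domain_protein <- function(sequence, id = "PROT") {
  glyi_protein(id, sequence,
               domains = data.frame(start = 1, end = nchar(sequence)))
}

# Alanine-scan substitution used to knock out planted sites.
knockout <- function(sequence, pos) {
  s <- strsplit(sequence, "")[[1]]
  s[pos] <- ifelse(s[pos] == "A", "G", "A")
  paste(s, collapse = "")
}

random_peptide <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
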