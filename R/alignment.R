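# Global pairwise alignment with affine gap penalties, used to anchor the
# conserved-site positions of a reference GLYI domain onto a candidate domain.
#
# Conventions:
#   * scores are maximized; a gap of length L costs gap_open + (L-1)*gap_extend
#   * tie-breaking during traceback is deterministic: diagonal first, then
#     gap-in-candidate (reference residue unmatched), then gap-in-reference

NEG_INF <- -1e12

#' Default alignment scoring for GLYI domain comparison
#'
#' BLOSUM62 substitution matrix (from Biostrings) with affine gap penalties.
#'
#' @param gap_open Penalty for the first residue of a gap (positive number).
#' @param gap_extend Penalty per additional gap residue.
#' @return A list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
default_scoring <- function(gap_open = 10, gap_extend = 0.5) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  list(matrix = env$BLOSUM62, gap_open = gap_open, gap_extend = gap_extend)
}

#' Simple match/mismatch scoring over an arbitrary alphabet
#'
#' Convenience scoring for tests and small alphabets.
#'
#' @param alphabet Character vector of residue letters.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Scoring list as in [default_scoring()].
#' @export
uniform_scoring <- function(alphabet, match = 1, mismatch = -1,
                            gap_open = 2, gap_extend = 0.5) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  list(matrix = m, gap_open = gap_open, gap_extend = gap_extend)
}

#' Optimal global alignment of a candidate domain against a reference domain
#'
#' Needleman-Wunsch with affine gap penalties over three dynamic-programming
#' states (match/mismatch, gap in reference, gap in candidate). Traceback
#' tie-breaking is deterministic: diagonal, then gap-in-candidate, then
#' gap-in-reference.
#'
#' @param candidate,reference Non-empty amino-acid strings.
#' @param scoring Scoring list (`matrix`, `gap_open`, `gap_extend`);
#'   defaults to BLOSUM62 with open 10 / extend 0.5.
#' @return A `glyi_alignment` list: `candidate_aligned` and
#'   `reference_aligned` (gapped strings of equal length), `score`, and
#'   `position_map` — an integer vector over reference positions giving the
#'   aligned candidate position, or `NA` where the reference residue is
#'   aligned to a gap.
#' @export
align_global <- function(candidate, reference, scoring = default_scoring()) {
  if (!nzchar(candidate) || !nzchar(reference)) {
    stop("align_global requires two non-empty sequences")
  }
  a <- strsplit(candidate, "")[[1]]   # rows (i)
  b <- strsplit(reference, "")[[1]]   # columns (j)
  n <- length(a); m <- length(b)
  sub <- scoring$matrix
  missing_letters <- setdiff(unique(c(a, b)), rownames(sub))
  if (length(missing_letters) > 0) {
    stop("letters absent from scoring matrix: ",
         paste(missing_letters, collapse = ", "))
  }
  go <- scoring$gap_open; ge <- scoring$gap_extend
  gap_cost <- function(L) go + (L - 1) * ge

  # state matrices: M diagonal, X gap-in-reference (consumes candidate),
  # Y gap-in-candidate (consumes reference)
  M <- matrix(NEG_INF, n + 1, m + 1)
  X <- matrix(NEG_INF, n + 1, m + 1)
  Y <- matrix(NEG_INF, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) X[2:(n + 1), 1] <- -gap_cost(1:n)
  if (m >= 1) Y[1, 2:(m + 1)] <- -gap_cost(1:m)

  for (i in 2:(n + 1)) {
    si <- sub[a[i - 1], ]
    for (j in 2:(m + 1)) {
      M[i, j] <- si[b[j - 1]] + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                    Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge, Y[i - 1, j] - go)
      Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge, X[i, j - 1] - go)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  # traceback; preference order encodes the documented tie-break
  state_at <- function(i, j, target) {
    vals <- c(M = M[i, j], Y = Y[i, j], X = X[i, j])
    names(vals)[which(abs(vals - target) < 1e-9)][1]
  }
  eps <- 1e-9
  i <- n + 1; j <- m + 1
  state <- state_at(i, j, score)
  al_a <- character(0); al_b <- character(0)
  pmap <- rep(NA_integer_, m)
  while (i > 1 || j > 1) {
    if (state == "M") {
      al_a <- c(a[i - 1], al_a); al_b <- c(b[j - 1], al_b)
      pmap[j - 1] <- i - 1L
      prev <- M[i, j] - sub[a[i - 1], b[j - 1]]
      i <- i - 1; j <- j - 1
      if (i == 1 && j == 1) break
      state <- state_at(i, j, prev)
    } else if (state == "Y") {          # gap in candidate, consumes reference
      al_a <- c("-", al_a); al_b <- c(b[j - 1], al_b)
      opts <- c(M = M[i, j - 1] - go, Y = Y[i, j - 1] - ge,
                X = X[i, j - 1] - go)
      state <- names(opts)[which(abs(opts - Y[i, j]) < eps)][1]
      j <- j - 1
    } else {                            # X: gap in reference, consumes candidate
      al_a <- c(a[i - 1], al_a); al_b <- c("-", al_b)
      opts <- c(M = M[i - 1, j] - go, Y = Y[i - 1, j] - go,
                X = X[i - 1, j] - ge)
      state <- names(opts)[which(abs(opts - X[i, j]) < eps)][1]
      i <- i - 1
    }
  }
  structure(list(
    candidate_aligned = paste(al_a, collapse = ""),
    reference_aligned = paste(al_b, collapse = ""),
    score = score,
    position_map = pmap
  ), class = "glyi_alignment")
}

#' Map reference conserved-site positions through an alignment
#'
#' For each conserved-site position of a reference profile, reports the
#' aligned candidate position and the residue observed there, or records that
#' the site column carries a gap in the candidate.
#'
#' @param alignment A `glyi_alignment` whose reference side is
#'   `profile$domain_sequence`.
#' @param profile A `glyi_reference_profile` (see [reference_profiles()]).
#' @return A data frame with one row per site: `site` (label), `role`
#'   (metal/gsh/dimer), `ref_pos`, `expected`, `cand_pos` (`NA` if gap),
#'   `observed` (`NA` if gap).
#' @export
map_reference_sites <- function(alignment, profile) {
  stopifnot(inherits(alignment, "glyi_alignment"))
  ungapped_ref <- gsub("-", "", alignment$reference_aligned, fixed = TRUE)
  if (!identical(ungapped_ref, profile$domain_sequence)) {
    stop("alignment reference side does not match the profile domain sequence")
  }
  sites <- profile$sites
  if (any(sites$ref_pos < 1 | sites$ref_pos > nchar(profile$domain_sequence))) {
    stop("site position outside the reference domain")
  }
  cand <- strsplit(gsub("-", "", alignment$candidate_aligned, fixed = TRUE),
                   "")[[1]]
  cand_pos <- alignment$position_map[sites$ref_pos]
  observed <- ifelse(is.na(cand_pos), NA_character_, cand[cand_pos])
  data.frame(
    site = sites$site, role = sites$role, ref_pos = sites$ref_pos,
    expected = sites$expected, cand_pos = cand_pos, observed = observed,
    stringsAsFactors = FALSE
  )
}
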