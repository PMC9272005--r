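# Reference GLYI domain profiles.
#
# The two canonical anchors for conserved-site checking are the Zn2+-dependent
# human enzyme (metal sites Q34, E100, H127, E173; GSH sites R38, N104; dimer
# interface G106) and the Ni2+-dependent E. coli enzyme (metal sites H5, E56,
# H74, E122). Their literature sequences are not redistributed here; instead
# the package constructs SYNTHETIC reference domains that carry the canonical
# residues at the canonical positions, embedded in fixed pseudo-random
# scaffold sequence. The Ni-type scaffold is derived from the Zn-type one by
# block insertions/deletions, so cross-profile alignment recovers the GSH and
# dimer-interface homologs exactly as it would for the real pair.

SCAFFOLD_SEED <- 104729L

with_fixed_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

make_site_table <- function(site, role, ref_pos, expected) {
  data.frame(site = site, role = role, ref_pos = ref_pos, expected = expected,
             stringsAsFactors = FALSE)
}

new_reference_profile <- function(name, metal_type, domain_sequence, sites) {
  residues <- strsplit(domain_sequence, "")[[1]]
  bad <- sites$ref_pos[residues[sites$ref_pos] != sites$expected]
  if (length(bad) > 0) {
    stop("profile ", name, ": expected residue mismatch at position(s) ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, metal_type = metal_type,
                 domain_sequence = domain_sequence, sites = sites),
            class = "glyi_reference_profile")
}

#' Synthetic reference GLYI domain profiles
#'
#' Returns the two reference profiles used for conserved-site checking: a
#' Zn-type profile (`HsGLYI_like`, 184 aa, sites Q34/R38/E100/N104/G106/
#' H127/E173) and a Ni-type profile (`EcGLYI_like`, 133 aa, metal sites
#' H5/E56/H74/E122 with GSH/dimer homologs at R9/N60/G62). Both scaffolds are
#' synthetic: deterministic pseudo-random sequence with the canonical
#' conserved residues planted at the canonical positions, the Ni-type domain
#' derived from the Zn-type by block indels so that the two are globally
#' alignable the way the real homologs are.
#'
#' @return Named list of two `glyi_reference_profile` objects, `Zn` and `Ni`.
#' @export
reference_profiles <- function() {
  alphabet <- names(AA_AVERAGE_MASS)
  zn <- with_fixed_rng(SCAFFOLD_SEED,
                       sample(alphabet, 184, replace = TRUE))
  zn_sites <- make_site_table(
    site = c("metal1", "gsh1", "metal2", "gsh2", "dimer", "metal3", "metal4"),
    role = c("metal", "gsh", "metal", "gsh", "dimer", "metal", "metal"),
    ref_pos = c(34L, 38L, 100L, 104L, 106L, 127L, 173L),
    expected = c("Q", "R", "E", "N", "G", "H", "E")
  )
  zn[zn_sites$ref_pos] <- zn_sites$expected

  # Ni-type scaffold: block-wise derivation from the Zn-type scaffold.
  # Coordinate correspondence: zn34->ni5 (Q exchanged for H), zn38->ni9,
  # zn100->ni56, zn104->ni60, zn106->ni62, zn127->ni74, zn173->ni122.
  ni <- c(zn[30:38], zn[54:100], zn[101:106], zn[116:127],
          c("G", "S"), zn[128:173], zn[174:184])
  ni[5] <- "H"
  ni_sites <- make_site_table(
    site = c("metal1", "gsh1", "metal2", "gsh2", "dimer", "metal3", "metal4"),
    role = c("metal", "gsh", "metal", "gsh", "dimer", "metal", "metal"),
    ref_pos = c(5L, 9L, 56L, 60L, 62L, 74L, 122L),
    expected = c("H", "R", "E", "N", "G", "H", "E")
  )
  ni[ni_sites$ref_pos] <- ni_sites$expected

  list(
    Zn = new_reference_profile("HsGLYI_like", "Zn",
                               paste(zn, collapse = ""), zn_sites),
    Ni = new_reference_profile("EcGLYI_like", "Ni",
                               paste(ni, collapse = ""), ni_sites)
  )
}

#' Write reference profiles and classification thresholds to a YAML rule file
#'
#' @param path Output YAML path.
#' @param profiles Profiles as returned by [reference_profiles()].
#' @param min_domain_len,zn_len_threshold Classification thresholds (aa).
#' @return `path`, invisibly.
#' @export
write_rules <- function(path, profiles = reference_profiles(),
                        min_domain_len = 100, zn_len_threshold = 140) {
  as_yaml_profile <- function(p) {
    list(name = p$name, metal_type = p$metal_type, synthetic = TRUE,
         domain_sequence = p$domain_sequence,
         sites = lapply(seq_len(nrow(p$sites)), function(i) {
           as.list(p$sites[i, , drop = FALSE])
         }))
  }
  obj <- list(
    min_domain_len = min_domain_len,
    zn_len_threshold = zn_len_threshold,
    profiles = lapply(unname(profiles), as_yaml_profile)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a YAML rule file written by [write_rules()]
#'
#' @param path YAML path.
#' @return List with `min_domain_len`, `zn_len_threshold` and `profiles`
#'   (named by metal type).
#' @export
read_rules <- function(path) {
  obj <- yaml::read_yaml(path)
  profiles <- lapply(obj$profiles, function(p) {
    sites <- do.call(rbind, lapply(p$sites, function(s) {
      data.frame(site = s$site, role = s$role,
                 ref_pos = as.integer(s$ref_pos), expected = s$expected,
                 stringsAsFactors = FALSE)
    }))
    new_reference_profile(p$name, p$metal_type, p$domain_sequence, sites)
  })
  names(profiles) <- vapply(profiles, function(p) p$metal_type, "")
  list(min_domain_len = obj$min_domain_len,
       zn_len_threshold = obj$zn_len_threshold,
       profiles = profiles)
}
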