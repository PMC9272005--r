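# Family curation: domain-length filtering, reference-anchored conserved-site
# checking, Ni2+/Zn2+ dependency and activity calls, architecture grouping,
# and localization consensus over external predictor labels.

#' Construct a protein record
#'
#' @param protein_id Identifier (variant id such as `TdGLYI-1B-4.2`).
#' @param sequence Amino-acid string, or `NA` for fixture-only records.
#' @param domains Data frame of PF00903 spans with columns `start`, `end`
#'   (1-based inclusive, aa), or with a `length` column when coordinates are
#'   unknown; zero rows mean no annotated domain.
#' @param length Protein length (aa); inferred from `sequence` when present.
#' @return A `glyi_protein` list.
#' @export
glyi_protein <- function(protein_id, sequence = NA_character_,
                         domains = data.frame(start = integer(0),
                                              end = integer(0)),
                         length = NA_integer_) {
  has_seq <- !is.na(sequence)
  if (has_seq) {
    check_alphabet(sequence)
    length <- nchar(sequence)
  }
  if (nrow(domains) > 0) {
    if (!("length" %in% names(domains)) &&
        all(c("start", "end") %in% names(domains))) {
      domains$length <- domains$end - domains$start + 1
    }
    if (all(c("start", "end") %in% names(domains))) {
      stopifnot(all(domains$start >= 1),
                all(domains$end >= domains$start))
      if (!is.na(length)) stopifnot(all(domains$end <= length))
      o <- order(domains$start)
      domains <- domains[o, , drop = FALSE]
      if (nrow(domains) > 1 &&
          any(domains$start[-1] <= domains$end[-nrow(domains)])) {
        stop("overlapping domain spans for ", protein_id)
      }
    }
  }
  structure(list(protein_id = protein_id,
                 sequence = if (has_seq) sequence else NA_character_,
                 length = length, domains = domains),
            class = "glyi_protein")
}

domain_lengths <- function(protein) {
  if (nrow(protein$domains) == 0) numeric(0) else protein$domains$length
}

#' Filter candidate GLYI proteins on domain presence and length
#'
#' A candidate is discarded when it carries no PF00903 domain
#' (`"domain absent"`) or when its longest domain is shorter than
#' `min_domain_len` (`"domain too short"`). The default threshold of 100 aa
#' separates the discarded 76-97 aa fragments from the retained >= 119 aa
#' domains.
#'
#' @param proteins Either a list of `glyi_protein` records or a
#'   `glyi_catalog` (whose `domain_aa` column holds N-terminal domain
#'   lengths, `NA` for absent).
#' @param min_domain_len Minimum functional domain length (aa).
#' @return A list with `kept` and `discarded`; `discarded` carries a
#'   `reason`. For catalog input both are data frames partitioning the rows;
#'   for list input, `kept` is a list and `discarded` a data frame of
#'   `protein_id`/`reason`.
#' @export
filter_candidates <- function(proteins, min_domain_len = 100) {
  if (inherits(proteins, "glyi_catalog") || is.data.frame(proteins)) {
    len <- proteins$domain_aa
    reason <- ifelse(is.na(len), "domain absent",
                     ifelse(len < min_domain_len, "domain too short", ""))
    kept <- proteins[reason == "", , drop = FALSE]
    discarded <- proteins[reason != "", , drop = FALSE]
    discarded$reason <- reason[reason != ""]
    return(list(kept = kept, discarded = discarded))
  }
  stopifnot(all(vapply(proteins, inherits, TRUE, "glyi_protein")))
  reason <- vapply(proteins, function(p) {
    lens <- domain_lengths(p)
    if (length(lens) == 0) "domain absent"
    else if (max(lens) < min_domain_len) "domain too short"
    else ""
  }, "")
  list(
    kept = proteins[reason == ""],
    discarded = data.frame(
      protein_id = vapply(proteins[reason != ""], function(p) p$protein_id, ""),
      reason = reason[reason != ""], stringsAsFactors = FALSE
    )
  )
}

#' Domain-architecture class of a filtered GLYI protein
#'
#' @param protein A `glyi_protein` that passed [filter_candidates()].
#' @param min_domain_len Qualifying span threshold (aa).
#' @return `"one-domain"` or `"two-domain"`; more than two qualifying spans
#'   raises an anomaly error.
#' @export
domain_architecture <- function(protein, min_domain_len = 100) {
  n <- sum(domain_lengths(protein) >= min_domain_len)
  if (n == 0) stop("no qualifying domain: ", protein$protein_id)
  if (n > 2) stop("anomalous architecture (", n, " qualifying domains): ",
                  protein$protein_id)
  c("one-domain", "two-domain")[n]
}

extract_nterminal_domain <- function(protein, min_domain_len) {
  d <- protein$domains
  if (!all(c("start", "end") %in% names(d))) {
    stop("domain coordinates unavailable for ", protein$protein_id)
  }
  d <- d[d$length >= min_domain_len, , drop = FALSE]
  if (nrow(d) == 0) stop("no qualifying domain: ", protein$protein_id)
  d <- d[which.min(d$start), ]
  substring(protein$sequence, d$start, d$end)
}

evaluate_profile <- function(domain_seq, profile, scoring, zn_len_threshold) {
  aln <- align_global(domain_seq, profile$domain_sequence, scoring)
  sites <- map_reference_sites(aln, profile)
  ok <- !is.na(sites$observed) & sites$observed == sites$expected
  # site 1 of the metal centre distinguishes the cofactor: Gln (Zn-type,
  # with a long domain) or His (Ni-type)
  site1 <- which(sites$site == "metal1")
  obs1 <- sites$observed[site1]
  dom_len <- nchar(domain_seq)
  site1_ok <- !is.na(obs1) &&
    ((obs1 == "Q" && dom_len >= zn_len_threshold) || obs1 == "H")
  ok[site1] <- site1_ok
  sites$ok <- ok
  list(
    alignment = aln, sites = sites,
    metal_ok = all(ok[sites$role == "metal"]),
    gsh_ok = all(ok[sites$role == "gsh"]),
    dimer_ok = all(ok[sites$role == "dimer"]),
    site1_residue = obs1
  )
}

#' Conserved-site check and metal-dependency call for one protein
#'
#' Aligns the N-terminal qualifying PF00903 domain against both reference
#' profiles and checks the four metal-binding sites, the two GSH-binding
#' sites and the dimer-interface glycine. A site passes only on exact residue
#' identity; the first metal site accepts Gln (Zn-type, requiring domain
#' length >= `zn_len_threshold`) or His (Ni-type). The profile whose metal
#' centre matches (or, failing both, the higher-scoring alignment) provides
#' the site mapping.
#'
#' @param protein A `glyi_protein` with sequence and domain coordinates.
#' @param profiles Profiles from [reference_profiles()].
#' @param scoring Alignment scoring; defaults to BLOSUM62, open 10, extend 0.5.
#' @param min_domain_len,zn_len_threshold Classification thresholds (aa).
#' @return A `glyi_site_check` list: `protein_id`, `checkable`,
#'   `metal_site_ok`, `gsh_site_ok`, `dimer_ok`, `active`, `predicted_metal`
#'   (`"Ni"`, `"Zn"` or `"none"`), `profile` (name used) and `detail` (per-site
#'   data frame).
#' @export
check_sites <- function(protein, profiles = reference_profiles(),
                        scoring = default_scoring(),
                        min_domain_len = 100, zn_len_threshold = 140) {
  if (is.na(protein$sequence)) {
    return(structure(list(protein_id = protein$protein_id, checkable = FALSE,
                          metal_site_ok = NA, gsh_site_ok = NA, dimer_ok = NA,
                          active = NA, predicted_metal = NA_character_,
                          profile = NA_character_, detail = NULL),
                     class = "glyi_site_check"))
  }
  domain_seq <- extract_nterminal_domain(protein, min_domain_len)
  evals <- lapply(profiles, evaluate_profile, domain_seq = domain_seq,
                  scoring = scoring, zn_len_threshold = zn_len_threshold)
  matching <- vapply(evals, function(e) e$metal_ok, TRUE)
  pick <- if (any(matching)) {
    scores <- vapply(evals, function(e) e$alignment$score, 0)
    scores[!matching] <- -Inf
    which.max(scores)
  } else {
    which.max(vapply(evals, function(e) e$alignment$score, 0))
  }
  e <- evals[[pick]]
  active <- e$metal_ok && e$gsh_ok && e$dimer_ok
  predicted <- "none"
  if (active) {
    predicted <- if (e$site1_residue == "Q") "Zn" else "Ni"
    if (predicted == "Ni" && nchar(domain_seq) >= zn_len_threshold) {
      warning(protein$protein_id, ": His metal centre but domain length ",
              nchar(domain_seq), " aa is in the Zn-type range")
    }
  }
  structure(list(protein_id = protein$protein_id, checkable = TRUE,
                 metal_site_ok = e$metal_ok, gsh_site_ok = e$gsh_ok,
                 dimer_ok = e$dimer_ok, active = active,
                 predicted_metal = predicted,
                 profile = profiles[[pick]]$name, detail = e$sites),
            class = "glyi_site_check")
}

#' Collect site-check results into a data frame
#'
#' @param checks List of `glyi_site_check` objects.
#' @return Data frame with columns `protein_id`, `metal_site_ok`,
#'   `gsh_site_ok`, `dimer_ok`, `predicted_metal`, `active`.
#' @export
site_check_table <- function(checks) {
  do.call(rbind, lapply(checks, function(x) {
    data.frame(protein_id = x$protein_id, metal_site_ok = x$metal_site_ok,
               gsh_site_ok = x$gsh_site_ok, dimer_ok = x$dimer_ok,
               predicted_metal = x$predicted_metal, active = x$active,
               stringsAsFactors = FALSE)
  }))
}

#' Load a conserved-site annotation table (Present/Absent form)
#'
#' Reads the per-protein site-check fixture (columns `protein_id`,
#' `metal_site`, `gsh_site`, `dimer`, `metal`, `active` with values
#' `Present`/`Absent` and metal `Ni`/`Zn`/`Absent`) into logical form.
#'
#' @param path TSV path; defaults to the bundled family table.
#' @return Data frame as from [site_check_table()].
#' @export
load_site_table <- function(path = system.file("extdata",
                                               "table2_site_checks.tsv",
                                               package = "glyoxalaseR")) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("protein_id", "metal_site", "gsh_site", "dimer", "metal", "active")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("site table schema error: missing ", paste(missing_cols, collapse = ", "))
  }
  as_flag <- function(x) x == "Present"
  data.frame(
    protein_id = raw$protein_id,
    metal_site_ok = as_flag(raw$metal_site),
    gsh_site_ok = as_flag(raw$gsh_site),
    dimer_ok = as_flag(raw$dimer),
    predicted_metal = ifelse(raw$metal %in% c("Ni", "Zn"), raw$metal, "none"),
    active = as_flag(raw$active),
    stringsAsFactors = FALSE
  )
}

variant_gene <- function(variant_id) sub("\\.[^.]*$", "", variant_id)

#' Family-level classification summary
#'
#' Tallies active proteins and their metal classes, and joins variant ids to
#' the catalog to count genes with at least one active product.
#'
#' @param site_results Data frame as from [site_check_table()] or
#'   [load_site_table()].
#' @param catalog Optional `glyi_catalog` for the gene join; variant ids in
#'   `site_results` must appear in `catalog$variant_id`.
#' @return A list of class `glyi_family_summary`: `n_candidates` (catalog
#'   variants, `NA` without a catalog), `n_filtered` (rows checked),
#'   `n_active`, `n_ni`, `n_zn`, `n_active_genes`.
#' @export
classify_family <- function(site_results, catalog = NULL) {
  n_active <- sum(site_results$active)
  n_ni <- sum(site_results$active & site_results$predicted_metal == "Ni")
  n_zn <- sum(site_results$active & site_results$predicted_metal == "Zn")
  stopifnot(n_active == n_ni + n_zn)
  n_active_genes <- NA_integer_
  n_candidates <- NA_integer_
  if (!is.null(catalog)) {
    unknown <- setdiff(site_results$protein_id, catalog$variant_id)
    if (length(unknown) > 0) {
      stop("site results reference unknown protein id(s): ",
           paste(unknown, collapse = ", "))
    }
    n_candidates <- nrow(catalog)
    active_ids <- site_results$protein_id[site_results$active]
    n_active_genes <- length(unique(variant_gene(active_ids)))
  }
  structure(list(n_candidates = n_candidates,
                 n_filtered = nrow(site_results),
                 n_active = n_active, n_ni = n_ni, n_zn = n_zn,
                 n_active_genes = n_active_genes),
            class = "glyi_family_summary")
}

#' @export
print.glyi_family_summary <- function(x, ...) {
  cat("GLYI family classification\n")
  cat(sprintf("  checked: %d  active: %d (Ni %d, Zn %d)\n",
              x$n_filtered, x$n_active, x$n_ni, x$n_zn))
  if (!is.na(x$n_active_genes)) {
    cat(sprintf("  genes with >=1 active product: %d\n", x$n_active_genes))
  }
  invisible(x)
}

LOCALIZATION_TOKENS <- c("Cyt", "C", "M", "-")

#' Subcellular-localization consensus over external predictor labels
#'
#' Consumes per-variant labels from one or more prediction tools (vocabulary
#' `Cyt` cytoplasm, `C` chloroplast, `M` mitochondrion, `-` no call;
#' multi-label cells such as `C/M` split on `/`). A variant *supports* an
#' organelle when any tool lists it. A variant counts as unambiguously
#' organellar when some tool supports C or M and no tool predicts Cyt;
#' per-gene organellar counts use that stricter rule, which reproduces the
#' published per-gene variant counts (mixed organellar/cytosolic variants are
#' set aside as ambiguous).
#'
#' @param labels Data frame: `protein_id` plus one column per tool.
#' @return List with `variants` (per-variant `supports_c`, `supports_m`,
#'   `supports_cyt`, `organellar`) and `per_gene` (gene, `n_variants`,
#'   `n_organellar`).
#' @export
localization_consensus <- function(labels) {
  stopifnot("protein_id" %in% names(labels))
  tools <- setdiff(names(labels), "protein_id")
  if (length(tools) == 0) stop("no predictor columns")
  tokens_by_variant <- lapply(seq_len(nrow(labels)), function(i) {
    toks <- unlist(strsplit(unlist(labels[i, tools], use.names = FALSE), "/",
                            fixed = TRUE))
    toks <- trimws(toks)
    bad <- setdiff(toks, LOCALIZATION_TOKENS)
    if (length(bad) > 0) {
      stop("unknown localization label '", paste(bad, collapse = "', '"),
           "' for ", labels$protein_id[i])
    }
    toks
  })
  supports_c <- vapply(tokens_by_variant, function(t) "C" %in% t, TRUE)
  supports_m <- vapply(tokens_by_variant, function(t) "M" %in% t, TRUE)
  supports_cyt <- vapply(tokens_by_variant, function(t) "Cyt" %in% t, TRUE)
  variants <- data.frame(
    protein_id = labels$protein_id,
    supports_c = supports_c, supports_m = supports_m,
    supports_cyt = supports_cyt,
    organellar = (supports_c | supports_m) & !supports_cyt,
    stringsAsFactors = FALSE
  )
  gene <- variant_gene(variants$protein_id)
  per_gene <- data.frame(
    gene_id = unique(gene),
    n_variants = as.vector(table(gene)[unique(gene)]),
    n_organellar = vapply(unique(gene), function(g) {
      sum(variants$organellar[gene == g])
    }, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(variants = variants, per_gene = per_gene)
}

#' Load a localization-prediction fixture
#'
#' @param path TSV with `protein_id` plus tool columns; defaults to the
#'   bundled table of predictions for the active variants.
#' @return Data frame suitable for [localization_consensus()].
#' @export
load_localization_table <- function(path = system.file(
  "extdata", "table3_localization.tsv", package = "glyoxalaseR")) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
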