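CATALOG_COLUMNS <- c(
  "chromosome", "gene_id", "ensembl_gene", "location", "transcript_id",
  "cds_bp", "exons", "protein_aa", "mw_kda", "pi", "domain_aa"
)

#' Load a GLYI gene/transcript/protein catalog from TSV
#'
#' Reads a tab-separated catalog in long format (one row per transcript;
#' gene-level columns repeated) into a `glyi_catalog` object. Coordinates in
#' the `location` column are `start-end`, 1-based inclusive. The
#' `domain_aa` column holds the length (aa) of the N-terminal PF00903 domain,
#' or `"Absent"` when no glyoxalase domain is annotated.
#'
#' @param path Path to a TSV file with columns `chromosome`, `gene_id`,
#'   `ensembl_gene`, `location`, `transcript_id`, `cds_bp`, `exons`,
#'   `protein_aa`, `mw_kda`, `pi`, `domain_aa`.
#' @return A `glyi_catalog`: a data frame (one row per transcript) with parsed
#'   `gene_start`/`gene_end`, `subgenome`, `variant_id` (gene id plus splice
#'   index, e.g. `TdGLYI-1A-1.2`) and numeric `domain_aa` (`NA` when absent).
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("catalog schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$transcript_id)) {
    dup <- unique(raw$transcript_id[duplicated(raw$transcript_id)])
    stop("duplicate transcript_id: ", paste(dup, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    out <- data.frame(
      chromosome = character(0), gene_id = character(0),
      ensembl_gene = character(0), gene_start = numeric(0),
      gene_end = numeric(0), subgenome = character(0),
      transcript_id = character(0), variant_id = character(0),
      cds_bp = integer(0), exons = integer(0), protein_aa = integer(0),
      mw_kda = numeric(0), pi = numeric(0), domain_aa = numeric(0),
      mw_kda_raw = character(0), pi_raw = character(0),
      domain_aa_raw = character(0), stringsAsFactors = FALSE
    )
    class(out) <- c("glyi_catalog", "data.frame")
    return(out)
  }
  bad <- integer(0)
  loc <- strsplit(raw$location, "-", fixed = TRUE)
  gene_start <- suppressWarnings(as.numeric(vapply(loc, `[`, "", 1L)))
  gene_end <- suppressWarnings(as.numeric(vapply(loc, `[`, "", 2L)))
  cds_bp <- suppressWarnings(as.integer(raw$cds_bp))
  exons <- suppressWarnings(as.integer(raw$exons))
  protein_aa <- suppressWarnings(as.integer(raw$protein_aa))
  domain_absent <- tolower(trimws(raw$domain_aa)) %in% c("absent", "-", "")
  domain_aa <- suppressWarnings(as.numeric(raw$domain_aa))
  domain_aa[domain_absent] <- NA_real_
  for (i in seq_len(nrow(raw))) {
    ok <- !is.na(gene_start[i]) && !is.na(gene_end[i]) &&
      gene_start[i] <= gene_end[i] &&
      !is.na(cds_bp[i]) && cds_bp[i] >= 3 && cds_bp[i] %% 3 == 0 &&
      !is.na(exons[i]) && exons[i] >= 1 &&
      !is.na(protein_aa[i]) && protein_aa[i] >= 1 &&
      (domain_absent[i] || (!is.na(domain_aa[i]) && domain_aa[i] >= 1))
    if (!ok) bad <- c(bad, i)
  }
  if (length(bad) > 0) {
    stop("malformed catalog row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  out <- data.frame(
    chromosome = raw$chromosome,
    gene_id = raw$gene_id,
    ensembl_gene = raw$ensembl_gene,
    gene_start = gene_start,
    gene_end = gene_end,
    subgenome = substring(raw$chromosome, nchar(raw$chromosome)),
    transcript_id = raw$transcript_id,
    variant_id = paste0(raw$gene_id, ".", sub("^.*\\.", "", raw$transcript_id)),
    cds_bp = cds_bp,
    exons = exons,
    protein_aa = protein_aa,
    mw_kda = suppressWarnings(as.numeric(raw$mw_kda)),
    pi = suppressWarnings(as.numeric(raw$pi)),
    domain_aa = domain_aa,
    # verbatim source strings, so write_catalog() round-trips byte-identically
    mw_kda_raw = raw$mw_kda,
    pi_raw = raw$pi,
    domain_aa_raw = raw$domain_aa,
    stringsAsFactors = FALSE
  )
  # Stop codon bookkeeping: CDS encodes the protein plus one stop codon
  inconsistent <- which(out$protein_aa != out$cds_bp / 3 - 1)
  if (length(inconsistent) > 0) {
    warning("protein length != cds/3 - 1 for transcript(s): ",
            paste(out$transcript_id[inconsistent], collapse = ", "))
  }
  class(out) <- c("glyi_catalog", "data.frame")
  out
}

#' Write a catalog back to its canonical TSV form
#'
#' Inverse of [load_catalog()]; round-trips byte-identically for canonical
#' fixtures (location re-joined as `start-end`, absent domains written as
#' `Absent`).
#'
#' @param catalog A `glyi_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "glyi_catalog"))
  fmt_num <- function(x) sub("\\.?0+$", "", formatC(x, format = "f", digits = 6))
  out <- data.frame(
    chromosome = catalog$chromosome,
    gene_id = catalog$gene_id,
    ensembl_gene = catalog$ensembl_gene,
    location = paste0(format(catalog$gene_start, scientific = FALSE, trim = TRUE),
                      "-",
                      format(catalog$gene_end, scientific = FALSE, trim = TRUE)),
    transcript_id = catalog$transcript_id,
    cds_bp = catalog$cds_bp,
    exons = catalog$exons,
    protein_aa = catalog$protein_aa,
    mw_kda = if ("mw_kda_raw" %in% names(catalog)) catalog$mw_kda_raw
             else fmt_num(catalog$mw_kda),
    pi = if ("pi_raw" %in% names(catalog)) catalog$pi_raw
         else fmt_num(catalog$pi),
    domain_aa = if ("domain_aa_raw" %in% names(catalog)) catalog$domain_aa_raw
                else ifelse(is.na(catalog$domain_aa), "Absent",
                            fmt_num(catalog$domain_aa)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistics for a GLYI catalog
#'
#' Tallies genes, transcripts, multi-splice genes (strictly more than one
#' transcript), per-chromosome and per-subgenome gene counts, and CDS-length
#' statistics over all transcripts.
#'
#' @param catalog A `glyi_catalog` from [load_catalog()].
#' @return A list of class `glyi_catalog_summary` with elements `n_genes`,
#'   `n_transcripts`, `n_multi_splice_genes`, `per_chromosome`,
#'   `per_subgenome`, `cds_min`, `cds_max`, `cds_mean` (exact),
#'   `cds_mean_rounded` (nearest integer) and `empty` flag.
#' @export
summarize_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "glyi_catalog"))
  if (nrow(catalog) == 0) {
    return(structure(list(
      n_genes = 0L, n_transcripts = 0L, n_multi_splice_genes = 0L,
      per_chromosome = integer(0), per_subgenome = integer(0),
      cds_min = NA_integer_, cds_max = NA_integer_, cds_mean = NA_real_,
      cds_mean_rounded = NA_integer_, empty = TRUE
    ), class = "glyi_catalog_summary"))
  }
  per_gene <- table(catalog$gene_id)
  gene_rows <- catalog[!duplicated(catalog$gene_id), ]
  structure(list(
    n_genes = length(per_gene),
    n_transcripts = nrow(catalog),
    n_multi_splice_genes = sum(per_gene > 1),
    per_chromosome = table(gene_rows$chromosome),
    per_subgenome = table(gene_rows$subgenome),
    cds_min = min(catalog$cds_bp),
    cds_max = max(catalog$cds_bp),
    cds_mean = mean(catalog$cds_bp),
    cds_mean_rounded = as.integer(round(mean(catalog$cds_bp))),
    empty = FALSE
  ), class = "glyi_catalog_summary")
}

#' @export
print.glyi_catalog_summary <- function(x, ...) {
  cat("GLYI catalog summary\n")
  cat(sprintf("  genes: %d  transcripts: %d  multi-splice genes: %d\n",
              x$n_genes, x$n_transcripts, x$n_multi_splice_genes))
  if (!x$empty) {
    cat("  subgenomes:",
        paste(sprintf("%s=%d", names(x$per_subgenome), x$per_subgenome),
              collapse = "  "), "\n")
    cat(sprintf("  CDS (bp): min %d, max %d, mean %.1f (~%d)\n",
                x$cds_min, x$cds_max, x$cds_mean, x$cds_mean_rounded))
  }
  invisible(x)
}
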