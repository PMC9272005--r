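# Seeded generators producing inputs with the structure every pipeline stage
# assumes: GLYI-domain protein families with planted/perturbed conserved
# sites, kinetics datasets on the mitochondrial assay designs, and Ct tables
# emulating the qPCR experiment layout. Each generator uses one RNG stream
# derived from its `seed` argument and returns its ground truth alongside
# the data.

#' Ground-truth kinetic parameters of the mitochondrial GLYI activity
#'
#' Vmax 0.519 umol min^-1 mg^-1, Km 0.092 mM (92 uM), competitive GSH
#' inhibition with Ki 6.5 mM.
#'
#' @return List with `vmax`, `km`, `ki`.
#' @export
dwm_glyi_params <- function() list(vmax = 0.519, km = 0.092, ki = 6.5)

#' Substrate design of the saturation-kinetics assay
#'
#' Twelve hemithioacetal concentrations spanning 0.025-1 mM, bracketing the
#' 92 uM Michaelis constant.
#'
#' @return Numeric vector (mM).
#' @export
mm_design <- function() {
  c(0.025, 0.05, 0.075, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.65, 0.8, 1)
}

#' Substrate x inhibitor design of the Dixon inhibition assay
#'
#' HA at 0.1, 0.25, 0.5 and 1 mM crossed with free GSH at 0.2, 1, 5, 10 and
#' 15 mM.
#'
#' @return Data frame with columns `S` and `I` (mM).
#' @export
dixon_design <- function() {
  expand.grid(S = c(0.1, 0.25, 0.5, 1), I = c(0.2, 1, 5, 10, 15),
              KEEP.OUT.ATTRS = FALSE)
}

#' Generate a synthetic kinetics dataset from known parameters
#'
#' Rates follow the competitive-inhibition model (plain Michaelis-Menten when
#' all inhibitor concentrations are zero and no `ki` is supplied) with
#' additive Gaussian noise of standard deviation `noise_sigma * vmax`,
#' truncated at zero.
#'
#' @param params List with `vmax`, `km` and optionally `ki` (required when
#'   any `I > 0`).
#' @param S Substrate concentrations (mM).
#' @param I Inhibitor concentrations (mM), recycled against `S`.
#' @param noise_sigma Noise level as a fraction of `vmax` (>= 0).
#' @param seed Integer seed.
#' @param replicates Technical replicates per design point.
#' @return List: `data` (a `glyi_kinetics`), `truth` (params, noise level,
#'   seed).
#' @export
make_kinetics <- function(params, S, I = 0, noise_sigma = 0, seed = 1,
                          replicates = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  stopifnot(length(S) >= 1)
  design <- data.frame(S = S, I = I)
  design <- design[rep(seq_len(nrow(design)), each = replicates), ]
  v_true <- if (any(design$I > 0)) {
    competitive_rate(params, design$S, design$I)
  } else {
    mm_rate(params, design$S)
  }
  set.seed(seed)
  v <- pmax(v_true + stats::rnorm(length(v_true), 0, noise_sigma * params$vmax), 0)
  list(
    data = kinetics_dataset(design$S, v, design$I,
                            replicate = rep(seq_len(replicates),
                                            times = nrow(design) / replicates)),
    truth = list(params = params, noise_sigma = noise_sigma, seed = seed)
  )
}

mutate_residue <- function(residues, pos) {
  # alanine scan; fall back to glycine if the site already holds alanine
  residues[pos] <- ifelse(residues[pos] == "A", "G", "A")
  residues
}

#' Generate a synthetic GLYI protein family with known ground truth
#'
#' Builds proteins by embedding a reference GLYI domain (Zn- or Ni-type
#' synthetic scaffold) into random flanking sequence. Active proteins keep
#' every conserved site intact; inactive proteins receive 1-7 planted
#' alanine substitutions at conserved sites, or a domain truncated below the
#' functional length. A fraction of proteins carry a second, C-terminal
#' domain copy whose first metal site is degenerate (the architecture seen
#' for two-domain plant GLYI, whose C-terminal domain is non-functional);
#' classification must rely on the N-terminal domain only.
#'
#' @param n Number of proteins (>= 1).
#' @param fraction_active Fraction of active proteins (exact count
#'   `round(n * fraction_active)`).
#' @param ni_fraction Probability that an active protein is Ni-type
#'   (default 23/28, the family's observed Ni share).
#' @param two_domain_fraction Probability of the two-domain architecture
#'   (default 17/28, the observed share among active variants).
#' @param seed Integer seed.
#' @return List: `proteins` (list of `glyi_protein`), `truth` (data frame
#'   with `protein_id`, `active`, `metal`, `n_mutations`, `truncated`,
#'   `architecture`).
#' @export
make_protein_family <- function(n, fraction_active = 0.5,
                                ni_fraction = 23 / 28,
                                two_domain_fraction = 17 / 28,
                                seed = 1) {
  stopifnot(n >= 1)
  profiles <- reference_profiles()
  alphabet <- names(AA_AVERAGE_MASS)
  set.seed(seed)
  n_active <- round(n * fraction_active)
  is_active <- rep(c(TRUE, FALSE), c(n_active, n - n_active))
  proteins <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    metal <- if (stats::runif(1) < ni_fraction) "Ni" else "Zn"
    profile <- profiles[[metal]]
    dom <- strsplit(profile$domain_sequence, "")[[1]]
    n_mut <- 0L
    truncated <- FALSE
    if (!is_active[i]) {
      if (stats::runif(1) < 0.3) {
        truncated <- TRUE
        dom <- dom[seq_len(sample(60:99, 1))]
      } else {
        n_mut <- sample(1:7, 1)
        pos <- sample(profile$sites$ref_pos, n_mut)
        dom <- mutate_residue(dom, pos)
      }
    }
    two_domain <- stats::runif(1) < two_domain_fraction && !truncated
    flank_n <- sample(5:40, 1)
    flank_c <- sample(5:40, 1)
    seq_parts <- c(sample(alphabet, flank_n, replace = TRUE), dom)
    d_start <- flank_n + 1L
    spans <- data.frame(start = d_start, end = d_start + length(dom) - 1L)
    if (two_domain) {
      linker <- sample(10:25, 1)
      cdom <- strsplit(profile$domain_sequence, "")[[1]]
      cdom <- mutate_residue(cdom, profile$sites$ref_pos[1])  # degenerate site
      seq_parts <- c(seq_parts, sample(alphabet, linker, replace = TRUE), cdom)
      c_start <- spans$end[1] + linker + 1L
      spans <- rbind(spans,
                     data.frame(start = c_start,
                                end = c_start + length(cdom) - 1L))
    }
    seq_parts <- c(seq_parts, sample(alphabet, flank_c, replace = TRUE))
    pid <- sprintf("SYNGLYI-%03d", i)
    proteins[[i]] <- glyi_protein(pid, paste(seq_parts, collapse = ""),
                                  domains = spans)
    truth[[i]] <- data.frame(
      protein_id = pid, active = is_active[i],
      metal = if (is_active[i]) metal else "none",
      n_mutations = n_mut, truncated = truncated,
      architecture = if (two_domain) "two-domain" else "one-domain",
      stringsAsFactors = FALSE
    )
  }
  list(proteins = proteins, truth = do.call(rbind, truth))
}

#' Write a synthetic family (or any protein records) to FASTA
#'
#' Standard FASTA wrapped at 60 columns, record ids = protein ids.
#'
#' @param proteins List of `glyi_protein` records with sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteins, function(p) p$sequence, ""))
  names(seqs) <- vapply(proteins, function(p) p$protein_id, "")
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Generate a synthetic Ct table with planted log2 expression effects
#'
#' Emulates the qPCR layout: target genes x conditions x tissues x
#' biological replicates, normalized against reference genes. Each gene gets
#' a baseline Ct drawn uniformly in [18, 30] cycles; a planted log2 effect
#' lowers the target Ct by that many cycles (one cycle per doubling);
#' biological replicates share a per-sample plate shift applied to every
#' gene of the sample (which the delta-delta-Ct normalization must cancel);
#' technical replicates add Gaussian Ct noise.
#'
#' @param genes Character vector of target gene ids.
#' @param conditions Condition labels; the first is the calibrator with zero
#'   effect.
#' @param tissues Tissue labels.
#' @param effects Data frame `gene_id`, `condition`, `tissue`, `log2_effect`
#'   (unlisted combinations default to 0). Effects on reference genes are a
#'   contract error.
#' @param ref_genes Reference gene ids (planted with zero effect).
#' @param ct_sd Technical Ct noise (cycles).
#' @param n_bio,n_tech Biological and technical replicates.
#' @param seed Integer seed.
#' @return List: `table` (a `glyi_ct_table`), `truth` (the effects grid with
#'   zeros filled in).
#' @export
make_ct_table <- function(genes,
                          conditions = c("control", "NaCl", "mannitol"),
                          tissues = c("shoot", "root"),
                          effects = NULL,
                          ref_genes = c("CDC", "RLI"),
                          ct_sd = 0.15, n_bio = 3, n_tech = 3, seed = 1) {
  if (!is.null(effects) && any(effects$gene_id %in% ref_genes)) {
    stop("effects planted on reference gene(s): ",
         paste(intersect(effects$gene_id, ref_genes), collapse = ", "))
  }
  grid <- expand.grid(gene_id = genes, condition = conditions,
                      tissue = tissues, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$log2_effect <- 0
  if (!is.null(effects)) {
    key <- function(d) paste(d$gene_id, d$condition, d$tissue)
    idx <- match(key(grid), key(effects))
    grid$log2_effect[!is.na(idx)] <- effects$log2_effect[idx[!is.na(idx)]]
  }
  if (any(grid$log2_effect[grid$condition == conditions[1]] != 0)) {
    stop("calibrator condition must carry zero effect")
  }
  set.seed(seed)
  all_genes <- c(ref_genes, genes)
  baseline <- stats::setNames(stats::runif(length(all_genes), 18, 30), all_genes)
  rows <- list()
  for (tis in tissues) for (cond in conditions) for (b in seq_len(n_bio)) {
    sample_id <- paste(cond, tis, b, sep = "_")
    plate_shift <- stats::rnorm(1, 0, 0.5)
    for (g in all_genes) {
      eff <- if (g %in% ref_genes) 0 else
        grid$log2_effect[grid$gene_id == g & grid$condition == cond &
                           grid$tissue == tis]
      ct <- baseline[[g]] - eff + plate_shift +
        stats::rnorm(n_tech, 0, ct_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, condition = cond, tissue = tis, gene_id = g,
        ct = ct, replicate = seq_len(n_tech), stringsAsFactors = FALSE
      )
    }
  }
  list(table = ct_table(do.call(rbind, rows), ref_genes = ref_genes),
       truth = grid)
}

#' Paths of the bundled family tables
#'
#' The catalog of candidate genes/transcripts, the per-protein conserved-site
#' annotation, and the per-variant localization predictions, shipped as
#' canonical TSV fixtures.
#'
#' @return Named list of file paths: `catalog`, `sites`, `localization`.
#' @export
table_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "glyoxalaseR")
    if (!nzchar(p)) stop("bundled fixture not found: ", f)
    p
  }
  list(catalog = path("table1_glyi_catalog.tsv"),
       sites = path("table2_site_checks.tsv"),
       localization = path("table3_localization.tsv"))
}
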