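# Relative qPCR quantification by 2^(-ddCt) with multiple reference genes,
# and the accompanying group-comparison statistics (t-test, one/two-factor
# ANOVA with Duncan's multiple range grouping).

#' Assemble a Ct table
#'
#' @param data Data frame with columns `sample_id`, `condition`, `tissue`,
#'   `gene_id`, `ct`, `replicate` (technical replicate index).
#' @param ref_genes Character vector of reference genes (default the two
#'   wheat references `CDC` and `RLI`), which must be measured in every
#'   sample.
#' @return A `glyi_ct_table` data frame with the reference set attached as an
#'   attribute.
#' @export
ct_table <- function(data, ref_genes = c("CDC", "RLI")) {
  needed <- c("sample_id", "condition", "tissue", "gene_id", "ct", "replicate")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("Ct table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(data$ct > 0))
  for (s in unique(data$sample_id)) {
    present <- unique(data$gene_id[data$sample_id == s])
    absent <- setdiff(ref_genes, present)
    if (length(absent) > 0) {
      stop("sample ", s, " lacks reference gene(s): ",
           paste(absent, collapse = ", "))
    }
  }
  attr(data, "ref_genes") <- ref_genes
  class(data) <- c("glyi_ct_table", "data.frame")
  data
}

#' Relative expression by the 2^(-ddCt) method
#'
#' Technical replicates are averaged per (sample, gene); each sample's
#' delta-Ct is `Ct_target - mean(Ct_references)` (arithmetic mean of
#' reference Cts, i.e. geometric mean normalization on the linear scale);
#' delta-delta-Ct subtracts the mean delta-Ct of the calibrator group, so the
#' calibrator's geometric-mean fold is exactly 1 by construction (the
#' arithmetic mean of folds exceeds 1 under replicate noise, as for any
#' log-normal quantity). Fold change is `2^(-ddCt)` (amplification
#' efficiency fixed at 2).
#'
#' @param table A `glyi_ct_table`.
#' @param calibrator_condition,calibrator_tissue Define the calibrator group;
#'   `calibrator_tissue = NULL` calibrates within each tissue separately
#'   (each tissue's own group at `calibrator_condition` is the reference).
#' @return Data frame: one row per biological sample x target gene with
#'   `dct`, `ddct`, `fold`, `log2_fold`.
#' @export
delta_delta_ct <- function(table, calibrator_condition,
                           calibrator_tissue = NULL) {
  stopifnot(inherits(table, "glyi_ct_table"))
  refs <- attr(table, "ref_genes")
  # average technical replicates
  agg <- stats::aggregate(ct ~ sample_id + condition + tissue + gene_id,
                          data = table, FUN = mean)
  samples <- unique(agg[, c("sample_id", "condition", "tissue")])
  ref_ct <- vapply(samples$sample_id, function(s) {
    mean(agg$ct[agg$sample_id == s & agg$gene_id %in% refs])
  }, 0)
  targets <- agg[!(agg$gene_id %in% refs), , drop = FALSE]
  targets$dct <- targets$ct - ref_ct[match(targets$sample_id, samples$sample_id)]
  out <- do.call(rbind, lapply(split(targets, targets$gene_id), function(g) {
    cal <- g$condition == calibrator_condition
    if (!is.null(calibrator_tissue)) cal <- cal & g$tissue == calibrator_tissue
    if (!any(cal)) {
      stop("calibrator group absent for gene ", g$gene_id[1])
    }
    if (is.null(calibrator_tissue)) {
      # per-tissue calibration
      g$ddct <- NA_real_
      for (tis in unique(g$tissue)) {
        sel <- g$tissue == tis
        base <- mean(g$dct[sel & cal])
        if (is.nan(base)) stop("calibrator group absent for gene ",
                               g$gene_id[1], " in tissue ", tis)
        g$ddct[sel] <- g$dct[sel] - base
      }
    } else {
      g$ddct <- g$dct - mean(g$dct[cal])
    }
    g
  }))
  out$fold <- 2^(-out$ddct)
  out$log2_fold <- -out$ddct
  rownames(out) <- NULL
  out[order(out$gene_id, out$tissue, out$condition, out$sample_id), ]
}

# Duncan's multiple range test critical value: studentized-range quantile at
# the protected level alpha_p = 1 - (1-alpha)^(p-1) for a span of p means.
duncan_critical <- function(p, df, alpha) {
  stats::qtukey(1 - (1 - (1 - alpha)^(p - 1)), nmeans = p, df = df)
}

# Compact letter display over means sorted descending. Following the
# multiple-range procedure, a non-significant range covers all means inside
# it, so homogeneous sets are runs; maximal runs each get one letter.
assign_letters <- function(means, nonsig) {
  k <- length(means)
  runs <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    runs[[i]] <- i:j
  }
  keep <- vapply(seq_len(k), function(a) {
    !any(vapply(seq_len(k), function(b) {
      b != a && length(runs[[b]]) > length(runs[[a]]) &&
        all(runs[[a]] %in% runs[[b]])
    }, TRUE))
  }, TRUE)
  runs <- unique(runs[keep])
  letters_out <- rep("", k)
  for (gi in seq_along(runs)) {
    letters_out[runs[[gi]]] <- paste0(letters_out[runs[[gi]]], letters[gi])
  }
  letters_out
}

#' Duncan's multiple range test
#'
#' Implemented from studentized-range quantiles with per-range protection
#' level `1 - (1-alpha)^(p-1)`; the harmonic mean of group sizes is used for
#' unbalanced designs. Groups sharing a letter are not significantly
#' different at level `alpha`.
#'
#' @param means Named vector of group means.
#' @param n Per-group sizes (scalar or vector aligned with `means`).
#' @param mse Error mean square from the ANOVA.
#' @param df Error degrees of freedom.
#' @param alpha Significance level.
#' @return Data frame `group`, `mean`, `letters`, ordered by decreasing mean.
#' @export
duncan_test <- function(means, n, mse, df, alpha = 0.05) {
  if (mse <= 0) stop("degenerate ANOVA: zero error variance")
  k <- length(means)
  n <- rep(n, length.out = k)
  nh <- k / sum(1 / n)                       # harmonic mean group size
  o <- order(means, decreasing = TRUE)
  m <- means[o]
  se <- sqrt(mse / nh)
  nonsig <- matrix(TRUE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- j - i + 1
      crit <- duncan_critical(p, df, alpha) * se
      nonsig[i, j] <- nonsig[j, i] <- (m[i] - m[j]) < crit
    }
  }
  # enforce containment: if an inner pair differs, the outer range differs too
  data.frame(group = names(m), mean = unname(m),
             letters = assign_letters(m, nonsig),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare expression (or activity) groups by ANOVA plus Duncan grouping
#'
#' Fixed-effects ANOVA (one or two factors) followed by Duncan's multiple
#' range grouping of the primary factor's means; with exactly two groups in
#' a one-factor design a pooled-variance t-test is reported as well.
#'
#' @param values Numeric response.
#' @param group Primary factor (e.g. condition).
#' @param block Optional second factor for the two-factor design
#'   (e.g. tissue).
#' @param alpha Significance level for the letter grouping.
#' @return List: `anova` (the `aov` summary table), `letters` (Duncan
#'   groups), `t_test_p` (two-group designs only, else `NA`).
#' @export
compare_groups <- function(values, group, block = NULL, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (any(table(group) < 2)) stop("need >= 2 replicates per group")
  cells <- if (is.null(block)) group else interaction(group, block)
  within_var <- tapply(values, cells, stats::var)
  if (all(within_var < 1e-12 * (stats::var(values) + 1), na.rm = TRUE)) {
    stop("degenerate ANOVA: zero within-group variance")
  }
  if (is.null(block)) {
    fit <- stats::aov(values ~ group)
  } else {
    block <- factor(block)
    fit <- stats::aov(values ~ group * block)
  }
  tab <- summary(fit)[[1]]
  res_row <- which(trimws(rownames(tab)) == "Residuals")
  mse <- tab[res_row, "Mean Sq"]
  df <- tab[res_row, "Df"]
  if (!is.finite(mse) || mse <= 0) {
    stop("degenerate ANOVA: zero within-group variance")
  }
  means <- tapply(values, group, mean)
  lettered <- duncan_test(means, n = as.vector(table(group)), mse = mse,
                          df = df, alpha = alpha)
  t_p <- NA_real_
  if (nlevels(group) == 2 && is.null(block)) {
    t_p <- stats::t.test(values ~ group, var.equal = TRUE)$p.value
  }
  list(anova = tab, letters = lettered, t_test_p = t_p)
}
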