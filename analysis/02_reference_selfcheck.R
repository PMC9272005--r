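#!/usr/bin/env Rscript
# Reference-anchored conserved-site checking, validated on the synthetic
# reference scaffolds themselves and on a seeded synthetic protein family.
suppressMessages(library(glyoxalaseR))
dir.create("results", showWarnings = FALSE)

prof <- reference_profiles()
mk <- function(s, id) glyi_protein(id, s, domains = data.frame(start = 1,
                                                               end = nchar(s)))
for (m in c("Zn", "Ni")) {
  r <- check_sites(mk(prof[[m]]$domain_sequence, prof[[m]]$name))
  cat(sprintf("%s self-check: active=%s, metal=%s\n",
              prof[[m]]$name, r$active, r$predicted_metal))
}

fam <- make_protein_family(40, fraction_active = 0.5, seed = 2024)
flt <- filter_candidates(fam$proteins)
tab <- site_check_table(lapply(flt$kept, check_sites))
pred_active <- stats::setNames(rep(FALSE, nrow(fam$truth)),
                               fam$truth$protein_id)
pred_active[tab$protein_id] <- tab$active
acc <- mean(pred_active == fam$truth$active)
cat(sprintf("\nSynthetic family (n=40, zero noise): activity recovery %.0f%%\n",
            100 * acc))
utils::write.table(tab, "results/synthetic_family_checks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
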