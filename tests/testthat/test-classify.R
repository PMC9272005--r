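test_that("domain filter reproduces the published 54/6 partition", {
  catalog <- load_catalog(table_fixtures()$catalog)
  f <- filter_candidates(catalog)
  expect_equal(nrow(f$kept), 54L)
  expect_equal(nrow(f$discarded), 6L)
  expect_setequal(
    f$discarded$variant_id,
    c("TdGLYI-4B-2.2", "TdGLYI-1A-3.1", "TdGLYI-1A-1.1", "TdGLYI-1B-1.1",
      "TdGLYI-3B-1.2", "TdGLYI-5A-2.2")
  )
  expect_equal(f$discarded$reason[f$discarded$variant_id == "TdGLYI-4B-2.2"],
               "domain absent")
  expect_true(all(f$discarded$domain_aa[f$discarded$reason ==
                                          "domain too short"] %in% 76:97))
  # partition: no loss, no duplication
  expect_equal(nrow(f$kept) + nrow(f$discarded), nrow(catalog))
  expect_length(intersect(f$kept$variant_id, f$discarded$variant_id), 0L)
})

test_that("domain filter applies the threshold to the longest span", {
  at <- function(len) glyi_protein("P", domains = data.frame(length = len),
                                   length = 400L)
  expect_equal(nrow(filter_candidates(list(at(99)))$discarded), 1L)
  expect_length(filter_candidates(list(at(100)))$kept, 1L)
  two <- glyi_protein("P2", domains = data.frame(length = c(80, 130)),
                      length = 400L)
  expect_length(filter_candidates(list(two))$kept, 1L)
  none <- glyi_protein("P0")
  expect_equal(filter_candidates(list(none))$discarded$reason, "domain absent")
})

test_that("reference domains classify as their own metal type", {
  prof <- reference_profiles()
  zn <- check_sites(full_domain_protein(prof$Zn$domain_sequence, "ZN"))
  expect_true(zn$active)
  expect_equal(zn$predicted_metal, "Zn")
  expect_true(zn$metal_site_ok && zn$gsh_site_ok && zn$dimer_ok)
  ni <- check_sites(full_domain_protein(prof$Ni$domain_sequence, "NI"))
  expect_true(ni$active)
  expect_equal(ni$predicted_metal, "Ni")
})

test_that("every single conserved-site substitution abolishes the activity call", {
  prof <- reference_profiles()
  for (metal in c("Zn", "Ni")) {
    p <- prof[[metal]]
    for (pos in p$sites$ref_pos) {
      res <- check_sites(full_domain_protein(knockout(p$domain_sequence, pos),
                                             paste0(metal, pos)))
      expect_false(res$active, info = paste(metal, pos))
      expect_equal(res$predicted_metal, "none", info = paste(metal, pos))
    }
  }
})

test_that("proteins without sequence are 'not checkable', distinct from inactive", {
  p <- glyi_protein("NOSEQ", domains = data.frame(length = 120), length = 200L)
  res <- check_sites(p)
  expect_false(res$checkable)
  expect_true(is.na(res$active))
})

test_that("architecture grouping counts qualifying spans and flags anomalies", {
  one <- glyi_protein("A", domains = data.frame(start = 5, end = 126),
                      length = 200L)
  two <- glyi_protein("B", domains = data.frame(start = c(5, 150),
                                                end = c(126, 270)),
                      length = 300L)
  expect_equal(domain_architecture(one), "one-domain")
  expect_equal(domain_architecture(two), "two-domain")
  three <- glyi_protein("C", domains = data.frame(start = c(1, 150, 300),
                                                  end = c(120, 270, 420)),
                        length = 500L)
  expect_error(domain_architecture(three), "anomalous")
})

test_that("two-domain proteins are classified on the N-terminal domain only", {
  # C-terminal copy with a degenerate metal site must not affect the call
  prof <- reference_profiles()
  zn <- prof$Zn$domain_sequence
  broken <- knockout(zn, prof$Zn$sites$ref_pos[1])
  seqstr <- paste0(zn, "GSGSGSGSGS", broken)
  p <- glyi_protein("TWODOM", seqstr,
                    domains = data.frame(
                      start = c(1, nchar(zn) + 11),
                      end = c(nchar(zn), nchar(zn) + 10 + nchar(broken))))
  expect_equal(domain_architecture(p), "two-domain")
  res <- check_sites(p)
  expect_true(res$active)
  expect_equal(res$predicted_metal, "Zn")
  # and the reverse: broken N-terminal domain is not rescued by an intact
  # C-terminal one
  p2 <- glyi_protein("TWODOM2", paste0(broken, "GSGSGSGSGS", zn),
                     domains = data.frame(
                       start = c(1, nchar(broken) + 11),
                       end = c(nchar(broken), nchar(broken) + 10 + nchar(zn))))
  expect_false(check_sites(p2)$active)
})

test_that("family summary reproduces the published activity and metal tallies", {
  catalog <- load_catalog(table_fixtures()$catalog)
  sites <- load_site_table()
  fam <- classify_family(sites, catalog)
  expect_equal(fam$n_filtered, 54L)
  expect_equal(fam$n_active, 28L)
  expect_equal(fam$n_ni, 23L)
  expect_equal(fam$n_zn, 5L)
  expect_equal(fam$n_active_genes, 9L)
  expect_equal(fam$n_active, fam$n_ni + fam$n_zn)
})

test_that("family summary is order-invariant and validates the join", {
  catalog <- load_catalog(table_fixtures()$catalog)
  sites <- load_site_table()
  set.seed(31)
  shuffled <- sites[sample(nrow(sites)), ]
  expect_equal(unclass(classify_family(shuffled, catalog)),
               unclass(classify_family(sites, catalog)))
  rogue <- sites
  rogue$protein_id[1] <- "TdGLYI-9Z-9.9"
  expect_error(classify_family(rogue, catalog), "unknown protein id")
  all_absent <- sites
  all_absent$active <- FALSE
  all_absent$predicted_metal <- "none"
  expect_equal(classify_family(all_absent, catalog)$n_active, 0L)
})

test_that("localization consensus reproduces the published per-gene counts", {
  loc <- localization_consensus(load_localization_table())
  per_gene <- loc$per_gene
  expect_equal(nrow(loc$variants), 28L)
  counts <- stats::setNames(per_gene$n_organellar, per_gene$gene_id)
  expect_equal(unname(counts[c("TdGLYI-1B-4", "TdGLYI-2A-1", "TdGLYI-2B-1",
                               "TdGLYI-5B-1")]), c(7L, 3L, 2L, 2L))
  # cytosol-only genes support no organelle
  expect_equal(unname(counts["TdGLYI-7A-1"]), 0L)
})

test_that("localization label handling splits multi-labels and validates tokens", {
  labs <- data.frame(protein_id = c("G-1.1", "G-1.2"),
                     tool1 = c("C/M", "-"), tool2 = c("-", "-"),
                     stringsAsFactors = FALSE)
  res <- localization_consensus(labs)
  expect_true(res$variants$supports_c[1] && res$variants$supports_m[1])
  expect_false(res$variants$supports_c[2] || res$variants$supports_m[2])
  expect_equal(res$per_gene$n_organellar, 1L)
  bad <- data.frame(protein_id = "G-1.1", tool1 = "Q", stringsAsFactors = FALSE)
  expect_error(localization_consensus(bad), "unknown localization label")
})

test_that("rule file round-trips profiles and thresholds through YAML", {
  tmp <- tempfile(fileext = ".yaml")
  write_rules(tmp)
  rules <- read_rules(tmp)
  prof <- reference_profiles()
  expect_equal(rules$min_domain_len, 100)
  expect_equal(rules$zn_len_threshold, 140)
  expect_equal(rules$profiles$Zn$domain_sequence, prof$Zn$domain_sequence)
  expect_equal(rules$profiles$Ni$sites, prof$Ni$sites)
  # the bundled synthetic rule file matches the in-code profiles
  bundled <- system.file("extdata", "glyi_reference_profiles_synthetic.yaml",
                         package = "glyoxalaseR")
  expect_true(nzchar(bundled))
  expect_equal(read_rules(bundled)$profiles$Zn$domain_sequence,
               prof$Zn$domain_sequence)
})
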