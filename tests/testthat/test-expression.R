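make_simple_ct <- function(target_ct, ref_ct, conditions, refs = "REF",
                           tissue = "shoot") {
  # one biological sample per condition, one technical replicate
  rows <- list()
  for (i in seq_along(conditions)) {
    s <- paste0("s", i)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = s, condition = conditions[i], tissue = tissue,
      gene_id = "TG", ct = target_ct[i], replicate = 1L)
    for (r in seq_along(refs)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, condition = conditions[i], tissue = tissue,
        gene_id = refs[r], ct = ref_ct[[r]][i], replicate = 1L)
    }
  }
  ct_table(do.call(rbind, rows), ref_genes = refs)
}

test_that("one target cycle below stable references doubles the fold", {
  tab <- make_simple_ct(target_ct = c(20, 19), ref_ct = list(c(22, 22)),
                        conditions = c("control", "NaCl"))
  fc <- delta_delta_ct(tab, "control")
  expect_equal(fc$fold[fc$condition == "control"], 1)
  expect_equal(fc$fold[fc$condition == "NaCl"], 2)
  expect_equal(fc$log2_fold[fc$condition == "NaCl"], 1)
})

test_that("two-reference normalization averages reference Cts", {
  # refs at 20 and 22 (mean 21), target 19 => dCt = -2, fold 4 vs dCt-0 calibrator
  tab <- make_simple_ct(target_ct = c(21, 19),
                        ref_ct = list(c(21, 20), c(21, 22)),
                        conditions = c("control", "NaCl"),
                        refs = c("REFA", "REFB"))
  fc <- delta_delta_ct(tab, "control")
  expect_equal(fc$dct[fc$condition == "NaCl"], -2)
  expect_equal(fc$fold[fc$condition == "NaCl"], 4)
})

test_that("single-reference results match the classic Livak arithmetic", {
  tab <- make_simple_ct(target_ct = c(24.3, 22.1),
                        ref_ct = list(c(20.7, 21.2)),
                        conditions = c("control", "NaCl"))
  fc <- delta_delta_ct(tab, "control")
  ddct_manual <- (22.1 - 21.2) - (24.3 - 20.7)
  expect_equal(fc$ddct[fc$condition == "NaCl"], ddct_manual)
  expect_equal(fc$fold[fc$condition == "NaCl"], 2^(-ddct_manual))
})

test_that("calibrator mean fold is one and plate shifts cancel", {
  eff <- data.frame(gene_id = "g1", condition = "NaCl", tissue = "shoot",
                    log2_effect = 1.5)
  sim <- make_ct_table(c("g1", "g2"), effects = eff, ct_sd = 0.1, seed = 17)
  fc <- delta_delta_ct(sim$table, "control")
  cal <- fc[fc$condition == "control", ]
  geo <- tapply(cal$log2_fold, paste(cal$gene_id, cal$tissue),
                function(x) 2^mean(x))
  expect_true(all(abs(geo - 1) < 1e-12))
  # adding a constant to every Ct of a sample changes nothing
  shifted <- sim$table
  s1 <- shifted$sample_id == shifted$sample_id[1]
  shifted$ct[s1] <- shifted$ct[s1] + 3.7
  fc2 <- delta_delta_ct(ct_table(as.data.frame(shifted),
                                 ref_genes = attr(sim$table, "ref_genes")),
                        "control")
  expect_equal(fc2$fold, fc$fold, tolerance = 1e-12)
})

test_that("planted log2 effects are recovered from synthetic Ct tables", {
  eff <- data.frame(gene_id = c("g1", "g2", "g3"),
                    condition = c("NaCl", "NaCl", "mannitol"),
                    tissue = c("shoot", "root", "shoot"),
                    log2_effect = c(-1, 0, 2))
  # zero noise: exact recovery
  sim0 <- make_ct_table(c("g1", "g2", "g3"), effects = eff, ct_sd = 0,
                        seed = 7)
  fc0 <- delta_delta_ct(sim0$table, "control")
  key <- paste(fc0$gene_id, fc0$condition, fc0$tissue)
  expect_equal(mean(fc0$log2_fold[key == "g1 NaCl shoot"]), -1)
  expect_equal(mean(fc0$log2_fold[key == "g3 mannitol shoot"]), 2)
  expect_equal(mean(fc0$log2_fold[key == "g2 NaCl root"]), 0)
  # noisy: within 3 noise-propagated standard errors
  sd_ct <- 0.1
  sim <- make_ct_table(c("g1", "g2", "g3"), effects = eff, ct_sd = sd_ct,
                       seed = 7, n_bio = 3, n_tech = 3)
  fc <- delta_delta_ct(sim$table, "control")
  key <- paste(fc$gene_id, fc$condition, fc$tissue)
  # per-sample dCt variance: target tech-mean (sd^2/3) plus the two-reference
  # mean (sd^2/6); the recovered effect is mean(dCt of 3 samples) minus
  # mean(dCt of 3 calibrator samples)
  var_dct <- sd_ct^2 / 3 + sd_ct^2 / 6
  se_effect <- sqrt(2 * var_dct / 3)
  for (i in seq_len(nrow(eff))) {
    k <- paste(eff$gene_id[i], eff$condition[i], eff$tissue[i])
    expect_lt(abs(mean(fc$log2_fold[key == k]) - eff$log2_effect[i]),
              3 * se_effect)
  }
})

test_that("Ct table construction validates references and effects", {
  bad <- data.frame(sample_id = "s1", condition = "control", tissue = "shoot",
                    gene_id = "TG", ct = 20, replicate = 1L)
  expect_error(ct_table(bad, ref_genes = "REF"), "lacks reference")
  expect_error(make_ct_table("g1",
                             effects = data.frame(gene_id = "CDC",
                                                  condition = "NaCl",
                                                  tissue = "shoot",
                                                  log2_effect = 1)),
               "reference gene")
  expect_error(make_ct_table("g1",
                             effects = data.frame(gene_id = "g1",
                                                  condition = "control",
                                                  tissue = "shoot",
                                                  log2_effect = 1)),
               "calibrator")
})

test_that("Duncan grouping separates clear means and shares letters otherwise", {
  set.seed(61)
  vals <- c(stats::rnorm(4, 0, 0.1), stats::rnorm(4, 0.02, 0.1),
            stats::rnorm(4, 8, 0.1))
  g <- rep(c("a", "b", "c"), each = 4)
  res <- compare_groups(vals, g)
  lt <- stats::setNames(res$letters$letters, res$letters$group)
  expect_equal(lt[["c"]], "a")                    # top mean alone
  expect_true(lt[["a"]] == lt[["b"]])             # indistinguishable pair
  # widely separated triple: three distinct letters
  vals3 <- c(stats::rnorm(4, 0, 0.05), stats::rnorm(4, 5, 0.05),
             stats::rnorm(4, 10, 0.05))
  res3 <- compare_groups(vals3, g)
  expect_length(unique(res3$letters$letters), 3L)
  # identical groups: everything shares one letter
  vals_eq <- rep(c(1.0, 1.1, 0.9, 1.05), 3)
  res_eq <- compare_groups(vals_eq, g)
  expect_length(unique(res_eq$letters$letters), 1L)
})

test_that("two-group Duncan decision agrees with the pooled t-test", {
  set.seed(62)
  for (delta in c(0, 0.3, 3)) {
    vals <- c(stats::rnorm(6, 0), stats::rnorm(6, delta))
    g <- rep(c("x", "y"), each = 6)
    res <- compare_groups(vals, g)
    t_sig <- res$t_test_p < 0.05
    duncan_sig <- res$letters$letters[1] != res$letters$letters[2]
    expect_equal(duncan_sig, t_sig, info = paste("delta", delta))
  }
})

test_that("two-factor ANOVA runs and degenerate variance errors", {
  set.seed(63)
  vals <- stats::rnorm(24, rep(c(0, 1, 2), each = 8))
  cond <- rep(c("c", "n", "m"), each = 8)
  tis <- rep(rep(c("shoot", "root"), each = 4), 3)
  res <- compare_groups(vals, cond, block = tis)
  expect_true("group:block" %in% trimws(rownames(res$anova)))
  expect_error(compare_groups(rep(1, 9), rep(c("a", "b", "c"), each = 3)),
               "degenerate")
})
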