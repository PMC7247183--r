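test_that("log2(FPKM + 1) transform is exact and monotone, with identical
           rows adjacent in the clustering order", {
  m <- matrix(c(0, 1, 3, 7), 1, dimnames = list("g1", paste0("c", 1:4)))
  hs <- transform_fpkm(m)
  expect_equal(unname(hs$transformed[1, ]), c(0, 1, 2, 3))
  expect_error(transform_fpkm(matrix(-1, 1, 1)), "negative")
  set.seed(60)
  m2 <- matrix(stats::rexp(40), 8, 5,
               dimnames = list(paste0("g", 1:8), paste0("c", 1:5)))
  m2[5, ] <- m2[2, ]   # identical pair
  hs2 <- transform_fpkm(m2)
  ord <- hs2$row_order
  expect_equal(abs(which(ord == 2) - which(ord == 5)), 1L)
  expect_true(all(sort(ord) == 1:8))
})

test_that("planted two-group expression designs are recovered by the row
           dendrogram", {
  cfg <- synthetic_config(seed = 61)
  ex <- generate_expression(cfg)
  hs <- transform_fpkm(ex$fpkm)
  ct <- stats::cutree(hs$dendrogram, 2)
  tab <- table(ct, ex$truth$gene_groups)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("ddCt fold changes follow the closed form with sane controls", {
  mk <- function(gene, cond, tp, tis, reps_dct) {
    do.call(rbind, lapply(seq_along(reps_dct), function(r)
      data.frame(gene_id = gene, condition = cond, timepoint_h = tp,
                 tissue = tis, replicate = r,
                 ct_target = 20 + reps_dct[r], ct_reference = 20,
                 stringsAsFactors = FALSE)))
  }
  rec <- rbind(mk("g1", "control", 0, "leaf", c(2, 2, 2)),
               mk("g1", "NaCl", 24, "leaf", c(3, 3, 3)),      # ddCt = 1
               mk("g1", "PEG", 48, "leaf", c(0, 0, 0)))       # ddCt = -2
  res <- ddct_fold_change(rec)
  expect_equal(res$fold_change[res$condition == "NaCl"], 0.5)
  expect_equal(res$fold_change[res$condition == "PEG"], 4)
  expect_equal(res$fold_change[res$condition == "control"], 1)
  # treated mean equal to control mean: fold 1, ns
  rec2 <- rbind(mk("g2", "control", 0, "leaf", c(1, 2, 3)),
                mk("g2", "NaCl", 6, "leaf", c(3, 2, 1)))
  r2 <- ddct_fold_change(rec2)
  expect_equal(r2$fold_change[r2$condition == "NaCl"], 1)
  calls <- call_stress_response(r2)
  expect_true(all(calls$calls$direction == "ns"))
  # error paths
  expect_error(ddct_fold_change(mk("g3", "NaCl", 6, "leaf", c(1, 1, 1))),
               "missing control")
  expect_error(ddct_fold_change(rbind(
    mk("g4", "control", 0, "leaf", c(1, 1)),
    mk("g4", "NaCl", 6, "leaf", 1))), "fewer than 2 replicates")
  expect_error(ddct_fold_change(within(rec, ct_target[1] <- 50)),
               "\\(0, 45\\)")
})

test_that("log2 fold change is antisymmetric under swapping treated and
           control", {
  set.seed(62)
  a <- stats::rnorm(3, 5); b <- stats::rnorm(3, 3)
  mk <- function(cond, d) data.frame(
    gene_id = "g", condition = cond, timepoint_h = ifelse(
      cond == "control", 0, 6),
    tissue = "leaf", replicate = 1:3, ct_target = 20 + d,
    ct_reference = 20, stringsAsFactors = FALSE)
  f1 <- ddct_fold_change(rbind(mk("control", a), mk("NaCl", b)))
  f2 <- ddct_fold_change(rbind(mk("control", b), mk("NaCl", a)))
  expect_equal(log2(f1$fold_change[f1$condition == "NaCl"]),
               -log2(f2$fold_change[f2$condition == "NaCl"]))
})

test_that("stress-response calls classify by fold direction and p-value", {
  res <- data.frame(gene_id = c("g1", "g2"), condition = "NaCl",
                    timepoint_h = 24, tissue = "leaf",
                    n_treated = 3, n_control = 3, ddct = c(-1, 1.3),
                    fold_change = c(2.0, 0.4), p_value = c(0.01, 0.20))
  out <- call_stress_response(res)
  expect_equal(out$calls$direction, c("up", "ns"))
  expect_equal(out$induced_counts$n_up, 1L)
})

test_that("simulated ddCt designs recover planted folds within 10% and
           keep null type-I error in check", {
  genes <- sprintf("g%03d", 1:200)
  planted <- data.frame(gene_id = genes[1:50], condition = "NaCl",
                        timepoint_h = 24, tissue = "leaf", ddct = -1.5)
  cfg <- synthetic_config(seed = 63, qpcr_ddct = planted)
  q <- generate_qpcr(cfg, gene_ids = genes)
  res <- ddct_fold_change(q$records)
  cell <- res[res$condition == "NaCl" & res$timepoint_h == 24 &
                res$tissue == "leaf", ]
  est <- cell$fold_change[match(genes[1:50], cell$gene_id)]
  expect_lt(abs(mean(est) - 2^1.5) / 2^1.5, 0.10)
  # null cells: all other treated cells have planted ddCt = 0
  null <- res[!(res$gene_id %in% genes[1:50] & res$condition == "NaCl" &
                  res$timepoint_h == 24 & res$tissue == "leaf") &
                res$condition != "control", ]
  expect_lte(mean(null$p_value <= 0.05, na.rm = TRUE), 0.07)
})

test_that("t-test p-values are uniform under the null", {
  set.seed(64)
  p <- replicate(1000, {
    stats::t.test(stats::rnorm(3), stats::rnorm(3))$p.value
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted leaf-NaCl-24h responders are counted by the summary", {
  genes <- sprintf("g%02d", 1:10)
  planted <- data.frame(gene_id = genes[1:5], condition = "NaCl",
                        timepoint_h = 24, tissue = "leaf", ddct = -2.5)
  cfg <- synthetic_config(seed = 65, qpcr_ddct = planted)
  q <- generate_qpcr(cfg, gene_ids = genes)
  calls <- call_stress_response(ddct_fold_change(q$records))
  ic <- calls$induced_counts
  cell <- ic[ic$condition == "NaCl" & ic$timepoint_h == 24 &
               ic$tissue == "leaf", ]
  expect_equal(cell$n_up, 5L)
})
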