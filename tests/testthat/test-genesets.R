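test_that("high-expression selection is a deterministic top fraction", {
  g <- data.frame(id = sprintf("g%04d", 1:1000), chrom = "chrS",
                  strand = "+", tss = seq(15000, by = 30000, length.out = 1000),
                  rpkm = rev(seq_len(1000)) / 10)
  top <- select_high_expressed(g, 0.15)
  expect_equal(nrow(top), 150)
  expect_equal(top$id[1], "g0001")  # highest rpkm
  expect_true(min(top$rpkm) >= max(g$rpkm[!g$id %in% top$id]))
  expect_equal(nrow(select_high_expressed(g, 1.0)), 1000)

  g$rpkm <- 1  # all tied: id order decides, deterministically
  t1 <- select_high_expressed(g, 0.1)
  expect_equal(t1$id, sprintf("g%04d", 1:100))
  expect_error(select_high_expressed(g[0, ], 0.15), "empty")
  expect_error(select_high_expressed(g, 0), "fraction")
})

test_that("ratio banding matches the published band edges", {
  expect_equal(classify_ratio(0.659), "HM-superior")
  expect_equal(classify_ratio(1.970), "TF-superior")
  expect_equal(classify_ratio(1.0), "similar")
  # boundaries belong to the middle band
  expect_equal(classify_ratio(0.90), "similar")
  expect_equal(classify_ratio(1.10), "similar")
  expect_equal(classify_ratio(0.8999), "HM-superior")
  expect_equal(classify_ratio(1.1001), "TF-superior")
  expect_error(classify_ratio(-1), "positive")
  expect_error(classify_ratio(Inf), "finite")
})

test_that("small sets are discarded and results stay internally coherent", {
  cfg <- sim_config(n_genes = 1200, n_tf = 3, n_hm = 2,
                    include_dnase = FALSE, chrom_length = 3.6e7,
                    tags_per_factor = 2e4, seed = 71L)
  g <- simulate_genes(cfg)
  a <- truth_assoc(g)
  high <- select_high_expressed(g, 0.15)
  set.seed(1)
  sets <- list(big = sample(high$id, 60),
               small = sample(high$id, 29),
               mixed = c(sample(high$id, 25),
                         setdiff(g$id, high$id)[1:40]))
  res <- evaluate_gene_sets(sets, a, g, seed = 2L)
  expect_false("small" %in% res$set_id)          # 29 < 30
  expect_false("mixed" %in% res$set_id)          # 25 high-expressed < 30
  expect_equal(attr(res, "n_discarded_small"), 2L)
  expect_true("big" %in% res$set_id)
  row <- res[res$set_id == "big", ]
  expect_equal(row$set_size, 60)
  if (isTRUE(row$significant) && row$hm_pcc > 0) {
    expect_equal(row$ratio, row$tf_pcc / row$hm_pcc)
    expect_equal(row$band, classify_ratio(row$ratio))
  }
  expect_error(evaluate_gene_sets(list(x = "nope"), a, g), "unknown gene ids")
})

# study conditions for the gene-set analysis: cross-class coupled factors
# (each class shares most of the expression signal, as the genome-wide
# redundancy analyses find) and moderate expression noise, so set-level
# PCCs land in the published 0.4-0.95 range after the high-expression cut
geneset_cfg <- function(n_genes, seed) {
  sim_config(n_genes = n_genes, n_tf = 4, n_hm = 4, include_dnase = FALSE,
             chrom_length = 30000 * n_genes, tags_per_factor = 2e4,
             noise_sd = 0.4,
             redundant_pairs = list(list("TF01", "HM01", 0.7),
                                    list("HM02", "TF02", 0.7),
                                    list("TF03", "HM03", 0.7),
                                    list("HM04", "TF04", 0.7)),
             seed = seed)
}

test_that("set bias drives the TF/HM predictive ratio in the right direction", {
  ratios <- list(TF = c(), HM = c())
  for (seed in 1:10) {
    g <- simulate_genes(geneset_cfg(1000, 100L + seed))
    sets <- simulate_gene_sets(g, 2, c(60, 60), bias = c("TF", "HM"),
                               seed = seed)
    res <- evaluate_gene_sets(sets, truth_assoc(g), g, seed = seed)
    bias <- attr(sets, "bias")
    for (i in seq_len(nrow(res))) {
      b <- bias[[res$set_id[i]]]
      if (is.finite(res$ratio[i]) && res$ratio[i] > 0)
        ratios[[b]] <- c(ratios[[b]], res$ratio[i])
    }
  }
  expect_gt(median(ratios$TF), median(ratios$HM))
  expect_gt(mean(ratios$HM < 0.90), 0.5)
  expect_gt(mean(ratios$TF > 1.10), 0.5)
})

test_that("neutral sets mostly land in the similar band", {
  all_ratio <- c()
  for (seed in 1:5) {
    g <- simulate_genes(geneset_cfg(4000, 200L + seed))
    sets <- simulate_gene_sets(g, 3, c(300, 300), bias = "neutral",
                               seed = seed)
    res <- evaluate_gene_sets(sets, truth_assoc(g), g, seed = seed)
    all_ratio <- c(all_ratio, res$ratio[is.finite(res$ratio) & res$ratio > 0])
  }
  bands <- vapply(all_ratio, classify_ratio, "")
  expect_gt(sum(bands == "similar"), sum(bands == "HM-superior"))
  expect_gt(sum(bands == "similar"), sum(bands == "TF-superior"))
  expect_lt(abs(median(all_ratio) - 1), 0.15)
})
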