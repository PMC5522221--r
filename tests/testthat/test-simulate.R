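test_that("fixed seed gives bit-identical genes and tracks", {
  cfg <- small_cfg(n_genes = 100, seed = 7L)
  g1 <- simulate_genes(cfg)
  g2 <- simulate_genes(cfg)
  expect_identical(g1, g2)
  t1 <- simulate_tracks(g1, cfg)
  t2 <- simulate_tracks(g2, cfg)
  expect_identical(t1, t2)
})

test_that("gene table honours its contracts", {
  cfg <- small_cfg(n_genes = 150, seed = 3L)
  g <- simulate_genes(cfg)
  expect_equal(nrow(g), 150)
  expect_false(anyDuplicated(g$id) > 0)
  expect_true(all(g$rpkm >= 0))
  expect_true(all(g$strand %in% c("+", "-")))
  expect_true(all(diff(g$tss) > 24000))
  expect_true(all(g$tss - 10000 >= 0 & g$tss + 10000 <= cfg$chrom_length))
})

test_that("infeasible TSS spacing is a sizing error", {
  expect_error(simulate_genes(sim_config(n_genes = 100, chrom_length = 50000)),
               "too short")
})

test_that("log expression follows the configured normal law", {
  cfg <- sim_config(n_genes = 4000, seed = 11L, expression_log_mean = 5,
                    expression_log_sd = 2, chrom_length = 1.2e8)
  g <- simulate_genes(cfg)
  z <- attr(g, "ground_truth")$z
  expect_lt(abs(mean(z) - 5), 0.12)   # 3 x sd/sqrt(n)
  expect_lt(abs(sd(z) - 2), 0.12)
  # clamping touches only the z < 0 tail
  expect_equal(log2(g$rpkm + 1)[z >= 0], z[z >= 0])
})

test_that("tag totals are conserved and positions stay on the chromosome", {
  cfg <- small_cfg(n_genes = 60, seed = 2L)
  g <- simulate_genes(cfg)
  trs <- simulate_tracks(g, cfg)
  for (tr in trs) {
    expect_equal(tr$total_tags, cfg$tags_per_factor)
    expect_equal(length(tr$positions), tr$total_tags)
    expect_true(all(tr$positions >= 0 & tr$positions < cfg$chrom_length))
  }
})

test_that("a zero effect weight decouples a factor from expression", {
  cfg <- sim_config(n_genes = 800, n_tf = 3, n_hm = 2,
                    include_dnase = FALSE, chrom_length = 2.5e7,
                    effect_weights = c(TF02 = 0), tags_per_factor = 2e4,
                    seed = 5L)
  g <- simulate_genes(cfg)
  trs <- simulate_tracks(g, cfg)
  y <- log_expression(g)
  expect_lt(abs(cor(trs$TF02$truth$log2_intensity, y)), 0.1)
  expect_gt(cor(trs$TF01$truth$log2_intensity, y), 0.2)
})

test_that("redundant pairs hit the target intensity correlation", {
  for (seed in c(1L, 2L, 3L)) {
    cfg <- sim_config(n_genes = 2000, n_tf = 3, n_hm = 2,
                      include_dnase = FALSE, chrom_length = 6e7,
                      tags_per_factor = 2e4, seed = seed,
                      redundant_pairs = list(list("TF01", "TF02", 0.9)))
    g <- simulate_genes(cfg)
    trs <- simulate_tracks(g, cfg)
    r <- cor(trs$TF01$truth$log2_intensity, trs$TF02$truth$log2_intensity)
    expect_gte(r, 0.85)
    expect_lte(r, 0.95)
  }
})

test_that("unknown factor in redundant_pairs is a config error", {
  expect_error(small_cfg(redundant_pairs = list(list("TF01", "NOPE", 0.5))),
               "unknown factor")
  expect_error(small_cfg(redundant_pairs = list(list("TF01", "TF02", 1.2))),
               "target correlation")
})

test_that("OLS on the true latent intensities recovers the recorded coefficients", {
  cfg <- sim_config(n_genes = 1000, n_tf = 3, n_hm = 2,
                    include_dnase = FALSE, chrom_length = 3e7,
                    tags_per_factor = 2e4, seed = 13L)
  g <- simulate_genes(cfg)
  gt <- attr(g, "ground_truth")
  fit <- summary(lm(log_expression(g) ~ gt$f))
  est <- fit$coefficients[-1, "Estimate"]
  se <- fit$coefficients[-1, "Std. Error"]
  expect_true(all(abs(est - gt$realized_coef) <= 2 * se))
})

test_that("gene sets respect size, pool and bias contracts", {
  cfg <- small_cfg(n_genes = 400, seed = 21L)
  g <- simulate_genes(cfg)
  expect_length(simulate_gene_sets(g, 0, c(30, 50)), 0)
  expect_error(simulate_gene_sets(g, 2, c(50, 30)), "min <= max")
  sets <- simulate_gene_sets(g, 5, c(30, 40),
                             bias = c("TF", "HM", "neutral", "TF", "HM"),
                             seed = 2L, high_fraction = 0.5)
  expect_length(sets, 5)
  sizes <- lengths(sets)
  expect_true(all(sizes >= 30 & sizes <= 40))
  pool <- select_high_expressed(g, 0.5)$id
  expect_true(all(unlist(sets) %in% pool))
  expect_equal(unname(attr(sets, "bias")),
               c("TF", "HM", "neutral", "TF", "HM"))
  for (s in sets) expect_false(anyDuplicated(s) > 0)
})
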