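test_that("rule-of-thumb bandwidth matches the closed form on a known sample", {
  set.seed(9)
  g <- tiny_genes(tss = 500000)
  d <- round(rnorm(1e4, 0, 1000))
  tr <- tiny_track(500000 + d)
  scheme <- make_scheme("TF")
  h <- rule_of_thumb_bandwidth(tr, g, scheme)
  expect_lt(abs(h - 0.9 * 1000 * 1e4^(-1 / 5)) / (0.9 * 1000 * 1e4^(-1 / 5)),
            0.05)
  # agrees exactly with the reference rule-of-thumb implementation
  expect_equal(as.numeric(h), stats::bw.nrd0(d[abs(d) < 10000]))
})

test_that("bandwidth is scale-equivariant and fails on degenerate samples", {
  g <- tiny_genes(tss = 500000)
  set.seed(10)
  d <- round(rnorm(500, 0, 800))
  h1 <- rule_of_thumb_bandwidth(tiny_track(500000 + d), g, make_scheme("TF"))
  h2 <- rule_of_thumb_bandwidth(tiny_track(500000 + 2 * d), g, make_scheme("TF"))
  expect_equal(as.numeric(h2), 2 * as.numeric(h1), tolerance = 1e-12)
  expect_error(rule_of_thumb_bandwidth(tiny_track(500100), g, make_scheme("TF")),
               "degenerate")
  expect_error(rule_of_thumb_bandwidth(tiny_track(rep(500100, 5)), g,
                                       make_scheme("TF")),
               "degenerate")
})

test_that("kernel weights are symmetric, positive and peak at the TSS", {
  scheme <- make_scheme("TF")
  ks <- kernel_spec(scheme, 1500)
  expect_true(all(ks$weights > 0))
  expect_equal(ks$weights, rev(ks$weights))
  expect_equal(which.max(ks$weights), 50)  # midpoints -100 and +100 tie
  expect_equal(ks$weights[50], ks$weights[51])
})

test_that("tfas matches direct kernel evaluation", {
  scheme <- make_scheme("TF")
  g <- tiny_genes(tss = 50000)
  b <- structure(list(factor_name = "TFX", factor_class = "TF",
                      scheme = scheme, gene_ids = g$id,
                      matrix = matrix(0, 1, 100)),
                 class = "binned_signal")
  # put N = 10 in a bin whose midpoint sits at d = +100 (bin 51)
  b$matrix[1, 51] <- 10
  a <- tfas(b, kernel_spec(scheme, 1000), pseudocount = 1)
  expect_equal(a$raw[1], 10 * dnorm(100, 0, 1000), tolerance = 1e-12)
  # a near-zero-offset check against the hand value 10/(1000*sqrt(2*pi))
  expect_equal(10 * dnorm(0, 0, 1000), 3.989423e-3, tolerance = 1e-6)
})

test_that("tfas and hmas match a naive double loop", {
  set.seed(30)
  scheme_tf <- make_scheme("TF")
  scheme_hm <- make_scheme("HM")
  M_tf <- matrix(rexp(5 * 100), 5, 100)
  M_hm <- matrix(rexp(5 * 20), 5, 20)
  mk <- function(M, scheme, class) {
    structure(list(factor_name = "F", factor_class = class, scheme = scheme,
                   gene_ids = sprintf("g%d", 1:5), matrix = M),
              class = "binned_signal")
  }
  h <- 1200
  a <- tfas(mk(M_tf, scheme_tf, "TF"), kernel_spec(scheme_tf, h))
  naive <- sapply(1:5, function(i) {
    s <- 0
    for (j in 1:100)
      s <- s + M_tf[i, j] * exp(-scheme_tf$bin_midpoints[j]^2 / (2 * h^2)) /
        (h * sqrt(2 * pi))
    s
  })
  expect_equal(a$raw, naive, tolerance = 1e-12)
  expect_equal(a$logged, log2(naive + 1), tolerance = 1e-12)

  bsum <- hmas(mk(M_hm, scheme_hm, "HM"))
  naive_hm <- sapply(1:5, function(i) sum(M_hm[i, ]))
  expect_equal(bsum$raw, naive_hm, tolerance = 1e-12)
})

test_that("hmas hand example, zero rows and bin-permutation invariance", {
  scheme <- make_scheme("HM")
  mk <- function(M) structure(list(factor_name = "H", factor_class = "HM",
                                   scheme = scheme,
                                   gene_ids = sprintf("g%d", seq_len(nrow(M))),
                                   matrix = M), class = "binned_signal")
  a <- hmas(mk(rbind(rep(1, 20), rep(0, 20))), pseudocount = 1)
  expect_equal(a$raw, c(20, 0))
  expect_equal(a$logged, c(log2(21), 0))
  set.seed(4)
  row <- runif(20)
  expect_equal(hmas(mk(rbind(row)))$raw, hmas(mk(rbind(sample(row))))$raw)
})

test_that("raising any bin strictly raises that gene's TFAS", {
  scheme <- make_scheme("TF")
  set.seed(5)
  M <- matrix(runif(2 * 100), 2, 100)
  mk <- function(M) structure(list(factor_name = "F", factor_class = "TF",
                                   scheme = scheme, gene_ids = c("a", "b"),
                                   matrix = M), class = "binned_signal")
  ks <- kernel_spec(scheme, 2000)
  base <- tfas(mk(M), ks)$raw
  M2 <- M; M2[1, 100] <- M2[1, 100] + 1  # even the most remote bin
  bumped <- tfas(mk(M2), ks)$raw
  expect_gt(bumped[1], base[1])
  expect_equal(bumped[2], base[2])
})

test_that("non-positive pseudocount with zero signal is a log-domain error", {
  scheme <- make_scheme("HM")
  b <- structure(list(factor_name = "H", factor_class = "HM", scheme = scheme,
                      gene_ids = "g1", matrix = matrix(0, 1, 20)),
                 class = "binned_signal")
  expect_error(hmas(b, pseudocount = 0), "log-domain")
})

test_that("assembly aligns columns and rejects mismatches", {
  cfg <- small_cfg(n_genes = 40, seed = 8L)
  g <- simulate_genes(cfg)
  trs <- simulate_tracks(g, cfg)
  a <- associate_tracks(trs, g)
  expect_equal(dim(a$logged), c(40, 5))
  expect_equal(a$factor_names, names(trs))
  expect_true(all(a$raw >= 0))
  expect_equal(a$logged, log2(a$raw + 1))

  expect_error(assoc_assemble(list()), "alignment")
  c1 <- list(factor_name = "A", factor_class = "TF", gene_ids = c("g1", "g2"),
             raw = c(1, 2), logged = log2(c(2, 3)), pseudocount = 1,
             bandwidth = NA_real_)
  c2 <- c1; c2$factor_name <- "B"; c2$gene_ids <- c("g1", "gX")
  expect_error(assoc_assemble(list(c1, c2)), "alignment")
})
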