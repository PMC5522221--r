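# Shared fixtures, all generated in code.

small_cfg <- function(n_genes = 200, seed = 7L, ...) {
  sim_config(n_genes = n_genes, n_tf = 3, n_hm = 2, include_dnase = FALSE,
             chrom_length = max(26000 * n_genes, 3e6),
             tags_per_factor = 2e4, seed = seed, ...)
}

# assoc_matrix built directly from the generator's ground-truth latent
# log intensities; used to test downstream modules at their own boundary
# without re-running the binning pipeline.
truth_assoc <- function(genes) {
  gt <- attr(genes, "ground_truth")
  structure(list(
    gene_ids = genes$id,
    factor_names = colnames(gt$f),
    factor_classes = gt$factor_class,
    raw = 2^gt$f,
    logged = gt$f,
    pseudocounts = stats::setNames(rep(1, ncol(gt$f)), colnames(gt$f)),
    bandwidths = stats::setNames(rep(NA_real_, ncol(gt$f)), colnames(gt$f))
  ), class = "assoc_matrix")
}

# hand-built one-gene fixture: a gene table row plus a track with given
# tag positions
tiny_genes <- function(tss = 50000, strand = "+", n = 1) {
  data.frame(id = sprintf("g%02d", seq_len(n)), chrom = "chrS",
             strand = rep_len(strand, n),
             tss = tss + (seq_len(n) - 1) * 40000,
             rpkm = seq_len(n), stringsAsFactors = FALSE)
}

tiny_track <- function(positions, total_tags = length(positions),
                       name = "TFX", class = "TF") {
  structure(list(factor_name = name, factor_class = class,
                 positions = positions, total_tags = total_tags),
            class = "tag_track")
}

# naive per-tag binning loop (independent oracle for bin_track)
naive_bin <- function(track, genes, scheme) {
  half <- scheme$window_upstream
  out <- matrix(0, nrow(genes), scheme$n_bins)
  for (i in seq_len(nrow(genes))) {
    w0 <- genes$tss[i] - half
    for (p in track$positions) {
      if (p >= w0 && p < w0 + 2 * half) {
        j <- floor((p - w0) / scheme$bin_width) + 1
        if (genes$strand[i] == "-") j <- scheme$n_bins + 1 - j
        out[i, j] <- out[i, j] + 1
      }
    }
  }
  out * 1e9 / (track$total_tags * scheme$bin_width)
}

# Gaussian chain A -> B -> C with known partial-correlation structure
chain_data <- function(n, seed = 1L) {
  set.seed(seed)
  A <- rnorm(n)
  B <- A + rnorm(n)
  C <- B + rnorm(n)
  cbind(A = A, B = B, C = C)
}
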