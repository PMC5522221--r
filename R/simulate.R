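# Synthetic-data generator. Ground truth for every random quantity is
# recorded so downstream recovery tests can compare against it.

# Latent model shared by simulate_genes() and simulate_tracks().
#
# Per gene i and factor k, a latent log2 intensity f_ik with unit variance;
# redundant pairs (a, b, rho) rebuild f_b = rho * f_a + sqrt(1 - rho^2) * e_b
# so cor(f_a, f_b) = rho in population. Log expression is
#   z_i = mean + s * (sum_k w_k f_ik + eps_i),  eps ~ N(0, noise_sd),
# with s chosen analytically so that z ~ N(mean, sd) exactly as configured.
# The realized coefficients s * w_k are the ground-truth regression
# coefficients of z on f.
.sim_latent <- function(cfg) {
  p <- length(cfg$factor_name)
  n <- cfg$n_genes
  w <- cfg$effect_weights[cfg$factor_name]

  # mixing matrix: f = e %*% t(L), e iid N(0,1)
  L <- diag(p)
  rownames(L) <- colnames(L) <- cfg$factor_name
  for (rp in cfg$redundant_pairs) {
    a <- rp[[1]]; b <- rp[[2]]; rho <- rp[[3]]
    L[b, ] <- rho * L[a, ]
    L[b, b] <- L[b, b] + sqrt(1 - rho^2)
  }
  Sigma <- L %*% t(L)

  var_signal <- drop(t(w) %*% Sigma %*% w)
  denom <- sqrt(var_signal + cfg$noise_sd^2)
  if (denom == 0)
    stop("degenerate expression model: all effect weights and noise are zero")
  s <- cfg$expression_log_sd / denom

  set.seed(cfg$seed)
  e <- matrix(stats::rnorm(n * p), n, p)
  f <- e %*% t(L)
  colnames(f) <- cfg$factor_name
  eps <- stats::rnorm(n, 0, cfg$noise_sd)
  z <- cfg$expression_log_mean + s * (drop(f %*% w) + eps)

  list(f = f, z = z, Sigma = Sigma,
       realized_coef = stats::setNames(s * w, cfg$factor_name),
       realized_noise_sd = s * cfg$noise_sd,
       scale = s)
}

#' Simulate a gene annotation table
#'
#' Places \code{n_genes} TSSs on one synthetic chromosome with consecutive
#' spacing > 24 kb (so ±10 kb TF windows and ±2 kb HM windows of different
#' genes never collide), assigns random strands, and draws expression so
#' that log2(RPKM + pseudocount) is N(expression_log_mean,
#' expression_log_sd) as configured. RPKM values falling below zero on the
#' natural scale are clamped to zero (unexpressed genes).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{data.frame} (one row per gene) with columns \code{id},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{rpkm}, carrying a
#'   \code{"ground_truth"} attribute: the latent factor matrix \code{f},
#'   the realized per-factor coefficients, the realized noise sd, the
#'   pre-clamping log expression \code{z}, and the population factor
#'   covariance.
#' @export
simulate_genes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spacing <- floor(cfg$chrom_length / cfg$n_genes)
  min_spacing <- 24001L
  if (spacing < min_spacing + 1L)
    stop(sprintf(
      "chromosome too short: %g bp allows %d bp per gene; > %d bp needed",
      cfg$chrom_length, spacing, min_spacing))

  lat <- .sim_latent(cfg)
  set.seed(cfg$seed + 1L)
  jitter <- floor(stats::runif(cfg$n_genes, 0, spacing - min_spacing + 1))
  tss <- (seq_len(cfg$n_genes) - 1L) * spacing + 12001L + as.integer(jitter)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

  rpkm <- pmax(2^lat$z - cfg$pseudocount, 0)
  genes <- data.frame(
    id = sprintf("g%05d", seq_len(cfg$n_genes)),
    chrom = "chrS",
    strand = strand,
    tss = tss,
    rpkm = rpkm,
    stringsAsFactors = FALSE
  )
  attr(genes, "ground_truth") <- list(
    f = lat$f,
    z = lat$z,
    realized_coef = lat$realized_coef,
    realized_noise_sd = lat$realized_noise_sd,
    Sigma = lat$Sigma,
    factor_class = cfg$factor_class,
    pseudocount = cfg$pseudocount
  )
  attr(genes, "chrom_length") <- cfg$chrom_length
  genes
}

#' Simulate per-factor tag tracks
#'
#' For each factor, per-gene tag intensity is \code{2^f_ik} (the latent
#' log2 intensity shared with \code{\link{simulate_genes}}, hence coupled
#' to expression through the recorded coefficients). A fixed total of
#' \code{tags_per_factor} tags is split into a uniform background fraction
#' and signal tags multinomially allocated across genes proportional to
#' intensity; each signal tag lands at TSS + strand-oriented
#' round(N(offset, spread)). Tag positions are single base coordinates
#' (read midpoints), clamped to the chromosome.
#'
#' @param genes output of \code{\link{simulate_genes}} (same \code{cfg}).
#' @param cfg the same \code{\link{sim_config}} used for \code{genes}.
#' @return a named list of \code{tag_track} objects: each a list with
#'   \code{factor_name}, \code{factor_class}, \code{positions} (integer
#'   bp), \code{total_tags}, and a \code{truth} list (per-gene log2
#'   intensity, realized coefficient, spatial profile, background count).
#' @export
simulate_tracks <- function(genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(genes))
  lat <- .sim_latent(cfg)
  set.seed(cfg$seed + 2L)

  n_bg <- round(cfg$background_fraction * cfg$tags_per_factor)
  n_sig <- cfg$tags_per_factor - n_bg
  plus <- genes$strand == "+"

  tracks <- lapply(seq_along(cfg$factor_name), function(k) {
    nm <- cfg$factor_name[k]
    lambda <- 2^lat$f[, k]
    counts <- as.vector(stats::rmultinom(1, n_sig, lambda / sum(lambda)))
    gi <- rep.int(seq_len(cfg$n_genes), counts)
    prof <- cfg$spatial_profile[[nm]]
    d <- round(stats::rnorm(length(gi), prof["offset"], prof["spread"]))
    pos <- genes$tss[gi] + ifelse(plus[gi], 1, -1) * d
    bg <- floor(stats::runif(n_bg, 0, cfg$chrom_length))
    pos <- as.integer(pmin(pmax(c(pos, bg), 0), cfg$chrom_length - 1))
    structure(list(
      factor_name = nm,
      factor_class = unname(cfg$factor_class[nm]),
      positions = pos,
      total_tags = length(pos),
      truth = list(
        log2_intensity = lat$f[, k],
        effect_weight = unname(cfg$effect_weights[nm]),
        realized_coef = unname(lat$realized_coef[nm]),
        offset = unname(prof["offset"]),
        spread = unname(prof["spread"]),
        n_background = n_bg
      )
    ), class = "tag_track")
  })
  names(tracks) <- cfg$factor_name
  tracks
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("tag_track %s [%s]: %d tags\n",
              x$factor_name, x$factor_class, x$total_tags))
  invisible(x)
}

#' Simulate gene sets with controlled TF/HM effect bias
#'
#' Emulates biological-process gene sets over the highly expressed genes.
#' Sets are sampled from the top \code{high_fraction} of genes by RPKM
#' (mirroring the downstream high-expression filter). A TF-favoured set
#' preferentially contains genes whose HM-specific expression component
#' (the part of the HM-driven component orthogonal to the TF-driven one
#' within the pool) is near its central value, so HM features add little
#' beyond what they share with TFs inside the set — and symmetrically for
#' HM-favoured sets; neutral sets are sampled uniformly. True bias labels
#' are recorded.
#'
#' @param genes output of \code{\link{simulate_genes}}.
#' @param n_sets number of sets.
#' @param size_range integer \code{c(min, max)} set size.
#' @param bias character vector (length \code{n_sets} or 1, recycled) in
#'   \code{c("TF", "HM", "neutral")}.
#' @param seed integer seed.
#' @param high_fraction expression quantile defining the sampling pool.
#' @param sharpness exponential down-weighting rate of the suppressed
#'   component's deviation (larger = stronger bias).
#' @return named list of character vectors of gene ids, with attribute
#'   \code{"bias"} giving each set's true label.
#' @export
simulate_gene_sets <- function(genes, n_sets, size_range, bias = "neutral",
                               seed = 1L, high_fraction = 0.15,
                               sharpness = 2) {
  if (n_sets == 0) return(stats::setNames(list(), character(0)))
  if (length(size_range) != 2 || size_range[1] > size_range[2])
    stop("size_range must be c(min, max) with min <= max")
  if (size_range[2] > nrow(genes)) stop("max set size exceeds n_genes")
  bias <- match.arg(bias, c("TF", "HM", "neutral"), several.ok = TRUE)
  bias <- rep_len(bias, n_sets)

  gt <- attr(genes, "ground_truth")
  if (is.null(gt)) stop("genes lacks ground truth; use simulate_genes()")
  tf_cols <- names(gt$factor_class)[gt$factor_class == "TF"]
  hm_cols <- names(gt$factor_class)[gt$factor_class != "TF"]
  tf_part <- drop(gt$f[, tf_cols, drop = FALSE] %*%
                    gt$realized_coef[tf_cols])
  hm_part <- drop(gt$f[, hm_cols, drop = FALSE] %*%
                    gt$realized_coef[hm_cols])

  pool <- select_high_expressed(genes, high_fraction)
  pool_idx <- match(pool$id, genes$id)
  if (size_range[1] > length(pool_idx))
    stop("min set size exceeds the high-expression pool")

  # class-specific residual within the pool: the part of one class's
  # expression component not explained by the other class's
  resid_in_pool <- function(part, other) {
    p <- part[pool_idx]; o <- other[pool_idx]
    stats::resid(stats::lm(p ~ o))
  }
  dev_w <- function(r) {
    u <- abs(r - stats::median(r)) / (stats::sd(r) + 1e-12)
    exp(-sharpness * u)
  }
  w_tf_fav <- dev_w(resid_in_pool(hm_part, tf_part))  # mute HM-specific info
  w_hm_fav <- dev_w(resid_in_pool(tf_part, hm_part))  # mute TF-specific info

  set.seed(seed)
  sets <- vector("list", n_sets)
  for (j in seq_len(n_sets)) {
    size <- if (size_range[1] == size_range[2]) size_range[1] else
      sample(seq(size_range[1], size_range[2]), 1)
    size <- min(size, length(pool_idx))
    pr <- switch(bias[j],
                 TF = w_tf_fav,
                 HM = w_hm_fav,
                 neutral = rep(1, length(pool_idx)))
    pick <- sample(length(pool_idx), size, prob = pr)
    sets[[j]] <- genes$id[pool_idx[pick]]
  }
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  attr(sets, "bias") <- stats::setNames(bias, names(sets))
  sets
}
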