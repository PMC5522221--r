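#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The generator emulates the statistical structure the downstream analyses
#' assume: per-factor tag tracks whose local density around each TSS follows
#' a factor-specific spatial profile, per-gene tag intensity coupled
#' log-linearly (with noise) to expression through known coefficients,
#' optionally engineered high-correlation factor pairs (redundancy), and a
#' single synthetic chromosome.
#'
#' Factors are named \code{TF01..}, \code{HM01..} and (optionally)
#' \code{DNase}. \code{effect_weights} are the relative log-scale couplings
#' between each factor's latent intensity and log2 expression; the generator
#' rescales them so that log2(RPKM + pseudocount) follows the configured
#' normal law exactly, and records the realized coefficients as ground truth
#' (see \code{\link{simulate_genes}}).
#'
#' @param n_genes number of genes (>= 10).
#' @param n_tf,n_hm number of TF and HM factors.
#' @param include_dnase add a DNase factor (class \code{"DNase"}, analysed
#'   with the HM class throughout).
#' @param chrom_length synthetic chromosome length in bp. Must allow TSS
#'   spacing > 24 kb so that the ±10 kb / ±2 kb windows never collide.
#' @param expression_log_mean,expression_log_sd mean and sd of
#'   log2(RPKM + pseudocount) across genes.
#' @param effect_weights named numeric vector of per-factor couplings;
#'   defaults to 1 for every factor. Names must match the factor names.
#' @param spatial_profile named list of \code{c(offset, spread)} pairs (bp)
#'   giving each factor's tag displacement distribution around the TSS
#'   (strand-oriented). Defaults: TFs centred on the TSS with 500 bp spread,
#'   HMs 800 bp spread, DNase 300 bp spread.
#' @param tags_per_factor total tags per track.
#' @param noise_sd sd of the per-gene expression noise on the log2 scale,
#'   relative to unit-variance factor latents (before rescaling).
#' @param background_fraction fraction of each track's tags scattered
#'   uniformly over the chromosome rather than placed around TSSs.
#' @param redundant_pairs list of \code{list(a, b, rho)} triples: factor
#'   \code{b}'s latent intensity is rebuilt as a mixture sharing factor
#'   \code{a}'s latent so that their population correlation equals
#'   \code{rho}. A factor may be the target (\code{b}) of at most one pair.
#' @param pseudocount pseudocount shared by expression and association
#'   features (log2(x + pseudocount)).
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 2000,
                       n_tf = 5,
                       n_hm = 4,
                       include_dnase = TRUE,
                       chrom_length = 6e7,
                       expression_log_mean = 5,
                       expression_log_sd = 2,
                       effect_weights = NULL,
                       spatial_profile = NULL,
                       tags_per_factor = 2e5,
                       noise_sd = 1,
                       background_fraction = 0.1,
                       redundant_pairs = list(),
                       pseudocount = 1,
                       seed = 1L) {
  stopifnot(is.numeric(n_genes), length(n_genes) == 1)
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (n_tf < 0 || n_hm < 0 || (n_tf + n_hm + include_dnase) < 1)
    stop("at least one factor is required")
  if (tags_per_factor < 1) stop("tags_per_factor must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  if (expression_log_sd <= 0) stop("expression_log_sd must be positive")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (seed >= 2^31 - 10 || seed < 0) stop("seed must be a non-negative 32-bit integer")

  fac <- factor_names(n_tf, n_hm, include_dnase)

  if (is.null(effect_weights)) {
    effect_weights <- stats::setNames(rep(1, length(fac$name)), fac$name)
  } else {
    if (is.null(names(effect_weights)) ||
        !all(names(effect_weights) %in% fac$name))
      stop("effect_weights must be named by factor name")
    w <- stats::setNames(rep(1, length(fac$name)), fac$name)
    w[names(effect_weights)] <- effect_weights
    effect_weights <- w
  }

  default_spread <- c(TF = 500, HM = 800, DNase = 300)
  prof <- lapply(seq_along(fac$name), function(i)
    c(offset = 0, spread = unname(default_spread[fac$class[i]])))
  names(prof) <- fac$name
  if (!is.null(spatial_profile)) {
    if (!all(names(spatial_profile) %in% fac$name))
      stop("spatial_profile names must be factor names")
    for (nm in names(spatial_profile)) {
      p <- spatial_profile[[nm]]
      if (length(p) != 2) stop("spatial_profile entries are c(offset, spread)")
      prof[[nm]] <- c(offset = unname(p[1]), spread = unname(p[2]))
    }
  }
  if (any(vapply(prof, function(p) p["spread"], 0) <= 0))
    stop("spread must be positive")

  seen_b <- character(0)
  for (rp in redundant_pairs) {
    if (length(rp) != 3) stop("redundant_pairs entries are list(a, b, rho)")
    a <- rp[[1]]; b <- rp[[2]]; rho <- rp[[3]]
    if (!a %in% fac$name || !b %in% fac$name)
      stop(sprintf("unknown factor name in redundant_pairs: %s/%s", a, b))
    if (a == b) stop("redundant pair must name two distinct factors")
    if (b %in% seen_b) stop(sprintf("factor %s is the target of two redundant pairs", b))
    if (abs(rho) >= 1) stop("target correlation must be in (-1, 1)")
    seen_b <- c(seen_b, b)
  }

  cfg <- list(
    n_genes = as.integer(n_genes), n_tf = as.integer(n_tf),
    n_hm = as.integer(n_hm), include_dnase = isTRUE(include_dnase),
    chrom_length = chrom_length,
    expression_log_mean = expression_log_mean,
    expression_log_sd = expression_log_sd,
    effect_weights = effect_weights,
    spatial_profile = prof,
    tags_per_factor = as.integer(tags_per_factor),
    noise_sd = noise_sd,
    background_fraction = background_fraction,
    redundant_pairs = redundant_pairs,
    pseudocount = pseudocount,
    seed = as.integer(seed),
    factor_name = fac$name, factor_class = fac$class
  )
  class(cfg) <- "sim_config"
  cfg
}

factor_names <- function(n_tf, n_hm, include_dnase) {
  name <- c(if (n_tf > 0) sprintf("TF%02d", seq_len(n_tf)),
            if (n_hm > 0) sprintf("HM%02d", seq_len(n_hm)),
            if (include_dnase) "DNase")
  class <- c(rep("TF", n_tf), rep("HM", n_hm),
             if (include_dnase) "DNase")
  list(name = name, class = stats::setNames(class, name))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d TFs, %d HMs%s, %d tags/factor, seed %d\n",
              x$n_genes, x$n_tf, x$n_hm,
              if (x$include_dnase) " + DNase" else "",
              x$tags_per_factor, x$seed))
  if (length(x$redundant_pairs))
    for (rp in x$redundant_pairs)
      cat(sprintf("  redundant pair: %s ~ %s (rho = %.2f)\n",
                  rp[[1]], rp[[2]], rp[[3]]))
  invisible(x)
}
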