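# Gene-set level comparison of TF-only vs HM-only predictive power among
# highly expressed genes, with BH-filtered correlation tests and ratio
# banding.

#' Select the highly expressed genes
#'
#' Ranks genes by RPKM (descending) and returns the top
#' ceil(fraction * n); ties at the cutoff are broken by gene id so the
#' selection is deterministic.
#'
#' @param genes gene table.
#' @param fraction fraction in (0, 1].
#' @return the selected rows of \code{genes}.
#' @export
select_high_expressed <- function(genes, fraction = 0.15) {
  if (nrow(genes) == 0) stop("empty gene table")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- ceiling(fraction * nrow(genes))
  ord <- order(-genes$rpkm, genes$id)
  genes[ord[seq_len(k)], , drop = FALSE]
}

#' Classify a TF/HM predictive-power ratio
#'
#' @param ratio finite positive ratio of TF-model PCC to HM-model PCC.
#' @return \code{"HM-superior"} (< 0.90), \code{"similar"}
#'   (0.90–1.10, boundaries included) or \code{"TF-superior"} (> 1.10).
#' @export
classify_ratio <- function(ratio) {
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be finite and positive")
  if (ratio < 0.90) "HM-superior"
  else if (ratio <= 1.10) "similar"
  else "TF-superior"
}

#' Per-set TF-vs-HM predictive comparison
#'
#' For each gene set: intersect with the highly expressed genes, discard
#' sets with fewer than \code{min_size} remaining members, fit SVR with
#' TF features only and with HM(+DNase) features only under
#' cross-validation, test each model's out-of-fold prediction/observation
#' correlation, BH-adjust the p-values across sets separately per model,
#' keep sets with both adjusted values < \code{alpha}, and band the
#' TF/HM PCC ratio.
#'
#' @param sets named list of gene-id vectors (synthetic or real
#'   biological-process sets).
#' @param assoc an \code{assoc_matrix} containing both TF and HM/DNase
#'   factors.
#' @param genes gene table aligned with \code{assoc}.
#' @param seed fold seed.
#' @param fraction high-expression fraction.
#' @param min_size minimum post-intersection set size.
#' @param folds CV folds (reduced to the set size when smaller, with a
#'   warning).
#' @param alpha BH-adjusted significance threshold.
#' @param pseudocount expression pseudocount.
#' @return a \code{geneset_results} data.frame: set_id, set_size,
#'   tf_pcc, hm_pcc, tf_p, hm_p, tf_q, hm_q, significant, ratio, band.
#'   Attribute \code{"n_discarded_small"} counts sets dropped by the
#'   size filter. \code{band} is NA for non-significant sets and for
#'   sets with non-positive HM PCC (undefined ratio, flagged in
#'   \code{band_note}).
#' @export
evaluate_gene_sets <- function(sets, assoc, genes, seed = 1L,
                               fraction = 0.15, min_size = 30,
                               folds = 10, alpha = 0.05,
                               pseudocount = 1) {
  stopifnot(identical(genes$id, assoc$gene_ids))
  unknown <- setdiff(unique(unlist(sets)), genes$id)
  if (length(unknown))
    stop("sets reference unknown gene ids, e.g. ", unknown[1])
  tf_cols <- assoc$factor_names[assoc$factor_classes == "TF"]
  hm_cols <- assoc$factor_names[assoc$factor_classes != "TF"]
  if (!length(tf_cols) || !length(hm_cols))
    stop("need both TF and HM/DNase factors")

  high <- select_high_expressed(genes, fraction)
  y_all <- log_expression(genes, pseudocount)

  rows <- list()
  n_small <- 0L
  for (sid in names(sets)) {
    member <- intersect(sets[[sid]], high$id)
    if (length(member) < min_size) { n_small <- n_small + 1L; next }
    idx <- match(member, genes$id)
    y <- y_all[idx]
    k <- folds
    if (k > length(idx)) {
      warning("set ", sid, ": fold count reduced to set size")
      k <- length(idx)
    }
    fold <- make_folds(length(idx), k, seed)
    rep_tf <- fit_svr(assoc$logged[idx, tf_cols, drop = FALSE], y,
                      folds = fold, seed = seed)
    rep_hm <- fit_svr(assoc$logged[idx, hm_cols, drop = FALSE], y,
                      folds = fold, seed = seed)
    rows[[sid]] <- data.frame(
      set_id = sid, set_size = length(idx),
      tf_pcc = rep_tf$pcc, hm_pcc = rep_hm$pcc,
      tf_p = stats::cor.test(rep_tf$predictions, y)$p.value,
      hm_p = stats::cor.test(rep_hm$predictions, y)$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(set_id = character(0), set_size = integer(0),
                      tf_pcc = numeric(0), hm_pcc = numeric(0),
                      tf_p = numeric(0), hm_p = numeric(0),
                      tf_q = numeric(0), hm_q = numeric(0),
                      significant = logical(0), ratio = numeric(0),
                      band = character(0), band_note = character(0))
    attr(out, "n_discarded_small") <- n_small
    class(out) <- c("geneset_results", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  out$tf_q <- stats::p.adjust(out$tf_p, method = "BH")
  out$hm_q <- stats::p.adjust(out$hm_p, method = "BH")
  out$significant <- out$tf_q < alpha & out$hm_q < alpha
  out$ratio <- ifelse(out$hm_pcc > 0, out$tf_pcc / out$hm_pcc, NA_real_)
  out$band <- NA_character_
  out$band_note <- ""
  for (i in seq_len(nrow(out))) {
    if (!out$significant[i]) next
    if (out$hm_pcc[i] <= 0 || !is.finite(out$ratio[i]) || out$ratio[i] <= 0) {
      out$band_note[i] <- "undefined ratio (non-positive HM PCC)"
      next
    }
    out$band[i] <- classify_ratio(out$ratio[i])
  }
  rownames(out) <- NULL
  attr(out, "n_discarded_small") <- n_small
  class(out) <- c("geneset_results", class(out))
  out
}
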