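# Per-gene scalar association strengths.
#
# TFAS (TF association strength): kernel-weighted sum over the 100 bins,
#   a_ik = sum_j N_ij * F(d_j),  F(d) = exp(-d^2 / 2h^2) / (h * sqrt(2*pi)),
# with h from Silverman's rule of thumb on the pooled tag-to-TSS
# distances. HMAS (HM/DNase association strength): plain sum over the 20
# bins. Both are then log2(x + pseudocount) transformed.

#' Silverman rule-of-thumb bandwidth from tag-to-TSS distances
#'
#' Pools the strand-oriented signed distances (tag - TSS, sign flipped on
#' minus-strand genes) of all tags falling inside the scheme's window of
#' any gene, and applies Silverman's rule
#' h = 0.9 * min(sd, IQR / 1.34) * n^(-1/5).
#'
#' @param track a \code{tag_track}.
#' @param genes gene table.
#' @param scheme window definition, usually \code{make_scheme("TF")}.
#' @return bandwidth in bp (positive scalar) with attribute \code{"n"} =
#'   number of pooled distances.
#' @export
rule_of_thumb_bandwidth <- function(track, genes, scheme) {
  d <- tss_distances(track, genes, scheme)
  if (length(unique(d)) < 2)
    stop("degenerate sample: need at least 2 distinct tag-to-TSS distances")
  h <- silverman_bw(d)
  if (!is.finite(h) || h <= 0)
    stop("degenerate sample: rule-of-thumb bandwidth is not positive")
  attr(h, "n") <- length(d)
  h
}

silverman_bw <- function(x) {
  0.9 * min(stats::sd(x), stats::IQR(x) / 1.34) * length(x)^(-1 / 5)
}

# Strand-oriented signed distances of in-window tags to the nearest TSS.
tss_distances <- function(track, genes, scheme) {
  pos <- sort(as.numeric(track$positions))
  half <- scheme$window_upstream
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    w0 <- genes$tss[i] - half
    lo <- findInterval(w0 - 0.5, pos) + 1L
    hi <- findInterval(w0 + 2 * half - 0.5, pos)
    if (hi < lo) next
    d <- pos[lo:hi] - genes$tss[i]
    if (genes$strand[i] == "-") d <- -d
    out[[i]] <- d
  }
  unlist(out)
}

#' Gaussian kernel weights at bin midpoints
#'
#' @param scheme bin scheme supplying midpoints d_j.
#' @param bandwidth kernel bandwidth h in bp.
#' @return a \code{kernel_spec} list with \code{bandwidth} and per-bin
#'   \code{weights} F(d_j) (normalized Gaussian density, area 1 over
#'   continuous d; no renormalization over the discrete midpoints).
#' @export
kernel_spec <- function(scheme, bandwidth) {
  stopifnot(bandwidth > 0)
  structure(list(bandwidth = bandwidth,
                 weights = stats::dnorm(scheme$bin_midpoints, 0, bandwidth),
                 midpoints = scheme$bin_midpoints),
            class = "kernel_spec")
}

#' TF association strength of one binned track
#'
#' @param binned a \code{binned_signal} with the TF scheme (100 bins).
#' @param kernel a \code{\link{kernel_spec}} on the same scheme.
#' @param pseudocount added inside the log2.
#' @return an \code{assoc_column} list: \code{factor_name},
#'   \code{factor_class}, \code{gene_ids}, \code{raw}, \code{logged},
#'   \code{pseudocount}, \code{bandwidth}.
#' @export
tfas <- function(binned, kernel, pseudocount = 1) {
  stopifnot(inherits(binned, "binned_signal"), inherits(kernel, "kernel_spec"))
  if (binned$scheme$n_bins != length(kernel$weights))
    stop("kernel and scheme bin counts differ")
  raw <- drop(binned$matrix %*% kernel$weights)
  new_assoc_column(binned, raw, pseudocount, bandwidth = kernel$bandwidth)
}

#' HM/DNase association strength of one binned track
#'
#' @param binned a \code{binned_signal} with the HM/DNase scheme (20 bins).
#' @param pseudocount added inside the log2.
#' @return an \code{assoc_column}; see \code{\link{tfas}}.
#' @export
hmas <- function(binned, pseudocount = 1) {
  stopifnot(inherits(binned, "binned_signal"))
  raw <- rowSums(binned$matrix)
  new_assoc_column(binned, raw, pseudocount, bandwidth = NA_real_)
}

new_assoc_column <- function(binned, raw, pseudocount, bandwidth) {
  raw <- unname(raw)
  if (pseudocount <= 0 && any(raw <= 0))
    stop("log-domain error: non-positive pseudocount with zero signal")
  structure(list(factor_name = binned$factor_name,
                 factor_class = binned$factor_class,
                 gene_ids = binned$gene_ids,
                 raw = raw,
                 logged = log2(raw + pseudocount),
                 pseudocount = pseudocount,
                 bandwidth = bandwidth),
            class = "assoc_column")
}

#' Assemble association columns into a genes × factors matrix
#'
#' @param columns list of \code{assoc_column}s sharing the same gene ids.
#' @return an \code{assoc_matrix} list: \code{gene_ids},
#'   \code{factor_names}, \code{factor_classes}, \code{raw} and
#'   \code{logged} matrices, \code{pseudocounts}, \code{bandwidths}.
#' @export
assoc_assemble <- function(columns) {
  if (length(columns) == 0) stop("alignment error: no columns to assemble")
  ids <- columns[[1]]$gene_ids
  for (cl in columns)
    if (!identical(cl$gene_ids, ids))
      stop("alignment error: gene ids differ across columns")
  nm <- unname(vapply(columns, function(cl) cl$factor_name, ""))
  if (anyDuplicated(nm)) stop("duplicate factor names")
  raw <- do.call(cbind, lapply(columns, function(cl) cl$raw))
  logged <- do.call(cbind, lapply(columns, function(cl) cl$logged))
  colnames(raw) <- colnames(logged) <- nm
  structure(list(
    gene_ids = ids,
    factor_names = nm,
    factor_classes = stats::setNames(
      vapply(columns, function(cl) cl$factor_class, ""), nm),
    raw = raw,
    logged = logged,
    pseudocounts = stats::setNames(
      vapply(columns, function(cl) cl$pseudocount, 0), nm),
    bandwidths = stats::setNames(
      vapply(columns, function(cl) cl$bandwidth, 0), nm)
  ), class = "assoc_matrix")
}

#' Bin all tracks and assemble the association matrix
#'
#' Convenience wrapper running \code{\link{bin_track}},
#' \code{\link{rule_of_thumb_bandwidth}} + \code{\link{tfas}} for TF
#' tracks and \code{\link{hmas}} for HM/DNase tracks, then
#' \code{\link{assoc_assemble}}.
#'
#' @param tracks named list of \code{tag_track}s.
#' @param genes gene table.
#' @param pseudocount shared feature pseudocount.
#' @return an \code{assoc_matrix}.
#' @export
associate_tracks <- function(tracks, genes, pseudocount = 1) {
  cols <- lapply(tracks, function(tr) {
    scheme <- make_scheme(tr$factor_class)
    b <- bin_track(tr, genes, scheme)
    if (tr$factor_class == "TF") {
      h <- rule_of_thumb_bandwidth(tr, genes, scheme)
      tfas(b, kernel_spec(scheme, h), pseudocount)
    } else {
      hmas(b, pseudocount)
    }
  })
  assoc_assemble(cols)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix: %d genes x %d factors (%s)\n",
              length(x$gene_ids), length(x$factor_names),
              paste(table(x$factor_classes), names(table(x$factor_classes)),
                    collapse = ", ")))
  invisible(x)
}

# Subset an assoc_matrix to named factors, preserving metadata.
#' Subset an association matrix by factor names
#' @param assoc an \code{assoc_matrix}.
#' @param factors character vector of factor names to keep.
#' @return an \code{assoc_matrix} with the selected columns.
#' @export
assoc_subset <- function(assoc, factors) {
  missing <- setdiff(factors, assoc$factor_names)
  if (length(missing))
    stop("unknown factors: ", paste(missing, collapse = ", "))
  structure(list(
    gene_ids = assoc$gene_ids,
    factor_names = factors,
    factor_classes = assoc$factor_classes[factors],
    raw = assoc$raw[, factors, drop = FALSE],
    logged = assoc$logged[, factors, drop = FALSE],
    pseudocounts = assoc$pseudocounts[factors],
    bandwidths = assoc$bandwidths[factors]
  ), class = "assoc_matrix")
}
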