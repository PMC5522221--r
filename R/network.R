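# Redundancy quantification and partial-correlation network inference.
#
# The network uses a shrinkage estimate of the correlation matrix
# (analytic Schafer-Strimmer intensity toward the identity), inverts it,
# and scales the negated inverse to unit diagonal to obtain partial
# correlations. Edges are ranked by |partial correlation|; for a fixed
# dataset this ordering matches significance-based ranking, and only the
# top edges are kept.

#' Pairwise Pearson correlations of association features
#'
#' @param assoc an \code{assoc_matrix} (logged features are used) or a
#'   plain numeric matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_heatmap <- function(assoc) {
  M <- if (inherits(assoc, "assoc_matrix")) assoc$logged else as.matrix(assoc)
  if (nrow(M) < 3) stop("need at least 3 genes")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: constant column(s): ",
         paste(colnames(M)[sds == 0], collapse = ", "))
  stats::cor(M)
}

#' Correlation between two models' predictions
#'
#' Pearson correlation of out-of-fold prediction vectors, e.g. of the
#' TF-only and the HM-only model — high values indicate the two feature
#' classes carry statistically redundant information about expression.
#'
#' @param report_a,report_b \code{model_report}s fitted on the same genes
#'   in the same order.
#' @return scalar correlation.
#' @export
cross_model_pcc <- function(report_a, report_b) {
  pa <- report_a$predictions; pb <- report_b$predictions
  if (length(pa) != length(pb))
    stop("alignment error: prediction vectors differ in length")
  stats::cor(pa, pb)
}

# Analytic shrinkage of a correlation matrix toward the identity.
# lambda* = sum_{i<j} var_hat(r_ij) / sum_{i<j} r_ij^2, clipped to
# [floor, 1]; var_hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - mean_w)^2
# with w_kij the products of standardized observations.
shrink_correlation <- function(M, floor = 1e-3) {
  n <- nrow(M); p <- ncol(M)
  R <- stats::cor(M)
  Xs <- scale(M)
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- Xs[, i] * Xs[, j]
      num <- num + n / (n - 1)^3 * sum((w - mean(w))^2)
      den <- den + R[i, j]^2
    }
  }
  lambda <- if (den == 0) 1 else min(1, max(floor, num / den))
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  attr(Rs, "lambda") <- lambda
  Rs
}

#' Infer a partial-correlation network
#'
#' Estimates partial correlations among the supplied variables (factor
#' association strengths plus, typically, log expression as one more
#' variable) from the shrunken correlation matrix, and keeps the
#' \code{n_edges} edges of largest absolute partial correlation.
#'
#' @param data numeric matrix (genes × variables) with column names;
#'   build it with \code{\link{network_data}}.
#' @param n_edges number of edges to keep (all pairs, with a warning, if
#'   fewer exist).
#' @param shrinkage_floor lower bound on the shrinkage intensity,
#'   guaranteeing invertibility on collinear data.
#' @return a \code{network_report} list: \code{nodes}, \code{edges}
#'   (data.frame node1/node2/pcor/rank/sign), \code{pcor_matrix},
#'   \code{shrinkage_intensity}, \code{n_edges_selected}.
#' @export
partial_correlation_network <- function(data, n_edges = 60,
                                        shrinkage_floor = 1e-3) {
  M <- as.matrix(data)
  p <- ncol(M)
  if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(p))
  if (nrow(M) <= p)
    warning("fewer genes than variables; estimates will be unstable")
  Rs <- shrink_correlation(M, floor = shrinkage_floor)
  Om <- tryCatch(solve(Rs), error = function(e)
    stop("estimation error: shrunk matrix is singular; raise shrinkage_floor"))
  D <- 1 / sqrt(diag(Om))
  P <- -Om * tcrossprod(D)
  diag(P) <- 1
  dimnames(P) <- dimnames(Rs)

  iu <- which(upper.tri(P), arr.ind = TRUE)
  ed <- data.frame(node1 = colnames(P)[iu[, 1]],
                   node2 = colnames(P)[iu[, 2]],
                   pcor = P[iu], stringsAsFactors = FALSE)
  # order-invariant ranking: |pcor| desc, then node names
  swap <- ed$node1 > ed$node2
  tmp <- ed$node1[swap]; ed$node1[swap] <- ed$node2[swap]; ed$node2[swap] <- tmp
  ed <- ed[order(-abs(ed$pcor), ed$node1, ed$node2), ]
  if (n_edges > nrow(ed)) {
    warning("requested more edges than pairs; returning all ", nrow(ed))
    n_edges <- nrow(ed)
  }
  ed <- ed[seq_len(n_edges), ]
  ed$rank <- seq_len(n_edges)
  ed$sign <- ifelse(ed$pcor >= 0, "positive", "negative")
  rownames(ed) <- NULL

  structure(list(nodes = colnames(P), edges = ed, pcor_matrix = P,
                 shrinkage_intensity = attr(Rs, "lambda"),
                 n_edges_selected = n_edges),
            class = "network_report")
}

#' Assemble the network input matrix
#'
#' @param assoc an \code{assoc_matrix}.
#' @param genes gene table (optional); when given, log2(RPKM +
#'   pseudocount) is appended as an \code{"expression"} column.
#' @param pseudocount expression pseudocount.
#' @return numeric matrix of logged features (+ expression).
#' @export
network_data <- function(assoc, genes = NULL, pseudocount = 1) {
  M <- assoc$logged
  if (!is.null(genes)) {
    stopifnot(identical(genes$id, assoc$gene_ids))
    M <- cbind(M, expression = log_expression(genes, pseudocount))
  }
  M
}

#' Leave-genes-out robustness of the network
#'
#' Re-infers the network \code{n_reps} times after removing
#' \code{n_remove} randomly chosen genes, and compares each replicate's
#' edge set to the full-data edge set.
#'
#' @param data network input matrix (see \code{\link{network_data}}).
#' @param n_reps replicates.
#' @param n_remove genes removed per replicate.
#' @param seed integer seed for the removal draws.
#' @param n_edges,shrinkage_floor passed to
#'   \code{\link{partial_correlation_network}}.
#' @return a \code{network_robustness} list: \code{edge_frequency}
#'   (selection frequency across replicates for every edge ever
#'   selected, full-data edges flagged), \code{jaccard} (per-replicate
#'   Jaccard similarity to the full-data edge set), \code{mean_jaccard},
#'   \code{full_network}.
#' @export
network_robustness <- function(data, n_reps = 50, n_remove = 200,
                               seed = 1L, n_edges = 60,
                               shrinkage_floor = 1e-3) {
  M <- as.matrix(data)
  if (nrow(M) <= n_remove + ncol(M))
    stop("sizing error: need n_genes > n_remove + n_variables")
  full <- partial_correlation_network(M, n_edges, shrinkage_floor)
  key <- function(ed) paste(ed$node1, ed$node2, sep = "|")
  full_keys <- key(full$edges)

  set.seed(seed)
  tab <- new.env(parent = emptyenv())
  jac <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    drop_idx <- if (n_remove > 0) sample(nrow(M), n_remove) else integer(0)
    sub <- if (length(drop_idx)) M[-drop_idx, , drop = FALSE] else M
    net <- partial_correlation_network(sub, n_edges, shrinkage_floor)
    ks <- key(net$edges)
    for (k in ks) assign(k, (if (exists(k, tab)) get(k, tab) else 0L) + 1L, tab)
    jac[r] <- length(intersect(ks, full_keys)) /
      length(union(ks, full_keys))
  }
  all_keys <- ls(tab)
  freq <- data.frame(
    edge = all_keys,
    frequency = vapply(all_keys, function(k) get(k, tab), 0L) / n_reps,
    in_full = all_keys %in% full_keys,
    stringsAsFactors = FALSE)
  freq <- freq[order(-freq$frequency, freq$edge), ]
  rownames(freq) <- NULL
  structure(list(edge_frequency = freq, jaccard = jac,
                 mean_jaccard = mean(jac), full_network = full),
            class = "network_robustness")
}

#' @export
print.network_report <- function(x, ...) {
  cat(sprintf("network_report: %d nodes, %d edges, shrinkage %.4f\n",
              length(x$nodes), nrow(x$edges), x$shrinkage_intensity))
  invisible(x)
}

#' @export
print.network_robustness <- function(x, ...) {
  cat(sprintf("network_robustness: %d reps, mean Jaccard %.3f\n",
              length(x$jaccard), x$mean_jaccard))
  invisible(x)
}
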