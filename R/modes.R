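# Combination-mode analysis: every non-empty factor subset is a "mode";
# one SVR per mode, all modes sharing the same CV fold assignment so PCC
# differences reflect the feature sets rather than fold noise.

#' Enumerate all non-empty factor subsets
#'
#' @param factor_names up to 20 factor names (2^n - 1 subsets; the guard
#'   prevents runaway enumeration).
#' @return list of character vectors, ordered by (cardinality,
#'   lexicographic); names are the comma-joined sorted members.
#' @export
enumerate_modes <- function(factor_names) {
  n <- length(factor_names)
  if (n < 1) stop("need at least one factor")
  if (n > 20) stop("size guard: refusing to enumerate 2^", n, " subsets")
  fac <- sort(factor_names)
  out <- list()
  for (c_ in seq_len(n)) {
    cmb <- utils::combn(fac, c_, simplify = FALSE)
    out <- c(out, cmb)
  }
  names(out) <- vapply(out, paste, "", collapse = ",")
  out
}

#' Cross-validated SVR accuracy of each mode
#'
#' @param subsets list of factor-name vectors (e.g. from
#'   \code{\link{enumerate_modes}}); duplicates are dropped with a
#'   warning.
#' @param assoc an \code{assoc_matrix} containing every factor used.
#' @param y log-expression response.
#' @param seed fold seed shared across all modes.
#' @param folds number of folds.
#' @param ... further arguments to \code{\link{fit_svr}}.
#' @return data.frame with \code{subset} (comma-joined name),
#'   \code{cardinality}, \code{pcc}, \code{cv_r2}; attribute
#'   \code{"members"} holds the subset list.
#' @export
evaluate_modes <- function(subsets, assoc, y, seed = 1L, folds = 10, ...) {
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  if (anyDuplicated(keys)) {
    warning("duplicate subsets dropped")
    subsets <- subsets[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  missing <- setdiff(unique(unlist(subsets)), assoc$factor_names)
  if (length(missing))
    stop("subsets reference unknown factors: ", paste(missing, collapse = ", "))

  fold <- make_folds(length(y), folds, seed)
  res <- lapply(seq_along(subsets), function(i) {
    s <- subsets[[i]]
    rep <- tryCatch(
      fit_svr(assoc$logged[, s, drop = FALSE], y, folds = fold,
              seed = seed, ...),
      error = function(e) stop("mode {", keys[i], "}: ",
                               conditionMessage(e), call. = FALSE))
    data.frame(subset = keys[i], cardinality = length(s),
               pcc = rep$pcc, cv_r2 = rep$cv_r2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "members") <- subsets
  attr(out, "fold_seed") <- seed
  out
}

#' Summarize a full mode enumeration
#'
#' Computes the per-cardinality maximum-PCC curve, the top modes at one
#' cardinality (those reaching at least \code{threshold_fraction} of the
#' all-factor mode's PCC), per-factor appearance frequencies among the
#' top modes, and pairwise co-occurrence counts.
#'
#' @param results output of \code{\link{evaluate_modes}} over a full
#'   enumeration.
#' @param cardinality subset size examined for over-representation.
#' @param threshold_fraction fraction of the all-factor PCC a mode must
#'   reach to count as a top mode.
#' @param restrict_to optional factor names: top modes must draw all
#'   members from this set (e.g. HMs only, excluding DNase).
#' @return a \code{mode_summary} list: \code{max_curve} (data.frame
#'   cardinality/max_pcc/best_subset), \code{all_factor_pcc},
#'   \code{top_modes}, \code{factor_frequency} (count and fraction),
#'   \code{cooccurrence} (symmetric count matrix), \code{cardinality},
#'   \code{threshold_fraction}.
#' @export
summarize_modes <- function(results, cardinality = 4,
                            threshold_fraction = 0.95,
                            restrict_to = NULL) {
  members <- attr(results, "members")
  factors <- sort(unique(unlist(members)))
  n <- length(factors)

  max_curve <- do.call(rbind, lapply(seq_len(n), function(c_) {
    sub <- results[results$cardinality == c_, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(cardinality = c_, max_pcc = NA_real_,
                        best_subset = NA_character_))
    best <- sub[order(-sub$pcc, sub$subset), ][1, ]
    data.frame(cardinality = c_, max_pcc = best$pcc,
               best_subset = best$subset, stringsAsFactors = FALSE)
  }))

  all_key <- paste(factors, collapse = ",")
  all_row <- results[results$subset == all_key, ]
  if (nrow(all_row) != 1)
    stop("results do not contain the all-factor mode; full enumeration required")
  all_pcc <- all_row$pcc

  cand <- results[results$cardinality == cardinality, , drop = FALSE]
  mem <- members[match(cand$subset, vapply(members, paste, "", collapse = ","))]
  if (!is.null(restrict_to)) {
    keep <- vapply(mem, function(s) all(s %in% restrict_to), TRUE)
    cand <- cand[keep, , drop = FALSE]
    mem <- mem[keep]
  }
  pass <- cand$pcc >= threshold_fraction * all_pcc
  top <- cand[pass, , drop = FALSE]
  top_mem <- mem[pass]
  if (nrow(top) == 0)
    warning("no modes at cardinality ", cardinality, " pass the threshold")

  counts <- stats::setNames(integer(n), factors)
  cooc <- matrix(0L, n, n, dimnames = list(factors, factors))
  for (s in top_mem) {
    counts[s] <- counts[s] + 1L
    cooc[s, s] <- cooc[s, s] + 1L
  }
  freq <- data.frame(factor_name = factors, count = as.integer(counts),
                     fraction = if (nrow(top)) as.numeric(counts) / nrow(top)
                                else rep(NA_real_, n),
                     stringsAsFactors = FALSE)

  structure(list(max_curve = max_curve, all_factor_pcc = all_pcc,
                 top_modes = top, factor_frequency = freq,
                 cooccurrence = cooc, cardinality = cardinality,
                 threshold_fraction = threshold_fraction),
            class = "mode_summary")
}

#' Best mode at a given cardinality
#'
#' @param results output of \code{\link{evaluate_modes}}.
#' @param cardinality subset size.
#' @return one-row data.frame (subset, cardinality, pcc, cv_r2) with
#'   attribute \code{"tied"} = TRUE when the maximum was not unique
#'   (lexicographically first reported).
#' @export
best_mode_at <- function(results, cardinality) {
  sub <- results[results$cardinality == cardinality, , drop = FALSE]
  if (nrow(sub) == 0) stop("no modes at cardinality ", cardinality)
  ord <- sub[order(-sub$pcc, sub$subset), ]
  best <- ord[1, ]
  attr(best, "tied") <- nrow(ord) > 1 && isTRUE(all.equal(ord$pcc[2], best$pcc))
  best
}

#' @export
print.mode_summary <- function(x, ...) {
  cat(sprintf(
    "mode_summary: all-factor PCC %.3f; %d top modes at cardinality %d (>= %.0f%%)\n",
    x$all_factor_pcc, nrow(x$top_modes), x$cardinality,
    100 * x$threshold_fraction))
  invisible(x)
}
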