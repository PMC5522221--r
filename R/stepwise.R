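# Stepwise selection of the top TFs for predicting log expression.
# Bidirectional: forward steps add the candidate that best improves the
# criterion, each followed by a backward pass removing any included
# factor whose removal improves it further. Stops when nothing improves
# or when the cap is reached. Ties are broken lexicographically by
# factor name, so permuting the candidate column order cannot change the
# selected set.

#' Stepwise selection of predictive factors
#'
#' @param X an \code{assoc_matrix} or numeric feature matrix of
#'   candidates.
#' @param y log-expression response.
#' @param cap maximum number of factors to select (15 mirrors selecting
#'   the "optimal" TFs from a larger downloaded pool).
#' @param criterion \code{"aic"} (default) or \code{"f_test"} with entry
#'   p < \code{p_enter} and removal p > \code{p_remove}.
#' @param p_enter,p_remove F-test thresholds (used when
#'   \code{criterion = "f_test"}).
#' @return a \code{selection_report} list: \code{selected} (factor names
#'   in final inclusion order), \code{steps} (data frame of actions with
#'   the criterion value after each), \code{cap}, \code{criterion_kind}.
#' @export
stepwise_select <- function(X, y, cap = 15, criterion = c("aic", "f_test"),
                            p_enter = 0.05, p_remove = 0.10) {
  criterion <- match.arg(criterion)
  X <- as_feature_matrix(X)
  check_model_inputs(X, y)
  if (length(y) <= cap + 1) stop("need n_genes > cap + 1")
  candidates <- sort(colnames(X))
  if (cap > length(candidates)) {
    warning("cap exceeds candidate count; returning all candidates")
    cap <- length(candidates)
  }

  n <- length(y)
  rss_of <- function(vars) {
    if (length(vars) == 0) return(sum((y - mean(y))^2))
    f <- stats::lm.fit(cbind(1, X[, vars, drop = FALSE]), y)
    sum(f$residuals^2)
  }
  aic_of <- function(rss, p) n * log(rss / n) + 2 * (p + 1)

  selected <- character(0)
  steps <- list()
  cur_rss <- rss_of(selected)

  improves_entry <- function(cand) {
    # returns criterion value after adding cand, or NA if not admissible
    new_rss <- rss_of(c(selected, cand))
    if (criterion == "aic") {
      aic_of(new_rss, length(selected) + 1)
    } else {
      p1 <- length(selected) + 1
      fstat <- (cur_rss - new_rss) / (new_rss / (n - p1 - 1))
      stats::pf(fstat, 1, n - p1 - 1, lower.tail = FALSE)
    }
  }

  repeat {
    if (length(selected) >= cap) break
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0) break
    vals <- vapply(pool, improves_entry, 0)
    best <- pool[order(vals, pool)][1]
    cur_crit <- if (criterion == "aic") aic_of(cur_rss, length(selected))
                else p_enter
    ok <- if (criterion == "aic") vals[best] < cur_crit
          else vals[best] < p_enter
    if (!ok) break
    selected <- c(selected, best)
    cur_rss <- rss_of(selected)
    steps[[length(steps) + 1]] <- data.frame(
      step = length(steps) + 1, action = "add", factor_name = best,
      criterion = unname(vals[best]), stringsAsFactors = FALSE)

    # backward pass
    repeat {
      if (length(selected) < 2) break
      drop_val <- vapply(selected, function(v) {
        new_rss <- rss_of(setdiff(selected, v))
        if (criterion == "aic") {
          aic_of(new_rss, length(selected) - 1)
        } else {
          p0 <- length(selected) - 1
          fstat <- (new_rss - cur_rss) / (cur_rss / (n - p0 - 2))
          stats::pf(fstat, 1, n - p0 - 2, lower.tail = FALSE)
        }
      }, 0)
      worst <- selected[order(if (criterion == "aic") drop_val else -drop_val,
                              selected)][1]
      ok_drop <- if (criterion == "aic")
        drop_val[worst] < aic_of(cur_rss, length(selected))
      else drop_val[worst] > p_remove
      if (!ok_drop) break
      selected <- setdiff(selected, worst)
      cur_rss <- rss_of(selected)
      steps[[length(steps) + 1]] <- data.frame(
        step = length(steps) + 1, action = "drop", factor_name = worst,
        criterion = unname(drop_val[worst]), stringsAsFactors = FALSE)
    }
  }

  structure(list(
    selected = selected,
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(0), action = character(0),
                 factor_name = character(0), criterion = numeric(0)),
    cap = cap,
    criterion_kind = criterion
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("stepwise selection (%s): %d factors: %s\n",
              x$criterion_kind, length(x$selected),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}
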