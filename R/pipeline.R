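# End-to-end orchestration with a provenance manifest.

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order — simulate genes/tracks/sets,
#' bin and associate, fit the log-linear and SVR models (TF-only,
#' HM(+DNase)-only, all factors), enumerate and evaluate combination
#' modes per class, infer the partial-correlation network with
#' robustness replicates, and run the gene-set TF/HM ratio analysis —
#' writing TSV/JSON outputs plus a manifest JSON (parameters, seeds,
#' package version, output checksums) under \code{outdir}.
#'
#' @param cfg a \code{\link{sim_config}}; all stage randomness derives
#'   from \code{cfg$seed}.
#' @param outdir output directory (created if absent).
#' @param stages character vector of stage toggles, a subset of
#'   \code{c("simulate", "associate", "fit", "modes", "network",
#'   "genesets")}. Later stages recompute their inputs in memory even if
#'   an earlier stage's file output is toggled off.
#' @param mode_cardinality cardinality examined in the mode summaries.
#' @param mode_threshold top-mode threshold fraction.
#' @param n_edges,n_reps,n_remove network parameters.
#' @param n_sets,set_size_range,set_bias gene-set generation parameters.
#' @param folds CV folds.
#' @return (invisibly) a list with the in-memory results of every stage
#'   run, plus \code{manifest}.
#' @export
run_pipeline <- function(cfg, outdir,
                         stages = c("simulate", "associate", "fit",
                                    "modes", "network", "genesets"),
                         mode_cardinality = 4, mode_threshold = 0.95,
                         n_edges = 60, n_reps = 50, n_remove = 200,
                         n_sets = 12, set_size_range = c(30, 80),
                         set_bias = c("TF", "HM", "neutral"),
                         folds = 10) {
  stopifnot(inherits(cfg, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- list()
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  genes <- run_stage("simulate", simulate_genes(cfg))
  tracks <- run_stage("simulate", simulate_tracks(genes, cfg))
  if ("simulate" %in% stages) {
    write_gene_table(genes, emit(file.path(outdir, "genes.tsv")))
    write_gene_bed(genes, emit(file.path(outdir, "genes.bed")))
    for (tr in tracks)
      write_tag_track(tr, emit(file.path(
        outdir, paste0("track_", tr$factor_name, ".bed"))))
    res$genes <- genes; res$tracks <- tracks
  }

  assoc <- run_stage("associate", associate_tracks(tracks, genes,
                                                   cfg$pseudocount))
  y <- log_expression(genes, cfg$pseudocount)
  if ("associate" %in% stages) {
    write_assoc(assoc, emit(file.path(outdir, "assoc.tsv")))
    res$assoc <- assoc
  }

  tf_cols <- assoc$factor_names[assoc$factor_classes == "TF"]
  hm_cols <- assoc$factor_names[assoc$factor_classes != "TF"]

  if ("fit" %in% stages) {
    fits <- run_stage("fit", {
      sets <- list(TF = tf_cols, HM = hm_cols, all = assoc$factor_names)
      lapply(sets, function(cols) {
        Xs <- assoc$logged[, cols, drop = FALSE]
        list(log_linear = fit_log_linear(Xs, y, folds, cfg$seed),
             svr = fit_svr(Xs, y, folds, cfg$seed))
      })
    })
    tab <- do.call(rbind, lapply(names(fits), function(nm) {
      do.call(rbind, lapply(c("log_linear", "svr"), function(md) {
        m <- fits[[nm]][[md]]
        data.frame(feature_class = nm, model = md, r2 = m$r2,
                   cv_r2 = m$cv_r2, pcc = m$pcc,
                   stability_rmse = m$stability_rmse)
      }))
    }))
    utils::write.table(tab, emit(file.path(outdir, "model_accuracy.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$fits <- fits
    res$model_accuracy <- tab
  }

  if ("modes" %in% stages) {
    res$modes <- run_stage("modes", lapply(
      list(TF = tf_cols, HM = hm_cols), function(cols) {
        ev <- evaluate_modes(enumerate_modes(cols), assoc, y,
                             seed = cfg$seed, folds = folds)
        list(results = ev,
             summary = summarize_modes(
               ev, cardinality = min(mode_cardinality, length(cols)),
               threshold_fraction = mode_threshold))
      }))
    for (cl in names(res$modes)) {
      utils::write.table(res$modes[[cl]]$results,
                         emit(file.path(outdir, paste0("modes_", cl, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$modes[[cl]]$summary$max_curve,
                         emit(file.path(outdir, paste0("max_curve_", cl, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$modes[[cl]]$summary$factor_frequency,
                         emit(file.path(outdir, paste0("frequency_", cl, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("network" %in% stages) {
    res$network <- run_stage("network", {
      nd <- network_data(assoc, genes, cfg$pseudocount)
      net <- partial_correlation_network(nd, n_edges = min(
        n_edges, choose(ncol(nd), 2)))
      rob <- network_robustness(nd, n_reps = n_reps, n_remove = n_remove,
                                seed = cfg$seed, n_edges = net$n_edges_selected)
      list(heatmap = correlation_heatmap(assoc), network = net,
           robustness = rob)
    })
    utils::write.table(res$network$network$edges,
                       emit(file.path(outdir, "network_edges.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(factor_name = rownames(res$network$heatmap),
                 res$network$heatmap, check.names = FALSE),
      emit(file.path(outdir, "correlation_heatmap.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("genesets" %in% stages) {
    res$genesets <- run_stage("genesets", {
      gs <- simulate_gene_sets(genes, n_sets = n_sets,
                               size_range = set_size_range,
                               bias = set_bias, seed = cfg$seed + 3L)
      list(sets = gs,
           results = evaluate_gene_sets(gs, assoc, genes, seed = cfg$seed,
                                        folds = folds))
    })
    utils::write.table(res$genesets$results,
                       emit(file.path(outdir, "geneset_ratios.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "chromexpr",
    version = as.character(utils::packageVersion("chromexpr")),
    seed = cfg$seed,
    stages = stages,
    parameters = list(
      n_genes = cfg$n_genes, n_tf = cfg$n_tf, n_hm = cfg$n_hm,
      include_dnase = cfg$include_dnase,
      tags_per_factor = cfg$tags_per_factor, noise_sd = cfg$noise_sd,
      pseudocount = cfg$pseudocount, folds = folds,
      mode_cardinality = mode_cardinality, mode_threshold = mode_threshold,
      n_edges = n_edges, n_reps = n_reps, n_remove = n_remove),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
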