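# Plain-text interchange: gene tables as TSV or BED6, tag tracks as BED3
# with a JSON sidecar, association matrices as TSV + JSON metadata. BED
# output is 0-based half-open with the TSS as a 1 bp interval.

#' Write / read a gene table
#'
#' @param genes gene table.
#' @param path output TSV path (columns id, chrom, strand, tss, rpkm).
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("id", "chrom", "strand", "tss", "rpkm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character",
                                        "character", "integer", "numeric"))
  stopifnot(all(c("id", "chrom", "strand", "tss", "rpkm") %in% names(g)))
  g
}

#' Write a gene table as BED6
#'
#' TSS as a 1 bp interval; the score column carries RPKM scaled into
#' 0-1000 (rank-preserving, capped as BED requires).
#'
#' @param genes gene table.
#' @param path output BED path.
#' @export
write_gene_bed <- function(genes, path) {
  score <- round(1000 * genes$rpkm / max(genes$rpkm, 1e-12))
  bed <- data.frame(genes$chrom, genes$tss, genes$tss + 1L, genes$id,
                    pmin(score, 1000L), genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a tag track
#'
#' Positions go to BED3 (1 bp half-open intervals); factor name, class,
#' total tag count and any ground-truth parameters go to a JSON sidecar
#' at \code{paste0(path, ".json")}.
#'
#' @param track a \code{tag_track}.
#' @param path output BED path.
#' @param chrom chromosome name for the BED records.
#' @export
write_tag_track <- function(track, path, chrom = "chrS") {
  p <- sort(track$positions)
  utils::write.table(data.frame(chrom, p, p + 1L), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- list(factor_name = track$factor_name,
               factor_class = track$factor_class,
               total_tags = track$total_tags)
  if (!is.null(track$truth))
    meta$truth <- track$truth[setdiff(names(track$truth), "log2_intensity")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tag_track
#' @export
read_tag_track <- function(path) {
  bed <- utils::read.table(path, sep = "\t",
                           colClasses = c("character", "integer", "integer"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(factor_name = meta$factor_name,
                 factor_class = meta$factor_class,
                 positions = bed[[2]],
                 total_tags = meta$total_tags,
                 truth = meta$truth),
            class = "tag_track")
}

#' Write / read an association matrix
#'
#' Logged features as TSV (genes × factors, gene_id first column);
#' factor classes, pseudocounts and bandwidths as a JSON sidecar.
#'
#' @param assoc an \code{assoc_matrix}.
#' @param path output TSV path.
#' @export
write_assoc <- function(assoc, path) {
  df <- data.frame(gene_id = assoc$gene_ids, assoc$logged,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(factor_names = assoc$factor_names,
         factor_classes = as.list(assoc$factor_classes),
         pseudocounts = as.list(assoc$pseudocounts),
         bandwidths = as.list(assoc$bandwidths)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_assoc
#' @export
read_assoc <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  logged <- as.matrix(df[, meta$factor_names, drop = FALSE])
  structure(list(gene_ids = df$gene_id,
                 factor_names = meta$factor_names,
                 factor_classes = unlist(meta$factor_classes),
                 raw = NULL,
                 logged = logged,
                 pseudocounts = unlist(meta$pseudocounts),
                 bandwidths = unlist(meta$bandwidths)),
            class = "assoc_matrix")
}
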