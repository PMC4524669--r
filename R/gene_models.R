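# Gene models: per-gene CDS/exon/intron intervals plus an optional ortholog
# id, used by the genic piRNA targeting analysis. Intervals are 1-based
# closed; introns are derived as the gaps between sorted exons.

#' Build a set of gene models from a feature table
#'
#' @param features Data frame with columns `gene_id`, `scaffold`, `strand`
#'   (`"+"`/`"-"`), `feature` (`"exon"` or `"CDS"`), `start`, `end` (1-based
#'   closed).
#' @param orthologs Optional data frame with columns `gene_id`,
#'   `ortholog_id` (e.g. the *D. melanogaster* ortholog), or a named vector.
#' @return A `GeneModelSet`: a data frame of features (with derived
#'   `"intron"` rows) carrying per-gene strand and ortholog metadata.
#' @export
gene_models <- function(features, orthologs = NULL) {
  need <- c("gene_id", "scaffold", "strand", "feature", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("features missing column(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(all(features$feature %in% c("exon", "CDS")),
            all(features$end >= features$start),
            all(features$strand %in% c("+", "-")))
  if (is.data.frame(orthologs)) {
    orthologs <- setNames(orthologs$ortholog_id, orthologs$gene_id)
  }
  rows <- split(features, features$gene_id)
  out <- lapply(rows, function(g) {
    ex <- g[g$feature == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    intr <- NULL
    if (nrow(ex) >= 2L) {
      gap_s <- ex$end[-nrow(ex)] + 1L
      gap_e <- ex$start[-1L] - 1L
      ok <- gap_e >= gap_s
      if (any(ok)) {
        intr <- data.frame(gene_id = g$gene_id[1], scaffold = g$scaffold[1],
                           strand = g$strand[1], feature = "intron",
                           start = gap_s[ok], end = gap_e[ok],
                           stringsAsFactors = FALSE)
      }
    }
    rbind(g[, need], intr)
  })
  gm <- do.call(rbind, out)
  rownames(gm) <- NULL
  gm$ortholog_id <- if (is.null(orthologs)) NA_character_ else
    unname(orthologs[gm$gene_id])
  class(gm) <- c("GeneModelSet", "data.frame")
  gm
}

#' Read gene models from a GFF3-like feature TSV
#'
#' Expects a tab-separated table with the [gene_models()] columns; a
#' convenience wrapper for annotation exported from standard GFF3 tooling.
#'
#' @param path TSV path.
#' @param orthologs Optional ortholog TSV (`gene_id`, `ortholog_id`).
#' @return A `GeneModelSet`.
#' @export
read_gene_models <- function(path, orthologs = NULL) {
  feats <- read.delim(path, stringsAsFactors = FALSE)
  orth <- if (is.null(orthologs)) NULL else
    read.delim(orthologs, stringsAsFactors = FALSE)
  gene_models(feats, orth)
}

gene_feature_ranges <- function(genes, feature) {
  g <- genes[genes$feature == feature, , drop = FALSE]
  GenomicRanges::GRanges(g$scaffold,
                         IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}
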