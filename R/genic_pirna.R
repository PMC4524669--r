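# Genic piRNA targeting: per-gene CDS piRNA densities, target selection with
# the ortholog filter, sense/antisense partition, exon/intron contrast, and
# ChIP IP:Input enrichment at candidate loci.

#' Per-gene genic piRNA densities
#'
#' Uses uniquely mapping reads only (`n_hits == 1`). A read counts for a gene
#' when its span intersects a CDS interval (a read overlapping two genes'
#' CDS counts for both); per-million densities use the read-level
#' genome-mapped total. Exon and intron densities are counts per kb of
#' feature. Genes without CDS features are excluded with a message.
#'
#' @param aln An [alignment_set()] of small-RNA genome mappings.
#' @param genes A [gene_models()] set.
#' @param target_threshold CDS per-million density at or above which the
#'   `is_target` flag is set (default 5).
#' @return `GenicPirnaTable` data frame: per gene `cds_count`,
#'   `cds_pirna_pm`, `sense_count`, `antisense_count`, `sense_biased`,
#'   `exon_density`, `intron_density`, `is_target`, `ortholog_id`.
#' @export
genic_density <- function(aln, genes, target_threshold = 5) {
  if (aln$genome_mapped_total <= 0) {
    stop("genome_mapped_total must be positive for per-million normalisation")
  }
  gene_ids <- unique(genes$gene_id)
  has_cds <- unique(genes$gene_id[genes$feature == "CDS"])
  dropped <- setdiff(gene_ids, has_cds)
  if (length(dropped)) {
    message("excluding ", length(dropped), " gene(s) without CDS: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  recs <- aln$records[aln$records$n_hits == 1L, , drop = FALSE]
  rg <- GenomicRanges::GRanges(recs$target,
                               IRanges::IRanges(recs$start,
                                                width = recs$read_length),
                               strand = recs$strand)
  count_feature <- function(feature) {
    fr <- gene_feature_ranges(genes, feature)
    ov <- GenomicRanges::findOverlaps(rg, fr, ignore.strand = TRUE)
    list(ranges = fr, hits = ov)
  }
  cds <- count_feature("CDS")
  exon <- count_feature("exon")
  intron <- count_feature("intron")
  feat_kb <- function(fr) {
    w <- tapply(BiocGenerics::width(fr), S4Vectors::mcols(fr)$gene_id, sum)
    w / 1000
  }
  cds_gene <- S4Vectors::mcols(cds$ranges)$gene_id[S4Vectors::subjectHits(cds$hits)]
  cds_read <- S4Vectors::queryHits(cds$hits)
  # a read hitting several CDS intervals of the same gene counts once
  pair <- !duplicated(paste(cds_read, cds_gene))
  cds_gene <- cds_gene[pair]; cds_read <- cds_read[pair]
  cds_counts <- table(factor(cds_gene, levels = has_cds))
  sense <- recs$strand[cds_read] ==
    setNames(genes$strand, genes$gene_id)[cds_gene]
  sense_counts <- tapply(sense, factor(cds_gene, levels = has_cds), sum)
  sense_counts[is.na(sense_counts)] <- 0L
  feat_count <- function(f) {
    g <- S4Vectors::mcols(f$ranges)$gene_id[S4Vectors::subjectHits(f$hits)]
    r <- S4Vectors::queryHits(f$hits)
    keep <- !duplicated(paste(r, g))
    table(factor(g[keep], levels = has_cds))
  }
  ex_kb <- feat_kb(exon$ranges)[has_cds]
  in_kb <- feat_kb(intron$ranges)[has_cds]
  ex_n <- feat_count(exon)
  in_n <- feat_count(intron)
  orth <- setNames(genes$ortholog_id, genes$gene_id)[has_cds]
  out <- data.frame(
    gene_id = has_cds,
    cds_count = as.integer(cds_counts),
    cds_pirna_pm = as.numeric(cds_counts) * 1e6 / aln$genome_mapped_total,
    sense_count = as.integer(sense_counts),
    antisense_count = as.integer(cds_counts) - as.integer(sense_counts),
    exon_density = as.numeric(ex_n) / unname(ex_kb),
    intron_density = ifelse(is.na(in_kb) | in_kb == 0, NA_real_,
                            as.numeric(in_n) / unname(in_kb)),
    ortholog_id = unname(orth),
    stringsAsFactors = FALSE)
  out$sense_biased <- out$sense_count > out$antisense_count
  out$is_target <- out$cds_pirna_pm >= target_threshold
  rownames(out) <- NULL
  out
}

#' Select genic piRNA target genes across libraries
#'
#' A gene is selected iff its CDS piRNA density reaches `threshold` per
#' million in at least one library ("either ... or" rule) and, when
#' required, a *D. melanogaster* ortholog is present (screening out TEs
#' mis-annotated as genes). Selection is monotone in `threshold`.
#'
#' @param tables A `GenicPirnaTable` or list of them (one per library).
#' @param threshold Per-million CDS density cutoff (default 5).
#' @param ortholog_required Drop genes without an ortholog (default TRUE).
#' @return Character vector of selected gene ids.
#' @export
select_targets <- function(tables, threshold = 5, ortholog_required = TRUE) {
  if (is.data.frame(tables)) tables <- list(tables)
  long <- do.call(rbind, lapply(tables, function(t)
    t[, c("gene_id", "cds_pirna_pm", "ortholog_id")]))
  mx <- tapply(long$cds_pirna_pm, long$gene_id, max)
  sel <- names(mx)[mx >= threshold]
  if (ortholog_required) {
    orth <- setNames(long$ortholog_id, long$gene_id)
    sel <- sel[!is.na(orth[sel]) & nzchar(orth[sel])]
  }
  sort(sel)
}

#' Sense/antisense partition of genic reads
#'
#' A read is sense when its strand equals the gene strand.
#'
#' @param gene_strand `"+"` or `"-"`.
#' @param read_strands Character vector of read strands.
#' @return List `sense_count`, `antisense_count`, `sense_biased`.
#' @export
strand_partition <- function(gene_strand, read_strands) {
  if (!gene_strand %in% c("+", "-")) stop("gene strand must be + or -")
  s <- sum(read_strands == gene_strand)
  a <- length(read_strands) - s
  list(sense_count = s, antisense_count = a, sense_biased = s > a)
}

#' Exon vs intron genic piRNA density contrast
#'
#' Paired t-test across genes of exon vs intron piRNA density; a positive
#' statistic indicates exon enrichment (consistent with cytoplasmic
#' processing of mature transcripts).
#'
#' @param table A `GenicPirnaTable` from [genic_density()].
#' @return List `mean_exon`, `mean_intron`, `t`, `p`, `n_genes`.
#' @export
exon_intron_contrast <- function(table) {
  ok <- is.finite(table$exon_density) & is.finite(table$intron_density)
  if (sum(ok) < 2L) {
    stop("need at least 2 genes with both exon and intron densities")
  }
  d <- table$exon_density[ok] - table$intron_density[ok]
  if (sd(d) == 0) {
    # degenerate paired sample: all differences identical
    tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    pval <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- t.test(table$exon_density[ok], table$intron_density[ok],
                 paired = TRUE)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  list(mean_exon = mean(table$exon_density[ok]),
       mean_intron = mean(table$intron_density[ok]),
       t = tstat, p = pval, n_genes = sum(ok))
}

#' ChIP IP:Input enrichment at loci
#'
#' Collapses duplicate reads (identical target/start/strand/length), keeps
#' unique mappers, normalises each library to per-million mapped, and reports
#' the IP:Input ratio per locus. Loci with zero input coverage get an
#' undefined (`NA`) ratio.
#'
#' @param ip_aln,input_aln [alignment_set()]s for IP and input libraries.
#' @param loci Data frame `locus`, `scaffold`, `start`, `end`.
#' @return Data frame `locus`, `ip_ppm`, `input_ppm`, `ratio`.
#' @export
chip_enrichment <- function(ip_aln, input_aln, loci) {
  ppm_at <- function(aln) {
    recs <- aln$records[aln$records$n_hits == 1L, , drop = FALSE]
    recs <- recs[!duplicated(recs[, c("target", "start", "strand",
                                      "read_length")]), , drop = FALSE]
    rg <- GenomicRanges::GRanges(recs$target,
                                 IRanges::IRanges(recs$start,
                                                  width = recs$read_length))
    lg <- GenomicRanges::GRanges(loci$scaffold,
                                 IRanges::IRanges(loci$start, loci$end))
    n <- GenomicRanges::countOverlaps(lg, rg)
    n * 1e6 / aln$genome_mapped_total
  }
  ip <- ppm_at(ip_aln)
  inp <- ppm_at(input_aln)
  data.frame(locus = loci$locus, ip_ppm = ip, input_ppm = inp,
             ratio = ifelse(inp > 0, ip / inp, NA_real_),
             stringsAsFactors = FALSE)
}
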