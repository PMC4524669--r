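# Expression analytics: RPKM, pseudocounted fold changes with the low-count
# filter, allele-specific SNP counting with exact contingency tests, and the
# six-way TE typology combining copy-number, piRNA and ping-pong asymmetries.

#' RPKM from counts
#'
#' `rpkm = count * 1e9 / (length_nt * mapped_total)`.
#'
#' @param counts Matrix (features x samples) or vector of read counts.
#' @param lengths Feature lengths in nt (recycled across samples).
#' @param mapped_totals Per-sample mapped read totals.
#' @return Matrix (or vector) of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths, mapped_totals) {
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(mapped_totals <= 0)) stop("mapped totals must be positive")
  if (is.matrix(counts)) {
    sweep(counts * 1e9 / lengths, 2L, mapped_totals, "/")
  } else {
    counts * 1e9 / (lengths * mapped_totals)
  }
}

#' Condition fold changes on RPKM with pseudocount and low-count filter
#'
#' Features with fewer than `min_total` reads summed across all samples are
#' dropped before anything else; folds are
#' `(mean RPKM_A + pseudocount) / (mean RPKM_B + pseudocount)` on
#' condition-mean RPKM.
#'
#' @param counts Matrix (features x samples).
#' @param lengths Feature lengths, nt.
#' @param mapped_totals Per-sample mapped totals.
#' @param conditions Character/factor of per-sample condition labels.
#' @param cond_a,cond_b The two condition labels to contrast.
#' @param pseudocount Added to both condition means (default 0.01).
#' @param min_total Minimum total reads across samples (default 40).
#' @return `GeneExpressionTable` data frame: `feature`, `total_count`,
#'   `rpkm_a`, `rpkm_b`, `fold`.
#' @export
fold_and_filter <- function(counts, lengths, mapped_totals, conditions,
                            cond_a, cond_b, pseudocount = 0.01,
                            min_total = 40L) {
  conditions <- as.character(conditions)
  if (!all(c(cond_a, cond_b) %in% conditions)) {
    stop("condition label(s) not present: ",
         paste(setdiff(c(cond_a, cond_b), conditions), collapse = ", "))
  }
  total <- rowSums(counts)
  keep <- total >= min_total
  counts <- counts[keep, , drop = FALSE]
  lengths <- lengths[keep]
  rpkm <- compute_rpkm(counts, lengths, mapped_totals)
  ra <- rowMeans(rpkm[, conditions == cond_a, drop = FALSE])
  rb <- rowMeans(rpkm[, conditions == cond_b, drop = FALSE])
  data.frame(feature = rownames(counts) %||%
               as.character(seq_len(nrow(counts))),
             total_count = unname(total[keep]),
             rpkm_a = unname(ra), rpkm_b = unname(rb),
             fold = unname((ra + pseudocount) / (rb + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Allele-specific read counts at a diagnostic SNP
#'
#' Partitions reads overlapping the SNP position by the base observed there;
#' reads showing neither diagnostic base (sequencing errors, Ns) are ignored
#' and reported.
#'
#' @param aln An [alignment_set()] of reads on the transcript/scaffold; the
#'   records must carry sequences.
#' @param target Transcript/scaffold name carrying the SNP.
#' @param position 1-based SNP position on the target.
#' @param base_a,base_b The two diagnostic bases (e.g. the strain-9 and
#'   strain-160 alleles).
#' @return List `count_a`, `count_b`, `ignored`.
#' @export
allele_counts <- function(aln, target, position, base_a, base_b) {
  recs <- aln$records[aln$records$target == target, , drop = FALSE]
  cover <- recs$start <= position &
    recs$start + recs$read_length - 1L >= position
  recs <- recs[cover & !is.na(recs$seq), , drop = FALSE]
  if (!nrow(recs)) return(list(count_a = 0L, count_b = 0L, ignored = 0L))
  seqs <- recs$seq
  minus <- recs$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])  # target orientation
  off <- position - recs$start + 1L
  base <- toupper(substring(seqs, off, off))
  list(count_a = sum(base == toupper(base_a)),
       count_b = sum(base == toupper(base_b)),
       ignored = sum(!base %in% toupper(c(base_a, base_b))))
}

#' Exact test for tissue-specific allele effects
#'
#' Two-sided Fisher's exact test contrasting allele counts between two
#' tissues (e.g. soma vs germline): rows are tissues, columns the two
#' alleles.
#'
#' @param counts_1,counts_2 Length-2 integer vectors of allele counts
#'   (allele A, allele B) for the two tissues; alternatively `counts_1` may
#'   be a 2x2 matrix and `counts_2` omitted.
#' @return List `odds_ratio`, `p`, `table`.
#' @export
allele_contingency_test <- function(counts_1, counts_2 = NULL) {
  tab <- if (is.matrix(counts_1)) counts_1 else
    rbind(counts_1, counts_2)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (sum(tab) == 0) stop("all-zero contingency table")
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Six-way TE typology from copy-number, piRNA and ping-pong asymmetries
#'
#' Classifies each differentially expressed TE by (i) which strain carries
#' more copies (log2 abundance ratio against `tau_abund`), (ii) whether the
#' inducer strain carries more maternal piRNA (log2 piRNA ratio against
#' `tau_pirna`, i.e. 2-fold by default), and (iii) how the F1 ping-pong pair
#' density compares between dysgenic and non-dysgenic germlines: `none` when
#' both densities are zero; `higher_in_dysgenic` when the dysgenic density
#' exceeds the non-dysgenic; maternally `defined` when the non-dysgenic
#' density is at least `maternal_ratio`-fold the dysgenic (infinite ratio
#' counts); `equilibrated` otherwise.
#'
#' Types: I = inducer-enriched copy number, inducer-enriched piRNA, maternal;
#' II = same but equilibrated; III = same but higher in dysgenic;
#' IV = copy number not inducer-enriched, inducer-enriched piRNA, maternal;
#' V = as IV with no pairs at all; VI = neither copy number nor piRNA
#' inducer-enriched, non-dysgenic density higher. Everything else is
#' `unclassified`.
#'
#' @param abund_log2 log2 inducer:reactive abundance ratio.
#' @param pirna_log2 log2 inducer:reactive maternal piRNA ratio.
#' @param expr_d,expr_nd Germline RPKM, dysgenic and non-dysgenic (carried
#'   through, not used by the decision tree).
#' @param ppd_d,ppd_nd Ping-pong pair density (per million piRNAs mapped) in
#'   dysgenic and non-dysgenic F1 germlines.
#' @param tau_abund Copy-number log2 threshold (default 0).
#' @param tau_pirna piRNA log2 threshold (default 1 = 2-fold).
#' @param maternal_ratio Non-dysgenic:dysgenic density fold for the
#'   maternally-defined call (default 2).
#' @return Character vector of types (`"I"` .. `"VI"`, `"unclassified"`).
#' @export
classify_te_type <- function(abund_log2, pirna_log2, expr_d, expr_nd,
                             ppd_d, ppd_nd, tau_abund = 0, tau_pirna = 1,
                             maternal_ratio = 2) {
  n <- length(abund_log2)
  args <- list(abund_log2, pirna_log2, expr_d, expr_nd, ppd_d, ppd_nd)
  if (any(vapply(args, function(x) any(is.na(x)) || length(x) != n,
                 logical(1)))) {
    stop("all six numeric fields must be present for every TE")
  }
  copy160 <- abund_log2 > tau_abund
  pirna160 <- pirna_log2 >= tau_pirna
  pp <- character(n)
  for (i in seq_len(n)) {
    pp[i] <- if (ppd_d[i] == 0 && ppd_nd[i] == 0) "none"
    else if (ppd_d[i] > ppd_nd[i]) "higher_in_dysgenic"
    else if (ppd_d[i] == 0 || ppd_nd[i] / ppd_d[i] >= maternal_ratio)
      "maternal"
    else "equilibrated"
  }
  type <- rep("unclassified", n)
  type[copy160 & pirna160 & pp == "maternal"] <- "I"
  type[copy160 & pirna160 & pp == "equilibrated"] <- "II"
  type[copy160 & pirna160 & pp == "higher_in_dysgenic"] <- "III"
  type[!copy160 & pirna160 & pp == "maternal"] <- "IV"
  type[!copy160 & pirna160 & pp == "none"] <- "V"
  type[!copy160 & !pirna160 & ppd_nd > ppd_d] <- "VI"
  type
}

#' Reference profiles of dysgenesis-responsive TE families
#'
#' Loads the bundled table of the fourteen TE families at least 2-fold more
#' expressed in the dysgenic *D. virilis* germline, with their strain
#' abundance and piRNA log2 ratios, germline RPKM, F1 ping-pong pair
#' densities, and assigned type.
#'
#' @return Data frame with columns `te`, `abund_log2`, `pirna_log2`,
#'   `expr_d`, `expr_nd`, `ppd_d`, `ppd_nd`, `te_type`.
#' @export
dysgenic_te_profiles <- function() {
  read.delim(system.file("extdata", "dysgenic_te_profiles.tsv",
                         package = "dysgenTE"),
             stringsAsFactors = FALSE, colClasses = c(te = "character"))
}
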