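# Strain-asymmetric TE abundance, the pileup homogeneity (age) statistic and
# the invasion-scenario interpretation grid.

#' Per-family TE abundance from a TE-library mapping
#'
#' Counts each read once toward its best TE target (ties between equally good
#' placements broken by first target name, deterministically) and normalises
#' to reads per million genome-mapped reads (multi-mappers included in the
#' denominator, each read counted once).
#'
#' @param aln An [alignment_set()] of reads placed on TE consensi.
#' @param lib A [repeat_library()]; families with no reads get abundance 0.
#' @return `AbundanceTable` data frame: `name`, `mapped_reads`,
#'   `abundance_pm`.
#' @export
compute_abundance <- function(aln, lib) {
  if (aln$genome_mapped_total <= 0) {
    stop("genome_mapped_total must be positive for per-million normalisation")
  }
  recs <- aln$records[aln$records$target %in% lib$name, , drop = FALSE]
  if (nrow(recs)) {
    recs <- recs[order(recs$read_id, recs$target), , drop = FALSE]
    recs <- recs[!duplicated(recs$read_id), , drop = FALSE]
    counts <- table(factor(recs$target, levels = lib$name))
  } else {
    counts <- setNames(rep(0L, nrow(lib)), lib$name)
  }
  data.frame(name = lib$name,
             mapped_reads = as.integer(counts),
             abundance_pm = as.numeric(counts) * 1e6 /
               aln$genome_mapped_total,
             stringsAsFactors = FALSE)
}

pileup_counts <- function(recs, cons_len) {
  m <- matrix(0L, 4L, cons_len, dimnames = list(c("A", "C", "G", "T"), NULL))
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_len(nrow(recs))) {
    s <- recs$seq[i]
    if (is.na(s)) next
    if (recs$strand[i] == "-") s <- revcomp(s)
    b <- base_idx[strsplit(s, "")[[1]]]
    pos <- recs$start[i]:(recs$start[i] + recs$read_length[i] - 1L)
    ok <- !is.na(b) & pos >= 1L & pos <= cons_len  # drop N and overhang
    if (any(ok)) {
      ij <- cbind(b[ok], pos[ok])
      # accumulate; duplicated cells within one read cannot occur
      m[ij] <- m[ij] + 1L
    }
  }
  m
}

#' Within-family sequence homogeneity (TE age statistic)
#'
#' For each family, piles reads up on the consensus and averages the major
#' nucleotide variant's frequency across all covered positions with coverage
#' at least `min_coverage`. A homogeneity near 1 indicates recent
#' activation/invasion (young, similar copies); older families accumulate
#' substitutions among copies and score lower. Non-ACGT calls are excluded
#' from the pileup. Families with no position reaching `min_coverage` are
#' flagged undefined (`NA`), not 0.
#'
#' @param aln An [alignment_set()] whose records carry read sequences.
#' @param lib A [repeat_library()].
#' @param min_coverage Minimum pileup depth for a position to contribute
#'   (default 4; 1 reproduces the literal all-covered-positions reading).
#' @return `HomogeneityTable` data frame: `name`, `homogeneity`,
#'   `covered_positions`, `mean_coverage`.
#' @export
compute_homogeneity <- function(aln, lib, min_coverage = 4L) {
  res <- lapply(seq_len(nrow(lib)), function(i) {
    recs <- aln$records[aln$records$target == lib$name[i] &
                          !is.na(aln$records$seq), , drop = FALSE]
    if (!nrow(recs)) {
      return(data.frame(name = lib$name[i], homogeneity = NA_real_,
                        covered_positions = 0L, mean_coverage = 0,
                        stringsAsFactors = FALSE))
    }
    m <- pileup_counts(recs, lib$length[i])
    depth <- colSums(m)
    use <- depth >= min_coverage
    if (!any(use)) {
      return(data.frame(name = lib$name[i], homogeneity = NA_real_,
                        covered_positions = 0L,
                        mean_coverage = mean(depth[depth > 0]),
                        stringsAsFactors = FALSE))
    }
    major <- apply(m[, use, drop = FALSE], 2L, max)
    data.frame(name = lib$name[i],
               homogeneity = mean(major / depth[use]),
               covered_positions = sum(use),
               mean_coverage = mean(depth[use]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Call per-family enrichment between two strains
#'
#' Ratio of per-million abundances with a pseudocount; a family is enriched
#' in A iff the ratio is at least `fold_threshold`, in B iff at most its
#' reciprocal.
#'
#' @param tab_a,tab_b `AbundanceTable`s from [compute_abundance()]; must
#'   cover the same family set.
#' @param fold_threshold Fold cutoff (default 3).
#' @param pseudocount Added to both per-million abundances (default 0.1).
#' @return `EnrichmentCall` data frame: `name`, `pm_a`, `pm_b`, `ratio`,
#'   `enriched_in` in `{A, B, neither}`.
#' @export
call_enrichment <- function(tab_a, tab_b, fold_threshold = 3,
                            pseudocount = 0.1) {
  if (!setequal(tab_a$name, tab_b$name)) {
    only_a <- setdiff(tab_a$name, tab_b$name)
    only_b <- setdiff(tab_b$name, tab_a$name)
    stop("abundance tables disagree on families; only in A: ",
         paste(only_a, collapse = ", "), "; only in B: ",
         paste(only_b, collapse = ", "))
  }
  tab_b <- tab_b[match(tab_a$name, tab_b$name), , drop = FALSE]
  ratio <- (tab_a$abundance_pm + pseudocount) /
    (tab_b$abundance_pm + pseudocount)
  enr <- ifelse(ratio >= fold_threshold, "A",
                ifelse(ratio <= 1 / fold_threshold, "B", "neither"))
  data.frame(name = tab_a$name, pm_a = tab_a$abundance_pm,
             pm_b = tab_b$abundance_pm, ratio = ratio, enriched_in = enr,
             stringsAsFactors = FALSE)
}

classify_one_scenario <- function(enriched_in, hom_enr, hom_other, pm_other,
                                  hom_high, hom_gap, absent_pm, side) {
  if (is.na(hom_enr) || is.na(hom_other)) return("unclassified")
  gap <- hom_enr - hom_other
  if (hom_enr >= hom_high && gap >= hom_gap) {
    if (pm_other <= absent_pm) {
      sprintf("invasion_absent_in_%s", if (side == "A") "B" else "A")
    } else {
      sprintf("reactivation_in_%s", side)
    }
  } else if (abs(gap) < hom_gap) {
    if (hom_enr >= hom_high && hom_other >= hom_high)
      "shared_recent_invasion" else "old_resident"
  } else "unclassified"
}

#' Interpret enrichment + homogeneity as an invasion scenario
#'
#' Applies the interpretation grid for asymmetric TE abundance: an element
#' enriched in one strain with high homogeneity there and a clear homogeneity
#' gap points to recent re-activation in that strain (or, if the element is
#' essentially absent from the other strain, a new invasion not yet shared);
#' enrichment with similar homogeneity in both strains points to a shared
#' recent invasion with excess movement in one strain when both are young,
#' or to an old resident otherwise.
#'
#' @param calls `EnrichmentCall` from [call_enrichment()].
#' @param hom_a,hom_b `HomogeneityTable`s for strains A and B.
#' @param hom_high Homogeneity above which a family counts as young
#'   (default 0.98).
#' @param hom_gap Minimum between-strain homogeneity difference to call
#'   asymmetric age (default 0.03).
#' @param absent_pm Abundance (per million) below which a family is treated
#'   as absent from a strain (default 1).
#' @return `calls` with columns `hom_a`, `hom_b` and `scenario` added.
#' @export
classify_scenario <- function(calls, hom_a, hom_b, hom_high = 0.98,
                              hom_gap = 0.03, absent_pm = 1) {
  ha <- setNames(hom_a$homogeneity, hom_a$name)[calls$name]
  hb <- setNames(hom_b$homogeneity, hom_b$name)[calls$name]
  scen <- vapply(seq_len(nrow(calls)), function(i) {
    e <- calls$enriched_in[i]
    if (e == "A") {
      classify_one_scenario("A", ha[i], hb[i], calls$pm_b[i],
                            hom_high, hom_gap, absent_pm, "A")
    } else if (e == "B") {
      classify_one_scenario("B", hb[i], ha[i], calls$pm_a[i],
                            hom_high, hom_gap, absent_pm, "B")
    } else {
      if (is.na(ha[i]) || is.na(hb[i])) "unclassified"
      else if (abs(ha[i] - hb[i]) < hom_gap) {
        if (ha[i] >= hom_high && hb[i] >= hom_high)
          "shared_recent_invasion" else "old_resident"
      } else "unclassified"
    }
  }, character(1))
  calls$hom_a <- unname(ha)
  calls$hom_b <- unname(hb)
  calls$scenario <- scen
  calls
}
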