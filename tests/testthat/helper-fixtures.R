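# Small fixtures and independent oracles used across test files.

# write a FASTA file from named sequences
write_fasta_tmp <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}

# exhaustive substring-scan placement oracle, independent of align_exact
brute_force_placements <- function(read, targets) {
  out <- list()
  for (tn in names(targets)) {
    tseq <- targets[[tn]]
    for (str in c("+", "-")) {
      pat <- if (str == "+") read else revcomp(read)
      k <- nchar(pat)
      if (k > nchar(tseq)) next
      for (s in seq_len(nchar(tseq) - k + 1L)) {
        if (substring(tseq, s, s + k - 1L) == pat) {
          out[[length(out) + 1L]] <- data.frame(target = tn, start = s,
                                                strand = str)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(target = character(), start = integer(),
               strand = character())
}

# brute-force maximum bipartite matching between plus reads and minus reads
# at the exact 10-nt 5'-5' overlap, via augmenting paths (independent of the
# per-position min() implementation)
brute_force_pingpong <- function(pos5_plus, pos5_minus) {
  np <- length(pos5_plus); nm <- length(pos5_minus)
  if (!np || !nm) return(list(pp_pairs = 0L, matched_read_count = 0L))
  adj <- lapply(seq_len(np),
                function(i) which(pos5_minus == pos5_plus[i] + 9L))
  match_m <- integer(nm)  # minus read -> plus read (0 = free)
  try_augment <- function(i, seen) {
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        if (match_m[j] == 0L || Recall(match_m[j], seen)) {
          match_m[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  pairs <- 0L
  for (i in seq_len(np)) {
    if (try_augment(i, rep(FALSE, nm))) pairs <- pairs + 1L
  }
  has_partner_p <- vapply(adj, function(a) length(a) > 0L, logical(1))
  has_partner_m <- pos5_minus %in% (pos5_plus + 9L)
  list(pp_pairs = pairs,
       matched_read_count = sum(has_partner_p) + sum(has_partner_m))
}

# small deterministic gene annotation: n genes laid head-to-tail on one
# scaffold, each with 2 exons, a CDS inside each exon, and one intron
toy_genes <- function(n = 10L, scaffold = "scf1", gene_span = 5000L,
                      with_orthologs = TRUE) {
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- (i - 1L) * gene_span
    strand <- if (i %% 2L == 0L) "-" else "+"
    rbind(
      data.frame(gene_id = sprintf("g%03d", i), scaffold = scaffold,
                 strand = strand, feature = "exon",
                 start = base + 101L, end = base + 1100L),
      data.frame(gene_id = sprintf("g%03d", i), scaffold = scaffold,
                 strand = strand, feature = "exon",
                 start = base + 2101L, end = base + 3100L),
      data.frame(gene_id = sprintf("g%03d", i), scaffold = scaffold,
                 strand = strand, feature = "CDS",
                 start = base + 201L, end = base + 1100L),
      data.frame(gene_id = sprintf("g%03d", i), scaffold = scaffold,
                 strand = strand, feature = "CDS",
                 start = base + 2101L, end = base + 3000L))
  }))
  orth <- if (with_orthologs) {
    data.frame(gene_id = sprintf("g%03d", seq_len(n)),
               ortholog_id = sprintf("Dmel_%03d", seq_len(n)))
  } else NULL
  gene_models(feats, orth)
}

# records data frame builder with defaults
rec <- function(read_id, target, start, strand = "+", read_length = 25L,
                mapq = 37L, n_hits = 1L, seq = NA_character_) {
  data.frame(read_id = read_id, target = target, start = start,
             strand = strand, read_length = read_length, mapq = mapq,
             n_hits = n_hits, seq = seq, stringsAsFactors = FALSE)
}
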