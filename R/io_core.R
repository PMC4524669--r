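# Readers/writers for the standard formats, the shared alignment-record model,
# and a fixture-scale exact mapper so the pipeline runs without an external
# aligner. Real data enters pre-aligned via load_alignments().

#' Load a repeat/TE consensus library from FASTA
#'
#' Reads a repeat library (one consensus sequence per TE family) into a
#' `RepeatLibrary`: a data frame with columns `name`, `sequence`, `length`
#' and `class_hint`. Sequences are uppercased; the alphabet is restricted to
#' A/C/G/T/N. Duplicate record names are an error.
#'
#' @param path Path to a FASTA file.
#' @param class_hints Optional named character vector mapping record names to
#'   a class label (e.g. `"LTR"`, `"non-LTR"`, `"DNA"`); unknown otherwise.
#' @return A `RepeatLibrary` data frame.
#' @export
load_repeat_library <- function(path, class_hints = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty repeat library: no FASTA records in '", path, "'")
  }
  nm <- sub("\\s.*$", "", names(seqs))
  repeat_library(setNames(toupper(as.character(seqs)), nm),
                 class_hints = class_hints)
}

#' Construct a RepeatLibrary from named sequences
#'
#' @param sequences Named character vector of consensus sequences.
#' @param class_hints Optional named character vector of class labels.
#' @return A `RepeatLibrary` data frame with columns `name`, `sequence`,
#'   `length`, `class_hint`.
#' @export
repeat_library <- function(sequences, class_hints = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("repeat library sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    dup <- unique(names(sequences)[duplicated(names(sequences))])
    stop("duplicate repeat name(s): ", paste(dup, collapse = ", "))
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("non-ACGTN characters in repeat(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  if (any(nchar(sequences) == 0L)) stop("zero-length repeat sequence")
  hint <- rep("unknown", length(sequences))
  if (!is.null(class_hints)) {
    idx <- match(names(sequences), names(class_hints))
    hint[!is.na(idx)] <- class_hints[idx[!is.na(idx)]]
  }
  lib <- data.frame(name = names(sequences),
                    sequence = unname(sequences),
                    length = unname(nchar(sequences)),
                    class_hint = hint,
                    stringsAsFactors = FALSE)
  class(lib) <- c("RepeatLibrary", "data.frame")
  lib
}

#' @export
print.RepeatLibrary <- function(x, ...) {
  cat("RepeatLibrary with", nrow(x), "entries (",
      sum(x$length), "bp total )\n")
  print(data.frame(name = x$name, length = x$length,
                   class_hint = x$class_hint), ...)
  invisible(x)
}

target_sequences <- function(targets) {
  if (inherits(targets, "RepeatLibrary")) {
    setNames(targets$sequence, targets$name)
  } else if (is.character(targets) && !is.null(names(targets))) {
    toupper(targets)
  } else {
    stop("targets must be a RepeatLibrary or a named character vector")
  }
}

empty_records <- function() {
  data.frame(read_id = character(), target = character(),
             start = integer(), strand = character(),
             read_length = integer(), mapq = integer(),
             n_hits = integer(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Construct an AlignmentSet
#'
#' An `AlignmentSet` bundles simplified alignment records with the two
#' read-level totals used for per-million normalisation: the number of reads
#' mapped to the reference genome (multi-mappers included, each read counted
#' once) and the total number of reads in the library.
#'
#' @param records Data frame with columns `read_id`, `target`, `start`
#'   (1-based leftmost), `strand` (`"+"`/`"-"`), `read_length`, `mapq`,
#'   `n_hits`, and optionally `seq` (read sequence, query orientation).
#' @param genome_mapped_total Reads mapped to the reference genome.
#' @param library_total Total reads in the library.
#' @return An `AlignmentSet`.
#' @export
alignment_set <- function(records, genome_mapped_total, library_total) {
  if (is.null(records$seq)) records$seq <- NA_character_
  need <- c("read_id", "target", "start", "strand", "read_length",
            "mapq", "n_hits")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(records)) {
    stopifnot(all(records$start >= 1L), all(records$n_hits >= 1L),
              all(records$strand %in% c("+", "-")),
              all(records$read_length >= 1L))
  }
  if (genome_mapped_total < 0 || library_total < 0 ||
      genome_mapped_total > library_total) {
    stop("require 0 <= genome_mapped_total <= library_total")
  }
  structure(list(records = records,
                 genome_mapped_total = as.numeric(genome_mapped_total),
                 library_total = as.numeric(library_total)),
            class = "AlignmentSet")
}

#' @export
print.AlignmentSet <- function(x, ...) {
  cat("AlignmentSet:", nrow(x$records), "records on",
      length(unique(x$records$target)), "targets;",
      x$genome_mapped_total, "genome-mapped /",
      x$library_total, "library reads\n")
  invisible(x)
}

#' Reverse-complement a nucleotide string
#' @param x Character vector of sequences.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Exact ungapped fixture-scale mapper
#'
#' Places each read at every exact ungapped substring match on either strand
#' of the targets. `n_hits` counts all placements of a read; emitted records
#' are capped at `max_hits` per read. Unique reads get `mapq = 37`,
#' multi-mapped reads `mapq = 0`. Unmapped reads are omitted from records but
#' counted in `library_total`. Intended for fixtures; real data enters
#' pre-aligned through [load_alignments()].
#'
#' @param reads Data frame with columns `id` and `sequence`, or a named
#'   character vector.
#' @param targets A `RepeatLibrary` or named character vector of sequences.
#' @param max_hits Cap on emitted placements per read (default 100).
#' @return An [alignment_set()]; `genome_mapped_total` is the number of reads
#'   with at least one placement.
#' @export
align_exact <- function(reads, targets, max_hits = 100L) {
  if (is.character(reads)) {
    reads <- data.frame(id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  if (nrow(reads) == 0L) stop("no reads supplied")
  tseq <- target_sequences(targets)
  rseq <- toupper(reads$sequence)
  rc <- revcomp(rseq)
  out <- vector("list", nrow(reads))
  n_mapped <- 0L
  for (i in seq_len(nrow(reads))) {
    hits_t <- character(); hits_s <- character(); hits_p <- integer()
    for (tn in names(tseq)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") rseq[i] else rc[i]
        if (nchar(pat) > nchar(tseq[[tn]])) next
        m <- gregexpr(pat, tseq[[tn]], fixed = TRUE)[[1]]
        if (m[1] != -1L) {
          # fixed gregexpr skips overlapping matches; rescan from inside
          pos <- integer()
          from <- 1L
          while (TRUE) {
            j <- regexpr(pat, substring(tseq[[tn]], from), fixed = TRUE)
            if (j == -1L) break
            pos <- c(pos, from + j - 1L)
            from <- from + j
          }
          hits_t <- c(hits_t, rep(tn, length(pos)))
          hits_s <- c(hits_s, rep(str, length(pos)))
          hits_p <- c(hits_p, pos)
        }
      }
    }
    nh <- length(hits_p)
    if (nh == 0L) next
    n_mapped <- n_mapped + 1L
    keep <- seq_len(min(nh, max_hits))
    out[[i]] <- data.frame(
      read_id = reads$id[i], target = hits_t[keep],
      start = hits_p[keep], strand = hits_s[keep],
      read_length = nchar(rseq[i]),
      mapq = if (nh == 1L) 37L else 0L,
      n_hits = nh, seq = rseq[i], stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(recs)) recs <- empty_records()
  alignment_set(recs, genome_mapped_total = n_mapped,
                library_total = nrow(reads))
}

#' Load alignments from SAM or BAM
#'
#' SAM text is converted to BAM internally; 1-based POS is preserved, the
#' reverse-strand FLAG becomes strand `"-"`, and an NH tag (if present) sets
#' `n_hits` (default 1). Unmapped reads are excluded from records but counted
#' in `library_total`.
#'
#' @param path SAM or BAM file.
#' @param genome_mapped_total Override for the genome-mapped read total
#'   (default: number of mapped reads in the file, each counted once).
#' @param library_total Override for the library read total (default: all
#'   reads in the file, mapped or not).
#' @return An [alignment_set()].
#' @export
load_alignments <- function(path, genome_mapped_total = NULL,
                            library_total = NULL) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "qwidth",
               "mapq", "seq"),
      tag = "NH"))[[1]]
  unmapped <- bitwAnd(res$flag, 4L) > 0L
  qn_all <- res$qname
  keep <- !unmapped
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(1L, length(res$flag))
  nh[is.na(nh)] <- 1L
  recs <- data.frame(
    read_id = res$qname[keep],
    target = as.character(res$rname[keep]),
    start = res$pos[keep],
    strand = as.character(res$strand[keep]),
    read_length = res$qwidth[keep],
    mapq = ifelse(is.na(res$mapq[keep]), 0L, res$mapq[keep]),
    n_hits = nh[keep],
    seq = as.character(res$seq)[keep],
    stringsAsFactors = FALSE)
  if (nrow(recs)) {
    # a minus-strand SAM SEQ is reference-oriented; store query orientation
    recs$seq[recs$strand == "-"] <- revcomp(recs$seq[recs$strand == "-"])
  } else {
    recs <- empty_records()
  }
  if (is.null(library_total)) library_total <- length(unique(qn_all))
  if (is.null(genome_mapped_total)) {
    genome_mapped_total <- length(unique(qn_all[keep]))
  }
  alignment_set(recs, genome_mapped_total, library_total)
}

#' Write an AlignmentSet to SAM
#'
#' Emits a minimal valid SAM file (header with `@SQ` lines from
#' `target_lengths`, CIGAR `<len>M`, FLAG 0/16). The query sequence is
#' written reference-oriented as SAM requires.
#'
#' @param aln An [alignment_set()].
#' @param target_lengths Named integer vector of target lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, target_lengths, path) {
  recs <- aln$records
  miss <- setdiff(unique(recs$target), names(target_lengths))
  if (length(miss)) stop("no length for target(s): ",
                         paste(miss, collapse = ", "))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                   as.integer(target_lengths)))
  seqf <- recs$seq
  seqf[is.na(seqf)] <- "*"
  minus <- recs$strand == "-" & seqf != "*"
  seqf[minus] <- revcomp(seqf[minus])
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                   recs$read_id, ifelse(recs$strand == "-", 16L, 0L),
                   recs$target, recs$start, recs$mapq, recs$read_length,
                   seqf, recs$n_hits)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(n) paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), path)
  invisible(path)
}

#' Read a FASTQ file into a reads data frame
#'
#' @param path FASTQ path.
#' @return Data frame with columns `id`, `sequence`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(seqs)),
             sequence = as.character(seqs), stringsAsFactors = FALSE)
}
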