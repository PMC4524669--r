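# Small-RNA size classing, structural-RNA filtering, and the ping-pong
# signature metrics: percent ping-pong, non-redundant pair counts and
# densities, 1U/10A biases, and row z-score matrices.

#' Class small RNAs by size after structural-RNA filtering
#'
#' Reads matching a structural-RNA library (tRNA/ncRNA/misc RNA/miRNA) are
#' filtered out first (exact substring match on either strand); the remainder
#' is classed as piRNA (23-30 nt), siRNA (21 nt) or other.
#'
#' @param reads Data frame with columns `id`, `sequence` (adapter-trimmed).
#' @param structural Optional [repeat_library()] (or named sequences) of
#'   structural RNAs to filter against.
#' @return `SmallRNAClassed` list: `pirna`, `sirna`, `other`, `filtered_out`
#'   (read data frames) and `totals` (read-level counts per class).
#' @export
class_small_rnas <- function(reads, structural = NULL) {
  if (nrow(reads) == 0L) {
    empty <- reads
    return(structure(list(pirna = empty, sirna = empty, other = empty,
                          filtered_out = empty,
                          totals = c(pirna = 0L, sirna = 0L, other = 0L,
                                     filtered_out = 0L, input = 0L)),
                     class = "SmallRNAClassed"))
  }
  is_struct <- rep(FALSE, nrow(reads))
  if (!is.null(structural)) {
    hit <- align_exact(reads, structural)$records$read_id
    is_struct <- reads$id %in% hit
  }
  kept <- reads[!is_struct, , drop = FALSE]
  len <- nchar(kept$sequence)
  cls <- ifelse(len >= 23L & len <= 30L, "pirna",
                ifelse(len == 21L, "sirna", "other"))
  out <- structure(list(pirna = kept[cls == "pirna", , drop = FALSE],
                        sirna = kept[cls == "sirna", , drop = FALSE],
                        other = kept[cls == "other", , drop = FALSE],
                        filtered_out = reads[is_struct, , drop = FALSE]),
                   class = "SmallRNAClassed")
  out$totals <- c(pirna = nrow(out$pirna), sirna = nrow(out$sirna),
                  other = nrow(out$other),
                  filtered_out = nrow(out$filtered_out),
                  input = nrow(reads))
  out
}

#' Non-redundant ping-pong pairs from 5' position counts
#'
#' The ping-pong amplification signature is an opposite-strand read pair
#' whose 5' ends overlap by exactly 10 nt: a plus-strand 5' at `p` partnered
#' by a minus-strand 5' at `p + 9`. Counting each read at most once, the
#' maximum number of such pairs is `sum_p min(c+(p), c-(p+9))` (each plus
#' position has exactly one partner position, so per-position `min()` is the
#' maximum bipartite matching). `matched_read_count` counts reads with at
#' least one candidate partner, the basis of percent ping-pong.
#'
#' @param pos5_plus Integer vector of plus-strand 5' positions.
#' @param pos5_minus Integer vector of minus-strand 5' positions (the
#'   rightmost base of each minus-strand read's span).
#' @return List `pp_pairs`, `matched_read_count`.
#' @export
pingpong_pairs <- function(pos5_plus, pos5_minus) {
  if (!length(pos5_plus) || !length(pos5_minus)) {
    return(list(pp_pairs = 0L, matched_read_count = 0L))
  }
  cp <- table(pos5_plus)
  cm <- table(pos5_minus)
  partner <- as.character(as.integer(names(cp)) + 9L)
  cm_at <- as.integer(cm[partner])
  cm_at[is.na(cm_at)] <- 0L
  pairs <- sum(pmin(as.integer(cp), cm_at))
  matched_plus <- sum(as.integer(cp)[cm_at > 0L])
  cp_at <- as.integer(cp[as.character(as.integer(names(cm)) - 9L)])
  cp_at[is.na(cp_at)] <- 0L
  matched_minus <- sum(as.integer(cm)[cp_at > 0L])
  list(pp_pairs = as.integer(pairs),
       matched_read_count = as.integer(matched_plus + matched_minus))
}

read_5prime <- function(recs) {
  ifelse(recs$strand == "+", recs$start,
         recs$start + recs$read_length - 1L)
}

#' Per-family ping-pong signature metrics
#'
#' For each TE family, computes from the piRNA-sized (23-30 nt) mappings the
#' percent ping-pong (percent of mapped piRNA reads with an opposite-strand
#' partner at the 10-nt 5'-5' overlap), the non-redundant pair count, pairs
#' per kb of consensus, and pairs per million piRNAs mapped in the library
#' (read-level total, multimappers counted once).
#'
#' @param aln An [alignment_set()] of small-RNA mappings on TE consensi.
#' @param lib A [repeat_library()].
#' @return `PingPongProfile` data frame: `name`, `n_pirna_mapped`,
#'   `matched_read_count`, `pp_pairs`, `pct_pingpong` (`NA` when no piRNA
#'   maps), `ppd_per_kb`, `ppd_pmm`.
#' @export
pingpong_metrics <- function(aln, lib) {
  recs <- aln$records
  recs <- recs[recs$read_length >= 23L & recs$read_length <= 30L &
                 recs$target %in% lib$name, , drop = FALSE]
  total_pirna <- length(unique(recs$read_id))
  res <- lapply(seq_len(nrow(lib)), function(i) {
    r <- recs[recs$target == lib$name[i], , drop = FALSE]
    n <- nrow(r)
    if (n == 0L) {
      return(data.frame(name = lib$name[i], n_pirna_mapped = 0L,
                        matched_read_count = 0L, pp_pairs = 0L,
                        pct_pingpong = NA_real_, ppd_per_kb = 0,
                        ppd_pmm = 0, stringsAsFactors = FALSE))
    }
    p5 <- read_5prime(r)
    pp <- pingpong_pairs(p5[r$strand == "+"], p5[r$strand == "-"])
    data.frame(name = lib$name[i], n_pirna_mapped = n,
               matched_read_count = pp$matched_read_count,
               pp_pairs = pp$pp_pairs,
               pct_pingpong = 100 * pp$matched_read_count / n,
               ppd_per_kb = pp$pp_pairs / (lib$length[i] / 1000),
               ppd_pmm = if (total_pirna > 0)
                 pp$pp_pairs * 1e6 / total_pirna else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Library-wide percent ping-pong
#'
#' Aggregates a [pingpong_metrics()] profile: percent of all mapped piRNA
#' reads with a 10-nt 5'-5' opposite-strand partner.
#'
#' @param profile A `PingPongProfile`.
#' @return A single percentage (`NA` if nothing mapped).
#' @export
overall_pingpong_pct <- function(profile) {
  n <- sum(profile$n_pirna_mapped)
  if (n == 0L) return(NA_real_)
  100 * sum(profile$matched_read_count) / n
}

#' 1U / 10A signature bias
#'
#' Fraction of reads with U(T) at position 1 and A at position 10, with
#' composition baselines: by default the mean per-position frequency of the
#' focal base over all read positions excluding the focal position
#' (`background = "off_position"`); `"whole_read"` uses the full composition.
#'
#' @param reads Data frame with columns `id`, `sequence`; reads shorter than
#'   10 nt are excluded from the 10A fraction.
#' @param background `"off_position"` (default) or `"whole_read"`.
#' @return `SignatureBias` list: `u1`, `a10`, `background_u`, `background_a`,
#'   `n_reads`.
#' @export
signature_bias <- function(reads, background = c("off_position",
                                                 "whole_read")) {
  background <- match.arg(background)
  seqs <- toupper(reads$sequence)
  seqs <- seqs[nchar(seqs) >= 10L]
  if (!length(seqs)) stop("no reads of length >= 10 nt")
  maxlen <- max(nchar(seqs))
  mat <- matrix(NA_character_, length(seqs), maxlen)
  sp <- strsplit(seqs, "")
  for (i in seq_along(sp)) mat[i, seq_along(sp[[i]])] <- sp[[i]]
  pos_freq <- function(base) {
    colSums(mat == base, na.rm = TRUE) / colSums(!is.na(mat))
  }
  fu <- pos_freq("T")
  fa <- pos_freq("A")
  bg_u <- if (background == "off_position") mean(fu[-1L]) else mean(fu)
  bg_a <- if (background == "off_position") mean(fa[-10L]) else mean(fa)
  list(u1 = unname(fu[1L]), a10 = unname(fa[10L]),
       background_u = bg_u, background_a = bg_a, n_reads = length(seqs))
}

#' Row z-scores of a metric matrix
#'
#' Centers and scales each row (TE family) across conditions. Constant rows
#' map to all zeros and are flagged in the `"constant_rows"` attribute.
#'
#' @param m Numeric matrix (families x conditions), at least 2 columns.
#' @param sd_type `"population"` (divide by the n-denominator sd, default) or
#'   `"sample"` (n-1).
#' @return Matrix of the same shape.
#' @export
row_zscores <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  mu <- rowMeans(m)
  dev <- m - mu
  n <- ncol(m)
  s <- sqrt(rowSums(dev^2) / if (sd_type == "population") n else n - 1L)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  z <- dev / s
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(m)[const] %||% which(const)
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
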