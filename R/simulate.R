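# Synthetic-data generators. Every downstream stage of the pipeline is
# exercised on data produced here, with planted, recoverable parameters:
# strain genomes differing in TE family copy number and within-family
# divergence, small-RNA libraries with a tunable ping-pong pair fraction and
# 1U/10A biases, genic piRNA targets, and recombinant F3 panels with planted
# protective loci. All generators are deterministic under a fixed seed.
# Divergence is substitution-only (no indels), so the homogeneity statistic
# has a closed-form expectation.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

#' Random nucleotide sequences
#'
#' @param n Number of sequences.
#' @param len Length (recycled).
#' @param base_probs Named probabilities for A/C/G/T.
#' @return Character vector.
#' @export
random_seq <- function(n, len,
                       base_probs = c(A = .25, C = .25, G = .25, T = .25)) {
  len <- rep_len(len, n)
  all <- sample(names(base_probs), sum(len), replace = TRUE,
                prob = base_probs)
  stops <- cumsum(len)
  starts <- c(1L, head(stops, -1L) + 1L)
  vapply(seq_len(n),
         function(i) paste(all[starts[i]:stops[i]], collapse = ""),
         character(1))
}

mutate_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < d
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(alt, b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Configuration for strain-genome simulation
#'
#' Defines two strain genomes that share a background but differ in TE family
#' copy number and within-family divergence, emulating an inducer/reactive
#' strain pair.
#'
#' @param seed Integer seed; identical seed gives identical output.
#' @param te_families Data frame with columns `name`, `consensus_length`,
#'   `copies_a`, `copies_b`, `divergence` (per-site substitution probability
#'   per copy, in \[0, 0.3\]).
#' @param background_length Shared non-repetitive background, bases.
#' @param read_length Read length for read simulation.
#' @param coverage Fold coverage for read simulation.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed, te_families, background_length = 5e4,
                       read_length = 100L, coverage = 10) {
  stopifnot(all(c("name", "consensus_length", "copies_a", "copies_b",
                  "divergence") %in% names(te_families)),
            all(te_families$copies_a >= 0), all(te_families$copies_b >= 0),
            all(te_families$divergence >= 0),
            all(te_families$divergence <= 0.3),
            coverage > 0, read_length >= 1)
  structure(list(seed = seed, te_families = te_families,
                 background_length = background_length,
                 read_length = as.integer(read_length), coverage = coverage),
            class = "SimConfig")
}

build_strain_genome <- function(background, fams, copy_col) {
  segs <- list(data.frame(target = "background", family = NA_character_,
                          seq = background, stringsAsFactors = FALSE))
  for (i in seq_len(nrow(fams))) {
    k <- fams[[copy_col]][i]
    if (k == 0) next
    cons <- fams$consensus[i]
    copies <- vapply(seq_len(k),
                     function(j) mutate_seq(cons, fams$divergence[i]),
                     character(1))
    segs[[length(segs) + 1L]] <-
      data.frame(target = fams$name[i], family = fams$name[i],
                 seq = copies, stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, segs)
  segs$width <- nchar(segs$seq)
  segs$end <- cumsum(segs$width)
  segs$start <- segs$end - segs$width + 1L
  segs
}

#' Simulate two strain genomes with planted TE copies
#'
#' Each genome is a shared random background followed by the planted copies
#' of each family; each copy is independently mutated from the consensus at
#' the family's divergence rate (substitutions only). The truth table records
#' the planted copy counts and divergences.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome_a`, `genome_b` (character sequences), `layout_a`,
#'   `layout_b` (segment tables with copy coordinates), `consensi` (a
#'   [repeat_library()] of the family consensus sequences) and `truth`.
#' @export
simulate_strain_genomes <- function(cfg) {
  with_seed(cfg$seed, {
    fams <- cfg$te_families
    fams$consensus <- random_seq(nrow(fams), fams$consensus_length)
    background <- random_seq(1L, cfg$background_length)
    layout_a <- build_strain_genome(background, fams, "copies_a")
    layout_b <- build_strain_genome(background, fams, "copies_b")
    list(genome_a = paste(layout_a$seq, collapse = ""),
         genome_b = paste(layout_b$seq, collapse = ""),
         layout_a = layout_a, layout_b = layout_b,
         consensi = repeat_library(setNames(fams$consensus, fams$name)),
         truth = data.frame(name = fams$name, copies_a = fams$copies_a,
                            copies_b = fams$copies_b,
                            divergence = fams$divergence,
                            ratio = (fams$copies_a) / pmax(fams$copies_b, 1),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate uniform-coverage reads from a genome
#'
#' Uniform start positions on both strands; expected read count is
#' `coverage * genome_length / read_length`, drawn Poisson.
#'
#' @param genome Character sequence.
#' @param read_length Read length (must not exceed the genome).
#' @param coverage Fold coverage (> 0).
#' @param seed Optional seed.
#' @return Data frame `id`, `sequence`, plus `start`, `strand` truth columns.
#' @export
simulate_reads <- function(genome, read_length, coverage, seed = NULL) {
  L <- nchar(genome)
  if (read_length > L) stop("read_length exceeds genome length")
  with_seed(seed, {
    n <- rpois(1L, coverage * L / read_length)
    if (n == 0L) {
      return(data.frame(id = character(), sequence = character(),
                        start = integer(), strand = character(),
                        stringsAsFactors = FALSE))
    }
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome, starts, starts + read_length - 1L)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    data.frame(id = sprintf("read_%06d", seq_len(n)), sequence = seqs,
               start = starts, strand = strand, stringsAsFactors = FALSE)
  })
}

#' Simulate pre-aligned TE-library mappings for both strains
#'
#' Emulates the entry point of real data (reads mapped to the TE consensus
#' library, normalised by genome-mapped totals) without an external aligner:
#' reads are drawn uniformly from each simulated strain genome and reads
#' falling entirely within a planted TE copy are recorded as alignments to
#' that family's consensus, carrying the (possibly diverged) copy sequence.
#'
#' @param cfg A [sim_config()].
#' @param genomes Optional pre-built result of [simulate_strain_genomes()].
#' @return List with `aln_a`, `aln_b` ([alignment_set()]s on the consensus
#'   library), `lib` (the consensus [repeat_library()]) and `truth`.
#' @export
simulate_te_alignments <- function(cfg, genomes = NULL) {
  if (is.null(genomes)) genomes <- simulate_strain_genomes(cfg)
  one_strain <- function(layout, tag) {
    L <- sum(layout$width)
    n <- rpois(1L, cfg$coverage * L / cfg$read_length)
    starts <- sample.int(L - cfg$read_length + 1L, n, replace = TRUE)
    ends <- starts + cfg$read_length - 1L
    seg <- findInterval(starts, layout$start)
    inside <- !is.na(layout$family[seg]) & ends <= layout$end[seg]
    idx <- which(inside)
    if (length(idx)) {
      off <- starts[idx] - layout$start[seg[idx]] + 1L
      strand <- sample(c("+", "-"), length(idx), replace = TRUE)
      seqs <- substring(layout$seq[seg[idx]], off,
                        off + cfg$read_length - 1L)
      seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
      recs <- data.frame(
        read_id = sprintf("%s_%06d", tag, idx),
        target = layout$family[seg[idx]], start = off, strand = strand,
        read_length = cfg$read_length, mapq = 37L, n_hits = 1L,
        seq = seqs, stringsAsFactors = FALSE)
    } else recs <- empty_records()
    alignment_set(recs, genome_mapped_total = n, library_total = n)
  }
  with_seed(cfg$seed + 1L, {
    list(aln_a = one_strain(genomes$layout_a, "a"),
         aln_b = one_strain(genomes$layout_b, "b"),
         lib = genomes$consensi, truth = genomes$truth)
  })
}

#' Simulate a repeat consensus library
#'
#' Default dimensions emulate a curated *D. virilis*-scale repeat library
#' (about two hundred families of a few kilobases each).
#'
#' @param n_families Number of families.
#' @param length_range Consensus length range, bases.
#' @param seed Optional seed.
#' @return A [repeat_library()].
#' @export
simulate_repeat_library <- function(n_families = 200L,
                                    length_range = c(2000L, 8000L),
                                    seed = NULL) {
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_families,
                   replace = TRUE)
    repeat_library(setNames(random_seq(n_families, lens),
                            sprintf("TE%03d", seq_len(n_families))))
  })
}

#' Specification for a small-RNA library simulation
#'
#' The defaults emulate an early-embryo small-RNA library: piRNA mass at
#' 23-30 nt, an endo-siRNA peak at 21 nt, slightly GC-rich composition
#' (U 0.21, A 0.22), a 1U bias of 0.33 on primary piRNAs and a 10A bias of
#' 0.25 on ping-pong partners.
#'
#' @param n_reads Number of TE-derived small RNAs.
#' @param size_probs Named probabilities over read lengths 18-30 nt.
#' @param pingpong_fraction Fraction `f` of piRNA reads emitted as members of
#'   10-nt 5'-5' overlap pairs.
#' @param u1_bias P(U at position 1) for primary piRNA reads.
#' @param a10_bias P(A at position 10) for secondary (pair partner) reads.
#' @param te_weights Optional named per-family abundance weights.
#' @param genic_targets Optional data frame `gene_id`, `density_pm`,
#'   `sense_fraction` of planted genic piRNA producers.
#' @param base_probs Background base composition.
#' @param mapped_total Genome-mapped read total used as the per-million
#'   denominator metadata (default: number of reads generated).
#' @return A `SmallRNASimSpec` list.
#' @export
smallrna_spec <- function(n_reads = 10000L,
                          size_probs = NULL,
                          pingpong_fraction = 0,
                          u1_bias = 0.33, a10_bias = 0.25,
                          te_weights = NULL, genic_targets = NULL,
                          base_probs = c(A = 0.22, C = 0.285,
                                         G = 0.285, T = 0.21),
                          mapped_total = NULL) {
  if (is.null(size_probs)) {
    size_probs <- setNames(numeric(13), 18:30)
    size_probs["21"] <- 0.15                      # endo-siRNA peak
    size_probs[as.character(23:30)] <-
      0.70 * c(.08, .16, .24, .22, .14, .08, .05, .03)  # piRNA mass
    size_probs[c("18", "19", "20", "22")] <- 0.15 / 4
  }
  stopifnot(abs(sum(size_probs) - 1) < 1e-8,
            pingpong_fraction >= 0, pingpong_fraction <= 1,
            u1_bias >= 0, u1_bias <= 1, a10_bias >= 0, a10_bias <= 1)
  structure(list(n_reads = n_reads, size_probs = size_probs,
                 pingpong_fraction = pingpong_fraction,
                 u1_bias = u1_bias, a10_bias = a10_bias,
                 te_weights = te_weights, genic_targets = genic_targets,
                 base_probs = base_probs, mapped_total = mapped_total),
            class = "SmallRNASimSpec")
}

biased_seq <- function(n, len, base_probs, pos1_T = NULL, pos10_A = NULL) {
  seqs <- random_seq(n, len, base_probs)
  if (!is.null(pos1_T)) {
    others <- base_probs[c("A", "C", "G")] / sum(base_probs[c("A", "C", "G")])
    first <- ifelse(runif(n) < pos1_T, "T",
                    sample(names(others), n, replace = TRUE, prob = others))
    substring(seqs, 1L, 1L) <- first
  }
  if (!is.null(pos10_A)) {
    others <- base_probs[c("C", "G", "T")] / sum(base_probs[c("C", "G", "T")])
    tenth <- ifelse(runif(n) < pos10_A, "A",
                    sample(names(others), n, replace = TRUE, prob = others))
    substring(seqs, 10L, 10L) <- tenth
  }
  seqs
}

#' Simulate a small-RNA library over a repeat library
#'
#' A fraction `f` of piRNA (23-30 nt) reads per family is emitted as 10-nt
#' 5'-5' overlap pairs (plus-read 5' at `p`, minus-read 5' at `p + 9` on the
#' consensus); remaining reads get uniform positions and strands. Primary
#' reads carry the 1U bias, pair partners the 10A bias. Planted genic reads
#' are placed on gene CDS/exon spans at the requested per-million densities
#' and sense fractions, as unique genome mappings.
#'
#' @param spec A [smallrna_spec()].
#' @param lib A [repeat_library()] of TE consensi.
#' @param genes Optional [gene_models()] (required when `spec$genic_targets`
#'   is set).
#' @param seed Optional seed.
#' @return List with `aln` (an [alignment_set()] over consensi and gene
#'   scaffolds), `reads` (id/sequence/length/role), and `truth`.
#' @export
simulate_smallrna <- function(spec, lib, genes = NULL, seed = NULL) {
  with_seed(seed, {
    n <- spec$n_reads
    lens <- as.integer(sample(names(spec$size_probs), n, replace = TRUE,
                              prob = spec$size_probs))
    w <- spec$te_weights
    if (is.null(w)) w <- setNames(rep(1, nrow(lib)), lib$name)
    te <- sample(names(w), n, replace = TRUE, prob = w)
    te_len <- setNames(lib$length, lib$name)[te]
    is_pi <- lens >= 23L & lens <= 30L
    role <- ifelse(is_pi, "primary", "other")
    strand <- sample(c("+", "-"), n, replace = TRUE)
    pos5 <- integer(n)

    # mark ping-pong pairs per family among piRNA reads
    f <- spec$pingpong_fraction
    if (f > 0) {
      for (fam in unique(te[is_pi])) {
        idx <- which(is_pi & te == fam)
        n_paired <- floor(round(f * length(idx)) / 2) * 2
        if (n_paired < 2) next
        sel <- sample(idx, n_paired)
        plus <- sel[seq_len(n_paired / 2)]
        minus <- sel[seq(n_paired / 2 + 1, n_paired)]
        L <- setNames(lib$length, lib$name)[fam]
        p <- sample(40:(L - 40L), n_paired / 2, replace = TRUE)
        strand[plus] <- "+"; pos5[plus] <- p
        strand[minus] <- "-"; pos5[minus] <- p + 9L
        role[minus] <- "secondary"
        role[plus] <- "paired_primary"
      }
    }
    unplaced <- pos5 == 0L
    # uniform placement for unpaired reads, clipped inside the consensus
    pos5[unplaced] <- ifelse(
      strand[unplaced] == "+",
      1L + floor(runif(sum(unplaced)) * (te_len[unplaced] -
                                           lens[unplaced] + 1L)),
      lens[unplaced] + floor(runif(sum(unplaced)) *
                               (te_len[unplaced] - lens[unplaced] + 1L)))
    start <- ifelse(strand == "+", pos5, pos5 - lens + 1L)

    seqs <- character(n)
    prim <- role %in% c("primary", "paired_primary") & is_pi
    sec <- role == "secondary"
    rest <- !prim & !sec
    if (any(prim)) seqs[prim] <- biased_seq(sum(prim), lens[prim],
                                            spec$base_probs,
                                            pos1_T = spec$u1_bias)
    if (any(sec)) seqs[sec] <- biased_seq(sum(sec), lens[sec],
                                          spec$base_probs,
                                          pos10_A = spec$a10_bias)
    if (any(rest)) seqs[rest] <- random_seq(sum(rest), lens[rest],
                                            spec$base_probs)

    recs <- data.frame(read_id = sprintf("sr_%06d", seq_len(n)),
                       target = te, start = start, strand = strand,
                       read_length = lens, mapq = 37L, n_hits = 1L,
                       seq = seqs, stringsAsFactors = FALSE)
    reads <- data.frame(id = recs$read_id, sequence = seqs, length = lens,
                        role = role, stringsAsFactors = FALSE)
    total <- n

    genic_truth <- NULL
    if (!is.null(spec$genic_targets)) {
      if (is.null(genes)) stop("genic_targets set but no gene models given")
      gt <- spec$genic_targets
      missing <- setdiff(gt$gene_id, unique(genes$gene_id))
      if (length(missing)) stop("gene id(s) absent from annotation: ",
                                paste(missing, collapse = ", "))
      denom <- if (is.null(spec$mapped_total)) n else spec$mapped_total
      glist <- list()
      for (i in seq_len(nrow(gt))) {
        cds <- genes[genes$gene_id == gt$gene_id[i] &
                       genes$feature == "CDS", , drop = FALSE]
        if (!nrow(cds)) stop("planted gene lacks CDS: ", gt$gene_id[i])
        cnt <- round(gt$density_pm[i] * denom / 1e6)
        if (cnt == 0) next
        pick <- sample(seq_len(nrow(cds)), cnt, replace = TRUE,
                       prob = cds$end - cds$start + 1)
        glen <- sample(23:30, cnt, replace = TRUE)
        gs <- cds$start[pick] +
          floor(runif(cnt) * pmax(cds$end[pick] - cds$start[pick] -
                                    glen + 2, 1))
        sense <- runif(cnt) < gt$sense_fraction[i]
        gstr <- ifelse(sense, cds$strand[pick],
                       ifelse(cds$strand[pick] == "+", "-", "+"))
        glist[[i]] <- data.frame(
          read_id = sprintf("g%02d_%05d", i, seq_len(cnt)),
          target = cds$scaffold[pick], start = gs, strand = gstr,
          read_length = glen, mapq = 37L, n_hits = 1L,
          seq = NA_character_, stringsAsFactors = FALSE)
      }
      if (length(glist)) {
        grecs <- do.call(rbind, glist)
        recs <- rbind(recs, grecs)
        total <- total + nrow(grecs)
      }
      genic_truth <- gt
      if (!is.null(spec$mapped_total)) total <- spec$mapped_total
    }
    aln <- alignment_set(recs, genome_mapped_total = total,
                         library_total = max(total, nrow(recs)))
    list(aln = aln, reads = reads,
         truth = list(pingpong_fraction = f,
                      n_pirna = sum(is_pi), genic = genic_truth))
  })
}

## ---- recombinant panel simulation -------------------------------------

#' Specification for the F3 maternal-protection panel
#'
#' Emulates the protection mapping design: inducer-strain (donor, "A")
#' great-grandmothers crossed into the reactive strain (recipient, "B") with
#' two rounds of backcrossing, each F3 female then test-crossed and scored
#' for the proportion of dysgenic testes among her progeny. Chromosome
#' lengths default to a six-element *D. virilis*-like karyotype; crossover
#' counts are Poisson (female meiosis only), positions uniform.
#'
#' @param n_females Panel size.
#' @param chr_lengths Named chromosome lengths, bases.
#' @param markers Data frame `chr`, `pos` of genotyped markers (defaults to
#'   telomeric, pericentric and one euchromatic marker per chromosome).
#' @param protective_loci Data frame `chr`, `pos`, `effect`: additive
#'   log-odds change in dysgenesis when the donor allele is present
#'   (negative = protective). May be empty (null panel).
#' @param base_logodds Baseline dysgenesis log-odds for a fully recipient
#'   female.
#' @param xo_rate Expected crossovers per chromosome per female meiosis.
#' @param n_testes Testes scored per female's progeny.
#' @return A `PanelSimSpec` list.
#' @export
f3_panel_spec <- function(n_females = 200L,
                          chr_lengths = c(X = 30e6, `2` = 28e6, `3` = 26e6,
                                          `4` = 25e6, `5` = 27e6, `6` = 2e6),
                          markers = NULL, protective_loci = NULL,
                          base_logodds = 1.0, xo_rate = 1.0,
                          n_testes = 40L) {
  if (length(chr_lengths) == 0L) stop("need at least one chromosome")
  if (is.null(markers)) {
    markers <- do.call(rbind, lapply(names(chr_lengths), function(ch) {
      L <- chr_lengths[[ch]]
      data.frame(chr = ch,
                 pos = round(c(0.02, 0.5, 0.85) * L),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(protective_loci)) {
    protective_loci <- data.frame(chr = character(), pos = numeric(),
                                  effect = numeric())
  }
  structure(list(n_females = n_females, chr_lengths = chr_lengths,
                 markers = markers, protective_loci = protective_loci,
                 base_logodds = base_logodds, xo_rate = xo_rate,
                 n_testes = as.integer(n_testes)),
            class = "PanelSimSpec")
}

# haplotype = list(bp = numeric breakpoints incl. 0 and L, st = states per
# segment); gamete of a meiosis with Poisson crossovers, uniform positions
meiosis_gamete <- function(h1, h2, L, xo_rate) {
  k <- rpois(1L, xo_rate)
  xo <- sort(runif(k, 0, L))
  cuts <- c(0, xo, L)
  use1 <- (sample.int(2L, 1L) + seq_len(length(cuts) - 1L)) %% 2L == 0L
  bp <- 0; st <- character()
  for (i in seq_len(length(cuts) - 1L)) {
    src <- if (use1[i]) h1 else h2
    a <- cuts[i]; b <- cuts[i + 1L]
    j <- which(src$bp[-length(src$bp)] < b & src$bp[-1L] > a)
    for (jj in j) {
      bp <- c(bp, min(b, src$bp[jj + 1L]))
      st <- c(st, src$st[jj])
    }
  }
  # merge adjacent equal states
  keep <- c(st[-1L] != st[-length(st)], TRUE)
  list(bp = c(0, bp[-1L][keep]), st = st[keep])
}

hap_state_at <- function(hap, pos) {
  hap$st[findInterval(pos, hap$bp, rightmost.closed = TRUE,
                      left.open = TRUE)]
}

hap_uniform <- function(L, state) list(bp = c(0, L), st = state)

#' Simulate the F3 maternal-protection panel
#'
#' Each F3 female's donor-strain content per chromosome is the composition of
#' two simulated backcross meioses from a fully heterozygous F1; her
#' phenotype is the proportion of dysgenic testes among `n_testes` progeny
#' testes, binomial around a logistic function of the planted protective-locus
#' genotypes.
#'
#' @param spec An [f3_panel_spec()].
#' @param seed Optional seed.
#' @return List with `genotypes` (females x markers, 1 = heterozygous for the
#'   donor allele, 0 = recipient homozygote), `phenotypes` (data frame
#'   `female`, `prop_dysgenic`, `n_testes`), and `blocks` (per-female list of
#'   donor-strain heterozygous spans, the truth for ancestry painting).
#' @export
simulate_f3_panel <- function(spec, seed = NULL) {
  with_seed(seed, {
    chs <- names(spec$chr_lengths)
    mk_names <- sprintf("%s:%d", spec$markers$chr,
                        round(spec$markers$pos))
    G <- matrix(0L, spec$n_females, nrow(spec$markers),
                dimnames = list(sprintf("f%03d", seq_len(spec$n_females)),
                                mk_names))
    P <- numeric(spec$n_females)
    blocks <- vector("list", spec$n_females)
    for (i in seq_len(spec$n_females)) {
      fem_blocks <- list()
      eta <- spec$base_logodds
      for (ch in chs) {
        L <- spec$chr_lengths[[ch]]
        g1 <- meiosis_gamete(hap_uniform(L, "A"), hap_uniform(L, "B"),
                             L, spec$xo_rate)
        g2 <- meiosis_gamete(g1, hap_uniform(L, "B"), L, spec$xo_rate)
        mi <- which(spec$markers$chr == ch)
        if (length(mi)) {
          G[i, mi] <- as.integer(
            hap_state_at(g2, spec$markers$pos[mi]) == "A")
        }
        li <- which(spec$protective_loci$chr == ch)
        if (length(li)) {
          het <- hap_state_at(g2, spec$protective_loci$pos[li]) == "A"
          eta <- eta + sum(spec$protective_loci$effect[li][het])
        }
        segA <- which(g2$st == "A")
        if (length(segA)) {
          fem_blocks[[ch]] <- data.frame(
            chr = ch, start = g2$bp[segA] + 1,
            end = g2$bp[segA + 1L], stringsAsFactors = FALSE)
        }
      }
      P[i] <- rbinom(1L, spec$n_testes, plogis(eta)) / spec$n_testes
      blocks[[i]] <- if (length(fem_blocks))
        do.call(rbind, fem_blocks) else
          data.frame(chr = character(), start = numeric(), end = numeric())
    }
    list(genotypes = G,
         phenotypes = data.frame(female = rownames(G), prop_dysgenic = P,
                                 n_testes = spec$n_testes,
                                 stringsAsFactors = FALSE),
         blocks = setNames(blocks, rownames(G)))
  })
}

#' Simulate an F2 zygotic-induction panel
#'
#' Emulates the paternal-chromosome induction design: F1 males (no crossing
#' over in *Drosophila* males) transmit whole chromosomes, so each F2 carries
#' each paternal chromosome from the inducer strain with probability 1/2;
#' dysgenesis is Bernoulli around a logistic function of the carried
#' chromosomes.
#'
#' @param n Number of F2 individuals.
#' @param chr_effects Named log-odds effect per chromosome (0 = null).
#' @param base_logodds Baseline log-odds of dysgenesis.
#' @param seed Optional seed.
#' @return List with `genotypes` (n x chromosomes, 0/1) and `dysgenic`
#'   (0/1 outcome).
#' @export
simulate_induction_panel <- function(n = 92L,
                                     chr_effects = c(`2` = 0, `3` = 0,
                                                     `4` = 0, `5` = 0,
                                                     `6` = 0),
                                     base_logodds = 0, seed = NULL) {
  with_seed(seed, {
    G <- matrix(rbinom(n * length(chr_effects), 1L, 0.5), n,
                dimnames = list(NULL, names(chr_effects)))
    eta <- base_logodds + as.vector(G %*% chr_effects)
    list(genotypes = G, dysgenic = rbinom(n, 1L, plogis(eta)))
  })
}

#' Simulate donor-unique read origins for ancestry painting
#'
#' Generates the positions of reads mapping uniquely to the donor (strain-A)
#' haplotype of a pseudo-diploid reference for one female: inside planted
#' heterozygous blocks, donor-unique reads accrue at `read_rate` per base;
#' outside them, only a residual `noise_rate` survives the unique-mapping
#' filter (with stringent quality filtering essentially no reads from
#' recipient-homozygous regions map uniquely to the donor haplotype).
#'
#' @param blocks Data frame `chr`, `start`, `end` of heterozygous donor
#'   spans (may have zero rows for a fully recipient female).
#' @param chr_lengths Named chromosome lengths.
#' @param read_rate Donor-unique reads per base inside het blocks.
#' @param noise_rate Residual rate outside blocks.
#' @param read_length Read length.
#' @param seed Optional seed.
#' @return Data frame `read_id`, `scaffold`, `start`, `read_length`.
#' @export
simulate_ancestry_origins <- function(blocks, chr_lengths,
                                      read_rate = 2e-3, noise_rate = 2e-6,
                                      read_length = 100L, seed = NULL) {
  with_seed(seed, {
    out <- list()
    if (nrow(blocks)) {
      for (i in seq_len(nrow(blocks))) {
        w <- blocks$end[i] - blocks$start[i] + 1
        k <- rpois(1L, read_rate * w)
        if (k == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          scaffold = blocks$chr[i],
          start = blocks$start[i] + floor(runif(k) * max(w - read_length, 1)),
          stringsAsFactors = FALSE)
      }
    }
    for (ch in names(chr_lengths)) {
      k <- rpois(1L, noise_rate * chr_lengths[[ch]])
      if (k == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold = ch,
        start = 1 + floor(runif(k) * (chr_lengths[[ch]] - read_length)),
        stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out) else
      data.frame(scaffold = character(), start = numeric())
    res <- res[order(res$scaffold, res$start), , drop = FALSE]
    rownames(res) <- NULL
    if (nrow(res)) res$read_id <- sprintf("u_%06d", seq_len(nrow(res)))
    else res$read_id <- character()
    res$read_length <- if (nrow(res)) as.integer(read_length) else integer()
    res[, c("read_id", "scaffold", "start", "read_length")]
  })
}
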