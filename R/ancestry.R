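# Maternal-protection genetics: pseudo-diploid construction, read-origin
# assignment, sliding-window ancestry painting, induction log-odds,
# single-marker QTL with permutation thresholds, and candidate-TE
# elimination from protective females.

#' Assemble a pseudo-diploid reference from two strain haplotypes
#'
#' Concatenates the per-scaffold consensus sequences of each strain in the
#' stated scaffold order into one haplotype per strain, recording each
#' scaffold's offset so concatenated coordinates can be mapped back.
#'
#' @param scaffolds_a,scaffolds_b Named character vectors of scaffold
#'   sequences for the two strains (same scaffold set).
#' @param order Scaffold order (default: names of `scaffolds_a`).
#' @return `PseudoDiploid` list: `hap_a`, `hap_b` (concatenated sequences),
#'   `offsets` (data frame `scaffold`, `offset_a`, `offset_b`, `length_a`,
#'   `length_b`).
#' @export
build_pseudodiploid <- function(scaffolds_a, scaffolds_b,
                                order = names(scaffolds_a)) {
  miss <- union(setdiff(order, names(scaffolds_a)),
                setdiff(order, names(scaffolds_b)))
  if (length(miss)) {
    stop("scaffold(s) missing from one strain: ",
         paste(miss, collapse = ", "))
  }
  la <- nchar(scaffolds_a[order])
  lb <- nchar(scaffolds_b[order])
  off_a <- cumsum(c(0, head(unname(la), -1L)))
  off_b <- cumsum(c(0, head(unname(lb), -1L)))
  structure(list(
    hap_a = paste(scaffolds_a[order], collapse = ""),
    hap_b = paste(scaffolds_b[order], collapse = ""),
    offsets = data.frame(scaffold = order, offset_a = off_a,
                         offset_b = off_b, length_a = unname(la),
                         length_b = unname(lb), stringsAsFactors = FALSE)),
    class = "PseudoDiploid")
}

#' Map concatenated haplotype-A coordinates back to scaffold coordinates
#'
#' @param pd A [build_pseudodiploid()].
#' @param pos Positions on the concatenated haplotype A (1-based).
#' @return Data frame `scaffold`, `start`.
#' @export
backmap_coords <- function(pd, pos) {
  idx <- findInterval(pos, pd$offsets$offset_a + 1)
  data.frame(scaffold = pd$offsets$scaffold[idx],
             start = pos - pd$offsets$offset_a[idx],
             stringsAsFactors = FALSE)
}

#' Assign read origins on a pseudo-diploid reference
#'
#' A read is assigned to a haplotype only when it has a sole best placement
#' (`n_hits == 1`) on that haplotype with confidence at least `mapq_min`
#' (mirroring stringent `-q`-style filtering of an aligner); everything else
#' is ambiguous. Reads from regions identical between the strains map to
#' both haplotypes and are therefore ambiguous by construction.
#'
#' @param aln An [alignment_set()] against the concatenated diploid.
#' @param hap_a,hap_b Target names of the two haplotypes.
#' @param mapq_min Minimum mapping quality (default 30).
#' @return Data frame `read_id`, `origin` (`"A"`, `"B"`, `"ambiguous"`),
#'   `target`, `start`, `read_length`.
#' @export
assign_reads <- function(aln, hap_a = "hapA", hap_b = "hapB",
                         mapq_min = 30L) {
  recs <- aln$records
  ok <- recs$n_hits == 1L & recs$mapq >= mapq_min
  origin <- ifelse(ok & recs$target == hap_a, "A",
                   ifelse(ok & recs$target == hap_b, "B", "ambiguous"))
  data.frame(read_id = recs$read_id, origin = origin, target = recs$target,
             start = recs$start, read_length = recs$read_length,
             stringsAsFactors = FALSE)
}

#' Paint ancestry from donor-unique read densities in sliding windows
#'
#' Tiles each scaffold with fixed windows and computes the donor-strain
#' unique-mapper density (base pairs of uniquely A-mapping reads per
#' window). A window is called heterozygous-for-donor (`het_A`) when its
#' density is at least `min_density_fraction` of the genome-wide mean
#' density; valleys are recipient-homozygous (`hom_B`). Runs shorter than
#' `min_run` windows are merged into their neighbours before spans are
#' emitted.
#'
#' @param origins Data frame of uniquely donor-mapping reads: `scaffold`,
#'   `start`, `read_length` (e.g. the A-origin rows of [assign_reads()]
#'   back-mapped with [backmap_coords()], or [simulate_ancestry_origins()]).
#' @param scaffold_lengths Named scaffold lengths.
#' @param window Window size, bases (default 10 kb).
#' @param min_density_fraction Fraction of the genome-wide mean density at
#'   or above which a window is `het_A` (default 0.25).
#' @param min_run Minimum run length, in windows, for a state to survive
#'   smoothing (default 3).
#' @return `AncestryPainting` list: `windows` (data frame `scaffold`,
#'   `start`, `end`, `bp_unique_a`, `state`) and `spans` (data frame
#'   `scaffold`, `start`, `end`, `state`, merged runs). With zero unique
#'   reads all windows are `no_call` and no spans are emitted.
#' @export
paint_ancestry <- function(origins, scaffold_lengths, window = 10000L,
                           min_density_fraction = 0.25, min_run = 3L) {
  stopifnot(window > 0)
  win_list <- lapply(names(scaffold_lengths), function(ch) {
    L <- scaffold_lengths[[ch]]
    starts <- seq(1, L, by = window)
    data.frame(scaffold = ch, start = starts,
               end = pmin(starts + window - 1, L),
               stringsAsFactors = FALSE)
  })
  wins <- do.call(rbind, win_list)
  wins$bp_unique_a <- 0
  if (nrow(origins)) {
    for (ch in unique(origins$scaffold)) {
      o <- origins[origins$scaffold == ch, , drop = FALSE]
      wi <- which(wins$scaffold == ch)
      # apportion each read's bases to the window(s) it overlaps
      rs <- o$start
      re <- o$start + o$read_length - 1
      w1 <- findInterval(rs, wins$start[wi])
      w2 <- findInterval(re, wins$start[wi])
      for (k in seq_along(rs)) {
        for (w in w1[k]:w2[k]) {
          if (w < 1 || w > length(wi)) next
          ov <- min(re[k], wins$end[wi[w]]) - max(rs[k], wins$start[wi[w]]) + 1
          wins$bp_unique_a[wi[w]] <- wins$bp_unique_a[wi[w]] + ov
        }
      }
    }
  }
  if (sum(wins$bp_unique_a) == 0) {
    wins$state <- "no_call"
    return(structure(list(windows = wins,
                          spans = data.frame(scaffold = character(),
                                             start = numeric(),
                                             end = numeric(),
                                             state = character())),
                     class = "AncestryPainting"))
  }
  thr <- min_density_fraction * mean(wins$bp_unique_a)
  wins$state <- ifelse(wins$bp_unique_a >= thr, "het_A", "hom_B")
  spans <- list()
  for (ch in unique(wins$scaffold)) {
    wi <- which(wins$scaffold == ch)
    st <- wins$state[wi]
    # absorb runs shorter than min_run into the surrounding state until
    # stable (two-state smoothing)
    repeat {
      r <- rle(st)
      short <- which(r$lengths < min_run)
      if (!length(short) || length(r$lengths) == 1L) break
      j <- short[which.min(r$lengths[short])]
      r$values[j] <- if (j > 1L) r$values[j - 1L] else r$values[j + 1L]
      st <- inverse.rle(r)
    }
    wins$state[wi] <- st
    r <- rle(st)
    e <- cumsum(r$lengths)
    s <- c(1L, head(e, -1L) + 1L)
    spans[[ch]] <- data.frame(scaffold = ch,
                              start = wins$start[wi[s]],
                              end = wins$end[wi[e]],
                              state = r$values, stringsAsFactors = FALSE)
  }
  spans <- do.call(rbind, spans)
  rownames(spans) <- NULL
  structure(list(windows = wins, spans = spans),
            class = "AncestryPainting")
}

#' Per-chromosome induction log-odds from an F2 panel
#'
#' Logistic regression (binomial family, logit link) of the dysgenesis
#' outcome on the paternally inherited chromosome indicators, with Wald
#' confidence intervals. Complete separation is flagged and the interval
#' reported as infinite.
#'
#' @param genotypes Matrix (individuals x chromosomes, 0/1).
#' @param outcome 0/1 dysgenesis indicator.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame `term`, `log_odds`, `se`, `ci_lo`, `ci_hi`,
#'   `separated`.
#' @export
induction_logodds <- function(genotypes, outcome, conf_level = 0.95) {
  df <- data.frame(genotypes, check.names = FALSE)
  df$.y <- outcome
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  separated <- sep_warn | se > 50 | abs(co) > 15
  out <- data.frame(term = names(co), log_odds = unname(co),
                    se = unname(se),
                    ci_lo = unname(co - z * se), ci_hi = unname(co + z * se),
                    separated = unname(separated),
                    stringsAsFactors = FALSE)
  out$ci_lo[out$separated] <- -Inf
  out$ci_hi[out$separated] <- Inf
  rownames(out) <- NULL
  out
}

marker_abs_t <- function(G, y) {
  # per-marker |t| from simple linear regression, vectorised over markers
  n <- length(y)
  r <- suppressWarnings(cor(G, y))
  r[is.na(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  abs(r) * sqrt((n - 2) / (1 - r2))
}

#' Single-marker QTL scan with a permutation genome-wide threshold
#'
#' Regresses the phenotype (proportion of dysgenic testes) on each marker
#' genotype, using |t| as the statistic; the genome-wide significance
#' threshold is the `1 - alpha` quantile of the maximum statistic over
#' markers across phenotype permutations (which handles the non-normal
#' proportion phenotype). Monomorphic markers are skipped.
#'
#' @param genotypes Matrix (individuals x markers, 0/1 or numeric).
#' @param phenotype Numeric phenotype per individual.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Optional seed for the permutations.
#' @return List `stats` (data frame `marker`, `abs_t`, `significant`),
#'   `threshold`, `perm_max` (the permutation null maxima), and
#'   `skipped` (monomorphic markers).
#' @export
single_marker_qtl <- function(genotypes, phenotype, n_perm = 5000L,
                              alpha = 0.05, seed = NULL) {
  mono <- apply(genotypes, 2L, function(g) length(unique(g)) < 2L)
  if (any(mono)) {
    message("skipping ", sum(mono), " monomorphic marker(s)")
  }
  G <- genotypes[, !mono, drop = FALSE]
  if (ncol(G) == 0L) stop("no polymorphic markers")
  obs <- marker_abs_t(G, phenotype)
  perm_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      max(marker_abs_t(G, sample(phenotype)))
    }, numeric(1))
  })
  thr <- unname(quantile(perm_max, 1 - alpha, type = 7))
  list(stats = data.frame(marker = colnames(G), abs_t = unname(obs),
                          significant = unname(obs > thr),
                          stringsAsFactors = FALSE),
       threshold = thr, perm_max = perm_max,
       skipped = colnames(genotypes)[mono])
}

#' Eliminate candidate inducer TEs using protective females
#'
#' Step 1 qualifies candidates: only TEs with greater piRNA abundance in the
#' inducer strain than in the reactive strain can drive dysgenesis. Step 2
#' eliminates any candidate for which at least one fully protective female
#' has piRNA abundance less than or equal to the reactive-strain baseline
#' (plus `tolerance`): such a female protects without that TE's piRNA, so
#' the TE alone cannot be the required maternal factor. The audit trail
#' names the eliminating female for each removed TE.
#'
#' @param abundance Matrix (TEs x females) of per-million piRNA abundances.
#' @param strain160 Named per-TE piRNA abundance in the inducer strain.
#' @param strain9 Named per-TE piRNA abundance in the reactive strain (the
#'   baseline).
#' @param protective Logical per female: full repressive ability.
#' @param tolerance Slack added to the baseline in step 2 (default 0,
#'   i.e. "less than or equal to" the baseline).
#' @return List `surviving` (TE names), `audit` (data frame `te`, `stage`,
#'   `eliminated_by`).
#' @export
eliminate_candidates <- function(abundance, strain160, strain9, protective,
                                 tolerance = 0) {
  tes <- rownames(abundance)
  stopifnot(!is.null(tes), all(tes %in% names(strain160)),
            all(tes %in% names(strain9)),
            length(protective) == ncol(abundance))
  if (!any(protective)) {
    warning("no protective females: elimination step is the identity")
  }
  audit <- list()
  qualified <- tes[strain160[tes] > strain9[tes]]
  for (te in setdiff(tes, qualified)) {
    audit[[te]] <- data.frame(te = te, stage = "qualification",
                              eliminated_by = NA_character_,
                              stringsAsFactors = FALSE)
  }
  surviving <- character()
  prot_idx <- which(protective)
  for (te in qualified) {
    elim <- prot_idx[abundance[te, prot_idx] <= strain9[te] + tolerance]
    if (length(elim)) {
      who <- colnames(abundance)[elim[1L]] %||% as.character(elim[1L])
      audit[[te]] <- data.frame(te = te, stage = "protective_female",
                                eliminated_by = who,
                                stringsAsFactors = FALSE)
    } else {
      surviving <- c(surviving, te)
    }
  }
  list(surviving = surviving,
       audit = if (length(audit)) do.call(rbind, c(audit,
                                                   make.row.names = FALSE))
       else data.frame(te = character(), stage = character(),
                       eliminated_by = character()))
}
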