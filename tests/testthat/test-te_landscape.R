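test_that("abundance normalisation follows the per-million definition", {
  lib <- repeat_library(c(teX = strrep("ACGT", 100),
                          teY = strrep("GGCC", 100)))
  recs <- rec(sprintf("r%03d", 1:500), "teX", start = 1L)
  aln <- alignment_set(recs, genome_mapped_total = 1e6,
                       library_total = 1e6)
  tab <- compute_abundance(aln, lib)
  expect_equal(tab$abundance_pm[tab$name == "teX"], 500)
  expect_equal(tab$abundance_pm[tab$name == "teY"], 0)
  expect_error(compute_abundance(alignment_set(recs, 0, 0), lib),
               "positive")
})

test_that("multi-placement reads count once, ties broken by target name", {
  lib <- repeat_library(c(aaa = strrep("A", 50), zzz = strrep("A", 50)))
  recs <- rbind(rec("r1", "zzz", 1L, n_hits = 2L, mapq = 0L),
                rec("r1", "aaa", 1L, n_hits = 2L, mapq = 0L))
  tab <- compute_abundance(alignment_set(recs, 10, 10), lib)
  expect_equal(tab$mapped_reads[tab$name == "aaa"], 1L)
  expect_equal(tab$mapped_reads[tab$name == "zzz"], 0L)
})

test_that("homogeneity matches hand-computed pileups", {
  cons <- strrep("A", 10)
  lib <- repeat_library(c(te1 = cons))
  # 4 reads covering all 10 positions; one G at position 5 in one read
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAA", "AAAAAAAAAA", "AAAAGAAAAA")
  recs <- rec(paste0("r", 1:4), "te1", 1L, read_length = 10L, seq = seqs)
  aln <- alignment_set(recs, 4, 4)
  hom <- compute_homogeneity(aln, lib, min_coverage = 4L)
  expect_equal(hom$homogeneity, (9 * 1.0 + 0.75) / 10)
  expect_equal(hom$covered_positions, 10L)
  # all reads identical to consensus -> exactly 1
  aln1 <- alignment_set(rec(paste0("s", 1:4), "te1", 1L, read_length = 10L,
                            seq = rep(cons, 4)), 4, 4)
  expect_equal(compute_homogeneity(aln1, lib, 4L)$homogeneity, 1.0)
  # scale invariance: duplicating every read leaves homogeneity unchanged
  dup <- alignment_set(rbind(recs, rec(paste0("d", 1:4), "te1", 1L,
                                       read_length = 10L, seq = seqs)),
                       8, 8)
  expect_equal(compute_homogeneity(dup, lib, 4L)$homogeneity,
               hom$homogeneity)
  # below min_coverage everywhere -> flagged undefined, not zero
  thin <- alignment_set(rec("r1", "te1", 1L, read_length = 10L,
                            seq = cons), 1, 1)
  expect_true(is.na(compute_homogeneity(thin, lib, 4L)$homogeneity))
})

test_that("minus-strand reads enter the pileup in target orientation", {
  cons <- "ACGTACGTAC"
  lib <- repeat_library(c(te1 = cons))
  recs <- rbind(
    rec("p", "te1", 1L, "+", 10L, seq = cons),
    rec("m", "te1", 1L, "-", 10L, seq = revcomp(cons)),
    rec("p2", "te1", 1L, "+", 10L, seq = cons),
    rec("m2", "te1", 1L, "-", 10L, seq = revcomp(cons)))
  hom <- compute_homogeneity(alignment_set(recs, 4, 4), lib, 4L)
  expect_equal(hom$homogeneity, 1.0)
})

test_that("enrichment calls use the pseudocounted ratio and are antisymmetric", {
  tab_a <- data.frame(name = c("t1", "t2", "t3"),
                      mapped_reads = c(30L, 10L, 0L),
                      abundance_pm = c(30, 10, 0))
  tab_b <- data.frame(name = c("t1", "t2", "t3"),
                      mapped_reads = c(5L, 10L, 20L),
                      abundance_pm = c(5, 10, 20))
  calls <- call_enrichment(tab_a, tab_b)
  expect_equal(calls$ratio[1], 30.1 / 5.1)
  expect_equal(calls$enriched_in, c("A", "neither", "B"))
  swapped <- call_enrichment(tab_b, tab_a)
  expect_equal(swapped$enriched_in,
               c(A = "B", neither = "neither", B = "A")[calls$enriched_in],
               ignore_attr = TRUE)
  bad <- tab_b; bad$name[3] <- "other"
  expect_error(call_enrichment(tab_a, bad), "disagree")
})

test_that("scenario grid distinguishes reactivation, shared invasion, residents", {
  calls <- data.frame(name = c("react", "shared", "old", "invader"),
                      pm_a = c(30, 30, 10, 30),
                      pm_b = c(5, 5, 10, 0.2),
                      ratio = c(5.9, 5.9, 1, 100),
                      enriched_in = c("A", "A", "neither", "A"))
  hom_a <- data.frame(name = calls$name,
                      homogeneity = c(0.995, 0.995, 0.90, 0.995))
  hom_b <- data.frame(name = calls$name,
                      homogeneity = c(0.92, 0.993, 0.90, 0.80))
  out <- classify_scenario(calls, hom_a, hom_b)
  expect_equal(out$scenario,
               c("reactivation_in_A", "shared_recent_invasion",
                 "old_resident", "invasion_absent_in_B"))
  # undefined homogeneity -> unclassified
  hom_b$homogeneity[1] <- NA
  expect_equal(classify_scenario(calls, hom_a, hom_b)$scenario[1],
               "unclassified")
})

test_that("planted copy-number asymmetry is recovered from simulated mappings", {
  # a strain-B-specific repeat balances total genome length so that
  # per-million normalisation compares like with like
  fams <- data.frame(name = c("ratio1", "ratio35", "ratio8", "fillerB"),
                     consensus_length = 2000L,
                     copies_a = c(4L, 7L, 8L, 0L),
                     copies_b = c(4L, 2L, 1L, 12L),
                     divergence = 0)
  cfg <- sim_config(seed = 101, te_families = fams,
                    background_length = 5e4, coverage = 10)
  sim <- simulate_te_alignments(cfg)
  ta <- compute_abundance(sim$aln_a, sim$lib)
  tb <- compute_abundance(sim$aln_b, sim$lib)
  calls <- call_enrichment(ta, tb)
  expect_equal(calls$enriched_in[1:3], c("neither", "A", "A"))
  expect_lt(abs(calls$ratio[3] / 8 - 1), 0.15)
})

test_that("homogeneity decreases with planted divergence", {
  hom_at <- function(d, seed) {
    fams <- data.frame(name = "te1", consensus_length = 2000L,
                       copies_a = 20L, copies_b = 0L, divergence = d)
    cfg <- sim_config(seed = seed, te_families = fams,
                      background_length = 1e4, coverage = 50)
    sim <- simulate_te_alignments(cfg)
    compute_homogeneity(sim$aln_a, sim$lib)$homogeneity
  }
  h0 <- hom_at(0, 7)
  h01 <- hom_at(0.01, 7)
  h10 <- hom_at(0.10, 7)
  expect_equal(h0, 1.0)
  expect_gt(h01, h10)
  expect_lt(abs(h01 - (1 - 0.01 * 19 / 20)), 0.02)
  expect_lt(abs(h10 - (1 - 0.10 * 19 / 20)), 0.02)
})
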