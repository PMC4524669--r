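test_that("pseudo-diploid assembly records offsets and survives reordering", {
  sa <- c(s1 = random_seq(1, 1000), s2 = random_seq(1, 1000))
  sb <- c(s1 = random_seq(1, 1000), s2 = random_seq(1, 800))
  pd <- build_pseudodiploid(sa, sb)
  expect_equal(nchar(pd$hap_a), 2000)
  expect_equal(pd$offsets$offset_a, c(0, 1000))
  # back-mapping concatenated coordinates to scaffold coordinates
  bm <- backmap_coords(pd, c(5, 1001, 1500))
  expect_equal(bm$scaffold, c("s1", "s2", "s2"))
  expect_equal(bm$start, c(5, 1, 500))
  # permuted order shifts offsets but back-mapping is invariant
  pd2 <- build_pseudodiploid(sa, sb, order = c("s2", "s1"))
  expect_equal(pd2$offsets$offset_a, c(0, 1000))
  bm2 <- backmap_coords(pd2, 1001 + 4)
  expect_equal(bm2$scaffold, "s1")
  expect_equal(bm2$start, 5)
  expect_error(build_pseudodiploid(sa, sb[1]), "missing")
})

test_that("read origin assignment requires a unique confident placement", {
  recs <- rbind(
    rec("uA", "hapA", 100L, mapq = 60L),
    rec("uB", "hapB", 200L, mapq = 60L),
    rec("shared", "hapA", 300L, mapq = 0L, n_hits = 2L),
    rec("shared", "hapB", 300L, mapq = 0L, n_hits = 2L),
    rec("lowq", "hapA", 400L, mapq = 10L))
  org <- assign_reads(alignment_set(recs, 4, 4), mapq_min = 30L)
  expect_equal(org$origin[org$read_id == "uA"], "A")
  expect_equal(org$origin[org$read_id == "uB"], "B")
  expect_true(all(org$origin[org$read_id == "shared"] == "ambiguous"))
  expect_equal(org$origin[org$read_id == "lowq"], "ambiguous")
})

test_that("ancestry painting recovers planted blocks within two windows", {
  blocks <- data.frame(chr = "chrT", start = c(4e6, 15e6),
                       end = c(6e6, 20e6))  # 2 Mb and 5 Mb
  origins <- simulate_ancestry_origins(blocks, c(chrT = 30e6), seed = 61)
  paint <- paint_ancestry(origins, c(chrT = 30e6))
  het <- paint$spans[paint$spans$state == "het_A", ]
  expect_equal(nrow(het), 2L)
  w <- 10000
  expect_true(all(abs(het$start - blocks$start) <= 2 * w))
  expect_true(all(abs(het$end - blocks$end) <= 2 * w))
})

test_that("pure-recipient and fully heterozygous females paint correctly", {
  none <- data.frame(chr = character(), start = numeric(), end = numeric())
  for (s in c(1, 2, 3)) {
    o <- simulate_ancestry_origins(none, c(chrT = 10e6), seed = s)
    p <- paint_ancestry(o, c(chrT = 10e6))
    expect_equal(sum(p$spans$state == "het_A"), 0L)
  }
  # zero unique reads: all windows no-call, no spans
  empty_origins <- data.frame(read_id = character(), scaffold = character(),
                              start = numeric(), read_length = integer())
  p0 <- paint_ancestry(empty_origins, c(chrT = 1e6))
  expect_true(all(p0$windows$state == "no_call"))
  expect_equal(nrow(p0$spans), 0L)
  # fully heterozygous: one spanning het call per scaffold
  full <- data.frame(chr = c("c1", "c2"), start = 1,
                     end = c(8e6, 5e6))
  of <- simulate_ancestry_origins(full, c(c1 = 8e6, c2 = 5e6), seed = 4)
  pf <- paint_ancestry(of, c(c1 = 8e6, c2 = 5e6))
  het <- pf$spans[pf$spans$state == "het_A", ]
  expect_equal(nrow(het), 2L)
  expect_equal(het$start, c(1, 1))
})

test_that("induction log-odds are calibrated and recover planted effects", {
  # null: CI covers 0 for most chromosomes over seeds
  cover <- 0L; tries <- 40L
  for (s in seq_len(tries)) {
    sim <- simulate_induction_panel(n = 500L, seed = 100 + s)
    fit <- induction_logodds(sim$genotypes, sim$dysgenic)
    row <- fit[fit$term == "`2`" | fit$term == "2", ]
    if (nrow(row) == 0) row <- fit[2, ]
    cover <- cover + (row$ci_lo <= 0 && row$ci_hi >= 0)
  }
  expect_gte(cover / tries, 0.93 - 0.08)  # binomial slack at 40 seeds
  # planted odds ratio 4 on one chromosome recovered within the CI
  hit <- 0L
  for (s in seq_len(40L)) {
    sim <- simulate_induction_panel(
      n = 500L, chr_effects = c(`2` = log(4), `3` = 0, `4` = 0, `5` = 0,
                                `6` = 0), seed = 200 + s)
    fit <- induction_logodds(sim$genotypes, sim$dysgenic)
    row <- fit[2, ]  # first chromosome term
    hit <- hit + (row$ci_lo <= log(4) && row$ci_hi >= log(4))
  }
  expect_gte(hit / 40, 0.9)
  # complete separation is flagged with an infinite interval
  g <- matrix(c(rep(1L, 10), rep(0L, 10)), ncol = 1,
              dimnames = list(NULL, "c1"))
  fit <- induction_logodds(g, c(rep(1L, 10), rep(0L, 10)))
  expect_true(fit$separated[2])
  expect_equal(fit$ci_hi[2], Inf)
})

test_that("QTL scan finds a planted protective locus above the threshold", {
  spec <- f3_panel_spec(n_females = 120L,
                        protective_loci = data.frame(chr = "5",
                                                     pos = 13.5e6,
                                                     effect = -2.5))
  found <- 0L
  for (s in 1:10) {
    panel <- simulate_f3_panel(spec, seed = 300 + s)
    scan <- single_marker_qtl(panel$genotypes,
                              panel$phenotypes$prop_dysgenic,
                              n_perm = 300L, seed = s)
    sig <- scan$stats$marker[scan$stats$significant]
    found <- found + any(grepl("^5:", sig))
  }
  expect_gte(found, 9L)
  # single marker, near-perfect correlation: statistic beats its threshold
  g <- cbind(m1 = rep(0:1, each = 25))
  y <- g[, 1] * 1 + rnorm(50, sd = 0.01)
  one <- single_marker_qtl(g, y, n_perm = 200L, seed = 5)
  expect_true(one$stats$significant[1])
  # monomorphic markers are skipped with a message
  gm <- cbind(g, mono = rep(1L, 50))
  expect_message(sk <- single_marker_qtl(gm, y, n_perm = 50L, seed = 1),
                 "monomorphic")
  expect_equal(sk$skipped, "mono")
})

test_that("permutation threshold grows with marker count on null panels", {
  set.seed(17)
  y <- rnorm(80)
  g_small <- matrix(rbinom(80 * 3, 1, 0.5), 80)
  g_large <- cbind(g_small, matrix(rbinom(80 * 27, 1, 0.5), 80))
  colnames(g_small) <- paste0("m", 1:3)
  colnames(g_large) <- paste0("m", 1:30)
  t_small <- single_marker_qtl(g_small, y, n_perm = 400L, seed = 2)$threshold
  t_large <- single_marker_qtl(g_large, y, n_perm = 400L, seed = 2)$threshold
  expect_gt(t_large, t_small)
})

test_that("candidate elimination reproduces a hand-enumerated survivor set", {
  tes <- paste0("t", 1:10)
  females <- paste0("f", 1:6)
  strain160 <- setNames(c(10, 50, 0.5, 40, 30, 20, 60, 25, 15, 35), tes)
  strain9 <- setNames(c(5, 10, 2, 10, 10, 10, 10, 10, 10, 10), tes)
  # t3: fails qualification (160 < 9). Protective females: f1, f4, f6.
  abund <- matrix(50, 10, 6, dimnames = list(tes, females))
  abund["t1", "f4"] <- 4     # <= baseline 5 in a protective female
  abund["t4", "f1"] <- 10    # equal to baseline: eliminated (boundary)
  abund["t5", "f2"] <- 1     # non-protective female: no effect
  abund["t6", "f6"] <- 8
  abund["t8", "f1"] <- 9
  abund["t9", "f4"] <- 2
  abund["t10", "f6"] <- 0
  protective <- c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE)
  res <- eliminate_candidates(abund, strain160, strain9, protective)
  expect_equal(sort(res$surviving), c("t2", "t5", "t7"))
  expect_equal(res$audit$stage[res$audit$te == "t3"], "qualification")
  expect_equal(res$audit$eliminated_by[res$audit$te == "t4"], "f1")
  # monotone: adding a protective female never enlarges the surviving set
  res2 <- eliminate_candidates(abund, strain160, strain9,
                               protective | c(FALSE, TRUE, rep(FALSE, 4)))
  expect_true(all(res2$surviving %in% res$surviving))
  expect_warning(eliminate_candidates(abund, strain160, strain9,
                                      rep(FALSE, 6)), "no protective")
})
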