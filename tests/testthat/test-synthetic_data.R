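test_that("strain genome simulation plants copies and respects divergence", {
  fams <- data.frame(name = c("teX", "teY"), consensus_length = c(400L, 300L),
                     copies_a = c(8L, 2L), copies_b = c(1L, 2L),
                     divergence = c(0, 0.05))
  cfg <- sim_config(seed = 3, te_families = fams, background_length = 2000L)
  g <- simulate_strain_genomes(cfg)
  expect_equal(nchar(g$genome_a), 2000 + 8 * 400 + 2 * 300)
  expect_equal(g$truth$ratio[1], 8)
  # zero divergence: every planted copy identical to the consensus
  copies_x <- g$layout_a$seq[g$layout_a$family %in% "teX"]
  expect_true(all(copies_x == g$consensi$sequence[1]))
  # d = 0.05: mean copy-consensus identity near 0.95
  copies_y <- c(g$layout_a$seq[g$layout_a$family %in% "teY"],
                g$layout_b$seq[g$layout_b$family %in% "teY"])
  ident <- vapply(copies_y, function(s) {
    mean(strsplit(s, "")[[1]] == strsplit(g$consensi$sequence[2], "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(ident) - 0.95), 0.02)
  # determinism
  g2 <- simulate_strain_genomes(cfg)
  expect_identical(g$genome_a, g2$genome_a)
  expect_identical(g$genome_b, g2$genome_b)
})

test_that("read simulation hits expected counts and is deterministic", {
  set.seed(5)
  genome <- random_seq(1, 100000)
  reads <- simulate_reads(genome, 100L, 10, seed = 9)
  expect_lt(abs(nrow(reads) - 10000), 4 * sqrt(10000))  # Poisson band
  expect_identical(reads, simulate_reads(genome, 100L, 10, seed = 9))
  # degenerate: tiny coverage can yield an empty but valid read set
  tiny <- simulate_reads(random_seq(1, 2000), 100L, 0.001, seed = 1)
  expect_true(nrow(tiny) >= 0)
  expect_error(simulate_reads("ACGT", 100L, 1), "exceeds")
  # emitted reads parse back through FASTQ I/O
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads[1:50, ], fq)
  back <- read_fastq(fq)
  expect_equal(back$sequence, reads$sequence[1:50])
})

test_that("small-RNA simulation plants pair structure and biases", {
  lib <- simulate_repeat_library(n_families = 5L,
                                 length_range = c(3000L, 3000L), seed = 2)
  # f = 1: every piRNA read is a pair member with a partner at 5' distance 9
  sim <- simulate_smallrna(smallrna_spec(n_reads = 400L,
                                         pingpong_fraction = 1),
                           lib, seed = 21)
  recs <- sim$aln$records
  role <- setNames(sim$reads$role, sim$reads$id)[recs$read_id]
  pir <- recs[role %in% c("paired_primary", "secondary"), ]
  p5 <- ifelse(pir$strand == "+", pir$start,
               pir$start + pir$read_length - 1L)
  for (fam in unique(pir$target)) {
    sel <- pir$target == fam
    plus <- sort(p5[sel & pir$strand == "+"])
    minus <- sort(p5[sel & pir$strand == "-"])
    expect_equal(minus, plus + 9L)
  }
  # rounding can leave at most one unpaired read per family
  expect_lt(sum(sim$reads$role == "primary"), 2 * nrow(lib))
  # u1 bias recovery at the planted 0.33
  big <- simulate_smallrna(smallrna_spec(n_reads = 10000L), lib, seed = 22)
  prim <- big$reads[big$reads$role == "primary" & big$reads$length >= 23, ]
  u1 <- mean(substring(prim$sequence, 1, 1) == "T")
  expect_lt(abs(u1 - 0.33), 0.02)
  # determinism
  expect_identical(sim$aln$records,
                   simulate_smallrna(smallrna_spec(n_reads = 400L,
                                                   pingpong_fraction = 1),
                                     lib, seed = 21)$aln$records)
})

test_that("genic read simulation requires known genes and plants densities", {
  lib <- simulate_repeat_library(n_families = 3L, seed = 4)
  genes <- toy_genes(5)
  spec <- smallrna_spec(n_reads = 1000L, mapped_total = 1e6,
                        genic_targets = data.frame(gene_id = "g999",
                                                   density_pm = 10,
                                                   sense_fraction = 1))
  expect_error(simulate_smallrna(spec, lib, genes, seed = 1), "absent")
  spec2 <- smallrna_spec(n_reads = 1000L, mapped_total = 1e6,
                         genic_targets = data.frame(gene_id = "g002",
                                                    density_pm = 12,
                                                    sense_fraction = 0.8))
  sim <- simulate_smallrna(spec2, lib, genes, seed = 1)
  genic <- sim$aln$records[sim$aln$records$target == "scf1", ]
  expect_equal(nrow(genic), 12L)  # 12 per million at a 1e6 denominator
  expect_equal(sim$aln$genome_mapped_total, 1e6)
})

test_that("F3 panel simulation produces backcross genotypes and phenotypes", {
  spec <- f3_panel_spec(n_females = 120L,
                        chr_lengths = c(c1 = 20e6, c2 = 20e6),
                        protective_loci = data.frame(chr = "c1", pos = 10e6,
                                                     effect = -8))
  panel <- simulate_f3_panel(spec, seed = 31)
  expect_equal(dim(panel$genotypes), c(120L, 6L))
  expect_true(all(panel$genotypes %in% 0:1))
  expect_true(all(panel$phenotypes$prop_dysgenic >= 0 &
                    panel$phenotypes$prop_dysgenic <= 1))
  # near-penetrant protective locus: carriers clearly less dysgenic
  carrier <- panel$genotypes[, "c1:10000000"] == 1L
  expect_gt(sum(carrier), 5)
  expect_lt(mean(panel$phenotypes$prop_dysgenic[carrier]),
            mean(panel$phenotypes$prop_dysgenic[!carrier]) - 0.3)
  # determinism of the genotype mosaic
  panel2 <- simulate_f3_panel(spec, seed = 31)
  expect_identical(panel$genotypes, panel2$genotypes)
  # null spec: genotype-phenotype association is at chance (checked via
  # correlation magnitude over a fresh null panel)
  null_panel <- simulate_f3_panel(f3_panel_spec(n_females = 150L),
                                  seed = 32)
  r <- abs(cor(null_panel$genotypes,
               null_panel$phenotypes$prop_dysgenic))
  expect_lt(max(r, na.rm = TRUE), 0.35)
  expect_error(f3_panel_spec(chr_lengths = numeric()), "chromosome")
})

test_that("het blocks from the panel are non-overlapping and within bounds", {
  spec <- f3_panel_spec(n_females = 20L,
                        chr_lengths = c(c1 = 15e6, c2 = 10e6))
  panel <- simulate_f3_panel(spec, seed = 8)
  for (b in panel$blocks) {
    if (!nrow(b)) next
    for (ch in unique(b$chr)) {
      bb <- b[b$chr == ch, ]
      expect_true(all(bb$start <= bb$end))
      expect_true(all(bb$end <= spec$chr_lengths[[ch]]))
      if (nrow(bb) > 1) {
        expect_true(all(bb$start[-1] > bb$end[-nrow(bb)]))
      }
    }
  }
})
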