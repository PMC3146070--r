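test_that("toy genome construction is deterministic and shaped as asked", {
  g <- toy_genome(1, 100000, include_X = TRUE)
  expect_equal(nrow(g), 2)
  expect_equal(genome_size(g), 200000)

  g6 <- toy_genome(5, 1e6, include_X = TRUE)
  expect_equal(nrow(g6), 6)
  expect_equal(sum(g6$is_X), 1)
  expect_equal(g6$chrom[g6$is_X], "chrX")
  expect_equal(g6$chrom[1:2], c("chrI", "chrII"))

  g_noX <- toy_genome(2, 50000, include_X = FALSE)
  expect_false(any(g_noX$is_X))

  expect_error(toy_genome(0, 1e5), "n_autosomes")
  expect_error(toy_genome(2, 500), "chrom_length")
  expect_error(genome_model(c("a", "a"), c(10, 10)), "unique")
  expect_error(genome_model("a", 10, is_X = TRUE), "autosome")
})

test_that("gene annotation honours class proportions, slots and seed", {
  g <- toy_genome(2, 50000, include_X = FALSE)
  all_soma <- annotate_genes(g, 10, class_proportions = c(soma = 1),
                             seed = 4)
  expect_true(all(all_soma$class == "soma"))

  a1 <- annotate_genes(g, 10, seed = 11)
  a2 <- annotate_genes(g, 10, seed = 11)
  expect_identical(a1, a2)
  a3 <- annotate_genes(g, 10, seed = 12)
  expect_false(identical(a1, a3))

  # genes stay within bounds and never overlap under slot placement
  expect_true(all(a1$start >= 0 & a1$end <= 50000))
  by_chr <- split(a1, a1$chrom)
  for (d in by_chr) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }

  # 100 genes at 50/50 proportions: class count inside the central 99%
  # binomial interval (computed from the binomial quantile function)
  g1 <- genome_model("chrI", 1e6)
  ah <- annotate_genes(g1, 100,
                       class_proportions = c(germline = 0.5, soma = 0.5),
                       seed = 1)
  n_germ <- sum(ah$class == "germline")
  expect_gte(n_germ, qbinom(0.005, 100, 0.5))
  expect_lte(n_germ, qbinom(0.995, 100, 0.5))

  expect_error(annotate_genes(g, 200), "slot")
})

test_that("strand-aware TSS/TES accessors follow the 0-based convention", {
  g <- tiny_genome()
  ann <- gene_annotation(data.frame(
    gene_id = c("plus", "minus"), chrom = "chrI", start = c(100, 100),
    end = c(400, 400), strand = c("+", "-")), g)
  expect_equal(unname(tss(ann)), c(100, 399))
  expect_equal(unname(tes(ann)), c(399, 100))
})

test_that("read simulation is deterministic, conserves count, stays in bounds", {
  g <- toy_genome(2, 20000, include_X = TRUE)
  ann <- annotate_genes(g, 5, gene_length_range = c(500, 1500), seed = 2)
  m <- enrichment_model("mes4_maintenance")
  r1 <- simulate_reads(g, ann, m, 500, seed = 9, replicate = 1)
  r2 <- simulate_reads(g, ann, m, 500, seed = 9, replicate = 1)
  expect_identical(r1, r2)
  r3 <- simulate_reads(g, ann, m, 500, seed = 9, replicate = 2)
  expect_false(identical(r1, r3))

  expect_equal(nrow(r1), 500)
  lens <- chrom_lengths(g)[r1$chrom]
  expect_true(all(r1$start >= 0 & r1$end <= lens))
  expect_true(all(r1$end - r1$start <= 36))
  # sorted by (chrom, start)
  expect_true(!is.unsorted(order(match(r1$chrom, g$chrom), r1$start)))
})

test_that("input-mode reads distribute across chromosomes by length", {
  g <- genome_model(c("chrI", "chrII", "chrIII"), c(40000, 20000, 20000))
  r <- simulate_reads(g, NULL, enrichment_model("input"), 2000, seed = 3)
  # marginal per-chromosome counts inside the central 99% binomial band
  share <- (g$length - 35) / sum(g$length - 35)
  counts <- table(factor(r$chrom, g$chrom))
  for (i in 1:3) {
    expect_gte(counts[i], qbinom(0.005, 2000, share[i]))
    expect_lte(counts[i], qbinom(0.995, 2000, share[i]))
  }
})

test_that("input-mode coverage is flat across the genome", {
  L <- 2e5
  g <- genome_model("chrI", L)
  r <- simulate_reads(g, NULL, enrichment_model("input"), 1e5, seed = 21)
  # reads (independent items) spread uniformly: chi-square over 10 windows
  # of valid start positions
  win <- findInterval(r$start, seq(0, L, length.out = 11),
                      rightmost.closed = TRUE)
  navail <- vapply(1:10, function(w) {
    lo <- (w - 1) * L / 10; hi <- w * L / 10
    max(min(hi, L - 35) - lo, 0)
  }, 0)
  p <- chisq.test(tabulate(win, 10), p = navail / sum(navail))$p.value
  expect_gt(p, 0.001)

  # and the resulting per-bp coverage is flat in the interior
  trk <- pileup(extend_reads(r, g), g)
  core <- trk$values$chrI[2001:198000]
  wm <- vapply(split(core, rep(1:10, each = length(core) / 10)), mean, 0)
  expect_lt(max(abs(wm / mean(core) - 1)), 0.05)
})

test_that("zero-weight classes receive no gene-body reads", {
  g <- toy_genome(2, 30000, include_X = FALSE)
  ann <- annotate_genes(g, 8, gene_length_range = c(500, 1500),
                        class_proportions = c(germline = 0.5, soma = 0.5),
                        seed = 6)
  m <- enrichment_model("mes4_maintenance", background_fraction = 0,
                        class_weights = c(germline = 1, soma = 0))
  r <- simulate_reads(g, ann, m, 2000, seed = 8)
  expect_true(all(r$name %in% ann$gene_id[ann$class == "germline"]))
  m_bad <- enrichment_model("mes4_maintenance", background_fraction = 0,
                            class_weights = c(germline = 1, soma = 0))
  soma_only <- ann[ann$class == "soma", ]
  expect_error(simulate_reads(g, gene_annotation(soma_only), m_bad, 10,
                              seed = 1), "zero")
})

test_that("five-prime bias shifts read starts toward the 5' end", {
  g <- genome_model("chrI", 60000)
  ann <- gene_annotation(homogeneous_genes(n = 15, strand = c("+", "-")), g)
  base <- enrichment_model("mes4_maintenance", background_fraction = 0,
                           positional_bias = "uniform", bias_strength = 0,
                           class_weights = c(germline = 1))
  bias <- enrichment_model("mes4_maintenance", background_fraction = 0,
                           positional_bias = "five_prime",
                           bias_strength = 0.8,
                           class_weights = c(germline = 1))
  rel_pos <- function(r) {
    i <- match(r$name, ann$gene_id)
    ifelse(ann$strand[i] == "+",
           (r$start - ann$start[i]) / (ann$end[i] - ann$start[i]),
           (ann$end[i] - 1 - r$start) / (ann$end[i] - ann$start[i]))
  }
  ru <- simulate_reads(g, ann, base, 5000, seed = 13)
  rb <- simulate_reads(g, ann, bias, 5000, seed = 13)
  expect_lt(mean(rel_pos(rb)), 0.5)
  expect_lt(mean(rel_pos(rb)), mean(rel_pos(ru)))
  expect_lt(t.test(rel_pos(ru), rel_pos(rb),
                   alternative = "greater")$p.value, 0.01)
})

test_that("expression tag tables encode class-tissue structure deterministically", {
  g <- toy_genome(2, 50000, include_X = FALSE)
  ann <- annotate_genes(g, 40, gene_length_range = c(500, 1000),
                        class_proportions = c(germline = 1/3, soma = 1/3,
                                              ubiquitous = 1/3), seed = 3)
  tags <- simulate_expression_tags(ann, depth = 10, seed = 5)
  expect_identical(tags, simulate_expression_tags(ann, depth = 10, seed = 5))

  soma_rows <- tags[ann$class == "soma", ]
  expect_true(all(soma_rows$germline == 0))
  germ_rows <- tags[ann$class == "germline", ]
  expect_true(all(germ_rows$muscle == 0 & germ_rows$nerve == 0 &
                    germ_rows$gut == 0))
  # P(Poisson(10) >= 1) = 1 - e^-10 per tissue: nearly all ubiquitous
  # genes are expressed everywhere
  ub <- tags[ann$class == "ubiquitous", ]
  frac <- mean(ub$germline >= 1 & ub$muscle >= 1 & ub$nerve >= 1 &
                 ub$gut >= 1)
  expect_gte(frac, 0.95)

  expect_error(simulate_expression_tags(ann, tissues = c("germline",
    "muscle", "nerve", "gut", "gonad")), "unknown tissue")
  expect_error(simulate_expression_tags(ann, tissues = c("muscle", "nerve",
    "gut")), "must include")
})
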